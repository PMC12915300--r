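test_that("formula parsing handles counts and trailing charges", {
  f <- parse_formula("C6H12O6")
  expect_equal(f$counts[["C"]], 6)
  expect_equal(f$counts[["H"]], 12)
  expect_equal(f$counts[["O"]], 6)
  expect_equal(f$charge, 0)

  g <- parse_formula("C18H33O2-")
  expect_equal(g$charge, -1)
  expect_equal(formula_string(g), "C18H33O2-")
  expect_equal(parse_formula("HCO3-")$charge, -1)
  expect_equal(parse_formula("NH4+")$charge, 1)

  expect_error(parse_formula("C6H12O6++"), class = "sulfidogen_parse_error")
  expect_error(parse_formula("Xx3"), class = "sulfidogen_parse_error")
  expect_error(parse_formula("6CH"), class = "sulfidogen_parse_error")
})

test_that("electron equivalents match full-oxidation bookkeeping", {
  expect_equal(electron_equivalents("C6H12O6"), 24)
  expect_equal(electron_equivalents("CH4"), 8)
  expect_equal(electron_equivalents("CO2"), 0)
  expect_equal(electron_equivalents("C3H8O3"), 14)
  expect_equal(electron_equivalents("C18H33O2-"), 102)
  expect_equal(electron_equivalents("C2H5NO2"), 6)
  expect_error(electron_equivalents("SO42-"),
               class = "sulfidogen_unsupported_species_error")
})

test_that("sulfate coupling reproduces the published stoichiometries", {
  tbl <- reaction_table()
  # R2 is printed unbalanced; every other row must match exactly
  for (i in which(tbl$label != "R2")) {
    row <- tbl[i, ]
    r <- balance_sulfate_coupling(row$formula, label = row$label)
    expect_equal(unname(-r$species[["SO4^2-"]]), row$coef_so4, info = row$label)
    expect_equal(unname(-r$species[["H+"]]), row$coef_h, info = row$label)
    expect_equal(unname(r$species[["CO2(g)"]]), row$coef_co2, info = row$label)
    expect_equal(unname(r$species[["H2S(aq)"]]), row$coef_h2s, info = row$label)
    expect_equal(unname(r$species[["H2O"]]), row$coef_h2o, info = row$label)
    nh4 <- if ("NH4+" %in% names(r$species)) unname(r$species[["NH4+"]]) else 0
    expect_equal(nh4, row$coef_nh4, info = row$label)
  }
  # conservation forces one ammonium per substrate nitrogen for C3H7NO2
  r2 <- balance_sulfate_coupling("C3H7NO2")
  expect_equal(unname(r2$species[["NH4+"]]), 1)
  expect_equal(unname(r2$species[["H2O"]]), 2)
  expect_equal(unname(-r2$species[["SO4^2-"]]), 1.5)
  expect_equal(unname(-r2$species[["H+"]]), 4)
})

test_that("balanced reactions conserve every element and charge (randomised)", {
  set.seed(99)
  for (i in 1:1000) {
    f <- random_chon_formula()
    r <- balance_sulfate_coupling(f)
    expect_true(isTRUE(is_balanced(r)), info = formula_string(f))
  }
})

test_that("the printed R2 row is flagged unbalanced, all other rows balanced", {
  tb <- recompute_reaction_energies()
  expect_false(tb$balanced[tb$label == "R2"])
  expect_true(all(tb$balanced[tb$label != "R2"]))
})

test_that("theoretical oxygen demand follows the electron balance", {
  expect_equal(theoretical_oxygen_demand("C6H12O6", 2.5), 480)
  expect_equal(theoretical_oxygen_demand("C3H8O3", 5), 560)
  expect_equal(theoretical_oxygen_demand("C6H12O6", 0), 0)
  # per-mole ThOD ratio glycerol:glucose is 14:24 at any concentration
  expect_equal(theoretical_oxygen_demand("C3H8O3", 3) /
                 theoretical_oxygen_demand("C6H12O6", 3), 14 / 24)
})

test_that("sulfide-per-COD ceiling is 15.625 uM per mg/L", {
  expect_equal(max_sulfide_per_cod(), 15.625)
  expect_equal(max_sulfide_per_cod() * 494, 7718.75)
})

test_that("standard reaction energy from the formation table", {
  r <- balance_sulfate_coupling("C6H12O6")
  dg <- delta_g_standard(r)
  expect_equal(dg$per_carbon_kj_mol, -121, tolerance = 0.02)
  expect_equal(dg$total_kj_mol, 6 * dg$per_carbon_kj_mol)
  # antisymmetry: reversing the reaction negates the energy
  rev <- reaction(-r$species, r$carbon_count)
  expect_equal(delta_g_standard(rev)$total_kj_mol, -dg$total_kj_mol)
  # empty reaction has zero energy
  expect_equal(delta_g_standard(
    reaction(c("H2O" = 0), carbon_count = 1))$total_kj_mol, 0)
  expect_error(delta_g_standard(reaction(c("CH4" = 1), 1)),
               "CH4", class = "sulfidogen_lookup_error")
})

test_that("reaction quotient: hand-computed glucose value, neutrality, additivity", {
  r <- balance_sulfate_coupling("C6H12O6")
  cond <- lake_conditions()
  # independent term-by-term evaluation
  by_hand <- 3 * log(1e-6) + 6 * log(0.05) -
    (log(2.5e-3) + 3 * log(0.14) + 6 * log(10^-4.2))
  expect_equal(reaction_quotient_ln(r, cond), by_hand)
  expect_equal(reaction_quotient_ln(r, cond), 10.494, tolerance = 1e-4)

  unit <- thermo_conditions(291, 0, setNames(
    rep(1, 5), c("C6H12O6", "SO4^2-", "CO2(g)", "H2S(aq)", "NH4+")))
  expect_equal(reaction_quotient_ln(r, unit), 0)

  doubled <- cond
  doubled$activities[["H2S(aq)"]] <- 2e-6
  expect_equal(reaction_quotient_ln(r, doubled) - reaction_quotient_ln(r, cond),
               3 * log(2))
  expect_error(reaction_quotient_ln(r, thermo_conditions(291, 4.2, c(X = 1))),
               class = "sulfidogen_lookup_error")
})

test_that("condition-adjusted energies match the published column within 3 kJ/mol C", {
  tb <- recompute_reaction_energies()
  expect_true(all(abs(tb$dgprime_per_c_recomputed - tb$dgprime_per_c_printed) < 3))
  # spot values from direct evaluation
  r3 <- tb[tb$label == "R3", ]
  expect_equal(r3$dgprime_per_c_recomputed, -116.77, tolerance = 1e-3)
  r1 <- tb[tb$label == "R1", ]
  expect_equal(r1$dgprime_per_c_recomputed, -154.07, tolerance = 1e-3)
})

test_that("quotient term vanishes at unit activities (dGr' = dGr0)", {
  r <- balance_sulfate_coupling("C6H12O6")
  unit <- thermo_conditions(291, 0, setNames(
    rep(1, 5), c("C6H12O6", "SO4^2-", "CO2(g)", "H2S(aq)", "NH4+")))
  expect_equal(delta_g_prime_per_carbon(r, unit, -121), -121)
  expect_error(delta_g_prime_per_carbon(
    reaction(c("H2O" = 1), carbon_count = 0), lake_conditions(), -1),
    class = "sulfidogen_domain_error")
})
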