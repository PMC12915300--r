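# Substrate-oxidation/sulfate-reduction thermodynamics.
#
# Complete oxidation of a C/H/O/N substrate coupled to sulfate reduction:
#   substrate + (e/8) SO4^2- + h H+ -> nC CO2 + (e/8) H2S + nN NH4+ + w H2O
# where e is the number of electrons released on full oxidation to CO2,
# NH4+ and H2O (degree-of-reduction bookkeeping), and h, w close the
# hydrogen and charge balances. All coefficients are multiples of 1/8, so
# balance checks are done exactly on 8x-scaled integer coefficients.

.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Ti", "V", "Cr", "Mn", "Fe", "Co",
  "Ni", "Cu", "Zn", "As", "Se", "Br", "Mo", "Ag", "Cd", "Sn", "Sb", "I",
  "Ba", "W", "Au", "Hg", "Pb", "U")

#' Parse an element-count formula with optional trailing charge
#'
#' Accepts strings such as `"C6H12O6"`, `"C18H33O2-"` or `"NH4+"`. The
#' charge suffix is a single sign, or a caret-prefixed magnitude and sign
#' (`"^2-"`) for multivalent ions; without the caret, trailing digits bind
#' to the preceding element, so `"SO4^2-"` is sulfate while `"SO42-"` is
#' read as 42 oxygens with a single negative charge.
#'
#' @param text Formula string.
#' @return An `elemental_formula`: list of integer element `counts` and
#'   integer `charge`.
#' @export
#' @examples
#' parse_formula("C18H33O2-")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("\\s", "", text)
  m <- regmatches(s, regexec("^((?:[A-Z][a-z]?[0-9]*)+)(\\^?[0-9]*[+-])?$", s))[[1]]
  if (length(m) == 0 || m[2] == "") {
    stop_sulfidogen(sprintf("malformed formula: '%s'", text),
                    "sulfidogen_parse_error")
  }
  tokens <- regmatches(m[2], gregexpr("[A-Z][a-z]?|[0-9]+", m[2]))[[1]]
  counts <- integer(0)
  i <- 1
  while (i <= length(tokens)) {
    el <- tokens[i]
    if (!el %in% .known_elements) {
      stop_sulfidogen(sprintf("unknown element symbol '%s' in '%s'", el, text),
                      "sulfidogen_parse_error")
    }
    n <- 1L
    if (i + 1 <= length(tokens) && grepl("^[0-9]+$", tokens[i + 1])) {
      n <- as.integer(tokens[i + 1]); i <- i + 1
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
    i <- i + 1
  }
  charge <- 0L
  if (!is.na(m[3]) && m[3] != "") {
    sign <- if (endsWith(m[3], "+")) 1L else -1L
    mag <- sub("[+-]$", "", sub("^\\^", "", m[3]))
    charge <- sign * (if (mag == "") 1L else as.integer(mag))
  }
  structure(list(counts = counts, charge = charge), class = "elemental_formula")
}

#' Canonical string form of an elemental formula
#'
#' @param f An `elemental_formula` (or a string, passed through parsing).
#' @return A single string, e.g. `"C6H12O6"` or `"C18H33O2-"`.
#' @export
formula_string <- function(f) {
  f <- as_formula(f)
  body <- paste0(names(f$counts),
                 ifelse(f$counts == 1, "", f$counts), collapse = "")
  q <- f$charge
  suffix <- if (q == 0) "" else if (abs(q) == 1) {
    if (q > 0) "+" else "-"
  } else {
    paste0("^", abs(q), if (q > 0) "+" else "-")  # unambiguous round trip
  }
  paste0(body, suffix)
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) f else parse_formula(f)
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(sprintf("<formula> %s\n", formula_string(x)))
  invisible(x)
}

count_of <- function(f, el) if (el %in% names(f$counts)) f$counts[[el]] else 0L

#' Electron equivalents released on complete oxidation
#'
#' Number of electrons a C/H/O/N species releases when fully oxidised to
#' CO2, NH4+ and H2O: `4C + H - 2O - 3N - charge`. This is the
#' degree-of-reduction count that fixes the sulfate coefficient (8 electrons
#' per sulfate reduced to sulfide) and the theoretical oxygen demand
#' (4 electrons per O2).
#'
#' @param f An `elemental_formula` or formula string.
#' @return Integer electron count.
#' @export
#' @examples
#' electron_equivalents("C6H12O6")  # 24
electron_equivalents <- function(f) {
  f <- as_formula(f)
  if (!all(names(f$counts) %in% c("C", "H", "O", "N"))) {
    stop_sulfidogen(
      sprintf("unsupported species for oxidation bookkeeping: %s",
              formula_string(f)),
      "sulfidogen_unsupported_species_error")
  }
  x <- count_of(f, "C"); y <- count_of(f, "H")
  z <- count_of(f, "O"); n <- count_of(f, "N")
  e <- 4L * x + y - 2L * z - 3L * n - f$charge
  # internal half-reaction verification:
  #   f + (2C - O) H2O -> C CO2 + N NH4+ + h H+ + e e-
  h <- y + 4L * x - 2L * z - 4L * n
  stopifnot(y + 2L * (2L * x - z) == 4L * n + h,       # hydrogen closes
            f$charge == n + h - e)                     # charge closes
  if (e < 0) {
    stop_sulfidogen(
      sprintf("%s is oxidised beyond the CO2/NH4+/H2O reference state",
              formula_string(f)),
      "sulfidogen_unsupported_species_error")
  }
  e
}

.fixed_species <- list(
  "SO4^2-"  = list(counts = c(S = 1L, O = 4L), charge = -2L),
  "H+"      = list(counts = c(H = 1L), charge = 1L),
  "CO2(g)"  = list(counts = c(C = 1L, O = 2L), charge = 0L),
  "H2S(aq)" = list(counts = c(H = 2L, S = 1L), charge = 0L),
  "NH4+"    = list(counts = c(N = 1L, H = 4L), charge = 1L),
  "H2O"     = list(counts = c(H = 2L, O = 1L), charge = 0L))

species_formula <- function(name) {
  if (name %in% names(.fixed_species)) {
    structure(.fixed_species[[name]], class = "elemental_formula")
  } else {
    parse_formula(name)
  }
}

#' Construct a reaction from signed stoichiometric coefficients
#'
#' @param species Named numeric vector of coefficients, reactants negative.
#' @param carbon_count Carbons in the substrate (per-carbon normalisation).
#' @param label Optional reaction label.
#' @return An object of class `srr_reaction`.
#' @export
reaction <- function(species, carbon_count, label = NULL) {
  stopifnot(is.numeric(species), !is.null(names(species)))
  structure(list(species = species[species != 0],
                 carbon_count = carbon_count, label = label),
            class = "srr_reaction")
}

#' @export
print.srr_reaction <- function(x, ...) {
  side <- function(sgn) paste(
    sprintf("%s%s",
            ifelse(abs(x$species[sgn(x$species)]) == 1, "",
                   paste0(format(abs(x$species[sgn(x$species)])), " ")),
            names(x$species[sgn(x$species)])), collapse = " + ")
  cat(sprintf("<reaction%s> %s == %s\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              side(function(v) v < 0), side(function(v) v > 0)))
  invisible(x)
}

#' Element and charge balance of a reaction
#'
#' All coefficients in sulfate-coupled oxidations are multiples of 1/8, so
#' the check scales them by 8, verifies integrality, and then requires each
#' element sum and the charge sum to be exactly zero.
#'
#' @param r An `srr_reaction`.
#' @return `TRUE`/`FALSE`, with attribute `imbalance` naming any deficit.
#' @export
is_balanced <- function(r) {
  stopifnot(inherits(r, "srr_reaction"))
  coef8 <- r$species * 8
  if (any(abs(coef8 - round(coef8)) > 1e-9)) {
    return(structure(FALSE, imbalance = "non-octal coefficient"))
  }
  coef8 <- round(coef8)
  sums <- c(charge = 0)
  for (i in seq_along(r$species)) {
    f <- species_formula(names(r$species)[i])
    for (el in names(f$counts)) {
      sums[el] <- (if (el %in% names(sums)) sums[[el]] else 0) +
        coef8[i] * f$counts[[el]]
    }
    sums["charge"] <- sums[["charge"]] + coef8[i] * f$charge
  }
  bad <- names(sums)[sums != 0]
  structure(length(bad) == 0,
            imbalance = if (length(bad)) paste(bad, collapse = ", ") else NULL)
}

#' Balance a substrate oxidation coupled to sulfate reduction
#'
#' Builds the stoichiometry for complete oxidation of a C/H/O/N substrate
#' with sulfate as the electron acceptor: the sulfate (and sulfide)
#' coefficient is `electron_equivalents/8`, each substrate N leaves as
#' NH4+, carbon as CO2, and the H+ and H2O coefficients close the hydrogen
#' and charge balances. The result always passes [is_balanced()].
#'
#' @param substrate An `elemental_formula` or formula string; the substrate
#'   coefficient is fixed at −1.
#' @param label Optional reaction label.
#' @return A balanced `srr_reaction`.
#' @export
#' @examples
#' balance_sulfate_coupling("C6H12O6")
balance_sulfate_coupling <- function(substrate, label = NULL) {
  f <- as_formula(substrate)
  if (any(f$counts != round(f$counts))) {
    stop_sulfidogen("atom counts must be integers", "sulfidogen_domain_error")
  }
  e <- electron_equivalents(f)
  x <- count_of(f, "C"); y <- count_of(f, "H")
  z <- count_of(f, "O"); n <- count_of(f, "N")
  w <- z + e / 2 - 2 * x
  h <- e / 4 + 4 * n + 2 * w - y
  coefs <- c(-1, -e / 8, -h, x, e / 8, n, w)
  names(coefs) <- c(formula_string(f), "SO4^2-", "H+", "CO2(g)", "H2S(aq)",
                    "NH4+", "H2O")
  r <- reaction(coefs, carbon_count = x, label = label)
  stopifnot(isTRUE(is_balanced(r)))
  r
}

#' Theoretical oxygen demand of a substrate solution
#'
#' Stoichiometric oxygen required for complete mineralisation:
#' `conc × electrons/4 × 32` in mg O2/L (4 electrons per O2, 32 g/mol).
#'
#' @param substrate An `elemental_formula` or formula string.
#' @param conc_mM Substrate concentration (mM), non-negative.
#' @return ThOD in mg O2/L.
#' @export
#' @examples
#' theoretical_oxygen_demand("C6H12O6", 2.5)  # 480 mg/L
theoretical_oxygen_demand <- function(substrate, conc_mM) {
  if (any(conc_mM < 0)) {
    stop_sulfidogen("concentration must be non-negative", "sulfidogen_domain_error")
  }
  conc_mM * electron_equivalents(substrate) / 4 * 32
}

#' Theoretical maximum sulfide production per unit COD
#'
#' One mg of O2-equivalent reducing power carries 1/32 mmol O2 × 4
#' electrons; 8 electrons reduce one sulfate to sulfide, giving
#' 15.625 µmol sulfide per mg O2 — i.e. 15.625 µM per mg L⁻¹ COD,
#' returned unrounded.
#'
#' @return Ceiling in µM sulfide per mg L⁻¹ COD.
#' @export
max_sulfide_per_cod <- function() {
  1000 / 32 * 4 / 8
}

#' Thermodynamic evaluation conditions
#'
#' Temperature, pH and the activity map used for reaction quotients. By
#' default the deep-layer lake conditions are loaded from the shipped
#' conditions fixture: T = 291 K, pH 4.2, {CO2(g)} = 0.05 atm,
#' {SO4^2-} = 0.14 M, {NH4+} = 0.01 M, {H2S(aq)} = 1e-6 M, plus the initial
#' substrate molarities. Activities are taken equal to concentrations
#' (partial pressure for gaseous CO2); water activity is fixed at 1.
#'
#' @param T_K Temperature in kelvin.
#' @param pH Solution pH (sets the H+ activity).
#' @param activities Named numeric vector of species activities.
#' @return An object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(T_K, pH, activities) {
  stopifnot(T_K > 0, is.numeric(activities), !is.null(names(activities)))
  if (any(activities <= 0)) {
    stop_sulfidogen("activities must be positive", "sulfidogen_domain_error")
  }
  structure(list(T_K = T_K, pH = pH, activities = activities),
            class = "thermo_conditions")
}

#' @rdname thermo_conditions
#' @export
lake_conditions <- function() {
  df <- readr::read_csv(fixture_path("conditions.csv"), show_col_types = FALSE,
                        progress = FALSE)
  acts <- setNames(df$value[df$kind == "activity"],
                   df$quantity[df$kind == "activity"])
  thermo_conditions(T_K = df$value[df$quantity == "temperature"],
                    pH = df$value[df$quantity == "pH"],
                    activities = acts)
}

activity_of <- function(cond, name) {
  if (name == "H2O") return(1)
  if (name == "H+") return(10^(-cond$pH))
  if (!name %in% names(cond$activities)) {
    stop_sulfidogen(sprintf("no activity supplied for species %s", name),
                    "sulfidogen_lookup_error")
  }
  cond$activities[[name]]
}

#' Natural log of the reaction quotient
#'
#' `ln Q = sum(coefficient × ln activity)` with H+ taken from the pH and
#' water activity fixed at 1.
#'
#' @param r An `srr_reaction`.
#' @param cond A [thermo_conditions].
#' @return Dimensionless ln Q.
#' @export
reaction_quotient_ln <- function(r, cond) {
  stopifnot(inherits(r, "srr_reaction"), inherits(cond, "thermo_conditions"))
  sum(vapply(seq_along(r$species), function(i) {
    r$species[[i]] * log(activity_of(cond, names(r$species)[i]))
  }, numeric(1)))
}

#' Standard Gibbs free energy table
#'
#' Standard Gibbs free energies of formation (kJ/mol, 298 K) for the
#' species used by the shipped reactions, with a provenance tag per entry.
#' Long-chain fatty-acid anions and amino acids carry group-additivity
#' estimates (tagged `estimate`); condition-adjusted energies in the
#' recomputed reaction table therefore start from the tabulated standard
#' reaction values rather than this table.
#'
#' @return A named numeric vector of ΔGf° with a `provenance` attribute.
#' @export
formation_energy_table <- function() {
  df <- readr::read_csv(fixture_path("formation_energies.csv"),
                        show_col_types = FALSE, progress = FALSE)
  structure(setNames(df$dgf_kj_mol, df$species),
            provenance = setNames(df$provenance, df$species))
}

#' Standard Gibbs free energy of reaction
#'
#' `ΔGr° = sum(coefficient × ΔGf°)`, total and per mole of substrate carbon.
#'
#' @param r An `srr_reaction`.
#' @param table Named vector of formation energies (kJ/mol), default
#'   [formation_energy_table()].
#' @return List with `total_kj_mol` and `per_carbon_kj_mol`.
#' @export
delta_g_standard <- function(r, table = formation_energy_table()) {
  stopifnot(inherits(r, "srr_reaction"))
  missing <- setdiff(names(r$species), names(table))
  if (length(missing)) {
    stop_sulfidogen(sprintf("no formation energy for species: %s",
                            paste(missing, collapse = ", ")),
                    "sulfidogen_lookup_error")
  }
  total <- sum(r$species * table[names(r$species)])
  list(total_kj_mol = total,
       per_carbon_kj_mol = if (r$carbon_count > 0) total / r$carbon_count
       else NA_real_)
}

#' Condition-adjusted Gibbs free energy per mole of carbon
#'
#' `ΔGr' = ΔGr° + R·T·lnQ / (1000 × nC)` with R = 8.314 J/(mol·K) and T
#' from the conditions. The standard per-carbon value is supplied
#' explicitly so tabulated values can be used directly; no van 't Hoff
#' temperature correction is applied between 298 K and the evaluation
#' temperature.
#'
#' @param r An `srr_reaction`.
#' @param cond A [thermo_conditions].
#' @param dg0_per_c Standard Gibbs free energy of reaction per mole of
#'   substrate carbon (kJ/mol C).
#' @return ΔGr' in kJ/mol C.
#' @export
delta_g_prime_per_carbon <- function(r, cond, dg0_per_c) {
  if (is.null(r$carbon_count) || r$carbon_count <= 0) {
    stop_sulfidogen("reaction has no substrate carbon to normalise by",
                    "sulfidogen_domain_error")
  }
  dg0_per_c + 8.314 * cond$T_K * reaction_quotient_ln(r, cond) /
    (1000 * r$carbon_count)
}

#' Published reaction table
#'
#' The seven substrate-oxidation/sulfate-reduction reactions as tabulated
#' in the source study, with their printed stoichiometric coefficients and
#' printed ΔGr° / ΔGr' per-carbon values. Formulas are stored as printed;
#' note the known label/formula swaps (alanine/glycine and
#' palmitate/oleate rows) and that the R2 row as printed is not
#' element-balanced.
#'
#' @return A tibble, one row per reaction.
#' @export
reaction_table <- function() {
  readr::read_csv(fixture_path("reactions.csv"), show_col_types = FALSE,
                  progress = FALSE)
}

printed_reaction <- function(row) {
  coefs <- c(-1, -row$coef_so4, -row$coef_h, row$coef_co2, row$coef_h2s,
             row$coef_nh4, row$coef_h2o)
  names(coefs) <- c(row$formula, "SO4^2-", "H+", "CO2(g)", "H2S(aq)",
                    "NH4+", "H2O")
  reaction(coefs, carbon_count = count_of(parse_formula(row$formula), "C"),
           label = row$label)
}

#' Recompute the reaction energy table at lake conditions
#'
#' For every published reaction: rebuilds the printed stoichiometry,
#' flags whether it is element/charge balanced, evaluates ln Q at the
#' supplied conditions, and adds the reaction-quotient term to the printed
#' standard per-carbon energy to recompute ΔGr'. Where the formation-energy
#' table covers all species, ΔGr° recomputed from formation energies is
#' reported alongside.
#'
#' @param cond A [thermo_conditions], default [lake_conditions()].
#' @return A tibble with printed and recomputed columns.
#' @export
recompute_reaction_energies <- function(cond = lake_conditions()) {
  tbl <- reaction_table()
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    row <- tbl[i, ]
    r <- printed_reaction(row)
    dg0_table <- tryCatch(delta_g_standard(r)$per_carbon_kj_mol,
                          error = function(e) NA_real_)
    tibble::tibble(
      label = row$label, substrate = row$substrate, formula = row$formula,
      balanced = isTRUE(is_balanced(r)),
      ln_q = reaction_quotient_ln(r, cond),
      dg0_per_c_printed = row$dg0_per_c_kj,
      dg0_per_c_from_table = dg0_table,
      dgprime_per_c_printed = row$dgprime_per_c_kj,
      dgprime_per_c_recomputed =
        delta_g_prime_per_carbon(r, cond, row$dg0_per_c_kj))
  })
  dplyr::bind_rows(rows)
}
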