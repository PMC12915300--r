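# Seeded generator of synthetic microcosm studies. Each replicate draws
# (lag, rate, plateau) from truncated-at-zero Gaussians and follows a
# piecewise-linear lag -> zero-order rise -> plateau sulfide curve — the
# same functional form the kinetics module fits, so noiseless recovery is
# exact. Metals deplete stoichiometrically from cumulative noiseless
# sulfide in a fixed precipitation order, pH interpolates from the acidic
# start toward a treatment ceiling with the cumulative sulfide fraction,
# and stylised VFA pulses (early acetate, mid-incubation butyrate)
# accompany production.

#' Treatment-level generative model
#'
#' @param name Treatment label.
#' @param lag_d,lag_sd Lag time mean and replicate-level sd (days).
#' @param rate_uM_d,rate_sd Zero-order production rate mean and sd (µM/d).
#' @param max_uM,max_sd Plateau (maximum sulfide) mean and sd (µM).
#' @param times Sampling schedule (days, strictly increasing).
#' @param n_replicates Replicate bottles per treatment.
#' @param producing_fraction Probability a replicate produces sulfide at
#'   all (models replicate failure, e.g. one-of-four with oleate).
#' @param noise_sd Additive Gaussian measurement noise sd (µM), clipped so
#'   concentrations stay non-negative; default 10 µM, the order of the
#'   colorimetric-assay scatter implied by replicate spreads.
#' @param cod_dose,mass_dose Dose metadata carried into summaries.
#' @param ph_start Initial pH (default 4.2).
#' @param ph_max,ph_max_sd Final-pH ceiling mean and replicate sd.
#' @return An object of class `treatment_model`.
#' @export
treatment_model <- function(name, lag_d, lag_sd, rate_uM_d, rate_sd,
                            max_uM, max_sd, times, n_replicates = 4,
                            producing_fraction = 1, noise_sd = 10,
                            cod_dose = NA_real_, mass_dose = NA_real_,
                            ph_start = 4.2, ph_max = NA_real_,
                            ph_max_sd = 0) {
  if (any(c(lag_d, rate_uM_d, max_uM) < 0) ||
      any(c(lag_sd, rate_sd, max_sd, noise_sd, ph_max_sd) < 0)) {
    stop_sulfidogen("model means and sds must be non-negative",
                    "sulfidogen_domain_error")
  }
  if (producing_fraction < 0 || producing_fraction > 1) {
    stop_sulfidogen("producing fraction must lie in [0, 1]",
                    "sulfidogen_domain_error")
  }
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop_sulfidogen("times must be strictly increasing", "sulfidogen_domain_error")
  }
  structure(list(name = name, lag_d = lag_d, lag_sd = lag_sd,
                 rate_uM_d = rate_uM_d, rate_sd = rate_sd, max_uM = max_uM,
                 max_sd = max_sd, times = times, n_replicates = n_replicates,
                 producing_fraction = producing_fraction, noise_sd = noise_sd,
                 cod_dose = cod_dose, mass_dose = mass_dose,
                 ph_start = ph_start, ph_max = ph_max, ph_max_sd = ph_max_sd),
            class = "treatment_model")
}

#' Geochemical coupling model for synthetic series
#'
#' @param metals_mM Initial dissolved metal concentrations (mM); defaults
#'   to the deep-layer inventory 12 Fe, 0.2 Zn, 0.006 As.
#' @param stoichiometry mol S(-II) consumed per mol metal precipitated.
#' @param order Precipitation order (first listed precipitates first);
#'   default As before Zn before Fe, reflecting faster arsenic-sulfide
#'   precipitation kinetics.
#' @param acetate_peak_mM,acetate_final_mM Stylised acetate pulse: linear
#'   rise from the lag to a mid-production peak, then linear decay to the
#'   final value at the last sample.
#' @param butyrate_mM,butyrate_rise_d Stylised butyrate onset at the
#'   plateau, rising linearly over `butyrate_rise_d` days and persisting.
#' @param include_vfa,include_metals,include_ph Toggle the co-trajectories.
#' @return An object of class `coupling_model`.
#' @export
coupling_model <- function(metals_mM = c(Fe = 12, Zn = 0.2, As = 0.006),
                           stoichiometry = c(As = 1.5, Zn = 1, Fe = 1),
                           order = c("As", "Zn", "Fe"),
                           acetate_peak_mM = 1.0, acetate_final_mM = 0.1,
                           butyrate_mM = 0.2, butyrate_rise_d = 5,
                           include_vfa = TRUE, include_metals = TRUE,
                           include_ph = TRUE) {
  if (any(metals_mM < 0)) {
    stop_sulfidogen("metal concentrations must be non-negative",
                    "sulfidogen_domain_error")
  }
  if (!all(order %in% names(metals_mM)) || !all(order %in% names(stoichiometry))) {
    stop_sulfidogen("every metal in `order` needs a concentration and stoichiometry",
                    "sulfidogen_domain_error")
  }
  structure(list(metals_mM = metals_mM, stoichiometry = stoichiometry,
                 order = order, acetate_peak_mM = acetate_peak_mM,
                 acetate_final_mM = acetate_final_mM,
                 butyrate_mM = butyrate_mM, butyrate_rise_d = butyrate_rise_d,
                 include_vfa = include_vfa, include_metals = include_metals,
                 include_ph = include_ph),
            class = "coupling_model")
}

rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  v <- rnorm(n, mean, sd)
  while (any(v < 0)) v[v < 0] <- rnorm(sum(v < 0), mean, sd)
  v
}

deplete_metals <- function(sulfide_mM, coupling) {
  out <- list()
  consumed_before <- 0
  for (metal in coupling$order) {
    m0 <- coupling$metals_mM[[metal]]
    stoich <- coupling$stoichiometry[[metal]]
    demand <- m0 * stoich
    available <- pmax(sulfide_mM - consumed_before, 0)
    removed <- pmin(available, demand) / stoich
    out[[metal]] <- pmax(m0 - removed, 0)  # guard FP dust at exact depletion
    consumed_before <- consumed_before + demand
  }
  out
}

#' Generate one synthetic replicate series
#'
#' Deterministic given the seed. Replicate parameters (lag L, rate k,
#' plateau Smax) are drawn from truncated-at-zero Gaussians; the noiseless
#' sulfide curve is `clamp(k (t - L), 0, Smax)`; Gaussian measurement noise
#' is added and clipped at zero. Metals, pH and VFAs derive from the
#' noiseless curve (the generating mechanism, not the noisy assay).
#'
#' @param model A [treatment_model].
#' @param coupling A [coupling_model].
#' @param seed Integer seed for this replicate.
#' @param replicate Replicate label.
#' @return A [microcosm_series].
#' @export
generate_replicate <- function(model, coupling = coupling_model(), seed,
                               replicate = "r1") {
  stopifnot(inherits(model, "treatment_model"),
            inherits(coupling, "coupling_model"))
  set.seed(seed)
  t <- model$times
  produces <- runif(1) < model$producing_fraction
  L <- rnorm_trunc0(1, model$lag_d, model$lag_sd)
  k <- rnorm_trunc0(1, model$rate_uM_d, model$rate_sd)
  smax <- rnorm_trunc0(1, model$max_uM, model$max_sd)
  s_true <- if (produces) pmin(pmax(k * (t - L), 0), smax) else rep(0, length(t))
  s_obs <- pmax(s_true + rnorm(length(t), 0, model$noise_sd), 0)

  metals <- NULL
  if (coupling$include_metals) metals <- deplete_metals(s_true / 1000, coupling)

  ph <- NULL
  if (coupling$include_ph && !is.na(model$ph_max)) {
    ceiling_ph <- max(rnorm(1, model$ph_max, model$ph_max_sd), model$ph_start)
    frac <- if (produces && smax > 0) s_true / smax else rep(0, length(t))
    ph <- model$ph_start + (ceiling_ph - model$ph_start) * frac
  }

  vfa <- NULL
  if (coupling$include_vfa && produces &&
      (coupling$acetate_peak_mM > 0 || coupling$butyrate_mM > 0)) {
    t_plateau <- L + smax / max(k, 1e-12)
    t_end <- max(t)
    t_mid <- (L + min(t_plateau, t_end)) / 2
    acet <- numeric(length(t))
    up <- t > L & t <= t_mid
    acet[up] <- coupling$acetate_peak_mM * (t[up] - L) / max(t_mid - L, 1e-12)
    down <- t > t_mid
    acet[down] <- coupling$acetate_peak_mM +
      (coupling$acetate_final_mM - coupling$acetate_peak_mM) *
      (t[down] - t_mid) / max(t_end - t_mid, 1e-12)
    but <- pmin(pmax(t - t_plateau, 0) / coupling$butyrate_rise_d, 1) *
      coupling$butyrate_mM
    vfa <- list(acetate = pmax(acet, 0), butyrate = but)
  }

  microcosm_series(model$name, replicate, times = t, sulfide = s_obs,
                   vfa = vfa, metals = metals, ph = ph)
}

#' Generate a multi-treatment synthetic study
#'
#' Per-replicate seeds are derived reproducibly from the master seed, so
#' the same seed regenerates a byte-identical dataset.
#'
#' @param models List of [treatment_model] objects (unique names).
#' @param coupling A [coupling_model] shared by all treatments.
#' @param seed Master integer seed.
#' @param path Optional CSV output path (interchange schema).
#' @return Named list of [microcosm_series] (invisibly when writing).
#' @export
generate_study <- function(models, coupling = coupling_model(), seed,
                           path = NULL) {
  if (inherits(models, "treatment_model")) models <- list(models)
  nms <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(nms)) {
    stop_sulfidogen("duplicate treatment names", "sulfidogen_validation_error")
  }
  n_total <- sum(vapply(models, function(m) m$n_replicates, numeric(1)))
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_total)
  out <- list()
  i <- 0
  for (m in models) {
    for (r in seq_len(m$n_replicates)) {
      i <- i + 1
      s <- generate_replicate(m, coupling, seed = seeds[i],
                              replicate = paste0("r", r))
      out[[series_key(s)]] <- s
    }
  }
  if (!is.null(path)) {
    write_timeseries(out, path)
    return(invisible(out))
  }
  out
}

#' Calibrated treatment presets for the reference microcosm study
#'
#' Nine treatment models whose lag/rate/maximum parameters encode the
#' published treatment summaries (means ± sd where printed; range endpoints
#' and efficiency-derived maxima otherwise — see the substrates fixture
#' for dose provenance). Sampling schedules are treatment-specific, denser
#' around the expected production onset, as a bench scientist would sample.
#'
#' @return Named list of [treatment_model] objects.
#' @export
study_presets <- function() {
  # half-day resolution only in the short expected-onset region, then 1-3 d
  # steps: interval finite-difference rates stay noise-robust while the lag
  # is still resolved at sub-day scale
  t_fast <- c(0, 1, 2, 3, 3.5, 4, 4.5, 5, 6, 8, 10, 12, 15, 18, 21)
  presets <- list(
    treatment_model("Coccomyxa", 4.3, 0.5, 59.6, 6.0, 404, 52,
                    times = t_fast, cod_dose = 494, mass_dose = 0.38,
                    ph_max = 5.81, ph_max_sd = 0.05),
    treatment_model("Duckweed", 4.3, 0.5, 53.3, 7.6, 616, 266,
                    times = t_fast, cod_dose = 494, mass_dose = 0.592,
                    ph_max = 5.95, ph_max_sd = 0.06),
    treatment_model("Euglena", 6.0, 0.5, 33.1, 4.1, 279, 51,
                    times = c(0, 2, 4, 5, 5.5, 6, 6.5, 7, 8, 10, 12, 14,
                              17, 20, 22),
                    cod_dose = 494, mass_dose = 0.489,
                    ph_max = 5.59, ph_max_sd = 0.09),
    treatment_model("Glycerol", 14, 2, 55, 8, 514, 133,
                    times = c(0, 3, 6, 9, 12, 13, 14, 15, 16, 17, 20, 23,
                              26, 29, 35, 41, 47),
                    cod_dose = 494, ph_max = 5.82, ph_max_sd = 0.02),
    treatment_model("Casamino acids", 6.5, 1.0, 74.6, 29.1, 637, 232,
                    times = c(0, 2, 4, 5, 6, 6.5, 7, 7.5, 8, 9, 12, 15, 18,
                              21, 24),
                    cod_dose = 494, ph_max = 6.12, ph_max_sd = 0.05),
    treatment_model("Glucose", 16, 2, 71.6, 10, 973, 339,
                    times = c(0, 4, 8, 12, 14, 15, 16, 17, 18, 19, 22, 26,
                              30, 34, 38, 43, 47),
                    producing_fraction = 0.75, cod_dose = 414,
                    ph_max = 5.09, ph_max_sd = 0.46),
    treatment_model("Galactose", 20, 2, 87.1, 10, 1142, 81,
                    times = c(0, 4, 8, 12, 16, 18, 19, 20, 21, 22, 23, 26,
                              30, 34, 38, 43, 47),
                    producing_fraction = 0.75, cod_dose = 426,
                    ph_max = 4.85, ph_max_sd = 0.22),
    treatment_model("Palmitate", 25, 3, 9.2, 2, 140, 21,
                    times = c(0, 5, 10, 15, 20, 22, 24, 25, 26, 27, 28, 31,
                              35, 39, 43, 47),
                    producing_fraction = 0.75, cod_dose = 264,
                    ph_max = 5.55, ph_max_sd = 0.26),
    treatment_model("Oleate", 30, 3, 3.0, 1, 45, 10,
                    times = c(0, 5, 10, 15, 20, 25, 27, 29, 30, 31, 32, 33,
                              36, 40, 44, 47),
                    producing_fraction = 0.25, cod_dose = 744,
                    ph_max = 5.73, ph_max_sd = 0.1))
  setNames(presets, vapply(presets, function(m) m$name, character(1)))
}
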