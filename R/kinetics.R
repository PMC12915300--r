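# Zero-order sulfide production kinetics under the rate-threshold window
# rule: the production window starts at the first sampling interval whose
# finite-difference rate exceeds the threshold (default 50 uM/d = 0.05 mM/d)
# and extends until the first subsequent interval whose rate falls below it.
# The zero-order rate is the endpoint slope over that window.

#' Finite-difference sulfide production rates between consecutive samples
#'
#' @param series A [microcosm_series].
#' @return A tibble with columns `start`, `end` (days) and `rate_uM_per_d`,
#'   one row per consecutive sampling interval (length `n - 1`). Negative
#'   rates (sulfide loss) are reported as-is, never clipped.
#' @export
#' @examples
#' s <- microcosm_series("x", "r1", c(0, 4, 6), c(0, 0, 120))
#' interval_rates(s)  # rates 0 and 60 uM/d
interval_rates <- function(series) {
  validate_microcosm_series(series)
  n <- length(series$times)
  if (n < 2) {
    stop_sulfidogen("at least 2 time points are needed to compute rates",
                    "sulfidogen_insufficient_data_error")
  }
  tibble::tibble(start = series$times[-n], end = series$times[-1],
                 rate_uM_per_d = diff(series$sulfide) / diff(series$times))
}

#' Detect the active sulfide-production window
#'
#' The window opens at the left endpoint of the first sampling interval whose
#' rate strictly exceeds `threshold` and closes at the left endpoint of the
#' first subsequent interval whose rate falls strictly below `threshold`; if
#' production never falls below the threshold again, the window extends to
#' the last observation. Intervals with a missing rate are treated as
#' inactive. Absence of a window is a value, not an error: it flags a
#' replicate that did not produce sulfide.
#'
#' @param series A [microcosm_series].
#' @param threshold Rate threshold in µM/d. The default, 50 µM/d
#'   (0.05 mM/d), is the study rule; slow treatments (lipid-like rates of
#'   3–9 µM/d) only yield a window under a lower threshold.
#' @return A `rate_window` (fields `start_time`, `end_time`, `n_points`)
#'   or `NULL` when no interval exceeds the threshold.
#' @export
#' @examples
#' s <- microcosm_series("x", "r1", c(0, 4, 6, 8, 10, 12),
#'                       c(0, 0, 120, 240, 360, 370))
#' detect_window(s)  # [4, 10], 4 points
detect_window <- function(series, threshold = 50) {
  r <- interval_rates(series)$rate_uM_per_d
  above <- !is.na(r) & r > threshold
  if (!any(above)) return(NULL)
  i0 <- which(above)[1]
  below_after <- which(!is.na(r) & r < threshold & seq_along(r) > i0)
  end_time <- if (length(below_after)) series$times[below_after[1]] else
    series$times[length(series$times)]
  rate_window(start_time = series$times[i0], end_time = end_time,
              n_points = sum(series$times >= series$times[i0] &
                               series$times <= end_time))
}

#' Construct a rate window
#'
#' @param start_time,end_time Window boundaries (days, observation times).
#' @param n_points Number of observations inside the closed window.
#' @return An object of class `rate_window`.
#' @export
rate_window <- function(start_time, end_time, n_points) {
  if (!(start_time < end_time)) {
    stop_sulfidogen("window start must precede its end", "sulfidogen_validation_error")
  }
  if (n_points < 2) {
    stop_sulfidogen("a rate window needs at least 2 observations",
                    "sulfidogen_validation_error")
  }
  structure(list(start_time = start_time, end_time = end_time,
                 n_points = n_points), class = "rate_window")
}

#' @export
print.rate_window <- function(x, ...) {
  cat(sprintf("<rate_window> [%g, %g] d, %d points\n",
              x$start_time, x$end_time, x$n_points))
  invisible(x)
}

#' Lag time before sulfide production
#'
#' Operationalised as the start of the detected production window, at
#' sampling-time resolution (no interpolation between samples).
#'
#' @inheritParams detect_window
#' @return Lag in days, or `NA` when the replicate never produced sulfide
#'   above the threshold.
#' @export
lag_time <- function(series, threshold = 50) {
  w <- detect_window(series, threshold)
  if (is.null(w)) NA_real_ else w$start_time
}

#' Zero-order sulfide production rate over a window
#'
#' Endpoint slope: sulfide at the window end minus sulfide at the window
#' start, divided by the elapsed time. Both window boundaries must coincide
#' with observation times.
#'
#' @param series A [microcosm_series].
#' @param window A [rate_window], e.g. from [detect_window()].
#' @return Rate in µM/d.
#' @export
zero_order_rate <- function(series, window) {
  validate_microcosm_series(series)
  idx <- function(t) {
    i <- which(abs(series$times - t) < 1e-9)
    if (!length(i)) {
      stop_sulfidogen(sprintf("window endpoint %g d is not an observation time", t),
                      "sulfidogen_alignment_error")
    }
    i[1]
  }
  i0 <- idx(window$start_time); i1 <- idx(window$end_time)
  (series$sulfide[i1] - series$sulfide[i0]) /
    (series$times[i1] - series$times[i0])
}

#' Sulfide production efficiency per unit COD
#'
#' @param max_sulfide_uM Maximum observed sulfide (µM).
#' @param cod_dose COD dose of the substrate (mg O2/L); must be positive.
#' @return Efficiency in µM sulfide per mg L⁻¹ COD, unrounded.
#' @export
#' @examples
#' efficiency_per_cod(404, 494)  # ~0.82
efficiency_per_cod <- function(max_sulfide_uM, cod_dose) {
  if (!is.numeric(cod_dose) || any(cod_dose <= 0)) {
    stop_sulfidogen("cod_dose must be positive", "sulfidogen_domain_error")
  }
  max_sulfide_uM / cod_dose
}

#' Sulfide yield per gram of substrate
#'
#' @param max_sulfide_uM Maximum observed sulfide (µM).
#' @param mass_dose Substrate mass dose (g/L); must be positive.
#' @return Yield in mM sulfide per g substrate.
#' @export
#' @examples
#' yield_per_gram(404, 0.38)  # ~1.06 mM/g
yield_per_gram <- function(max_sulfide_uM, mass_dose) {
  if (!is.numeric(mass_dose) || any(mass_dose <= 0)) {
    stop_sulfidogen("mass_dose must be positive", "sulfidogen_domain_error")
  }
  (max_sulfide_uM / 1000) / mass_dose
}

#' Time to removal of a dissolved metal(loid)
#'
#' First observation time at which the analyte concentration is at or below
#' `limit` (default 0, the detection floor).
#'
#' @param series A [microcosm_series] carrying the analyte in its metal map.
#' @param analyte Metal label, e.g. `"Zn"`.
#' @param limit Concentration limit (mM).
#' @return Days until removal, or `NA` if the limit is never reached.
#' @export
removal_time <- function(series, analyte, limit = 0) {
  validate_microcosm_series(series)
  if (!analyte %in% names(series$metals)) {
    stop_sulfidogen(sprintf("analyte %s not measured in %s/%s", analyte,
                            series$treatment, series$replicate),
                    "sulfidogen_key_error")
  }
  conc <- series$metals[[analyte]]
  hit <- which(!is.na(conc) & conc <= limit)
  if (!length(hit)) NA_real_ else series$times[hit[1]]
}

#' Kinetics summary for one replicate
#'
#' Applies the window rule and eq-1 endpoint slope to a replicate and
#' derives the per-COD efficiency and per-gram yield when doses are given.
#' Maximum sulfide is the maximum observed value (not a fitted plateau).
#'
#' @inheritParams detect_window
#' @param cod_dose Optional COD dose (mg O2/L) for the efficiency column.
#' @param mass_dose Optional mass dose (g/L) for the yield column.
#' @return A one-row tibble with columns `treatment`, `replicate`,
#'   `produced`, `lag_d`, `rate_uM_per_d`, `max_sulfide_uM`,
#'   `efficiency_uM_per_mgL_COD`, `yield_mM_per_g`, `window_start_d`,
#'   `window_end_d`, `window_n`, `final_ph`.
#' @export
replicate_kinetics <- function(series, threshold = 50, cod_dose = NULL,
                               mass_dose = NULL) {
  validate_microcosm_series(series)
  w <- detect_window(series, threshold)
  produced <- !is.null(w)
  max_s <- if (all(is.na(series$sulfide))) NA_real_ else
    max(series$sulfide, na.rm = TRUE)
  ph <- series$ph
  final_ph <- if (is.null(ph) || all(is.na(ph))) NA_real_ else
    ph[max(which(!is.na(ph)))]
  tibble::tibble(
    treatment = series$treatment, replicate = series$replicate,
    produced = produced,
    lag_d = if (produced) w$start_time else NA_real_,
    rate_uM_per_d = if (produced) zero_order_rate(series, w) else NA_real_,
    max_sulfide_uM = max_s,
    efficiency_uM_per_mgL_COD =
      if (!is.null(cod_dose) && !is.na(cod_dose) && !is.na(max_s))
        efficiency_per_cod(max_s, cod_dose) else NA_real_,
    yield_mM_per_g =
      if (!is.null(mass_dose) && !is.na(mass_dose) && !is.na(max_s))
        yield_per_gram(max_s, mass_dose) else NA_real_,
    window_start_d = if (produced) w$start_time else NA_real_,
    window_end_d = if (produced) w$end_time else NA_real_,
    window_n = if (produced) w$n_points else NA_integer_,
    final_ph = final_ph)
}

#' Treatment-level summary over producing replicates
#'
#' Means and sample (n−1) standard deviations of each kinetic quantity over
#' the replicates that produced sulfide; `n` counts producing replicates
#' only, so a treatment where one of four bottles produced reports `n = 1`
#' with mean only and no standard deviation.
#'
#' @param replicates A tibble of [replicate_kinetics()] rows (one treatment).
#' @return A one-row tibble of `n`, mean and sd columns.
#' @export
summarize_treatment <- function(replicates) {
  stopifnot(is.data.frame(replicates))
  trt <- unique(replicates$treatment)
  if (length(trt) != 1) {
    stop_sulfidogen("summarize_treatment expects replicates of one treatment",
                    "sulfidogen_validation_error")
  }
  prod <- replicates[replicates$produced, , drop = FALSE]
  n <- nrow(prod)
  mstat <- function(v) if (n >= 1) mean(v) else NA_real_
  sstat <- function(v) if (n >= 2) sd(v) else NA_real_
  quantities <- c("lag_d", "rate_uM_per_d", "max_sulfide_uM",
                  "efficiency_uM_per_mgL_COD", "yield_mM_per_g", "final_ph")
  out <- tibble::tibble(treatment = trt, n = n,
                        n_replicates = nrow(replicates))
  for (q in quantities) {
    v <- prod[[q]]
    v <- v[!is.na(v)]
    out[[paste0(q, "_mean")]] <- if (length(v)) mean(v) else NA_real_
    out[[paste0(q, "_sd")]] <- if (length(v) >= 2) sd(v) else NA_real_
  }
  out
}

#' Per-replicate and per-treatment kinetics for a whole study
#'
#' Runs [replicate_kinetics()] on every series, joining COD and mass doses
#' from a substrate table by treatment name, then summarises each treatment
#' over its producing replicates.
#'
#' @param series_list Named list of [microcosm_series], e.g. from
#'   [read_timeseries()] or [generate_study()].
#' @param threshold Rate threshold (µM/d) for the window rule.
#' @param substrates Substrate table with columns `name`, `cod_dose_mg_l`,
#'   `mass_dose_g_l` (default [substrate_table()]).
#' @return A list with tibbles `replicates` and `treatments`.
#' @export
study_kinetics <- function(series_list, threshold = 50,
                           substrates = substrate_table()) {
  reps <- dplyr::bind_rows(lapply(series_list, function(s) {
    row <- substrates[substrates$name == s$treatment, , drop = FALSE]
    replicate_kinetics(
      s, threshold = threshold,
      cod_dose = if (nrow(row)) row$cod_dose_mg_l[1] else NULL,
      mass_dose = if (nrow(row)) row$mass_dose_g_l[1] else NULL)
  }))
  treatments <- reps |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(~ summarize_treatment(dplyr::mutate(.x, treatment = .y$treatment))[-1]) |>
    dplyr::ungroup()
  list(replicates = reps, treatments = treatments)
}
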