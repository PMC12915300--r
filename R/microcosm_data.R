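# Microcosm time-series containers, validation and CSV interchange.
#
# One CSV schema is used everywhere (long/tidy, one row per time point per
# replicate):
#   treatment,replicate,time_d,sulfide_uM[,acetate_mM,butyrate_mM,
#   propionate_mM,Fe_mM,Zn_mM,As_mM,pH,source_filter]
# Units are fixed by the schema (days; µM sulfide; mM VFAs and metals) and
# never auto-converted. Missing values are empty cells and are read as
# "absent", never as zero: the study design measures some analytes on a
# subset of time points only.

.vfa_columns <- c("acetate_mM", "butyrate_mM", "propionate_mM")
.required_columns <- c("treatment", "replicate", "time_d", "sulfide_uM")

#' Construct a single-replicate microcosm time series
#'
#' A `microcosm_series` holds the time-stamped measurements of one replicate
#' bottle: sulfide (µM) at every sampling time, and optionally volatile
#' fatty acids (mM), dissolved metals (mM) and pH. Times are days since
#' substrate amendment.
#'
#' @param treatment Treatment label (substrate name).
#' @param replicate Replicate label within the treatment.
#' @param times Strictly increasing numeric vector of sampling times (days).
#' @param sulfide Sulfide concentrations (µM), same length as `times`;
#'   `NA` marks a missing measurement.
#' @param vfa Optional named list of VFA concentration vectors (mM), names
#'   among `"acetate"`, `"butyrate"`, `"propionate"`.
#' @param metals Optional named list of dissolved metal(loid) concentration
#'   vectors (mM), e.g. `list(Fe = ..., Zn = ..., As = ...)`.
#' @param ph Optional pH vector, same length as `times`.
#' @param source_filter Optional label of the inoculum filter the replicate
#'   was seeded from (supplementary metadata; not used by any calculation).
#' @return An object of class `microcosm_series`.
#' @export
#' @examples
#' microcosm_series("Coccomyxa", "r1", times = c(0, 4, 8),
#'                  sulfide = c(0, 10, 250))
microcosm_series <- function(treatment, replicate, times, sulfide,
                             vfa = NULL, metals = NULL, ph = NULL,
                             source_filter = NULL) {
  x <- structure(
    list(treatment = as.character(treatment),
         replicate = as.character(replicate),
         source_filter = if (is.null(source_filter)) NULL else as.character(source_filter),
         times = as.numeric(times),
         sulfide = as.numeric(sulfide),
         vfa = vfa, metals = metals,
         ph = if (is.null(ph)) NULL else as.numeric(ph)),
    class = "microcosm_series")
  validate_microcosm_series(x)
}

#' Validate a microcosm series against its invariants
#'
#' Checks that times are strictly increasing, that every measurement vector
#' matches `times` in length, and that all non-missing concentrations are
#' non-negative (pH excepted). Returns the object invisibly unchanged on
#' success and throws a classed validation error otherwise.
#'
#' @param x A `microcosm_series`.
#' @return `x`, invisibly.
#' @export
validate_microcosm_series <- function(x) {
  if (!inherits(x, "microcosm_series")) {
    stop_sulfidogen("`x` must be a microcosm_series", "sulfidogen_validation_error")
  }
  t <- x$times
  if (length(t) < 1 || anyNA(t)) {
    stop_sulfidogen("times must be non-missing", "sulfidogen_validation_error")
  }
  d <- diff(t)
  if (any(d == 0)) {
    stop_sulfidogen(
      sprintf("duplicate sampling time %g in %s/%s", t[which(d == 0)[1] + 1],
              x$treatment, x$replicate),
      "sulfidogen_validation_error")
  }
  if (any(d < 0)) {
    stop_sulfidogen(
      sprintf("times must be strictly increasing in %s/%s", x$treatment, x$replicate),
      "sulfidogen_validation_error")
  }
  check_len <- function(v, what) {
    if (length(v) != length(t)) {
      stop_sulfidogen(
        sprintf("%s has length %d but there are %d times (%s/%s)",
                what, length(v), length(t), x$treatment, x$replicate),
        "sulfidogen_validation_error")
    }
  }
  check_nonneg <- function(v, what) {
    if (any(v < 0, na.rm = TRUE)) {
      stop_sulfidogen(sprintf("negative %s concentration in %s/%s",
                              what, x$treatment, x$replicate),
                      "sulfidogen_validation_error")
    }
  }
  check_len(x$sulfide, "sulfide")
  check_nonneg(x$sulfide, "sulfide")
  for (nm in names(x$vfa)) {
    check_len(x$vfa[[nm]], nm); check_nonneg(x$vfa[[nm]], nm)
  }
  for (nm in names(x$metals)) {
    check_len(x$metals[[nm]], nm); check_nonneg(x$metals[[nm]], nm)
  }
  if (!is.null(x$ph)) check_len(x$ph, "pH")
  invisible(x)
}

#' @export
print.microcosm_series <- function(x, ...) {
  extras <- c(names(x$vfa), names(x$metals), if (!is.null(x$ph)) "pH")
  cat(sprintf("<microcosm_series> %s/%s: %d time points over %g d%s\n",
              x$treatment, x$replicate, length(x$times), max(x$times),
              if (length(extras)) paste0(" (+", paste(extras, collapse = ", "), ")") else ""))
  invisible(x)
}

series_key <- function(x) paste(x$treatment, x$replicate, sep = "/")

#' Read microcosm time series from a tidy CSV file
#'
#' Expects the long interchange schema documented above. Each
#' (treatment, replicate) pair becomes one [microcosm_series], with rows
#' sorted by time. Optional analyte columns that are entirely missing for a
#' replicate are dropped from that series (absent, not zero).
#'
#' @param path Path to a CSV file.
#' @return A named list of `microcosm_series` (names `"treatment/replicate"`).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) {
    stop_sulfidogen(sprintf("file not found: %s", path), "sulfidogen_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          treatment = readr::col_character(),
                          replicate = readr::col_character(),
                          .default = readr::col_double()))
  missing <- setdiff(.required_columns, names(df))
  if (length(missing)) {
    stop_sulfidogen(sprintf("missing required column(s): %s",
                            paste(missing, collapse = ", ")),
                    "sulfidogen_schema_error")
  }
  if ("source_filter" %in% names(df)) {
    df$source_filter <- as.character(df$source_filter)
  }
  dup <- duplicated(df[c("treatment", "replicate", "time_d")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_sulfidogen(
      sprintf("duplicate (treatment, replicate, time) at row %d: %s/%s t=%g",
              i, df$treatment[i], df$replicate[i], df$time_d[i]),
      "sulfidogen_validation_error")
  }
  value_cols <- setdiff(names(df), c("treatment", "replicate", "source_filter"))
  for (col in value_cols) {
    bad <- which(df[[col]] < 0)
    if (col != "pH" && length(bad)) {
      stop_sulfidogen(sprintf("negative value in column %s at row %d", col, bad[1]),
                      "sulfidogen_validation_error")
    }
  }
  vfa_cols <- intersect(.vfa_columns, names(df))
  metal_cols <- setdiff(grep("_mM$", names(df), value = TRUE), .vfa_columns)
  groups <- split(df, list(df$treatment, df$replicate), drop = TRUE, sep = "\r")
  out <- lapply(groups, function(g) {
    g <- g[order(g$time_d), , drop = FALSE]
    pick <- function(cols, strip) {
      kept <- cols[vapply(cols, function(cl) !all(is.na(g[[cl]])), logical(1))]
      if (!length(kept)) return(NULL)
      setNames(lapply(kept, function(cl) g[[cl]]), sub(strip, "", kept))
    }
    sf <- if ("source_filter" %in% names(g)) g$source_filter[1] else NULL
    if (!is.null(sf) && is.na(sf)) sf <- NULL
    microcosm_series(
      treatment = g$treatment[1], replicate = g$replicate[1],
      times = g$time_d, sulfide = g$sulfide_uM,
      vfa = pick(vfa_cols, "_mM$"), metals = pick(metal_cols, "_mM$"),
      ph = if ("pH" %in% names(g) && !all(is.na(g$pH))) g$pH else NULL,
      source_filter = sf)
  })
  names(out) <- vapply(out, series_key, character(1))
  out[order(names(out))]
}

series_to_rows <- function(x) {
  row <- tibble::tibble(treatment = x$treatment, replicate = x$replicate,
                        time_d = x$times, sulfide_uM = x$sulfide)
  for (nm in names(x$vfa)) row[[paste0(nm, "_mM")]] <- x$vfa[[nm]]
  for (nm in names(x$metals)) row[[paste0(nm, "_mM")]] <- x$metals[[nm]]
  if (!is.null(x$ph)) row$pH <- x$ph
  if (!is.null(x$source_filter)) row$source_filter <- x$source_filter
  row
}

#' Write microcosm series to the tidy CSV interchange format
#'
#' Rows are ordered deterministically by (treatment, replicate, time) and
#' columns follow the canonical schema order, so two writes of the same data
#' are byte-identical. Numbers are written at full double precision (up to
#' 15 significant digits); missing values are empty cells.
#'
#' @param series A `microcosm_series` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  if (inherits(series, "microcosm_series")) series <- list(series)
  lapply(series, validate_microcosm_series)
  canonical <- c(.required_columns, .vfa_columns,
                 "Fe_mM", "Zn_mM", "As_mM", "pH", "source_filter")
  if (length(series)) {
    rows <- dplyr::bind_rows(lapply(series, series_to_rows))
    extra <- setdiff(names(rows), canonical)
    rows <- rows[c(intersect(canonical, names(rows)), sort(extra))]
    rows <- dplyr::arrange(rows, .data$treatment, .data$replicate, .data$time_d)
  } else {
    rows <- tibble::tibble(treatment = character(), replicate = character(),
                           time_d = double(), sulfide_uM = double())
  }
  tryCatch(readr::write_csv(rows, path, na = ""),
           error = function(e) stop_sulfidogen(
             sprintf("cannot write %s: %s", path, conditionMessage(e)),
             "sulfidogen_io_error"))
  invisible(path)
}

#' Convert microcosm series to one long tibble
#'
#' @param series A `microcosm_series` or list of them.
#' @return A tibble in the CSV interchange schema.
#' @export
series_table <- function(series) {
  if (inherits(series, "microcosm_series")) series <- list(series)
  dplyr::bind_rows(lapply(series, series_to_rows))
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "sulfidogen")
  if (p == "") stop_sulfidogen(sprintf("fixture %s not found", file), "sulfidogen_io_error")
  p
}

#' Substrate property table
#'
#' Compositional/proximate/elemental characterisation of the high-density
#' biomass substrates plus the COD (mg O2/L) and, where known, mass (g/L)
#' dose of every substrate used in the microcosms. The `dose_provenance`
#' column flags mass doses back-computed from published per-gram sulfide
#' yields rather than stated directly.
#'
#' @return A tibble, one row per substrate.
#' @export
substrate_table <- function() {
  readr::read_csv(fixture_path("substrates.csv"), show_col_types = FALSE,
                  progress = FALSE)
}
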