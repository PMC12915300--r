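# Exact small-sample nonparametric inference: the two-sample
# Mann-Whitney U test with p-values by complete enumeration of group
# labelings (exact at the study's n <= 4 per group), and Kendall's tau-b
# with exact permutation p-values at small n. Normal approximations with
# tie corrections take over beyond the enumeration limits.

new_test_result <- function(statistic, p_value, method, n, alternative) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, alternative = alternative),
            class = "sulfidogen_test")
}

#' @export
print.sulfidogen_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%s, n = %s)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = ",")))
  invisible(x)
}

#' Mann-Whitney U test with exact enumeration at small n
#'
#' U is computed from midrank sums (`U = R1 - n1(n1+1)/2`). When
#' `n1 + n2 <= 12` (or `exact = TRUE`) the p-value is the fraction of all
#' `choose(n1+n2, n1)` group labelings of the pooled data whose U is as or
#' more extreme than observed — exact under exchangeability, including
#' ties. Otherwise the tie-corrected normal approximation with continuity
#' correction is used. Alternatives refer to `x`: `"greater"` means `x`
#' tends to exceed `y` (large U).
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` chooses by `n1 + n2 <= 12`.
#' @return A `sulfidogen_test` with fields `statistic` (U for `x`),
#'   `p_value`, `method`, `n`, `alternative`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8), alternative = "less")  # p = 1/70
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    stop_sulfidogen("both samples must be non-empty", "sulfidogen_domain_error")
  }
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- exact %||% (n1 + n2 <= 12)
  eps <- 1e-9
  if (use_exact) {
    labelings <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[labelings], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
      less      = mean(u_all <= u_obs + eps),
      greater   = mean(u_all >= u_obs - eps))
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z_upper <- (u_obs - mu - 0.5) / sigma   # continuity-corrected
    z_lower <- (u_obs - mu + 0.5) / sigma
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::pnorm(z_lower),
                                 stats::pnorm(z_upper, lower.tail = FALSE))),
      less      = stats::pnorm(z_lower),
      greater   = stats::pnorm(z_upper, lower.tail = FALSE))
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  new_test_result(setNames(u_obs, "U"), p, method, c(n1 = n1, n2 = n2),
                  alternative)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  smaller <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(smaller), ncol = n)
  row <- 1
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(smaller))) {
      out[row, ] <- c(k, rest[smaller[i, ]])
      row <- row + 1
    }
  }
  out
}

kendall_s <- function(x, y) {
  # concordant-minus-discordant pair count
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  sum(dx[lower.tri(dx)] * dy[lower.tri(dy)])
}

#' Kendall's tau-b rank correlation with exact permutation p at small n
#'
#' tau-b applies the usual tie corrections to the concordant-minus-
#' discordant pair count. For `n <= 8` (or `exact = TRUE`) the p-value
#' enumerates all `n!` pairings of `y` against `x`; beyond that the normal
#' approximation with the full tie-corrected variance is used.
#'
#' @param x,y Numeric sequences of equal length >= 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact Force or forbid permutation enumeration; default `NULL`
#'   chooses by `n <= 8`.
#' @return A `sulfidogen_test` with the tau-b statistic.
#' @export
#' @examples
#' kendall_tau(1:3, c(3, 2, 1))  # tau = -1
kendall_tau <- function(x, y, alternative = c("two.sided", "less", "greater"),
                        exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) {
    stop_sulfidogen("x and y must have equal length", "sulfidogen_domain_error")
  }
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) {
    stop_sulfidogen("need at least 2 paired observations", "sulfidogen_domain_error")
  }
  s_obs <- kendall_s(x, y)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1t <- sum(tx * (tx - 1) / 2); n2t <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1t) * (n0 - n2t))
  tau <- if (denom > 0) s_obs / denom else NA_real_
  use_exact <- exact %||% (n <= 8)
  eps <- 1e-9
  if (use_exact) {
    perms <- all_permutations(n)
    s_all <- vapply(seq_len(nrow(perms)),
                    function(i) kendall_s(x, y[perms[i, ]]), numeric(1))
    p <- switch(alternative,
      two.sided = mean(abs(s_all) >= abs(s_obs) - eps),
      less      = mean(s_all <= s_obs + eps),
      greater   = mean(s_all >= s_obs - eps))
    method <- "Kendall tau-b (exact permutation)"
  } else {
    ti <- as.numeric(tx); uj <- as.numeric(ty)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(ti * (ti - 1) * (2 * ti + 5))
    vu <- sum(uj * (uj - 1) * (2 * uj + 5))
    v1 <- sum(ti * (ti - 1)) * sum(uj * (uj - 1)) / (2 * n * (n - 1))
    v2 <- sum(ti * (ti - 1) * (ti - 2)) * sum(uj * (uj - 1) * (uj - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- s_obs / sqrt(var_s)
    p <- switch(alternative,
      two.sided = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)),
      less      = stats::pnorm(z),
      greater   = stats::pnorm(z, lower.tail = FALSE))
    method <- "Kendall tau-b (normal approximation, tie-corrected)"
  }
  new_test_result(setNames(tau, "tau"), p, method, n, alternative)
}

#' Pairwise Mann-Whitney comparisons of kinetic parameters
#'
#' Applies the two-sample test to every treatment pair for each requested
#' per-replicate kinetic parameter, over producing replicates only. No
#' multiple-testing correction is applied by default (matching plain
#' P < 0.05 interpretation); `adjust = "holm"` enables a Holm adjustment.
#'
#' @param replicates Per-replicate kinetics tibble from [study_kinetics()].
#' @param parameters Columns to compare.
#' @param alternative Passed to [mann_whitney()].
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with one row per (parameter, treatment pair).
#' @export
pairwise_mann_whitney <- function(replicates,
                                  parameters = c("lag_d", "rate_uM_per_d",
                                                 "max_sulfide_uM"),
                                  alternative = "two.sided",
                                  adjust = "none", alpha = 0.05) {
  prod <- replicates[replicates$produced, , drop = FALSE]
  trts <- sort(unique(prod$treatment))
  rows <- list()
  for (param in parameters) {
    for (i in seq_along(trts)) {
      for (j in seq_along(trts)) {
        if (j <= i) next
        a <- prod[[param]][prod$treatment == trts[i]]
        b <- prod[[param]][prod$treatment == trts[j]]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (!length(a) || !length(b)) next
        t <- mann_whitney(a, b, alternative = alternative)
        rows[[length(rows) + 1]] <- tibble::tibble(
          parameter = param, treatment_a = trts[i], treatment_b = trts[j],
          n_a = length(a), n_b = length(b),
          U = unname(t$statistic), p_value = t$p_value)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    if (adjust != "none") out$p_value <- stats::p.adjust(out$p_value, adjust)
    out$significant <- out$p_value < alpha
  }
  out
}
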