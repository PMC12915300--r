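# Shared fixtures and independent oracles used across test files.

make_series <- function(times, sulfide, treatment = "T", replicate = "r1", ...) {
  microcosm_series(treatment, replicate, times = times, sulfide = sulfide, ...)
}

# Piecewise-linear lag -> zero-order -> plateau curve sampled without noise.
ideal_series <- function(lag, rate, smax, times, ...) {
  make_series(times, pmin(pmax(rate * (times - lag), 0), smax), ...)
}

# Independent Mann-Whitney oracle: U by direct pair counting, exact p by
# enumerating every group labeling (no rank arithmetic shared with the
# implementation).
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
oracle_mw_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  labelings <- combn(length(pooled), n1)
  us <- apply(labelings, 2, function(idx) {
    oracle_u(pooled[idx], pooled[-idx])
  })
  u_obs <- oracle_u(x, y)
  mu <- n1 * length(y) / 2
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(us - mu) >= abs(u_obs - mu) - eps),
         less = mean(us <= u_obs + eps),
         greater = mean(us >= u_obs - eps))
}

# Random C/H/O/N formula with a non-negative electron count.
random_chon_formula <- function() {
  repeat {
    x <- sample(1:12, 1)
    y <- sample(1:(2 * x + 3), 1)
    z <- sample(0:(x + 2), 1)
    n <- sample(0:min(x, 3), 1)
    q <- sample(-2:1, 1)
    if (4 * x + y - 2 * z - 3 * n - q >= 0) {
      counts <- c(C = x, H = y)
      if (z > 0) counts["O"] <- z
      if (n > 0) counts["N"] <- n
      return(structure(list(counts = counts, charge = as.integer(q)),
                       class = "elemental_formula"))
    }
  }
}
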