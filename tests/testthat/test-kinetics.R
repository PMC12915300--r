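test_that("interval rates are forward finite differences, unclipped", {
  s <- make_series(c(0, 4, 6), c(0, 0, 120))
  expect_equal(interval_rates(s)$rate_uM_per_d, c(0, 60))
  expect_equal(interval_rates(make_series(c(0, 2, 5), c(7, 7, 7)))$rate_uM_per_d,
               c(0, 0))
  expect_equal(interval_rates(make_series(c(0, 1, 2), c(0, 50, 20)))$rate_uM_per_d,
               c(50, -30))
  expect_error(interval_rates(make_series(0, 5)),
               class = "sulfidogen_insufficient_data_error")
})

test_that("interval rates agree with a brute-force slope oracle on random series", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    t <- sort(runif(n, 0, 30))
    t <- t + seq_len(n) * 1e-3  # enforce strict increase
    s <- cumsum(abs(rnorm(n, 20, 30)))
    sr <- make_series(t, s)
    brute <- vapply(seq_len(n - 1),
                    function(j) (s[j + 1] - s[j]) / (t[j + 1] - t[j]),
                    numeric(1))
    expect_equal(interval_rates(sr)$rate_uM_per_d, brute)
  }
})

test_that("window rule: first crossing opens, first drop closes", {
  s <- make_series(c(0, 4, 6, 8, 10, 12), c(0, 0, 120, 240, 360, 370))
  w <- detect_window(s, 50)
  expect_equal(w$start_time, 4)
  expect_equal(w$end_time, 10)
  expect_equal(w$n_points, 4)
  expect_equal(lag_time(s), 4)
  expect_equal(zero_order_rate(s, w), 60)

  # never produced
  expect_null(detect_window(make_series(0:5, rep(0, 6)), 50))
  expect_true(is.na(lag_time(make_series(0:5, rep(0, 6)))))

  # single supra-threshold interval at the very end -> window spans it
  s2 <- make_series(c(0, 2, 4, 6), c(0, 10, 20, 200))
  w2 <- detect_window(s2, 50)
  expect_equal(w2$start_time, 4)
  expect_equal(w2$end_time, 6)
  expect_equal(w2$n_points, 2)

  # production from the first interval -> lag is the first observation time
  s3 <- make_series(c(0, 2, 4), c(0, 150, 300))
  expect_equal(lag_time(s3), 0)

  # negative rates never open a window
  s4 <- make_series(c(0, 2, 4, 6), c(100, 0, 0, 0))
  expect_null(detect_window(s4, 50))
})

test_that("raising the threshold never widens the window", {
  set.seed(12)
  for (i in 1:20) {
    t <- seq(0, 24, by = 2)
    s <- make_series(t, pmax(cumsum(rnorm(length(t), 25, 40)), 0))
    prev <- detect_window(s, 10)
    for (thr in c(20, 40, 80)) {
      cur <- detect_window(s, thr)
      if (is.null(prev)) {
        expect_null(cur)
      } else if (!is.null(cur)) {
        expect_gte(cur$start_time, prev$start_time)
        expect_lte(cur$end_time - cur$start_time,
                   prev$end_time - prev$start_time + 1e-12)
      }
      prev <- cur
    }
  }
})

test_that("zero-order rate requires aligned endpoints and handles flat windows", {
  s <- make_series(c(0, 5), c(100, 400))
  expect_equal(zero_order_rate(s, rate_window(0, 5, 2)), 60)
  expect_equal(zero_order_rate(make_series(c(0, 3), c(50, 50)),
                               rate_window(0, 3, 2)), 0)
  expect_error(zero_order_rate(s, rate_window(0, 4, 2)),
               class = "sulfidogen_alignment_error")
})

test_that("efficiency and yield reproduce the published per-dose columns", {
  expect_equal(round(efficiency_per_cod(404, 494), 2), 0.82)
  expect_equal(round(efficiency_per_cod(616, 494), 2), 1.25)
  expect_equal(round(efficiency_per_cod(279, 494), 2), 0.56)
  expect_equal(efficiency_per_cod(0, 494), 0)
  expect_equal(round(yield_per_gram(404, 0.38), 2), 1.06)
  expect_equal(yield_per_gram(1000, 1), 1)
  expect_equal(round(yield_per_gram(279, 0.489), 2), 0.57)
  expect_error(efficiency_per_cod(100, 0), class = "sulfidogen_domain_error")
  expect_error(yield_per_gram(100, -1), class = "sulfidogen_domain_error")
})

test_that("efficiency and yield are homogeneous of degree -1 in the dose", {
  expect_equal(efficiency_per_cod(404, 2 * 494),
               efficiency_per_cod(404, 494) / 2)
  expect_equal(yield_per_gram(404, 2 * 0.38), yield_per_gram(404, 0.38) / 2)
})

test_that("removal time is the first observation at or below the limit", {
  s <- make_series(c(0, 5, 10, 15), c(0, 50, 150, 200),
                   metals = list(Zn = c(0.2, 0.2, 0.05, 0),
                                 Fe = c(12, 12, 11.9, 11.8)))
  expect_equal(removal_time(s, "Zn"), 15)
  expect_true(is.na(removal_time(s, "Fe")))
  expect_equal(removal_time(s, "Zn", limit = 0.5), 0)
  expect_error(removal_time(s, "As"), class = "sulfidogen_key_error")
})

test_that("treatment summaries count producing replicates only", {
  mk <- function(rep, lag) replicate_kinetics(
    ideal_series(lag, 60, 300, times = c(0, lag, lag + 5, lag + 10),
                 replicate = rep))
  reps <- dplyr::bind_rows(mk("r1", 4), mk("r2", 4), mk("r3", 5), mk("r4", 4))
  out <- summarize_treatment(reps)
  expect_equal(out$n, 4)
  expect_equal(out$lag_d_mean, 4.25)
  expect_equal(out$lag_d_sd, 0.5)

  # oleate-like case: one of four produces -> n = 1, no sd
  flat <- replicate_kinetics(make_series(c(0, 10, 20, 30), rep(0, 4),
                                         replicate = "r9"))
  reps2 <- dplyr::bind_rows(mk("r1", 4), flat,
                            dplyr::mutate(flat, replicate = "r10"),
                            dplyr::mutate(flat, replicate = "r11"))
  out2 <- summarize_treatment(reps2)
  expect_equal(out2$n, 1)
  expect_equal(out2$n_replicates, 4)
  expect_equal(out2$lag_d_mean, 4)
  expect_true(is.na(out2$lag_d_sd))

  # nothing produced -> empty summary with n = 0
  out3 <- summarize_treatment(dplyr::bind_rows(flat))
  expect_equal(out3$n, 0)
  expect_true(is.na(out3$rate_uM_per_d_mean))
})

test_that("noiseless aligned series are recovered exactly", {
  lag <- 4; rate <- 60; smax <- 360
  onset <- lag + smax / rate
  s <- ideal_series(lag, rate, smax, times = c(0, 2, lag, 6, 8, onset, 12, 14))
  k <- replicate_kinetics(s, cod_dose = 494, mass_dose = 0.38)
  expect_equal(k$lag_d, lag)
  expect_equal(k$rate_uM_per_d, rate)
  expect_equal(k$max_sulfide_uM, smax)
  expect_equal(k$efficiency_uM_per_mgL_COD, smax / 494)
  expect_equal(k$yield_mM_per_g, smax / 1000 / 0.38)
})
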