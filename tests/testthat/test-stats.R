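test_that("separated samples give the textbook one-sided enumeration p", {
  t <- mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8), alternative = "less")
  expect_equal(unname(t$statistic), 0)
  expect_equal(t$p_value, 1 / 70)
  # symmetric direction
  t2 <- mann_whitney(c(5, 6, 7, 8), c(1, 2, 3, 4), alternative = "greater")
  expect_equal(unname(t2$statistic), 16)
  expect_equal(t2$p_value, 1 / 70)
})

test_that("identical exchangeable samples are maximally non-significant", {
  t <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_equal(t$p_value, 1)
  expect_equal(unname(t$statistic), 4.5)  # all ties: U = n1 n2 / 2
})

test_that("exact p equals brute-force enumeration for all sizes <= 5", {
  set.seed(20)
  for (i in 1:200) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    # integer draws produce frequent ties; midranks must agree with oracle
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    alt <- sample(c("two.sided", "less", "greater"), 1)
    got <- mann_whitney(x, y, alternative = alt)
    expect_equal(unname(got$statistic), oracle_u(x, y))
    expect_equal(got$p_value, oracle_mw_p(x, y, alt),
                 info = sprintf("x=%s y=%s alt=%s", toString(x), toString(y), alt))
  }
})

test_that("exact p matches wilcox.test where it is also exact (no ties)", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(4); y <- rnorm(4)
    got <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(got$statistic), unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("U(x,y) + U(y,x) = n1 n2 and p is monotone-transform invariant", {
  set.seed(22)
  for (i in 1:30) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(unname(mann_whitney(x, y)$statistic) +
                   unname(mann_whitney(y, x)$statistic), 20)
    p0 <- mann_whitney(x, y)$p_value
    expect_equal(mann_whitney(exp(x), exp(y))$p_value, p0)
    expect_equal(mann_whitney(2 * x + 7, 2 * y + 7)$p_value, p0)
  }
})

test_that("normal approximation tracks the exact p at moderate n", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    pe <- mann_whitney(x, y, exact = TRUE)$p_value
    pa <- mann_whitney(x, y, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.05)
  }
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "sulfidogen_domain_error")
})

test_that("Kendall tau-b: perfect orderings, oracle agreement, exact p", {
  expect_equal(unname(kendall_tau(1:3, 1:3)$statistic), 1)
  expect_equal(unname(kendall_tau(1:3, c(3, 2, 1))$statistic), -1)
  set.seed(24)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    got <- kendall_tau(x, y)
    # base R as the independent tau-b implementation
    ref <- suppressWarnings(stats::cor(x, y, method = "kendall"))
    if (!is.na(ref)) expect_equal(unname(got$statistic), ref)
    # exact permutation p cross-checked against cor.test where tie-free
    if (!anyDuplicated(x) && !anyDuplicated(y)) {
      reft <- stats::cor.test(x, y, method = "kendall", exact = TRUE)
      expect_equal(got$p_value, reft$p.value)
    }
  }
  expect_error(kendall_tau(1:3, 1:4), class = "sulfidogen_domain_error")
})

test_that("tau normal approximation is sane at larger n", {
  set.seed(25)
  x <- rnorm(30); y <- x + rnorm(30, sd = 2)
  exact_like <- stats::cor.test(x, y, method = "kendall")$p.value
  got <- kendall_tau(x, y)$p_value
  expect_lt(abs(got - exact_like), 0.02)
})

test_that("pairwise comparison table covers producing treatments", {
  set.seed(26)
  reps <- dplyr::bind_rows(lapply(c(4, 4.5, 5, 4.2), function(l) {
    replicate_kinetics(ideal_series(l, 60, 300,
                                    times = c(0, l, l + 5, l + 10),
                                    treatment = "A",
                                    replicate = paste0("a", l)))
  }))
  reps_b <- dplyr::bind_rows(lapply(c(14, 15, 15.5, 14.2), function(l) {
    replicate_kinetics(ideal_series(l, 80, 900,
                                    times = c(0, l, l + 5, l + 12),
                                    treatment = "B",
                                    replicate = paste0("b", l)))
  }))
  tab <- pairwise_mann_whitney(dplyr::bind_rows(reps, reps_b))
  expect_equal(nrow(tab), 3)  # one pair x three parameters
  lagrow <- tab[tab$parameter == "lag_d", ]
  expect_equal(lagrow$p_value, 2 / 70)  # complete separation, two-sided
  expect_true(lagrow$significant)
})
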