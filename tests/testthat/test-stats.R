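test_that("Mann-Whitney exact p matches full enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  o <- mwu_enum_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic_U, 0)
  expect_equal(o$U, 0)
  expect_equal(r$p_two_sided, 0.1)
  expect_equal(o$p, 0.1)
  expect_equal(r$method, "exact")

  set.seed(15)
  for (rep in 1:20) {
    x <- sample(seq(1, 200), sample(3:6, 1))
    y <- sample(setdiff(seq(201, 400), x), sample(3:6, 1))
    y <- y - 200 + runif(length(y), -0.4, 0.4)  # interleave, keep tie-free
    r <- mann_whitney_u(x, y)
    o <- mwu_enum_oracle(x, y)
    expect_equal(r$statistic_U, o$U)
    expect_equal(r$p_two_sided, o$p, tolerance = 1e-12)
  }
})

test_that("U and p are invariant under strictly increasing transforms", {
  x <- c(0.3, 1.7, 4.4, 9.1); y <- c(0.9, 2.2, 6.3)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(exp(x), exp(y))
  expect_equal(a$statistic_U, b$statistic_U)
  expect_equal(a$p_two_sided, b$p_two_sided)
})

test_that("identical samples give p = 1 and ties trigger the approximation", {
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$method, "normal_approx")
})

test_that("normal approximation tracks the exact p within 0.02 at n = 8 + 8", {
  set.seed(25)
  worst <- 0
  for (rep in 1:200) {
    x <- rnorm(8); y <- rnorm(8, sample(c(0, 0.5, 1.5), 1))
    exact <- mann_whitney_u(x, y)            # 16 <= 16, tie-free: exact
    approx <- mann_whitney_u(x, y, exact_max_n = 0L)
    expect_equal(approx$method, "normal_approx")
    worst <- max(worst, abs(exact$p_two_sided - approx$p_two_sided))
  }
  expect_lte(worst, 0.02)
})

test_that("t test: trivial identity and closed-form oracle", {
  expect_equal(t_test_unpaired(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)
  set.seed(33)
  for (rep in 1:20) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1), 0.5)
    r <- t_test_unpaired(x, y)
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tstat), n1 + n2 - 2)
    expect_equal(r$statistic, tstat, tolerance = 1e-10)
    expect_equal(r$p_two_sided, p, tolerance = 1e-10)
  }
  expect_error(t_test_unpaired(c(1, 1), c(2, 2)), "variance")
})

test_that("two-way ANOVA matches the balanced cell-means oracle", {
  set.seed(44)
  a <- rep(rep(c("u", "v"), each = 3), 4)
  b <- rep(c("p", "q", "r"), 8)
  y <- rnorm(24, ave(seq_len(24) %% 3))
  r <- anova_two_way(y, a, b)
  o <- anova_ss_oracle(y, a, b)
  expect_equal(r$sum_sq[r$term == "A"], o$ss_a, tolerance = 1e-9)
  expect_equal(r$sum_sq[r$term == "B"], o$ss_b, tolerance = 1e-9)
  expect_equal(r$sum_sq[r$term == "A:B"], o$ss_ab, tolerance = 1e-9)
  expect_equal(r$sum_sq[r$term == "Residuals"], o$ss_resid,
               tolerance = 1e-9)
  # SS conservation
  expect_equal(sum(r$sum_sq), o$ss_total, tolerance = 1e-9)
})

test_that("purely additive balanced design has zero interaction SS", {
  a <- rep(c("lo", "hi"), each = 4)
  b <- rep(c("x", "y"), 4)
  eff_a <- ifelse(a == "hi", 2, 0)
  eff_b <- ifelse(b == "y", 5, 0)
  y <- 1 + eff_a + eff_b
  r <- anova_two_way(y, a, b)
  expect_lt(abs(r$sum_sq[r$term == "A:B"]), 1e-18)
  expect_lt(abs(r$sum_sq[r$term == "Residuals"]), 1e-18)
})

test_that("null two-way ANOVA F statistics average near 1", {
  set.seed(55)
  fs <- replicate(300, {
    y <- rnorm(24)
    a <- rep(c("u", "v"), each = 12)
    b <- rep(c("p", "q", "r"), 8)
    anova_two_way(y, a, b)$F[1]
  })
  expect_gt(mean(fs), 0.7)
  expect_lt(mean(fs), 1.4)
})

test_that("Fisher exact: enumeration oracle, symmetry, degenerate margin", {
  r <- fisher_exact_2x2(3, 1, 1, 3)
  o <- fisher_enum_oracle(3, 1, 1, 3)
  expect_equal(r$p_two_sided, o, tolerance = 1e-10)
  expect_equal(r$p_two_sided, 34 / 70, tolerance = 1e-10)
  expect_equal(r$sample_or, 9)

  # transposition: p and OR both unchanged (the OR is transpose-invariant)
  t1 <- fisher_exact_2x2(2, 7, 8, 2)
  t2 <- fisher_exact_2x2(2, 8, 7, 2)
  expect_equal(t1$p_two_sided, t2$p_two_sided, tolerance = 1e-12)
  expect_equal(t1$odds_ratio, t2$odds_ratio, tolerance = 1e-6)

  # row swap leaves p unchanged and inverts the OR
  t3 <- fisher_exact_2x2(8, 2, 2, 7)
  expect_equal(t1$p_two_sided, t3$p_two_sided, tolerance = 1e-12)
  expect_equal(t1$odds_ratio, 1 / t3$odds_ratio, tolerance = 1e-6)

  z <- fisher_exact_2x2(0, 5, 0, 7)
  expect_equal(z$p_two_sided, 1)
  expect_false(z$or_defined)

  # CI brackets the estimate
  ok <- fisher_exact_2x2(10, 3, 4, 9)
  expect_lte(ok$ci_low, ok$odds_ratio)
  expect_gte(ok$ci_high, ok$odds_ratio)
})

test_that("Fisher p oracle agreement on random small tables", {
  set.seed(66)
  for (rep in 1:25) {
    tb <- rpois(4, 4)
    if (sum(tb) == 0) next
    r <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    if (any(c(tb[1] + tb[2], tb[3] + tb[4], tb[1] + tb[3],
              tb[2] + tb[4]) == 0)) {
      expect_equal(r$p_two_sided, 1)
    } else {
      expect_equal(r$p_two_sided,
                   fisher_enum_oracle(tb[1], tb[2], tb[3], tb[4]),
                   tolerance = 1e-9)
    }
  }
})

test_that("carrier frequency formats with half-up rounding", {
  expect_equal(carrier_frequency(13, 17654)$label, "0.07%")
  expect_equal(carrier_frequency(13, 17654)$percent, 0.07)
  expect_equal(carrier_frequency(0, 1000)$label, "0.00%")
  expect_equal(carrier_frequency(1, 4)$label, "25.00%")
  expect_equal(carrier_frequency(1, 800)$label, "0.13%")  # 0.125 rounds up
  expect_error(carrier_frequency(5, 0))
  expect_error(carrier_frequency(5, 4))
})

test_that("U test type-I error is calibrated near the nominal level", {
  set.seed(77)
  rejects <- 0L
  n_rep <- 2000L
  for (i in seq_len(n_rep)) {
    p <- mann_whitney_u(rnorm(50), rnorm(50))$p_two_sided
    if (p < 0.05) rejects <- rejects + 1L
  }
  rate <- rejects / n_rep
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})
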