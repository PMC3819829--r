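test_that("simple regression handles exact and degenerate inputs", {
  f <- simple_regression(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$slope_se, 0)

  f <- simple_regression(c(0, 1, 2, 1), rep(3, 4))
  expect_equal(f$slope, 0)

  expect_error(simple_regression(rep(1, 5), rnorm(5)), "constant")
  expect_error(simple_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("simple regression matches lm() and drops incomplete pairs", {
  set.seed(12)
  for (i in 1:10) {
    x <- rbinom(50, 2, 0.4); y <- rnorm(50, 0.3 * x)
    x[sample(50, 2)] <- NA
    f <- simple_regression(x, y)
    m <- summary(lm(y ~ x))$coefficients
    expect_equal(f$slope, m["x", "Estimate"], tolerance = 1e-10)
    expect_equal(f$slope_se, m["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(f$p_value, m["x", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(f$n_used, 48L)
  }
})

test_that("two-predictor regression isolates mediation limits", {
  set.seed(13)
  n <- 100
  x <- rbinom(n, 2, 0.5); m <- rnorm(n); noise <- rnorm(n)
  # y = m exactly: full mediation limit
  f <- two_predictor_regression(x, m, m)
  expect_equal(f$slope_m, 1, tolerance = 1e-10)
  expect_equal(f$slope_x, 0, tolerance = 1e-10)
  # y = x exactly: no mediation
  f <- two_predictor_regression(x, noise, x)
  expect_equal(f$slope_x, 1, tolerance = 1e-10)
  expect_equal(f$slope_m, 0, tolerance = 1e-10)
  expect_error(two_predictor_regression(x, 2 * x, rnorm(n)), "collinear")
})

test_that("two-predictor regression matches lm() coefficients and SEs", {
  set.seed(14)
  for (i in 1:10) {
    x <- rbinom(60, 2, 0.3); m <- rnorm(60, 0.5 * x); y <- rnorm(60, m + 0.2 * x)
    f <- two_predictor_regression(x, m, y)
    s <- summary(lm(y ~ m + x))$coefficients
    expect_equal(f$slope_m, s["m", "Estimate"], tolerance = 1e-10)
    expect_equal(f$slope_m_se, s["m", "Std. Error"], tolerance = 1e-10)
    expect_equal(f$slope_x, s["x", "Estimate"], tolerance = 1e-10)
    expect_equal(f$slope_x_se, s["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(f$intercept, s["(Intercept)", "Estimate"], tolerance = 1e-8)
  }
})

test_that("Sobel statistic follows the delta-method arithmetic", {
  s <- sobel_statistic(1, 0.1, 1, 0.1)
  expect_equal(s$se, sqrt(0.02), tolerance = 1e-12)
  expect_equal(s$z, 1 / sqrt(0.02), tolerance = 1e-12)

  s <- sobel_statistic(2, 0.5, 3, 1)
  expect_equal(s$se, 2.5)
  expect_equal(s$z, 2.4)
  expect_equal(s$p_analytic, 2 * pnorm(-2.4), tolerance = 1e-12)

  s0 <- sobel_statistic(0, 0.2, 1.3, 0.4)
  expect_equal(s0$indirect, 0)
  expect_equal(s0$z, 0)
  expect_equal(s0$p_analytic, 1)

  s_inf <- sobel_statistic(1, 0, 2, 0)
  expect_identical(s_inf$z, Inf)
  expect_equal(s_inf$p_analytic, 0)
  s_null <- sobel_statistic(0, 0, 5, 0)
  expect_equal(s_null$z, 0)
  expect_equal(s_null$p_analytic, 1)
})

test_that("Sobel z and p are invariant to rescaling the mediator", {
  set.seed(15)
  n <- 80
  x <- rbinom(n, 2, 0.4); m <- rnorm(n, 0.5 * x); y <- rnorm(n, 0.6 * m)
  base <- mediation_test(x, m, y)
  for (c_ in c(-3, 0.01, 7)) {
    sc <- mediation_test(x, c_ * m, y)
    expect_equal(sc$sobel$z, base$sobel$z, tolerance = 1e-9)
    expect_equal(sc$sobel$p_analytic, base$sobel$p_analytic, tolerance = 1e-9)
    expect_equal(sc$fit_xm$slope, c_ * base$fit_xm$slope, tolerance = 1e-9)
    expect_equal(sc$fit_y$slope_m, base$fit_y$slope_m / c_, tolerance = 1e-9)
  }
})

test_that("indirect-effect estimate is unbiased on planted-effect data", {
  set.seed(16)
  reps <- 300; n <- 150
  est <- replicate(reps, {
    x <- rbinom(n, 2, 0.3)
    m <- 0.5 * x + rnorm(n)
    y <- 0.7 * m + rnorm(n)
    r <- mediation_test(x, m, y)
    r$sobel$indirect
  })
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.35), 2 * mc_se + 1e-9)
})
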