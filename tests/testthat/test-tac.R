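# Exponential time-activity fitting, model selection and integration.

test_that("noiseless exponentials are recovered exactly", {
  t <- c(0, 4, 12, 24, 48, 96)
  f1 <- fit_exponentials(t, 1000 * exp(-0.1 * t))
  expect_equal(unname(coef(f1)), c(1000, 0.1), tolerance = 1e-8)
  expect_equal(f1$dof, 4L)

  t2 <- seq(0, 150, length.out = 10)
  a2 <- 800 * exp(-0.3 * t2) + 200 * exp(-0.02 * t2)
  f2 <- fit_exponentials(t2, a2, 2)
  expect_equal(unname(coef(f2)), c(800, 200, 0.3, 0.02), tolerance = 1e-3)
})

test_that("fit preconditions and degenerate shapes are handled", {
  expect_error(fit_exponentials(c(0, 1, 2, 3), exp(-(0:3)), 2),
               "at least 5 points")
  expect_error(fit_exponentials(c(0, 1, 1, 2), rep(1, 4)), "increasing")
  expect_warning(
    fit_exponentials(c(0, 2, 8, 20, 60), 100 * exp(-0.1 * c(0, 2, 8, 20, 60)),
                     2),
    "3 data points per phase")
  # an uptake-shaped curve has a negative amplitude: phases merge
  t <- seq(1, 120, length.out = 12)
  a <- 500 * (exp(-0.02 * t) - exp(-0.5 * t))
  expect_warning(fm <- fit_exponentials(t, a, 2), "negative fitted amplitude")
  expect_identical(fm$model$n_phases, 1L)
})

test_that("extra-sum-of-squares F statistic matches the hand formula", {
  dat <- data.frame(time_h = 1:12, activity_MBq = exp(-(1:12) / 10))
  fs <- fake_exp_fit(rss = 2, dof = 10, n_phases = 1, data = dat)
  fc <- fake_exp_fit(rss = 1, dof = 8, n_phases = 2, data = dat)
  res <- f_test_select(fs, fc)
  expect_equal(res$F, 4.0)  # ((2-1)/2) / (1/8)
  expect_equal(res$dfn, 2)
  expect_equal(res$dfd, 8)

  tie <- f_test_select(fs, fake_exp_fit(2, 8, 2, dat))
  expect_equal(tie$F, 0)
  expect_identical(tie$chosen_label, "simple")

  expect_error(f_test_select(fc, fs), "more phases")
  expect_error(
    f_test_select(fake_exp_fit(1, 10, 1, dat), fake_exp_fit(2, 8, 2, dat)),
    "inconsistent")
  dat2 <- dat
  dat2$activity_MBq <- dat2$activity_MBq * 2
  expect_error(f_test_select(fs, fake_exp_fit(1, 8, 2, dat2)), "identical")
})

test_that("F test prefers the bi-exponential on genuinely biphasic data", {
  t <- seq(0, 120, length.out = 20)
  set.seed(5)
  a <- (700 * exp(-0.25 * t) + 300 * exp(-0.015 * t)) * (1 + rnorm(20, 0, 0.01))
  f1 <- fit_exponentials(t, a, 1)
  f2 <- fit_exponentials(t, a, 2)
  res <- f_test_select(f1, f2)
  expect_identical(res$chosen_label, "complex")
  expect_lt(res$p, 1e-6)
})

test_that("AICc selection breaks ties toward fewer phases", {
  t <- seq(0, 96, length.out = 12)
  a <- 1000 * exp(-0.08 * t)
  f1 <- fit_exponentials(t, a, 1)
  expect_identical(aic_select(list(f1)), f1)
  f2 <- suppressWarnings(tryCatch(fit_exponentials(t, a, 2),
                                  error = function(e) NULL))
  if (!is.null(f2)) {
    best <- aic_select(list(f1, f2))
    expect_identical(best$model$n_phases, 1L)
  }
  other <- fit_exponentials(t + 1, a, 1)
  expect_error(aic_select(list(f1, other)), "same data")
})

test_that("AICc picks the mono-exponential on mono truth in >= 90% of runs", {
  t <- seq(1, 96, length.out = 20)
  set.seed(31)
  wins <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    atrue <- 1000 * exp(-0.05 * t)
    a <- atrue * (1 + rnorm(20, 0, 0.02))
    sg <- 0.02 * atrue
    f1 <- fit_exponentials(t, a, 1, sg, "inverse_variance")
    f2 <- tryCatch(
      suppressWarnings(fit_exponentials(t, a, 2, sg, "inverse_variance")),
      error = function(e) NULL)
    cand <- if (is.null(f2)) list(f1) else list(f1, f2)
    if (aic_select(cand)$model$n_phases == 1L) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.90)
})

test_that("closed-form time-integrated activity matches quadrature", {
  expect_equal(time_integrated_activity(exp_model(1, 1)), 1)
  set.seed(17)
  for (i in 1:10) {
    k <- sample(1:3, 1)
    m <- exp_model(runif(k, 50, 1500), runif(k, 0.005, 0.5))
    expect_equal(time_integrated_activity(m), tia_quadrature(m),
                 tolerance = 1e-6)
    tf <- sort(runif(2, 0, 200))
    expect_equal(time_integrated_activity(m, tf[1], tf[2]),
                 tia_quadrature(m, tf[1], tf[2]), tolerance = 1e-6)
  }
})

test_that("time-integrated activity is monotone in amplitude and half-life", {
  m <- exp_model(c(800, 200), c(0.3, 0.02))
  up_amp <- exp_model(c(900, 200), c(0.3, 0.02))
  up_half <- exp_model(c(800, 200), c(0.3, 0.015))
  expect_gt(time_integrated_activity(up_amp), time_integrated_activity(m))
  expect_gt(time_integrated_activity(up_half), time_integrated_activity(m))
})

test_that("coverage fraction flags inadequate sampling windows", {
  m <- exp_model(100, 0.1)
  expect_equal(as.numeric(coverage_fraction(m, 0, Inf)), 1)
  # three effective half-lives leave 1/8 of the integral uncovered
  t3 <- 3 * log(2) / 0.1
  cf <- coverage_fraction(m, 0, t3)
  expect_equal(as.numeric(cf), 0.875)
  expect_true(attr(cf, "meets_recommendation"))
  short <- coverage_fraction(m, 0, log(2) / 0.1)
  expect_false(attr(short, "meets_recommendation"))
  # bi-exponential against the quadrature oracle
  b <- exp_model(c(500, 100), c(0.2, 0.01))
  expect_equal(as.numeric(coverage_fraction(b, 5, 150)),
               tia_quadrature(b, 5, 150) / tia_quadrature(b),
               tolerance = 1e-6)
})

test_that("fit covariance propagates into a finite TIA uncertainty", {
  t <- seq(0, 96, length.out = 15)
  set.seed(9)
  a <- 1000 * exp(-0.05 * t) * (1 + rnorm(15, 0, 0.02))
  f <- fit_exponentials(t, a, 1)
  s <- tia_uncertainty(f)
  expect_true(is.finite(s))
  expect_gt(s, 0)
  # uncertainty is a few percent of the integral at 2% point noise
  expect_lt(s / time_integrated_activity(f), 0.2)
})
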