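# Whole-body probe measurements -> retention curve.

test_that("net count rate follows Poisson counting statistics", {
  r <- suppressWarnings(net_count_rate(500, 600))
  expect_equal(r$rate_cps, 500 / 600)
  # 500 counts sit just under the 5% relative-noise criterion
  expect_equal(r$sigma_cps / r$rate_cps, 1 / sqrt(500))
  expect_lt(r$sigma_cps / r$rate_cps, 0.05)
  expect_true(r$low_counts)

  r2 <- net_count_rate(1000, 60, 1)
  expect_equal(r2$rate_cps, 1000 / 60 - 1)
  expect_equal(r2$sigma_cps, sqrt(1000) / 60)
  expect_false(r2$low_counts)

  expect_warning(r0 <- net_count_rate(0, 60), "500")
  expect_equal(r0$rate_cps, 0)
  expect_equal(r0$sigma_cps, 0)

  expect_warning(bad <- net_count_rate(1000, 10, 200), "background exceeds")
  expect_false(bad$valid)
  expect_error(net_count_rate(100, 0), "duration")
})

test_that("minimum counts for a target precision", {
  expect_identical(min_counts_for_precision(0.05), 400L)
  expect_identical(min_counts_for_precision(0.0447), 501L)
  expect_identical(min_counts_for_precision(0.01), 10000L)
  expect_error(min_counts_for_precision(0))
  expect_error(min_counts_for_precision(1))
})

test_that("geometric mean of opposed views", {
  expect_equal(geometric_mean_rate(4, 9), 6)
  set.seed(3)
  x <- runif(20, 0.1, 1000)
  expect_equal(geometric_mean_rate(x, x), x)
  expect_error(geometric_mean_rate(10, 0), "non-positive")
})

make_readings <- function(times, counts, duration = 60, view = "single",
                          bkg_counts = 0, bkg_duration = 600) {
  rbind(
    data.frame(time_h = -1, counts = bkg_counts, duration_s = bkg_duration,
               view = "single", is_background = TRUE),
    data.frame(time_h = times, counts = counts, duration_s = duration,
               view = view, is_background = FALSE))
}

test_that("retention curve normalises to the pre-void baseline", {
  # baseline 100 cps at t=0, 50 cps at 24 h, admin 6893 MBq -> 3446.5 MBq
  rd <- make_readings(c(0, 24), c(6000, 3000))
  rc <- build_retention_curve(rd, 6893)
  expect_equal(rc$activity_MBq, c(6893, 3446.5))
  expect_equal(attr(rc, "baseline_rate_cps"), 100)
  # retained fraction at baseline is exactly 1, all fractions non-negative
  expect_equal(rc$activity_MBq[1], 6893)
  expect_true(all(rc$activity_MBq >= 0))
})

test_that("residual activity from a prior therapy is subtracted", {
  # baseline 110 cps, reading 60 cps, residual 10 -> fraction 0.5
  rd <- make_readings(c(0, 24), c(6600, 3600))
  rc <- build_retention_curve(rd, 1000, residual_rate_cps = 10)
  expect_equal(rc$activity_MBq[2] / rc$activity_MBq[1], 0.5)
})

test_that("replicate readings average and shrink sigma by sqrt(k)", {
  rd1 <- make_readings(c(0, 24), c(60000, 30000))
  rc1 <- build_retention_curve(rd1, 1000)
  k <- 4L
  rd4 <- make_readings(c(0, rep(24, k) + seq(0, 0.2, length.out = k)),
                       c(60000, rep(30000, k)))
  rc4 <- build_retention_curve(rd4, 1000)
  expect_identical(nrow(rc4), 2L)  # replicates collapsed to one point
  expect_equal(rc4$sigma_MBq[2], rc1$sigma_MBq[2] / sqrt(k))
  expect_equal(rc4$activity_MBq[2], rc1$activity_MBq[2])
})

test_that("retention curve is invariant to count-duration choices", {
  rd_a <- make_readings(c(0, 24, 48), c(6000, 3000, 1500), duration = 60)
  rd_b <- make_readings(c(0, 24, 48), c(12000, 6000, 3000), duration = 120)
  expect_equal(build_retention_curve(rd_a, 500)$activity_MBq,
               build_retention_curve(rd_b, 500)$activity_MBq)
})

test_that("AP/PA pairs combine by geometric mean", {
  rd <- rbind(
    data.frame(time_h = -1, counts = 0, duration_s = 600, view = "single",
               is_background = TRUE),
    data.frame(time_h = 0, counts = 36000, duration_s = 60,
               view = "single", is_background = FALSE),
    data.frame(time_h = 24, counts = 24000, duration_s = 60, view = "AP",
               is_background = FALSE),
    data.frame(time_h = 24.1, counts = 13500, duration_s = 60, view = "PA",
               is_background = FALSE))
  rc <- build_retention_curve(rd, 1000)
  # geomean(400, 225) = 300 cps against a 600 cps baseline
  expect_equal(rc$activity_MBq[2], 500)
  expect_identical(attr(rc, "view_used")[2], "geometric_mean")
})

test_that("each reading uses the most recent prior background", {
  rd <- rbind(
    data.frame(time_h = c(-1, 20), counts = c(0, 60000),
               duration_s = c(600, 600), view = "single",
               is_background = c(TRUE, TRUE)),
    data.frame(time_h = c(0, 24), counts = c(6000, 9000),
               duration_s = 60, view = "single", is_background = FALSE))
  rc <- build_retention_curve(rd, 1000)
  # second reading corrected with the 100 cps background taken at 20 h
  expect_equal(rc$activity_MBq[2], 1000 * (150 - 100) / 100)
})

test_that("degenerate probe inputs are rejected or flagged", {
  no_bkg <- data.frame(time_h = c(0, 24), counts = c(600, 300),
                       duration_s = 60, view = "single",
                       is_background = FALSE)
  expect_error(build_retention_curve(no_bkg, 1000), "background")
  only_bkg <- data.frame(time_h = -1, counts = 0, duration_s = 600,
                         view = "single", is_background = TRUE)
  expect_error(build_retention_curve(only_bkg, 1000), "baseline")
  rising <- make_readings(c(0, 24), c(3000, 6000))
  expect_warning(build_retention_curve(rising, 1000), "contamination")
})

test_that("synthetic probe series round-trips through the curve builder", {
  g <- gen_probe_series(6893, seed = 11)
  rc <- suppressWarnings(build_retention_curve(g$readings, 6893))
  expect_equal(nrow(rc), length(g$truth$schedule_h))
  frac_est <- rc$activity_MBq / rc$activity_MBq[1]
  # counts ~2e4 at baseline: Poisson noise well under 5% per point
  expect_lt(max(abs(frac_est - g$truth$fractions)), 0.05)
})
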