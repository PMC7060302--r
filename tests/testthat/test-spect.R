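# SPECT VOI quantification: TEW, Chang, VOIs, thresholds, block extrema.

test_that("triple-energy-window correction matches the hand formula", {
  win <- energy_windows()  # 20% peak, 6% scatter at 364 keV
  expect_equal(win$peak[["width"]], 72.8)
  expect_equal(win$lower[["width"]], 21.84)
  expect_equal(tew_correct(1000, 0, 0, win), 1000)
  # hand evaluation: 1000 - 36.4 * (120 + 60) / 21.84 = 700
  expect_equal(tew_correct(1000, 120, 60, win), 700, tolerance = 1e-9)
  expect_equal(tew_correct(10, 500, 500, win), 0)  # clamped
})

test_that("TEW correction is linear above the clamp and element-wise", {
  win <- energy_windows()
  a <- tew_correct(2000, 100, 80, win)
  expect_equal(tew_correct(2 * 2000, 2 * 100, 2 * 80, win), 2 * a)
  arr <- array(c(1000, 10), dim = c(2, 1, 1))
  sc <- tew_correct(arr, array(120, dim(arr)), array(60, dim(arr)), win)
  expect_equal(dim(sc), dim(arr))
  expect_equal(sc[1, 1, 1], 700)
  expect_equal(sc[2, 1, 1], 0)
  expect_true(all(sc >= 0))
})

test_that("energy windows validate ordering and overlap", {
  expect_error(energy_windows(peak_frac = -0.1), "positive")
  bad <- energy_windows()
  bad$lower["center"] <- 360  # overlaps the main window
  expect_error(validate_energy_windows(bad), "overlap")
})

test_that("Chang correction is the identity at mu = 0 and >= 1 inside", {
  img <- voxel_image(array(runif(16 * 16), c(16, 16, 1)), 8)
  mask <- make_circle_mask(16, 8, 50)
  out0 <- chang_attenuation_correct(img, mask, mu_per_cm = 0)
  expect_equal(out0$data, img$data)
  out <- chang_attenuation_correct(img, mask, mu_per_cm = 0.11,
                                   n_angles = 32)
  sel <- mask & img$data > 0
  expect_true(all(out$data[sel] >= img$data[sel]))
  expect_equal(out$data[!mask], img$data[!mask])
  expect_true("chang" %in% out$corrections)
})

test_that("Chang factor at the centre of a circular slice is exp(mu R)", {
  # radius 100 mm, voxel 2 mm; every ray from the centre has length R
  mask <- make_circle_mask(128, 2, 100, centre_vox = c(64, 64))
  f <- chang_factors(mask[, , 1], 2, matrix(c(64, 64), 1),
                     mu_per_cm = 0.11, n_angles = 64)
  expect_equal(f, exp(0.11 * 10), tolerance = 0.01)
})

test_that("64-ray Chang factors agree with a dense-ray oracle off-centre", {
  mask <- make_circle_mask(64, 4, 100, centre_vox = c(32, 32))
  pts <- matrix(c(42, 35, 20, 44), ncol = 2, byrow = TRUE)
  f64 <- chang_factors(mask[, , 1], 4, pts, 0.11, 64)
  f4096 <- chang_factors(mask[, , 1], 4, pts, 0.11, 4096)
  expect_equal(f64, f4096, tolerance = 0.02)
})

test_that("VOI count rate sums in-mask rates and reports the volume", {
  img <- voxel_image(array(1, c(10, 10, 10)), 10)  # 1 ml voxels
  mask <- array(FALSE, c(10, 10, 10))
  mask[1:10, 1:10, 1:10] <- TRUE
  v <- voi_count_rate(img, mask)
  expect_equal(v$rate_cps, 1000)
  expect_equal(v$volume_ml, 1000)
  one <- array(FALSE, c(10, 10, 10))
  one[3, 4, 5] <- TRUE
  img$data[3, 4, 5] <- 7.5
  expect_equal(voi_count_rate(img, one)$rate_cps, 7.5)
  expect_error(voi_count_rate(img, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("average projection rate over views and durations", {
  expect_equal(average_projection_rate(rep(1000, 64), 10), 100)
  expect_equal(average_projection_rate(500, 5), 100)
  # mixed durations against a hand sum
  expect_equal(average_projection_rate(c(1000, 3000), c(10, 20)),
               (100 + 150) / 2)
  stack <- array(1, dim = c(4, 4, 3))  # 16 counts per view
  expect_equal(average_projection_rate(stack, 8), 2)
})

test_that("activity conversion applies Q, recovery and dead time", {
  expect_equal(activity_from_voi(29.2, 29.2, 1, 1), 1)
  expect_equal(activity_from_voi(29.2, 29.2, 0.5, 1.2), 2.4)
  expect_error(activity_from_voi(10, 29.2, 0), "positive")
  # exact inversion against the forward scaling
  set.seed(8)
  A <- runif(20, 0.1, 500)
  Q <- 29.2
  R <- runif(20, 0.2, 1)
  DTF <- runif(20, 1, 1.3)
  expect_equal(activity_from_voi(Q * R * A / DTF, Q, R, DTF), A)
})

test_that("adaptive threshold recovers a hard-edged sphere volume", {
  sp <- data.frame(cx_mm = 65.3, cy_mm = 62.9, cz_mm = 64.7,
                   diameter_mm = 43.4, conc_cps_per_ml = 10)
  g <- gen_sphere_phantom(c(32, 32, 32), 4, sp, psf_fwhm_mm = 0, seed = 7)
  mk <- adaptive_threshold_mask(g$image, 42.8, c(16, 16, 16))
  vox_ml <- voxel_volume_ml(g$image)
  expect_lt(abs(attr(mk, "volume_ml") - 42.8), vox_ml)
  expect_equal(sum(mk) * vox_ml, attr(mk, "volume_ml"))
  # near-zero threshold captures the full object support
  full <- adaptive_threshold_mask(g$image, sum(g$image$data > 0) * vox_ml,
                                  c(16, 16, 16))
  expect_gte(sum(full), sum(g$image$data > 0.5 * max(g$image$data)))
  expect_error(adaptive_threshold_mask(g$image, 42.8, c(1, 1, 1)),
               "background")
  expect_error(adaptive_threshold_mask(g$image, 1e6, c(16, 16, 16)),
               "unreachable")
})

test_that("block-27 extrema match an exhaustive brute-force scan", {
  img_u <- voxel_image(array(3.7, c(5, 5, 5)), 4)
  b <- block27_extrema(img_u, array(TRUE, c(5, 5, 5)))
  expect_equal(b$max_block_mean, 3.7)
  expect_equal(b$min_block_mean, 3.7)

  spike <- array(0, c(7, 7, 7))
  spike[4, 4, 4] <- 27
  bs <- block27_extrema(voxel_image(spike, 4), array(TRUE, c(7, 7, 7)))
  expect_equal(bs$max_block_mean, 1)  # 27 / 27
  expect_equal(bs$min_block_mean, 0)

  set.seed(13)
  for (i in 1:20) {
    arr <- array(rnorm(6^3), c(6, 6, 6))
    mask <- array(runif(6^3) > 0.2, c(6, 6, 6))
    mask[2:5, 2:5, 2:5] <- TRUE  # guarantee an interior block
    got <- block27_extrema(voxel_image(arr, 4), mask)
    want <- block27_brute(arr, mask)
    expect_equal(got$max_block_mean, want$max)
    expect_equal(got$min_block_mean, want$min)
  }
  expect_error(block27_extrema(voxel_image(array(1, c(4, 4, 4)), 4),
                               array(FALSE, c(4, 4, 4))),
               "interior")
})

test_that("NIfTI round trip preserves values and voxel sizes", {
  img <- voxel_image(array(rpois(8 * 8 * 4, 20), c(8, 8, 4)),
                     c(4.67, 4.67, 4.67))
  path <- tempfile(fileext = ".nii.gz")
  write_voxel_image(img, path)
  back <- read_voxel_image(path)
  expect_equal(back$data, img$data, ignore_attr = TRUE)
  expect_equal(back$voxel_mm, img$voxel_mm, tolerance = 1e-5)
  unlink(path)
})

test_that("the measurement chain recovers activity from a blurred sphere", {
  # forward: known activities -> blurred phantoms -> measured recovery
  # curve; inverse: VOI rate of a held-out sphere -> fitted R -> activity
  Q <- 29.2
  conc_MBq_ml <- 0.3
  phantom_R <- function(diam) {
    sp <- data.frame(cx_mm = 64.7, cy_mm = 63.1, cz_mm = 64.3,
                     diameter_mm = diam, conc_cps_per_ml = Q * conc_MBq_ml)
    g <- gen_sphere_phantom(c(32, 32, 32), 4, sp, psf_fwhm_mm = 15,
                            seed = 21)
    tr <- g$truth$spheres[[1]]
    A_true <- conc_MBq_ml * tr$volume_ml
    v <- voi_count_rate(g$image, tr$mask)
    list(R = recovery_coefficient(v$rate_cps, Q, A_true),
         vol = tr$volume_ml, rate = v$rate_cps, A_true = A_true)
  }
  cal <- lapply(c(20, 28, 36, 52, 64, 80), phantom_R)
  rc <- fit_recovery_curve(vapply(cal, `[[`, 1, "vol"),
                           vapply(cal, `[[`, 1, "R"))
  held_out <- phantom_R(44)
  A_est <- activity_from_voi(held_out$rate, Q,
                             interpolate_recovery(rc, held_out$vol), 1)
  expect_equal(A_est, held_out$A_true, tolerance = 0.05)
})
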