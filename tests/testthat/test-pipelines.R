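# Orchestration pipelines and file IO.

test_that("whole-body pipeline matches the closed form on mono-exp truth", {
  g <- gen_probe_series(6893, phase_fractions = 1, lambdas_per_h = 0.02,
                        counter_sensitivity_cps_per_MBq = 0.1,
                        background_cps = 0, seed = 12)
  rep <- suppressWarnings(wb_dose(g$readings, 6893, 17.5))
  tia_true <- 6893 / 0.02
  expect_equal(rep$tia_MBq_h, tia_true, tolerance = 0.03)
  expect_equal(rep$dose_Gy, tia_true * s_wb_from_mass(17.5)$value,
               tolerance = 0.03)
  expect_equal(rep$red_marrow_Gy, rep$dose_Gy / 1.6)
  expect_true(rep$coverage_ok)
})

test_that("whole-body pipeline surfaces stage errors and plans fractions", {
  bad <- data.frame(time_h = c(0, 24), counts = c(600, 300),
                    duration_s = 60, view = "single",
                    is_background = FALSE)
  expect_error(suppressWarnings(wb_dose(bad, 6893, 17.5)), "probe stage")
  g <- gen_probe_series(6893, seed = 12)
  rep <- suppressWarnings(
    wb_dose(g$readings, 6893, 17.5, target_Gy = 4, n_fractions = 2))
  expect_equal(rep$plan$next_fraction_MBq,
               plan_next_fractions(6893, rep$dose_Gy, 4, 2))
  # F test picked the bi-exponential on the bi-exponential generator
  expect_identical(rep$fit$model$n_phases, 2L)
})

test_that("camera characterisation recovers the generator truth", {
  acts <- seq(10, 400, length.out = 20)
  low <- gen_deadtime_series(acts, 170, 12.8e-6, noise_cv = 0.01, seed = 8)
  high <- gen_deadtime_series(acts, 170, 0.47e-6, noise_cv = 0.01, seed = 9)
  rec_v <- c(2, 6, 16, 42, 110, 220)
  Q_true <- 29.2
  rec_R <- 1 * rec_v^1.4 / (rec_v^1.4 + 6^1.4)
  recovery <- data.frame(insert_volume_ml = rec_v,
                         voi_rate_cps = Q_true * 2 * rec_R,
                         true_activity_MBq = 2)
  cam <- characterise_camera(
    deadtime = list(low = low$series, high = high$series),
    calibration = list(voi_rate_cps = 438, activity_conc_MBq_per_ml = 0.015,
                       voi_volume_ml = 1000,
                       sub_voi_rates = c(0.99, 1.0, 1.01)),
    recovery = recovery, mode_switch_cps = 20000)
  expect_equal(cam$Q, Q_true)
  expect_equal(cam$tau_low_s, 12.8e-6, tolerance = 0.02)
  expect_equal(cam$tau_high_s, 0.47e-6, tolerance = 0.1)
  expect_equal(cam$recovery$v50, 6, tolerance = 0.05)
  expect_true(attr(cam, "qc")$uniformity$pass)
})

test_that("lesion pipeline reproduces activities through the camera model", {
  cam <- camera_model(29.2, tau_low_s = 12.8e-6, tau_high_s = 0.47e-6,
                      mode_switch_cps = 20000)
  # noiseless VOI rates generated from a known activity curve
  A0 <- 140
  lam <- log(2) / 120
  tt <- c(48, 120, 168)
  A_t <- A0 * exp(-lam * tt)
  voi <- data.frame(scan_time_h = tt, rate_cps = 29.2 * A_t,
                    volume_ml = 42.8)
  rep <- lesion_dose(voi, cam, mass_g = 42.8,
                     s_model = power_law_s(0.031, -0.981, "mGy/(MBq.s)",
                                           "g"))
  expect_equal(rep$tia_MBq_h, A0 / lam, tolerance = 1e-6)
  expect_equal(rep$s_value$units, "Gy/(MBq.h)")
  expect_equal(rep$dose_Gy,
               (A0 / lam) * 0.031 * 42.8^-0.981 * 3.6, tolerance = 1e-6)
  expect_warning(
    lesion_dose(voi[1:2, ], cam, 42.8,
                s_model = s_value(7.8e-4, "mGy/(MBq.s)")),
    "fewer than 3 scans")
})

test_that("prepared activities and fixed S values are accepted directly", {
  g <- gen_lesion_tac(1010, 41.43, noise_cv = 0, seed = 1)
  voi <- data.frame(scan_time_h = g$tac$time_h,
                    activity_MBq = g$tac$activity_MBq)
  rep <- lesion_dose(voi, mass_g = 711,
                     s_model = s_value(0.49e-4, "mGy/(MBq.s)"),
                     region = "liver")
  expect_equal(rep$tia_MBq_h, g$truth$tia_MBq_h, tolerance = 1e-6)
  expect_equal(rep$dose_Gy, g$truth$tia_MBq_h * 0.49e-4 * 3.6,
               tolerance = 1e-6)
})

test_that("camera model JSON round trip", {
  v <- c(1, 2, 5, 10, 30, 60, 120, 220)
  rc <- fit_recovery_curve(v, v^1.5 / (v^1.5 + 5^1.5))
  cam <- camera_model(29.2, recovery = rc, tau_low_s = 12.8e-6,
                      tau_high_s = 0.47e-6, mode_switch_cps = 20000)
  path <- tempfile(fileext = ".json")
  write_camera_model(cam, path)
  back <- read_camera_model(path)
  expect_equal(back$Q, cam$Q)
  expect_equal(back$tau_low_s, cam$tau_low_s)
  expect_equal(back$mode_switch_cps, cam$mode_switch_cps)
  expect_equal(interpolate_recovery(back$recovery, c(3, 20, 100)),
               interpolate_recovery(cam$recovery, c(3, 20, 100)))
  unlink(path)
})

test_that("probe CSV and config files parse into pipeline inputs", {
  probe_path <- system.file("extdata", "example_probe.csv",
                            package = "mibgdose")
  cfg_path <- system.file("extdata", "example_config.yaml",
                          package = "mibgdose")
  cfg <- read_run_config(cfg_path)
  readings <- read_probe_csv(probe_path, cfg$patient$admin_datetime)
  expect_true(any(readings$is_background))
  expect_true(all(readings$time_h[!readings$is_background] >= 0))
  rep <- suppressWarnings(
    wb_dose(readings, cfg$patient$admin_activity_MBq, cfg$patient$mass_kg,
            sigma_mass_kg = cfg$patient$sigma_mass_kg,
            target_Gy = cfg$protocol$target_wb_dose_Gy,
            n_fractions = cfg$protocol$n_fractions))
  expect_gt(rep$dose_Gy, 0)
  expect_gt(rep$plan$next_fraction_MBq, 0)
})

test_that("dose reports serialise to JSON-ready lists", {
  g <- gen_probe_series(6893, seed = 12)
  rep <- suppressWarnings(wb_dose(g$readings, 6893, 17.5))
  lst <- report_as_list(rep)
  expect_identical(lst$kind, "whole_body")
  expect_equal(lst$dose_Gy, rep$dose_Gy)
  path <- tempfile(fileext = ".json")
  write_report_json(lst, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$dose_Gy, rep$dose_Gy)
  expect_identical(back$provenance$tool, "mibgdose")
  unlink(path)
})
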