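# Orchestration of the full dosimetry workflow: whole-body dose from probe
# readings, camera characterisation from phantom series, and lesion/organ
# dose from VOI measurements. These are the functions the command-line
# interface wraps.

#' Whole-body dose from probe readings
#'
#' Runs the full whole-body chain: retention curve from raw readings,
#' mono- vs bi-exponential fit compared by the extra-sum-of-squares F
#' test, closed-form time-integrated activity, mass-derived S value and
#' the MIRD dose, with first-order uncertainties and the measurement
#' coverage fraction. Optionally plans the remaining fractions.
#'
#' @param readings probe readings data.frame (see
#'   [build_retention_curve()]).
#' @param admin_activity_MBq net administered activity (MBq).
#' @param mass_kg patient mass (kg).
#' @param sigma_mass_kg standard uncertainty of the mass (kg).
#' @param residual_rate_cps residual rate from a prior therapy (cps).
#' @param alpha significance level of the F test (default 0.05).
#' @param max_phases largest candidate phase count (default 2).
#' @param target_Gy,n_fractions when both given, the remaining-fraction
#'   activity is planned from this fraction's dose.
#' @return an object of class `wb_dose_report` (a named list) with the
#'   retention curve, selected fit, time-integrated activity, S value,
#'   dose, red-marrow surrogate, coverage fraction and any plan.
#' @export
wb_dose <- function(readings, admin_activity_MBq, mass_kg,
                    sigma_mass_kg = 0, residual_rate_cps = 0,
                    alpha = 0.05, max_phases = 2L,
                    target_Gy = NULL, n_fractions = NULL) {
  curve <- tryCatch(
    build_retention_curve(readings, admin_activity_MBq, residual_rate_cps),
    error = function(e) stop("probe stage: ", conditionMessage(e),
                             call. = FALSE))
  fits <- list(fit_exponentials(curve$time_h, curve$activity_MBq, 1L))
  ftest <- NULL
  chosen <- fits[[1L]]
  if (max_phases >= 2L && nrow(curve) >= 5L) {
    fit2 <- tryCatch(
      suppressWarnings(
        fit_exponentials(curve$time_h, curve$activity_MBq, 2L)),
      error = function(e) NULL)
    if (!is.null(fit2) && fit2$model$n_phases == 2L) {
      fits <- c(fits, list(fit2))
      ftest <- f_test_select(fits[[1L]], fit2, alpha)
      chosen <- ftest$chosen
    }
  }
  tia <- time_integrated_activity(chosen)
  sigma_tia <- tia_uncertainty(chosen)
  s <- s_wb_from_mass(mass_kg)
  s$sigma <- s_uncertainty_from_mass(wb_s_power_law(), mass_kg,
                                     sigma_mass_kg)
  dose <- absorbed_dose(tia, s,
                        if (is.na(sigma_tia)) 0 else sigma_tia)
  cov_frac <- coverage_fraction(chosen, min(curve$time_h),
                                max(curve$time_h))
  plan <- NULL
  if (!is.null(target_Gy) && !is.null(n_fractions) && n_fractions >= 2) {
    plan <- list(
      A1_MBq = admin_activity_MBq, D1_Gy = dose$dose_Gy,
      target_Gy = target_Gy, N = n_fractions,
      next_fraction_MBq = plan_next_fractions(
        admin_activity_MBq, dose$dose_Gy, target_Gy, n_fractions),
      assumption = "dose per unit activity of fraction 1 applies to later fractions")
  }
  structure(
    list(curve = curve, fits = fits, f_test = ftest, fit = chosen,
         tia_MBq_h = tia, sigma_tia_MBq_h = sigma_tia, s_value = s,
         dose_Gy = dose$dose_Gy, sigma_dose_Gy = dose$sigma_Gy,
         dose_per_GBq = dose_per_unit_activity(dose$dose_Gy,
                                               admin_activity_MBq),
         red_marrow_Gy = estimate_red_marrow_dose(dose$dose_Gy),
         coverage = as.numeric(cov_frac),
         coverage_ok = attr(cov_frac, "meets_recommendation"),
         mass_kg = mass_kg, admin_activity_MBq = admin_activity_MBq,
         plan = plan),
    class = "wb_dose_report")
}

#' @export
print.wb_dose_report <- function(x, ...) {
  cat("Whole-body dosimetry\n")
  cat(sprintf("  administered %.4g MBq, patient mass %.4g kg\n",
              x$admin_activity_MBq, x$mass_kg))
  cat(sprintf("  fit: %d phase(s)%s\n", x$fit$model$n_phases,
              if (!is.null(x$f_test)) {
                sprintf(" (F = %.3g on %d, %d; p = %.3g)",
                        x$f_test$F, x$f_test$dfn, x$f_test$dfd, x$f_test$p)
              } else ""))
  cat(sprintf("  A~ = %.6g MBq.h (coverage %.1f%%%s)\n", x$tia_MBq_h,
              100 * x$coverage,
              if (x$coverage_ok) "" else ", below 80% recommendation"))
  cat(sprintf("  S = %.4g Gy/(MBq.h); D = %.3g +/- %.2g Gy (%.2f Gy/GBq)\n",
              x$s_value$value, x$dose_Gy, x$sigma_dose_Gy, x$dose_per_GBq))
  cat(sprintf("  red-marrow surrogate %.3g Gy\n", x$red_marrow_Gy))
  if (!is.null(x$plan)) {
    cat(sprintf("  plan: %.0f MBq per remaining fraction (target %.3g Gy in %d)\n",
                x$plan$next_fraction_MBq, x$plan$target_Gy, x$plan$N))
  }
  invisible(x)
}

#' Characterise a camera from phantom series
#'
#' Combines the three characterisation measurements into a
#' [camera_model()]: dead time from a graded-activity series (per mode),
#' calibration factor from a uniform cylinder, and a recovery curve from
#' insert measurements. Includes the sub-VOI uniformity check as a QC
#' flag.
#'
#' @param deadtime a data.frame `activity_MBq`, `observed_cps`, or a
#'   list of two such frames (`low`, `high`) for dual-mode cameras.
#' @param calibration a list with `voi_rate_cps`,
#'   `activity_conc_MBq_per_ml`, `voi_volume_ml` and optionally
#'   `sub_voi_rates`.
#' @param recovery a data.frame `insert_volume_ml`, `voi_rate_cps`,
#'   `true_activity_MBq`.
#' @param mode_switch_cps high-count-rate mode threshold (default `Inf`).
#' @param linear_cutoff_cps low-rate cutoff for the dead-time fit.
#' @return a [camera_model()] with a `qc` attribute (uniformity check,
#'   per-mode tau fits).
#' @export
characterise_camera <- function(deadtime, calibration, recovery = NULL,
                                mode_switch_cps = Inf,
                                linear_cutoff_cps = 1e4) {
  Q <- calibration_factor(calibration$voi_rate_cps,
                          calibration$activity_conc_MBq_per_ml,
                          calibration$voi_volume_ml)
  qc <- list()
  if (!is.null(calibration$sub_voi_rates)) {
    qc$uniformity <- check_calibration_uniformity(calibration$sub_voi_rates)
    if (!qc$uniformity$pass) {
      warning("calibration VOI fails the sub-VOI uniformity check")
    }
  }
  fit_mode <- function(df) estimate_tau(df$activity_MBq, df$observed_cps,
                                        linear_cutoff_cps)
  if (is.data.frame(deadtime)) {
    dt_low <- fit_mode(deadtime)
    dt_high <- dt_low
  } else {
    dt_low <- fit_mode(deadtime$low)
    dt_high <- fit_mode(deadtime$high)
  }
  qc$deadtime_low <- dt_low
  qc$deadtime_high <- dt_high
  rc <- NULL
  if (!is.null(recovery)) {
    R <- recovery_coefficient(recovery$voi_rate_cps, Q,
                              recovery$true_activity_MBq)
    rc <- fit_recovery_curve(recovery$insert_volume_ml, R)
    qc$recovery_rss <- rc$rss
  }
  cam <- camera_model(Q, recovery = rc, tau_low_s = dt_low$tau_s,
                      tau_high_s = dt_high$tau_s,
                      mode_switch_cps = mode_switch_cps)
  attr(cam, "qc") <- qc
  cam
}

#' Lesion or organ dose from VOI measurements
#'
#' Converts per-scan VOI count rates to activities through the camera
#' model, fits a mono-exponential (or, with enough scans and a
#' significant F test, bi-exponential) time-activity curve, integrates to
#' the time-integrated activity and applies the mass-scaled S value.
#' Cross-dose between regions is neglected. Fewer than 3 scans trigger a
#' warning (not an error).
#'
#' @param voi either a data.frame of prepared activities (`scan_time_h`,
#'   `activity_MBq`) or of raw measurements (`scan_time_h`, `rate_cps`,
#'   `volume_ml`, optional `projection_rate_cps`) converted through
#'   `camera`.
#' @param camera a [camera_model()]; may be `NULL` when `voi` already
#'   holds activities.
#' @param mass_g region mass in g (density 1 g/ml: mass and volume are
#'   interchangeable).
#' @param s_model S-value source: a [power_law_s] (evaluated at
#'   `mass_g`) or a fixed [s_value].
#' @param sigma_mass_g mass uncertainty (g).
#' @param region label for the report.
#' @param max_phases candidate phase limit (default 1; the clinical scan
#'   schedule rarely supports more).
#' @param alpha F-test level when `max_phases > 1`.
#' @return an object of class `region_dose_report`.
#' @export
lesion_dose <- function(voi, camera = NULL, mass_g, s_model,
                        sigma_mass_g = 0, region = "lesion",
                        max_phases = 1L, alpha = 0.05) {
  if (!"scan_time_h" %in% names(voi)) stop("voi needs scan_time_h")
  if (!"activity_MBq" %in% names(voi)) {
    if (is.null(camera)) stop("camera needed to convert count rates")
    req <- c("rate_cps", "volume_ml")
    if (!all(req %in% names(voi))) {
      stop("voi needs columns rate_cps and volume_ml (or activity_MBq)")
    }
    proj <- if ("projection_rate_cps" %in% names(voi)) {
      voi$projection_rate_cps
    } else rep(NA_real_, nrow(voi))
    rows <- lapply(seq_len(nrow(voi)), function(i) {
      voi_measurement(voi$scan_time_h[i], voi$rate_cps[i],
                      voi$volume_ml[i], camera, proj[i])
    })
    voi <- do.call(rbind, rows)
    names(voi)[names(voi) == "scan_time_h"] <- "scan_time_h"
  }
  if (nrow(voi) < 3L) {
    warning("fewer than 3 scans; time-activity fit accuracy is limited")
  }
  if (nrow(voi) == 2L) {
    # exactly determined two-point mono-exponential (no residual dof)
    lam <- log(voi$activity_MBq[1L] / voi$activity_MBq[2L]) /
      (voi$scan_time_h[2L] - voi$scan_time_h[1L])
    if (lam <= 0) stop("two-scan activities must be decreasing")
    model <- exp_model(voi$activity_MBq[1L] *
                         exp(lam * voi$scan_time_h[1L]), lam)
    fit <- structure(
      list(model = model, rss = 0, dof = 0L,
           covariance = matrix(NA_real_, 2L, 2L), weights = "unweighted",
           data = data.frame(time_h = voi$scan_time_h,
                             activity_MBq = voi$activity_MBq)),
      class = "exp_fit")
    max_phases <- 1L
  } else {
    fit <- fit_exponentials(voi$scan_time_h, voi$activity_MBq, 1L)
  }
  if (max_phases >= 2L && nrow(voi) >= 5L) {
    fit2 <- tryCatch(
      suppressWarnings(
        fit_exponentials(voi$scan_time_h, voi$activity_MBq, 2L)),
      error = function(e) NULL)
    if (!is.null(fit2) && fit2$model$n_phases == 2L) {
      fit <- f_test_select(fit, fit2, alpha)$chosen
    }
  }
  tia <- time_integrated_activity(fit)
  sigma_tia <- tia_uncertainty(fit)
  if (inherits(s_model, "power_law_s")) {
    s <- predict(s_model, mass_g)
    s$sigma <- s_uncertainty_from_mass(s_model, mass_g, sigma_mass_g)
  } else if (inherits(s_model, "s_value")) {
    s <- s_model
  } else {
    stop("s_model must be a power_law_s or s_value")
  }
  dose <- absorbed_dose(tia, s, if (is.na(sigma_tia)) 0 else sigma_tia)
  cov_frac <- coverage_fraction(fit, min(voi$scan_time_h),
                                max(voi$scan_time_h))
  structure(
    list(region = region, voi = voi, fit = fit, tia_MBq_h = tia,
         sigma_tia_MBq_h = sigma_tia, s_value = dose$s,
         dose_Gy = dose$dose_Gy, sigma_dose_Gy = dose$sigma_Gy,
         mass_g = mass_g, coverage = as.numeric(cov_frac),
         coverage_ok = attr(cov_frac, "meets_recommendation"),
         assumptions = "cross-dose between regions neglected"),
    class = "region_dose_report")
}

#' @export
print.region_dose_report <- function(x, ...) {
  cat(sprintf("%s dosimetry (mass %.4g g)\n", x$region, x$mass_g))
  cat(sprintf("  %d scans, %d-phase fit, A~ = %.6g MBq.h (coverage %.1f%%)\n",
              nrow(x$voi), x$fit$model$n_phases, x$tia_MBq_h,
              100 * x$coverage))
  cat(sprintf("  S = %.4g %s; D = %.3g +/- %.2g Gy\n",
              x$s_value$value, x$s_value$units, x$dose_Gy, x$sigma_dose_Gy))
  invisible(x)
}

#' Serialise a dose report to a plain list (for JSON export)
#'
#' @param report a `wb_dose_report` or `region_dose_report`.
#' @return a named list of plain values.
#' @export
report_as_list <- function(report) {
  if (inherits(report, "wb_dose_report")) {
    list(kind = "whole_body",
         admin_activity_MBq = report$admin_activity_MBq,
         mass_kg = report$mass_kg,
         n_phases = report$fit$model$n_phases,
         amplitudes_MBq = report$fit$model$amplitudes,
         lambdas_per_h = report$fit$model$lambdas,
         f_test = if (!is.null(report$f_test)) {
           report$f_test[c("F", "dfn", "dfd", "p", "chosen_label")]
         },
         tia_MBq_h = report$tia_MBq_h,
         sigma_tia_MBq_h = report$sigma_tia_MBq_h,
         s_Gy_per_MBq_h = report$s_value$value,
         sigma_s = report$s_value$sigma,
         dose_Gy = report$dose_Gy, sigma_dose_Gy = report$sigma_dose_Gy,
         dose_per_GBq = report$dose_per_GBq,
         red_marrow_Gy = report$red_marrow_Gy,
         coverage = report$coverage, plan = report$plan)
  } else if (inherits(report, "region_dose_report")) {
    list(kind = "region", region = report$region, mass_g = report$mass_g,
         n_phases = report$fit$model$n_phases,
         amplitudes_MBq = report$fit$model$amplitudes,
         lambdas_per_h = report$fit$model$lambdas,
         tia_MBq_h = report$tia_MBq_h,
         sigma_tia_MBq_h = report$sigma_tia_MBq_h,
         s_value = report$s_value$value, s_units = report$s_value$units,
         dose_Gy = report$dose_Gy, sigma_dose_Gy = report$sigma_dose_Gy,
         coverage = report$coverage, assumptions = report$assumptions)
  } else {
    stop("unsupported report class")
  }
}
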