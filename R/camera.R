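# Quantitative gamma-camera characterisation for 131I imaging: volumetric
# calibration factor, partial-volume recovery curve, and paralysable dead
# time (two count-rate modes with a hard switch threshold).

#' Camera calibration factor from a volumetric phantom
#'
#' `Q = C_voi / (conc * volume)`: the count rate in a VOI centred within a
#' uniformly filled phantom, divided by the decay-corrected activity it
#' contains.
#'
#' @param voi_rate_cps count rate in the VOI (cps, > 0).
#' @param activity_conc_MBq_per_ml activity concentration at scan time
#'   (MBq/ml, > 0).
#' @param voi_volume_ml VOI volume (ml, > 0).
#' @return calibration factor Q in cps/MBq.
#' @export
calibration_factor <- function(voi_rate_cps, activity_conc_MBq_per_ml,
                               voi_volume_ml) {
  if (voi_rate_cps <= 0 || activity_conc_MBq_per_ml <= 0 ||
      voi_volume_ml <= 0) {
    stop("all inputs must be positive")
  }
  voi_rate_cps / (activity_conc_MBq_per_ml * voi_volume_ml)
}

#' Check calibration uniformity across sub-VOIs
#'
#' The calibration VOI should be free of partial-volume and noise effects;
#' this is tested by comparing rate densities of several small sub-VOIs.
#'
#' @param sub_voi_rates at least 3 sub-VOI rate densities.
#' @param tolerance maximum allowed relative deviation from the mean
#'   (default 0.10).
#' @return a list with `pass` and `spread` (max relative deviation).
#' @export
check_calibration_uniformity <- function(sub_voi_rates, tolerance = 0.10) {
  if (length(sub_voi_rates) < 3L) stop("need at least 3 sub-VOI rates")
  m <- mean(sub_voi_rates)
  if (m <= 0) stop("mean sub-VOI rate must be positive")
  spread <- max(abs(sub_voi_rates - m)) / m
  list(pass = spread <= tolerance, spread = spread)
}

#' Recovery coefficient of a phantom insert
#'
#' `R = C_obs / (Q * A)`: the observed count rate in a VOI matching the
#' true insert volume, relative to the rate expected from the known
#' activity at full recovery.
#'
#' @param obs_rate_cps observed count rate (cps, >= 0).
#' @param Q calibration factor (cps/MBq, > 0).
#' @param true_activity_MBq known activity in the insert (MBq, > 0).
#' @return recovery coefficient.
#' @export
recovery_coefficient <- function(obs_rate_cps, Q, true_activity_MBq) {
  if (any(Q <= 0) || any(true_activity_MBq <= 0)) {
    stop("Q and activity must be > 0")
  }
  if (any(obs_rate_cps < 0)) stop("observed rate must be >= 0")
  obs_rate_cps / (Q * true_activity_MBq)
}

#' Fit a recovery curve over insert volume
#'
#' Least-squares fit of a saturating power-logistic model
#' `R(v) = R_max * v^n / (v^n + v50^n)`, monotone non-decreasing in volume
#' by construction. On non-convergence the curve falls back to monotone
#' piecewise-linear interpolation of the measured points, flagged in the
#' result.
#'
#' @param volumes_ml at least 4 distinct insert volumes (ml).
#' @param R_values measured recovery coefficients (0 < R <= 1.05,
#'   tolerating noise).
#' @return an object of class `recovery_curve` with the data, fitted
#'   parameters `R_max`, `v50`, `n` and a `method` tag
#'   (`"power_logistic"` or `"monotone_linear"`).
#' @export
fit_recovery_curve <- function(volumes_ml, R_values) {
  if (length(volumes_ml) < 4L) stop("need at least 4 (volume, R) pairs")
  if (length(volumes_ml) != length(R_values)) stop("length mismatch")
  if (any(volumes_ml <= 0)) stop("volumes must be positive")
  if (anyDuplicated(volumes_ml)) stop("volumes must be distinct")
  if (any(R_values <= 0) || any(R_values > 1.05)) {
    stop("recovery values must be in (0, 1.05]")
  }
  ord <- order(volumes_ml)
  v <- volumes_ml[ord]
  R <- R_values[ord]
  df <- data.frame(v = v, R = R)
  # logit-log linearisation for starting values:
  # log(R / (Rmax - R)) = n log(v) - n log(v50)
  Rmax0 <- min(max(R) * 1.02, 1.05)
  p <- pmin(pmax(R / Rmax0, 0.01), 0.99)
  lin <- lm(log(p / (1 - p)) ~ log(v))
  n0 <- min(max(coef(lin)[[2L]], 0.2), 8)
  v50_0 <- exp(-coef(lin)[[1L]] / coef(lin)[[2L]])
  if (!is.finite(v50_0) || v50_0 <= 0) v50_0 <- median(v)
  fit <- tryCatch(
    nlsLM(R ~ Rmax * v^n / (v^n + v50^n), data = df,
          start = list(Rmax = Rmax0, v50 = v50_0, n = n0),
          lower = c(1e-3, 1e-6, 0.1), upper = c(1.05, max(v) * 10, 10),
          control = nls.lm.control(maxiter = 500, ftol = 1e-12,
                                   ptol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    structure(list(volumes_ml = v, R = R, R_max = cf[["Rmax"]],
                   v50 = cf[["v50"]], n = cf[["n"]],
                   method = "power_logistic",
                   rss = sum(residuals(fit)^2)),
              class = "recovery_curve")
  } else {
    warning("recovery-curve fit did not converge; ",
            "using monotone piecewise-linear interpolation")
    Rmono <- cummax(R)  # enforce monotonicity on the interpolant
    structure(list(volumes_ml = v, R = R, R_max = max(Rmono),
                   v50 = NA_real_, n = NA_real_,
                   method = "monotone_linear",
                   interp = approxfun(v, Rmono, rule = 2)),
              class = "recovery_curve")
  }
}

#' @export
print.recovery_curve <- function(x, ...) {
  if (x$method == "power_logistic") {
    cat(sprintf(
      "Recovery curve: R(v) = %.4g * v^%.3g / (v^%.3g + %.4g^%.3g)\n",
      x$R_max, x$n, x$n, x$v50, x$n))
  } else {
    cat("Recovery curve: monotone piecewise-linear (fit fallback)\n")
  }
  cat(sprintf("  fitted on %d volumes spanning %.3g-%.3g ml\n",
              length(x$volumes_ml), min(x$volumes_ml), max(x$volumes_ml)))
  invisible(x)
}

#' @export
predict.recovery_curve <- function(object, volume_ml, ...) {
  interpolate_recovery(object, volume_ml)
}

#' Evaluate a recovery curve at a volume
#'
#' Evaluates the fitted model; volumes below the smallest measured insert
#' return the model value with an extrapolation warning. Results are
#' clamped to `(0, R_max]`.
#'
#' @param curve a [fit_recovery_curve()] result.
#' @param volume_ml volume to evaluate at (ml, > 0); vectorised.
#' @return recovery coefficient(s).
#' @export
interpolate_recovery <- function(curve, volume_ml) {
  if (!inherits(curve, "recovery_curve")) stop("curve must be a recovery_curve")
  if (any(volume_ml <= 0)) stop("volume must be positive")
  if (any(volume_ml < min(curve$volumes_ml))) {
    warning("volume below the smallest measured insert; extrapolating")
  }
  r <- if (curve$method == "power_logistic") {
    curve$R_max * volume_ml^curve$n / (volume_ml^curve$n + curve$v50^curve$n)
  } else {
    curve$interp(volume_ml)
  }
  pmin(pmax(r, .Machine$double.eps), curve$R_max)
}

#' Observed count rate of a paralysable detector
#'
#' `C_obs = C_inc * exp(-C_inc * tau)`: each incident event extends the
#' dead period, so the observed rate peaks at `1/(tau e)` when the
#' incident rate reaches `1/tau`.
#'
#' @param incident_cps incident count rate (cps, >= 0); vectorised.
#' @param tau_s system dead time (seconds, >= 0).
#' @return observed count rate (cps).
#' @export
paralysable_rate <- function(incident_cps, tau_s) {
  if (any(incident_cps < 0) || tau_s < 0) stop("inputs must be >= 0")
  incident_cps * exp(-incident_cps * tau_s)
}

#' Estimate the paralysable dead time from a graded-activity series
#'
#' Two-stage procedure: (i) a zero-intercept linear fit of observed rate
#' against activity over the low-rate points (below `linear_cutoff_cps`)
#' gives an initial sensitivity estimate, from which incident rates at
#' every activity step are extrapolated; (ii) a nonlinear least-squares
#' fit of the paralysable model `obs = s A exp(-s A tau)` over all points
#' refines the sensitivity and determines `tau` (low-rate points carry a
#' few percent of paralysable losses themselves, so the linear slope is
#' only a starting value).
#'
#' @param activities_MBq known (decay-corrected) activities, increasing.
#' @param observed_cps observed count rates at those activities.
#' @param linear_cutoff_cps observed-rate cutoff defining the linear
#'   regime (default 10,000 cps).
#' @return a list with `tau_s`, `sensitivity_cps_per_MBq` (refined),
#'   `sensitivity_linear` (the initial zero-intercept slope) and the
#'   number of points in each regime.
#' @export
estimate_tau <- function(activities_MBq, observed_cps,
                         linear_cutoff_cps = 1e4) {
  if (length(activities_MBq) != length(observed_cps)) {
    stop("length mismatch")
  }
  low <- observed_cps < linear_cutoff_cps
  if (sum(low) < 3L) {
    stop("need at least 3 points in the low-rate (linear) regime")
  }
  if (sum(!low) < 2L) {
    stop("need at least 2 points above the linear cutoff")
  }
  lin <- lm(observed_cps ~ 0 + activities_MBq, subset = low)
  sens0 <- coef(lin)[[1L]]
  if (sens0 <= 0) stop("non-positive fitted sensitivity")
  inc0 <- sens0 * activities_MBq
  tau0 <- {
    hi <- !low
    cand <- -log(pmin(observed_cps[hi] / inc0[hi], 1)) / inc0[hi]
    max(mean(cand), 1e-9)
  }
  # tau fitted in microseconds: comparable parameter scales keep the
  # Jacobian well conditioned; nls.lm handles the tau = 0 boundary
  A <- activities_MBq
  obs <- observed_cps
  fit <- minpack.lm::nls.lm(
    par = c(s = sens0, tau_us = max(tau0 * 1e6, 1e-3)),
    fn = function(p) obs - p[["s"]] * A *
      exp(-p[["s"]] * A * p[["tau_us"]] * 1e-6),
    lower = c(1e-12, 0),
    control = nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info == 0L || fit$info == 9L) {
    stop("dead-time fit did not converge: ", fit$message)
  }
  cf <- fit$par
  list(tau_s = cf[["tau_us"]] * 1e-6, sensitivity_cps_per_MBq = cf[["s"]],
       sensitivity_linear = sens0,
       n_linear = sum(low), n_nonlinear = sum(!low))
}

#' Dead-time correction factor by fixed-point iteration
#'
#' Solves `DTF = exp(DTF * tau * C_obs)` (the inversion of the
#' paralysable model) on the physical branch, starting from `DTF = 1`.
#' The equation has a real solution only for `C_obs * tau < 1/e`, the
#' observed-rate maximum of a paralysable detector; the fixed-point
#' iteration converges monotonically to the smaller root (DTF >= 1).
#' A Newton fallback handles slow convergence near the peak.
#'
#' @param observed_cps observed count rate (cps, >= 0); vectorised.
#' @param tau_s dead time (s, >= 0).
#' @param tol convergence tolerance on successive iterates (default 1e-9).
#' @param max_iter maximum fixed-point iterations before the Newton
#'   fallback (default 100).
#' @return dead-time correction factor(s), >= 1.
#' @examples
#' dead_time_factor(25000, 0.47e-6)  # 1.012
#' @export
dead_time_factor <- function(observed_cps, tau_s, tol = 1e-9,
                             max_iter = 100L) {
  if (any(observed_cps < 0) || tau_s < 0) stop("inputs must be >= 0")
  x <- observed_cps * tau_s
  if (any(x >= exp(-1))) {
    stop("observed rate at or beyond the paralysable maximum ",
         "(obs * tau >= 1/e); no physical correction exists")
  }
  solve_one <- function(xi) {
    if (xi == 0) return(1)
    d <- 1
    for (i in seq_len(max_iter)) {
      d_new <- exp(d * xi)
      if (abs(d_new - d) <= tol) return(d_new)
      d <- d_new
    }
    # Newton on f(d) = d - exp(d * xi)
    for (i in seq_len(50L)) {
      f <- d - exp(d * xi)
      fp <- 1 - xi * exp(d * xi)
      d_new <- d - f / fp
      if (abs(d_new - d) <= tol) return(d_new)
      d <- d_new
    }
    d
  }
  vapply(x, solve_one, numeric(1L))
}

#' Assemble a camera model
#'
#' Bundles the quantities needed to convert VOI count rates to activity:
#' calibration factor, recovery curve and per-mode paralysable dead
#' times. Cameras with a high-count-rate mode switch dead-time constants
#' at a hard threshold.
#'
#' @param Q calibration factor (cps/MBq, > 0).
#' @param recovery a [fit_recovery_curve()] result, or `NULL` when no
#'   partial-volume correction is applied.
#' @param tau_low_s dead time of the normal mode (s, >= 0).
#' @param tau_high_s dead time of the high-count-rate mode (defaults to
#'   `tau_low_s` for single-mode cameras).
#' @param mode_switch_cps observed rate at which the high-count-rate mode
#'   activates (default `Inf`: never).
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(Q, recovery = NULL, tau_low_s = 0,
                         tau_high_s = tau_low_s, mode_switch_cps = Inf) {
  if (Q <= 0) stop("Q must be positive")
  if (tau_low_s < 0 || tau_high_s < 0) stop("dead times must be >= 0")
  if (mode_switch_cps <= 0) stop("mode_switch_cps must be positive")
  if (!is.null(recovery) && !inherits(recovery, "recovery_curve")) {
    stop("recovery must be a recovery_curve or NULL")
  }
  structure(list(Q = Q, recovery = recovery, tau_low_s = tau_low_s,
                 tau_high_s = tau_high_s,
                 mode_switch_cps = mode_switch_cps),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera model: Q = %.4g cps/MBq\n", x$Q))
  if (is.finite(x$mode_switch_cps)) {
    cat(sprintf("  tau = %.3g us (< %.3g cps), %.3g us (high-rate mode)\n",
                x$tau_low_s * 1e6, x$mode_switch_cps, x$tau_high_s * 1e6))
  } else {
    cat(sprintf("  tau = %.3g us (single mode)\n", x$tau_low_s * 1e6))
  }
  cat(if (is.null(x$recovery)) "  no recovery curve\n" else
    "  recovery curve attached\n")
  invisible(x)
}

#' Dead time applicable at an observed rate
#'
#' @param camera a [camera_model()].
#' @param observed_cps observed count rate; vectorised.
#' @return the dead time (s) of the operating mode at each rate.
#' @export
tau_for_rate <- function(camera, observed_cps) {
  stopifnot(inherits(camera, "camera_model"))
  ifelse(observed_cps >= camera$mode_switch_cps,
         camera$tau_high_s, camera$tau_low_s)
}
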