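# Seeded synthetic-data generators. Each generator emulates one measurement
# set of the dosimetry workflow and returns the emitted dataset together
# with the ground-truth parameters ("truth") that produced it, so every
# fitting stage can be validated by round trip. Noise models: Poisson for
# detected counts, multiplicative Gaussian for rates.

# run code under a fixed seed without disturbing the session RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a whole-body probe measurement series
#'
#' Poisson counts from a multi-exponential retention curve viewed by an
#' external counter: expected rate `sensitivity * sum_j A_j e^(-lambda_j t)
#' + background`. The series includes a pre-void baseline reading at
#' `t = 0` and one pre-administration background reading. The default
#' schedule emulates clinical practice: readings every 2 h over the first
#' day, then every 6 h.
#'
#' @param A0_MBq administered activity (MBq).
#' @param phase_fractions fraction of `A0_MBq` per phase (sums to 1).
#' @param lambdas_per_h effective decay constant per phase (1/h).
#' @param schedule_h reading times (hours post administration, including 0).
#' @param counter_sensitivity_cps_per_MBq counter sensitivity.
#' @param background_cps ambient background rate.
#' @param duration_s reading duration (s).
#' @param seed RNG seed (mandatory; same seed, same output).
#' @return a list with `readings` (data.frame as accepted by
#'   [build_retention_curve()]) and `truth` (generator parameters and the
#'   noiseless retained fractions at the schedule).
#' @export
gen_probe_series <- function(A0_MBq, phase_fractions = c(0.7, 0.3),
                             lambdas_per_h = c(0.15, 0.02),
                             schedule_h = c(seq(0, 24, by = 2),
                                            seq(30, 120, by = 6)),
                             counter_sensitivity_cps_per_MBq = 0.05,
                             background_cps = 0.5,
                             duration_s = 60, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (abs(sum(phase_fractions) - 1) > 1e-9) {
    stop("phase_fractions must sum to 1")
  }
  if (any(lambdas_per_h <= 0)) stop("lambdas must be positive")
  amps <- A0_MBq * phase_fractions
  model <- exp_model(amps, lambdas_per_h)
  with_seed(seed, {
    a_true <- predict(model, schedule_h)
    rate <- counter_sensitivity_cps_per_MBq * a_true + background_cps
    counts <- rpois(length(rate), rate * duration_s)
    bkg_counts <- rpois(1L, background_cps * 600)
    readings <- rbind(
      data.frame(time_h = -0.5, counts = bkg_counts, duration_s = 600,
                 view = "single", is_background = TRUE),
      data.frame(time_h = schedule_h, counts = counts,
                 duration_s = duration_s, view = "single",
                 is_background = FALSE))
    list(readings = readings,
         truth = list(generator = "gen_probe_series", A0_MBq = A0_MBq,
                      amplitudes_MBq = amps, lambdas_per_h = lambdas_per_h,
                      sensitivity = counter_sensitivity_cps_per_MBq,
                      background_cps = background_cps,
                      schedule_h = schedule_h,
                      fractions = a_true / a_true[1L], seed = seed))
  })
}

#' Simulate a graded-activity dead-time series
#'
#' Observed count rates from a paralysable detector at increasing source
#' activities, with multiplicative Gaussian rate noise. A high-count-rate
#' mode with its own dead time activates above `mode_switch_cps`
#' (observed rate).
#'
#' @param activity_steps_MBq increasing source activities.
#' @param sensitivity_cps_per_MBq detector sensitivity.
#' @param tau_low_s,tau_high_s dead times of the two modes (s).
#' @param mode_switch_cps observed-rate threshold for the high mode
#'   (default `Inf`: single mode).
#' @param noise_cv coefficient of variation of the rate noise.
#' @param seed RNG seed (mandatory).
#' @return a list with `series` (data.frame `activity_MBq`,
#'   `observed_cps`) and `truth`.
#' @export
gen_deadtime_series <- function(activity_steps_MBq,
                                sensitivity_cps_per_MBq = 170,
                                tau_low_s = 12.8e-6,
                                tau_high_s = tau_low_s,
                                mode_switch_cps = Inf,
                                noise_cv = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.unsorted(activity_steps_MBq, strictly = TRUE)) {
    stop("activities must be strictly increasing")
  }
  if (tau_low_s < 0 || tau_high_s < 0) stop("dead times must be >= 0")
  with_seed(seed, {
    inc <- sensitivity_cps_per_MBq * activity_steps_MBq
    obs_low <- paralysable_rate(inc, tau_low_s)
    obs <- ifelse(obs_low >= mode_switch_cps,
                  paralysable_rate(inc, tau_high_s), obs_low)
    if (noise_cv > 0) {
      obs <- obs * (1 + rnorm(length(obs), 0, noise_cv))
      obs <- pmax(obs, 0)
    }
    list(series = data.frame(activity_MBq = activity_steps_MBq,
                             observed_cps = obs),
         truth = list(generator = "gen_deadtime_series",
                      sensitivity = sensitivity_cps_per_MBq,
                      tau_low_s = tau_low_s, tau_high_s = tau_high_s,
                      mode_switch_cps = mode_switch_cps,
                      incident_cps = inc, noise_cv = noise_cv, seed = seed))
  })
}

# separable Gaussian blur of a 3-D array, zero-padded, kernel renormalised
gaussian_blur3 <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  out <- arr
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    x <- seq(-half, half)
    kern <- exp(-x^2 / (2 * s^2))
    kern <- kern / sum(kern)
    out <- convolve_axis(out, kern, axis)
  }
  out
}

convolve_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  half <- (length(kern) - 1L) / 2
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1L])
  n <- da[1L]
  res <- matrix(0, n, ncol(m))
  for (k in seq_along(kern)) {
    off <- k - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    res[ok, ] <- res[ok, ] + kern[k] * m[src[ok], ]
  }
  b <- array(res, da)
  aperm(b, order(perm))
}

#' Simulate a sphere phantom image
#'
#' Analytic rasterisation of uniform spheres in a uniform background
#' (partial-voxel edge weighting by subsampling), followed by an
#' isotropic Gaussian point-spread blur and optional Poisson count noise.
#' The truth records each sphere's enclosed rate before and after blur
#' (the enclosed-after-blur fraction is the exact recovery coefficient
#' of a volume-matched VOI).
#'
#' @param grid_dim image dimensions, length 3.
#' @param voxel_mm voxel size (scalar or length 3, mm).
#' @param spheres data.frame with columns `cx_mm`, `cy_mm`, `cz_mm`
#'   (centre coordinates, mm from the image corner), `diameter_mm` and
#'   `conc_cps_per_ml`.
#' @param background_conc_cps_per_ml background concentration.
#' @param psf_fwhm_mm full width at half maximum of the Gaussian PSF
#'   (0 disables blurring). 15 mm emulates a high-energy collimator's
#'   reconstructed resolution.
#' @param poisson_duration_s when positive, voxel counts are drawn as
#'   Poisson(rate * duration) and converted back to rates.
#' @param subsample edge-voxel subsampling factor per axis (default 8; 512
#'   fraction levels keep threshold-volume granularity below one voxel).
#'
#' @param seed RNG seed (mandatory).
#' @return a list with `image` (a [voxel_image()], cps units) and
#'   `truth` (per-sphere enclosed rates and masks, PSF, seed).
#' @export
gen_sphere_phantom <- function(grid_dim = c(64L, 64L, 64L), voxel_mm = 4,
                               spheres, background_conc_cps_per_ml = 0,
                               psf_fwhm_mm = 15, poisson_duration_s = 0,
                               subsample = 8L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  req <- c("cx_mm", "cy_mm", "cz_mm", "diameter_mm", "conc_cps_per_ml")
  if (!all(req %in% names(spheres))) {
    stop("spheres needs columns: ", paste(req, collapse = ", "))
  }
  if (psf_fwhm_mm < 0) stop("FWHM must be >= 0")
  # reject overlapping spheres
  ns <- nrow(spheres)
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) for (j in seq(i + 1L, ns)) {
      dist <- sqrt(sum((unlist(spheres[i, 1:3]) -
                          unlist(spheres[j, 1:3]))^2))
      if (dist < (spheres$diameter_mm[i] + spheres$diameter_mm[j]) / 2) {
        stop("spheres overlap")
      }
    }
  }
  vox_ml <- prod(voxel_mm) / 1000
  cx <- (seq_len(grid_dim[1L]) - 0.5) * voxel_mm[1L]
  cy <- (seq_len(grid_dim[2L]) - 0.5) * voxel_mm[2L]
  cz <- (seq_len(grid_dim[3L]) - 0.5) * voxel_mm[3L]
  with_seed(seed, {
    img <- array(background_conc_cps_per_ml * vox_ml, grid_dim)
    truth_spheres <- vector("list", ns)
    sub <- (seq_len(subsample) - 0.5) / subsample
    for (s in seq_len(ns)) {
      r <- spheres$diameter_mm[s] / 2
      ctr <- c(spheres$cx_mm[s], spheres$cy_mm[s], spheres$cz_mm[s])
      if (any(ctr - r < 0) || any(ctr + r > grid_dim * voxel_mm)) {
        stop("sphere extends outside the grid")
      }
      dx2 <- outer(cx - ctr[1L], cy - ctr[2L],
                   function(a, b) a^2 + b^2)
      frac <- array(0, grid_dim)
      half_diag <- sqrt(sum((voxel_mm / 2)^2))
      for (k in seq_len(grid_dim[3L])) {
        d <- sqrt(dx2 + (cz[k] - ctr[3L])^2)
        inside <- d <= r - half_diag
        edge <- !inside & d <= r + half_diag
        fk <- matrix(0, grid_dim[1L], grid_dim[2L])
        fk[inside] <- 1
        if (any(edge)) {
          eidx <- which(edge, arr.ind = TRUE)
          for (row in seq_len(nrow(eidx))) {
            i <- eidx[row, 1L]; j <- eidx[row, 2L]
            xs <- (i - 1 + sub) * voxel_mm[1L] - ctr[1L]
            ys <- (j - 1 + sub) * voxel_mm[2L] - ctr[2L]
            zs <- (k - 1 + sub) * voxel_mm[3L] - ctr[3L]
            g <- expand.grid(x = xs, y = ys, z = zs)
            fk[i, j] <- mean(g$x^2 + g$y^2 + g$z^2 <= r^2)
          }
        }
        frac[, , k] <- fk
      }
      delta <- (spheres$conc_cps_per_ml[s] - background_conc_cps_per_ml) *
        vox_ml
      img <- img + frac * delta
      mask <- frac > 0.5
      truth_spheres[[s]] <- list(
        center_mm = ctr, diameter_mm = spheres$diameter_mm[s],
        volume_ml = 4 / 3 * pi * r^3 / 1000,
        rasterised_rate_cps = sum(frac) * spheres$conc_cps_per_ml[s] * vox_ml,
        enclosed_rate_cps = sum(frac * delta) +
          background_conc_cps_per_ml * vox_ml * sum(frac),
        mask = mask)
    }
    unblurred <- img
    if (psf_fwhm_mm > 0) {
      sigma_vox <- psf_fwhm_mm / 2.3548200450309493 / voxel_mm
      img <- gaussian_blur3(img, sigma_vox)
    }
    if (poisson_duration_s > 0) {
      counts <- rpois(length(img), pmax(img, 0) * poisson_duration_s)
      img <- array(counts / poisson_duration_s, grid_dim)
    }
    # post-blur enclosed rate within each sphere's volume-matched mask
    for (s in seq_len(ns)) {
      msk <- truth_spheres[[s]]$mask
      truth_spheres[[s]]$blurred_in_mask_rate_cps <- sum(img[msk])
      truth_spheres[[s]]$recovery <-
        sum(img[msk]) / truth_spheres[[s]]$enclosed_rate_cps
    }
    list(image = voxel_image(img, voxel_mm, units = "cps"),
         truth = list(generator = "gen_sphere_phantom",
                      spheres = truth_spheres,
                      background_conc_cps_per_ml = background_conc_cps_per_ml,
                      psf_fwhm_mm = psf_fwhm_mm,
                      unblurred_total_cps = sum(unblurred),
                      blurred_total_cps = sum(img), seed = seed))
  })
}

#' Simulate a lesion/organ time-activity curve
#'
#' Mono-exponential activity samples with multiplicative Gaussian noise,
#' emulating SPECT-derived VOI activities at a clinical scan schedule
#' (e.g. days 2, 5 and 7 post administration).
#'
#' @param A0_MBq activity at time zero (MBq).
#' @param T_eff_h effective half-life (hours).
#' @param scan_times_h scan times (hours, > 0).
#' @param noise_cv coefficient of variation of the noise.
#' @param seed RNG seed (mandatory).
#' @return a list with `tac` (data.frame `time_h`, `activity_MBq`,
#'   `sigma_MBq`) and `truth`.
#' @export
gen_lesion_tac <- function(A0_MBq, T_eff_h,
                           scan_times_h = c(48, 120, 168),
                           noise_cv = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(scan_times_h <= 0)) stop("scan times must be positive")
  model <- mono_exp_model(A0_MBq, T_eff_h)
  with_seed(seed, {
    a_true <- predict(model, scan_times_h)
    a <- a_true
    if (noise_cv > 0) a <- a_true * (1 + rnorm(length(a_true), 0, noise_cv))
    a <- pmax(a, a_true * 1e-3)
    list(tac = data.frame(time_h = scan_times_h, activity_MBq = a,
                          sigma_MBq = noise_cv * a_true),
         truth = list(generator = "gen_lesion_tac", A0_MBq = A0_MBq,
                      T_eff_h = T_eff_h,
                      tia_MBq_h = time_integrated_activity(model),
                      noise_cv = noise_cv, seed = seed))
  })
}
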