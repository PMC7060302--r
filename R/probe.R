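# Whole-body retention from external probe counts. Raw timed counts are
# background-corrected, optionally combined across AP/PA views by geometric
# mean, and normalised to the pre-void baseline reading to yield retained
# activity in absolute units.

#' Net count rate with Poisson uncertainty
#'
#' `rate = counts / duration - background`; the Poisson uncertainty is
#' `sqrt(counts) / duration` (background uncertainty is not propagated
#' here). Counts of 500 or fewer are flagged: the relative Poisson noise
#' then exceeds ~4.5%, against the < 5% precision recommendation.
#'
#' @param counts detected counts (non-negative integers); vectorised.
#' @param duration_s acquisition duration in seconds (> 0).
#' @param background_rate_cps background count rate to subtract (>= 0).
#' @return a data.frame with `rate_cps`, `sigma_cps`, `low_counts`
#'   (TRUE when counts <= 500) and `valid` (FALSE when the background
#'   exceeds the signal, i.e. negative net rate).
#' @examples
#' net_count_rate(1000, 60, 1)  # 15.667 cps +/- 0.527
#' @export
net_count_rate <- function(counts, duration_s, background_rate_cps = 0) {
  if (any(duration_s <= 0)) stop("duration_s must be positive")
  if (any(background_rate_cps < 0)) stop("background rate must be >= 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / duration_s - background_rate_cps
  sigma <- sqrt(counts) / duration_s
  low <- counts <= 500
  valid <- rate >= 0
  if (any(low)) {
    warning("some readings have <= 500 counts; Poisson noise exceeds ~4.5%")
  }
  if (any(!valid)) {
    warning("background exceeds signal for some readings; flagged invalid")
  }
  data.frame(rate_cps = rate, sigma_cps = sigma, low_counts = low,
             valid = valid)
}

#' Minimum counts for a target Poisson precision
#'
#' The smallest count number `N` with `1/sqrt(N) <= relative_noise`,
#' i.e. `ceiling(1 / relative_noise^2)`.
#'
#' @param relative_noise target relative Poisson noise, in (0, 1).
#' @return an integer count.
#' @examples
#' min_counts_for_precision(0.05)  # 400
#' @export
min_counts_for_precision <- function(relative_noise) {
  if (!is.numeric(relative_noise) || length(relative_noise) != 1L ||
      relative_noise <= 0 || relative_noise >= 1) {
    stop("relative_noise must be in (0, 1)")
  }
  # small guard against floating-point overshoot at exact integer targets
  as.integer(ceiling(1 / relative_noise^2 - 1e-9))
}

#' Geometric mean of anterior-posterior and posterior-anterior rates
#'
#' @param rate_ap_cps,rate_pa_cps count rates from the two opposed views;
#'   both must be positive.
#' @return `sqrt(AP * PA)` in cps.
#' @export
geometric_mean_rate <- function(rate_ap_cps, rate_pa_cps) {
  if (any(rate_ap_cps <= 0) || any(rate_pa_cps <= 0)) {
    stop("geometric mean undefined for non-positive rates")
  }
  sqrt(rate_ap_cps * rate_pa_cps)
}

# internal: cluster times so that readings within `window_h` of the first
# member of a group share a time point
cluster_times <- function(time_h, window_h = 0.25) {
  ord <- order(time_h)
  grp <- integer(length(time_h))
  g <- 0L
  start <- -Inf
  for (i in ord) {
    if (time_h[i] - start > window_h) {
      g <- g + 1L
      start <- time_h[i]
    }
    grp[i] <- g
  }
  grp
}

#' Build a whole-body retention curve from probe readings
#'
#' Each patient reading is corrected with the most recent prior background
#' (falling back to the pre-administration background when none precedes
#' it), replicate readings within 15 min are averaged into one time point,
#' AP and PA views at a time point are combined by geometric mean, and all
#' rates are normalised to the first (pre-void) reading so that retained
#' activity equals the net administered activity at time zero:
#' `A(t) = A_admin * (rate(t) - residual) / (baseline - residual)`.
#'
#' @param readings a data.frame with columns `time_h` (hours post
#'   administration; background rows may be negative), `counts`,
#'   `duration_s`, `view` (one of `"single"`, `"AP"`, `"PA"`) and
#'   `is_background` (logical). At least one background row and one
#'   patient row are required.
#' @param admin_activity_MBq net administered activity (MBq, > 0).
#' @param residual_rate_cps net count rate remaining from a previous
#'   therapy, measured before this administration (0 if none).
#' @return an object of class `retention_curve`: a data.frame with
#'   `time_h`, `activity_MBq`, `sigma_MBq` plus attributes
#'   `admin_activity_MBq`, `baseline_rate_cps`, `residual_rate_cps` and a
#'   per-point `view_used` provenance vector.
#' @export
build_retention_curve <- function(readings, admin_activity_MBq,
                                  residual_rate_cps = 0) {
  req <- c("time_h", "counts", "duration_s", "view", "is_background")
  if (!all(req %in% names(readings))) {
    stop("readings must have columns: ", paste(req, collapse = ", "))
  }
  if (admin_activity_MBq <= 0) stop("admin_activity_MBq must be positive")
  if (residual_rate_cps < 0) stop("residual_rate_cps must be >= 0")
  bkg <- readings[readings$is_background, , drop = FALSE]
  pat <- readings[!readings$is_background, , drop = FALSE]
  if (nrow(bkg) < 1L) stop("at least one background reading is required")
  if (nrow(pat) < 1L) stop("no patient readings; pre-void baseline missing")
  if (any(pat$time_h < 0)) stop("patient readings must have time_h >= 0")
  bkg <- bkg[order(bkg$time_h), , drop = FALSE]
  bkg_rate <- bkg$counts / bkg$duration_s
  # most recent prior background; pre-administration background as fallback
  assign_bkg <- function(t) {
    prior <- which(bkg$time_h <= t)
    if (length(prior)) bkg_rate[max(prior)] else bkg_rate[1L]
  }
  b <- vapply(pat$time_h, assign_bkg, numeric(1L))
  net <- withCallingHandlers(
    net_count_rate(pat$counts, pat$duration_s, b),
    warning = function(w) invokeRestart("muffleWarning"))
  if (any(pat$counts <= 500)) {
    warning("some patient readings have <= 500 counts")
  }
  grp <- cluster_times(pat$time_h)
  groups <- sort(unique(grp))
  tt <- rr <- ss <- numeric(length(groups))
  view_used <- character(length(groups))
  for (i in seq_along(groups)) {
    sel <- grp == groups[i]
    tt[i] <- mean(pat$time_h[sel])
    views <- toupper(pat$view[sel])
    if (any(views == "AP") && any(views == "PA")) {
      r_ap <- mean(net$rate_cps[sel][views == "AP"])
      s_ap <- sqrt(sum(net$sigma_cps[sel][views == "AP"]^2)) /
        sum(views == "AP")
      r_pa <- mean(net$rate_cps[sel][views == "PA"])
      s_pa <- sqrt(sum(net$sigma_cps[sel][views == "PA"]^2)) /
        sum(views == "PA")
      if (r_ap <= 0 || r_pa <= 0) {
        stop("non-positive net view rate; cannot form geometric mean")
      }
      rr[i] <- geometric_mean_rate(r_ap, r_pa)
      ss[i] <- 0.5 * rr[i] * sqrt((s_ap / r_ap)^2 + (s_pa / r_pa)^2)
      view_used[i] <- "geometric_mean"
    } else {
      k <- sum(sel)
      rr[i] <- mean(net$rate_cps[sel])
      ss[i] <- sqrt(sum(net$sigma_cps[sel]^2)) / k
      view_used[i] <- if (k > 1L) "averaged_single" else "single"
    }
  }
  baseline <- rr[1L]
  if (baseline - residual_rate_cps <= 0) {
    stop("baseline net rate does not exceed the residual rate")
  }
  if (any(rr[-1L] > baseline)) {
    warning(paste("net rate above baseline after t = 0;",
                  "geometry or contamination suspect"))
  }
  frac <- (rr - residual_rate_cps) / (baseline - residual_rate_cps)
  frac <- pmax(frac, 0)
  scale <- admin_activity_MBq / (baseline - residual_rate_cps)
  out <- data.frame(time_h = tt,
                    activity_MBq = admin_activity_MBq * frac,
                    sigma_MBq = ss * scale)
  structure(out, class = c("retention_curve", "data.frame"),
            admin_activity_MBq = admin_activity_MBq,
            baseline_rate_cps = baseline,
            residual_rate_cps = residual_rate_cps,
            view_used = view_used)
}

#' @export
print.retention_curve <- function(x, ...) {
  cat(sprintf(
    "Whole-body retention curve: %d time points, %.4g MBq administered\n",
    nrow(x), attr(x, "admin_activity_MBq")))
  cat(sprintf("Baseline %.4g cps, residual %.4g cps\n",
              attr(x, "baseline_rate_cps"), attr(x, "residual_rate_cps")))
  print(data.frame(unclass(x)[c("time_h", "activity_MBq", "sigma_MBq")]),
        ...)
  invisible(x)
}
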