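# Mono/multi-exponential time-activity curve fitting, statistical model
# selection (extra-sum-of-squares F test, AICc) and closed-form
# time-integrated activity.
#
# The fitted model is A(t) = sum_j A_j exp(-lambda_j t) with effective
# decay constants lambda_j (biological clearance + physical decay).

#' Construct an exponential time-activity model
#'
#' @param amplitudes phase amplitudes (MBq); finite.
#' @param lambdas effective decay constants per phase (1/h); positive.
#' @return an object of class `exp_model`, with phases ordered by
#'   decreasing decay constant (fastest first).
#' @export
exp_model <- function(amplitudes, lambdas) {
  if (length(amplitudes) != length(lambdas) || length(lambdas) < 1L) {
    stop("amplitudes and lambdas must have equal positive length")
  }
  if (any(!is.finite(amplitudes)) || any(lambdas <= 0)) {
    stop("amplitudes must be finite and lambdas positive")
  }
  ord <- order(lambdas, decreasing = TRUE)
  structure(list(amplitudes = amplitudes[ord], lambdas = lambdas[ord],
                 n_phases = length(lambdas)),
            class = "exp_model")
}

#' Exponential model from an initial activity and effective half-life
#'
#' Convenience constructor for the common mono-exponential case reported
#' as `A0` and `T_eff`: `lambda = ln(2) / T_eff`.
#'
#' @param A0_MBq initial activity (MBq).
#' @param T_eff_h effective half-life (hours).
#' @return an [exp_model] with one phase.
#' @export
mono_exp_model <- function(A0_MBq, T_eff_h) {
  if (T_eff_h <= 0) stop("effective half-life must be positive")
  exp_model(A0_MBq, log(2) / T_eff_h)
}

#' @export
print.exp_model <- function(x, ...) {
  cat(sprintf("%d-phase exponential model\n", x$n_phases))
  for (j in seq_len(x$n_phases)) {
    cat(sprintf("  A%d = %.6g MBq, lambda%d = %.6g 1/h (T1/2 = %.4g h)\n",
                j, x$amplitudes[j], j, x$lambdas[j], log(2) / x$lambdas[j]))
  }
  invisible(x)
}

#' @export
predict.exp_model <- function(object, times_h, ...) {
  vapply(times_h, function(t) {
    sum(object$amplitudes * exp(-object$lambdas * t))
  }, numeric(1L))
}

# ---------------------------------------------------------------------------

# Curve-stripping starting values: peel the slowest phase from the tail by
# log-linear regression, subtract, recurse on the residual. Falls back to a
# geometric spread around the mono-exponential rate when stripping runs out
# of positive residuals (common on noisy data).
strip_start <- function(time_h, activity, n_phases) {
  stopifnot(all(activity > 0))
  loglin <- function(t, a) {
    f <- lm(log(a) ~ t)
    c(A = exp(coef(f)[[1L]]), lambda = max(-coef(f)[[2L]], 1e-6))
  }
  mono <- loglin(time_h, activity)
  if (n_phases == 1L) {
    return(list(A = mono[["A"]], lambda = mono[["lambda"]]))
  }
  A <- numeric(n_phases)
  lam <- numeric(n_phases)
  t <- time_h
  a <- activity
  ok <- TRUE
  for (j in seq(n_phases, 2L)) {
    m <- max(3L, ceiling(length(t) / j))
    idx <- seq(length(t) - m + 1L, length(t))
    ph <- loglin(t[idx], a[idx])
    A[j] <- ph[["A"]]
    lam[j] <- ph[["lambda"]]
    resid <- a - ph[["A"]] * exp(-ph[["lambda"]] * t)
    keep <- which(resid > 0 & seq_along(t) < min(idx))
    if (length(keep) < 2L) {
      ok <- FALSE
      break
    }
    t <- t[keep]
    a <- resid[keep]
  }
  if (ok) {
    ph <- loglin(t, a)
    A[1L] <- ph[["A"]]
    lam[1L] <- ph[["lambda"]]
  }
  if (!ok || any(lam <= 0) || anyDuplicated(signif(lam, 6L))) {
    # spread phases geometrically around the mono-exponential rate
    spread <- 4^(seq_len(n_phases) - (n_phases + 1) / 2)
    lam <- rev(mono[["lambda"]] * spread)
    A <- rep(mono[["A"]] / n_phases, n_phases)
  }
  # order: phase 1 fastest
  ord <- order(lam, decreasing = TRUE)
  list(A = A[ord], lambda = lam[ord])
}

#' Fit a multi-exponential model to time-activity data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `A(t) = sum_j A_j exp(-lambda_j t)` with starting values from curve
#' stripping. At least `2 n_phases + 1` points are required; a warning is
#' issued when fewer than 3 points per phase are available. A negative
#' fitted amplitude triggers a refit with one phase fewer (phases merged),
#' with a warning.
#'
#' @param time_h measurement times (hours), strictly increasing.
#' @param activity_MBq activities (must be positive for the stripping
#'   initialisation).
#' @param n_phases number of exponential phases (1--3).
#' @param sigma_MBq optional per-point standard uncertainties, used when
#'   `weight_scheme = "inverse_variance"`.
#' @param weight_scheme `"unweighted"` (default) or `"inverse_variance"`.
#' @return an object of class `exp_fit`: the fitted [exp_model], residual
#'   sum of squares `rss`, degrees of freedom `dof = n - 2 n_phases`,
#'   parameter `covariance` (rows/cols `A1, lambda1, ...` in fast-to-slow
#'   phase order), the data, and the weighting tag.
#' @examples
#' t <- c(0, 4, 12, 24, 48, 96)
#' fit <- fit_exponentials(t, 1000 * exp(-0.1 * t))
#' coef(fit)
#' @export
fit_exponentials <- function(time_h, activity_MBq, n_phases = 1L,
                             sigma_MBq = NULL,
                             weight_scheme = c("unweighted",
                                               "inverse_variance")) {
  weight_scheme <- match.arg(weight_scheme)
  n <- length(time_h)
  if (length(activity_MBq) != n) stop("time and activity length mismatch")
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(activity_MBq <= 0)) {
    stop("activities must be positive for curve-stripping initialisation")
  }
  if (n_phases < 1L || n_phases > 3L) stop("n_phases must be 1, 2 or 3")
  if (n < 2L * n_phases + 1L) {
    stop(sprintf("at least %d points needed for %d phases (got %d)",
                 2L * n_phases + 1L, n_phases, n))
  }
  if (n < 3L * n_phases) {
    warning("fewer than 3 data points per phase; fit may be unstable")
  }
  w <- NULL
  if (weight_scheme == "inverse_variance") {
    if (is.null(sigma_MBq) || any(sigma_MBq <= 0)) {
      stop("inverse-variance weighting needs positive sigma_MBq")
    }
    w <- 1 / sigma_MBq^2
  }
  start <- strip_start(time_h, activity_MBq, n_phases)
  k <- n_phases
  pnames <- c(paste0("A", seq_len(k)), paste0("l", seq_len(k)))
  rhs <- paste(sprintf("A%d * exp(-l%d * t)", seq_len(k), seq_len(k)),
               collapse = " + ")
  form <- as.formula(paste("a ~", rhs))
  df <- data.frame(t = time_h, a = activity_MBq)
  lower <- c(rep(-Inf, k), rep(1e-8, k))
  # deterministic multi-start: curve-stripping values first, then (for
  # multi-phase fits) geometric spreads around the mono-exponential rate,
  # guarding against local optima; best converged RSS wins
  starts <- list(c(start$A, start$lambda))
  if (k >= 2L) {
    mono <- strip_start(time_h, activity_MBq, 1L)
    for (fac in c(2, 4, 8)) {
      spread <- fac^(seq_len(k) - (k + 1) / 2)
      starts <- c(starts, list(c(rep(mono$A / k, k),
                                 sort(mono$lambda * spread,
                                      decreasing = TRUE))))
    }
    # uptake-shaped curves (initial rise) have a negative fast amplitude
    if (which.max(activity_MBq) > 1L) {
      for (st in starts) {
        starts <- c(starts, list(c(-st[1L], st[-1L])))
      }
    }
  }
  fit <- NULL
  best_rss <- Inf
  for (st in starts) {
    args <- list(form, data = df,
                 start = as.list(setNames(st, pnames)), lower = lower,
                 control = nls.lm.control(maxiter = 500, ftol = 1e-10,
                                          ptol = 1e-10))
    if (!is.null(w)) args$weights <- w
    cand <- tryCatch(suppressWarnings(do.call(nlsLM, args)),
                     error = function(e) NULL)
    if (!is.null(cand)) {
      rss_c <- if (is.null(w)) sum(residuals(cand)^2) else
        sum(w * (df$a - fitted(cand))^2)
      if (rss_c < best_rss) {
        fit <- cand
        best_rss <- rss_c
      }
    }
  }
  if (is.null(fit)) {
    stop(sprintf(
      "exponential fit (%d phases) did not converge from any start; %s",
      k, paste(sprintf("%s=%.4g", pnames, starts[[1L]]),
               collapse = ", ")), call. = FALSE)
  }
  cf <- coef(fit)
  amps <- cf[seq_len(k)]
  lams <- cf[k + seq_len(k)]
  if (any(amps < 0)) {
    if (k == 1L) {
      stop("fitted amplitude negative in mono-exponential fit")
    }
    warning("negative fitted amplitude; refitting with one phase fewer")
    return(fit_exponentials(time_h, activity_MBq, k - 1L, sigma_MBq,
                            weight_scheme))
  }
  model <- exp_model(amps, lams)
  # covariance reordered to match the fast-to-slow phase ordering
  ord <- order(lams, decreasing = TRUE)
  perm <- c(ord, k + ord)
  cv <- tryCatch(vcov(fit)[perm, perm, drop = FALSE],
                 error = function(e) matrix(NA_real_, 2L * k, 2L * k))
  nm <- c(paste0("A", seq_len(k)), paste0("lambda", seq_len(k)))
  dimnames(cv) <- list(nm, nm)
  res <- activity_MBq - predict(model, time_h)
  rss <- if (is.null(w)) sum(res^2) else sum(w * res^2)
  structure(
    list(model = model, rss = rss, dof = n - 2L * k, covariance = cv,
         weights = weight_scheme,
         data = data.frame(time_h = time_h, activity_MBq = activity_MBq),
         nls = fit),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential time-activity fit (%s)\n", x$weights))
  print(x$model)
  cat(sprintf("  RSS %.6g on %d degrees of freedom\n", x$rss, x$dof))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  k <- object$model$n_phases
  setNames(c(object$model$amplitudes, object$model$lambdas),
           c(paste0("A", seq_len(k)), paste0("lambda", seq_len(k))))
}

#' @export
vcov.exp_fit <- function(object, ...) object$covariance

#' @export
predict.exp_fit <- function(object, times_h = object$data$time_h, ...) {
  predict(object$model, times_h)
}

#' @export
fitted.exp_fit <- function(object, ...) predict(object)

#' @export
residuals.exp_fit <- function(object, ...) {
  object$data$activity_MBq - fitted(object)
}

#' @export
summary.exp_fit <- function(object, ...) {
  k <- object$model$n_phases
  se <- sqrt(pmax(diag(object$covariance), 0))
  out <- data.frame(estimate = coef(object), se = se)
  half <- log(2) / object$model$lambdas
  structure(list(coefficients = out, half_lives_h = half, rss = object$rss,
                 dof = object$dof,
                 tia_MBq_h = time_integrated_activity(object)),
            class = "summary.exp_fit")
}

#' @export
print.summary.exp_fit <- function(x, ...) {
  print(x$coefficients)
  cat("Effective half-lives (h):", sprintf("%.4g", x$half_lives_h), "\n")
  cat(sprintf("RSS %.6g on %d dof; A~(0, Inf) = %.6g MBq.h\n",
              x$rss, x$dof, x$tia_MBq_h))
  invisible(x)
}

# internal: extract an exp_model from exp_fit / exp_model
as_exp_model <- function(model) {
  if (inherits(model, "exp_fit")) return(model$model)
  if (inherits(model, "exp_model")) return(model)
  stop("model must be an exp_model or exp_fit")
}

#' Extra-sum-of-squares F test between nested exponential fits
#'
#' `F = ((rss_s - rss_c) / (df_s - df_c)) / (rss_c / df_c)`; the more
#' complex model is chosen iff `p < alpha`.
#'
#' @param fit_simple,fit_complex nested [fit_exponentials()] results on the
#'   same data, the complex one with more phases.
#' @param alpha significance level (default 0.05).
#' @return a list with `F`, `dfn`, `dfd`, `p`, `chosen` (the selected
#'   `exp_fit`) and `chosen_label` (`"simple"` or `"complex"`).
#' @export
f_test_select <- function(fit_simple, fit_complex, alpha = 0.05) {
  stopifnot(inherits(fit_simple, "exp_fit"), inherits(fit_complex, "exp_fit"))
  if (!isTRUE(all.equal(fit_simple$data, fit_complex$data))) {
    stop("fits must be on identical data")
  }
  if (fit_complex$model$n_phases <= fit_simple$model$n_phases) {
    stop("fit_complex must have more phases than fit_simple")
  }
  if (fit_complex$rss > fit_simple$rss * (1 + 1e-12)) {
    stop("complex fit has larger RSS than simple fit; fits inconsistent")
  }
  dfn <- fit_simple$dof - fit_complex$dof
  dfd <- fit_complex$dof
  Fval <- ((fit_simple$rss - fit_complex$rss) / dfn) /
    (fit_complex$rss / dfd)
  Fval <- max(Fval, 0)
  p <- pf(Fval, dfn, dfd, lower.tail = FALSE)
  complex_wins <- p < alpha
  list(F = Fval, dfn = dfn, dfd = dfd, p = p,
       chosen = if (complex_wins) fit_complex else fit_simple,
       chosen_label = if (complex_wins) "complex" else "simple",
       alpha = alpha)
}

# small-sample-corrected Akaike information criterion from RSS
aicc_from_fit <- function(fit) {
  n <- nrow(fit$data)
  k <- 2L * fit$model$n_phases + 1L  # parameters + error variance
  aic <- n * log(fit$rss / n) + 2 * k
  if (n - k - 1L <= 0L) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Select among exponential fits by corrected AIC
#'
#' Returns the fit minimising the small-sample-corrected Akaike
#' information criterion (AICc); ties are broken toward fewer phases.
#'
#' @param fits a list of [fit_exponentials()] results on identical data.
#' @return the selected `exp_fit`, with an attribute `aicc` giving the
#'   criterion value per candidate.
#' @export
aic_select <- function(fits) {
  if (!is.list(fits) || length(fits) < 1L ||
      !all(vapply(fits, inherits, logical(1L), "exp_fit"))) {
    stop("fits must be a list of exp_fit objects")
  }
  if (length(fits) == 1L) return(fits[[1L]])
  ref <- fits[[1L]]$data
  for (f in fits[-1L]) {
    if (!isTRUE(all.equal(ref, f$data))) stop("fits must share the same data")
  }
  aicc <- vapply(fits, aicc_from_fit, numeric(1L))
  phases <- vapply(fits, function(f) f$model$n_phases, integer(1L))
  best <- order(aicc, phases)[1L]
  out <- fits[[best]]
  attr(out, "aicc") <- aicc
  out
}

#' Time-integrated activity of an exponential model
#'
#' Closed form: `sum_j A_j / lambda_j * (exp(-lambda_j t1) -
#' exp(-lambda_j t2))`, with `t2 = Inf` allowed (total number of nuclear
#' transformations, MBq.h).
#'
#' @param model an [exp_model] or `exp_fit`.
#' @param t_start,t_end integration bounds in hours, `t_start < t_end`.
#' @return time-integrated activity in MBq.h.
#' @examples
#' time_integrated_activity(mono_exp_model(1010, 41.43))  # ~60,370 MBq.h
#' @export
time_integrated_activity <- function(model, t_start = 0, t_end = Inf) {
  m <- as_exp_model(model)
  if (!(t_start < t_end)) stop("t_start must be below t_end")
  upper <- if (is.infinite(t_end)) 0 else exp(-m$lambdas * t_end)
  sum(m$amplitudes / m$lambdas * (exp(-m$lambdas * t_start) - upper))
}

#' Uncertainty of the time-integrated activity of a fitted model
#'
#' First-order propagation of the fit covariance through the closed-form
#' integral over `[0, Inf)`.
#'
#' @param fit an `exp_fit`.
#' @return standard uncertainty of the time-integrated activity (MBq.h).
#' @export
tia_uncertainty <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  m <- fit$model
  grad <- c(1 / m$lambdas, -m$amplitudes / m$lambdas^2)
  cv <- fit$covariance
  if (anyNA(cv)) return(NA_real_)
  sqrt(max(drop(t(grad) %*% cv %*% grad), 0))
}

#' Fraction of the total time-integrated activity covered by measurements
#'
#' The ratio of the time-integrated activity between the first and last
#' measurements to the total from zero to infinity. A fraction of at least
#' 0.8 indicates the sampling adequately characterises the curve.
#'
#' @param model an [exp_model] or `exp_fit`.
#' @param t_first,t_last first and last measurement times (hours),
#'   `0 <= t_first < t_last` (`t_last = Inf` allowed).
#' @return the coverage fraction, with attribute `meets_recommendation`
#'   (`TRUE` iff >= 0.8).
#' @export
coverage_fraction <- function(model, t_first, t_last) {
  if (t_first < 0 || !(t_first < t_last)) {
    stop("need 0 <= t_first < t_last")
  }
  frac <- time_integrated_activity(model, t_first, t_last) /
    time_integrated_activity(model, 0, Inf)
  structure(frac, meets_recommendation = frac >= 0.8)
}
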