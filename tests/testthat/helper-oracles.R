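# Independent oracles used across the suite.

# numeric-quadrature time-integrated activity: adaptive quadrature over a
# finite window plus the analytic tail of the slowest phase
tia_quadrature <- function(model, t_start = 0, t_end = Inf) {
  m <- if (inherits(model, "exp_fit")) model$model else model
  f <- function(t) predict(m, t)
  if (is.infinite(t_end)) {
    t_split <- t_start + 10 * max(log(2) / m$lambdas)
    finite <- integrate(f, t_start, t_split, rel.tol = 1e-10,
                        subdivisions = 500L)$value
    tail <- sum(m$amplitudes / m$lambdas * exp(-m$lambdas * t_split))
    finite + tail
  } else {
    integrate(f, t_start, t_end, rel.tol = 1e-10,
              subdivisions = 500L)$value
  }
}

# exhaustive 3x3x3 block-mean scan (triple loop, no shared code with the
# implementation)
block27_brute <- function(arr, mask) {
  d <- dim(arr)
  best_max <- -Inf
  best_min <- Inf
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    sub_m <- mask[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    if (!all(sub_m)) next
    m <- mean(arr[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)])
    if (m > best_max) best_max <- m
    if (m < best_min) best_min <- m
  }
  list(max = best_max, min = best_min)
}

# circular body mask as a single-slice logical array, centre at a voxel
make_circle_mask <- function(n, voxel_mm, radius_mm,
                             centre_vox = c(n / 2, n / 2)) {
  xy <- (seq_len(n) - 0.5) * voxel_mm
  cx <- (centre_vox[1] - 0.5) * voxel_mm
  cy <- (centre_vox[2] - 0.5) * voxel_mm
  d <- sqrt(outer((xy - cx)^2, (xy - cy)^2, "+"))
  array(d <= radius_mm, dim = c(n, n, 1))
}

# build a minimal exp_fit skeleton with prescribed rss/dof on shared data
# (for exercising the F-test arithmetic in isolation)
fake_exp_fit <- function(rss, dof, n_phases, data) {
  structure(list(model = exp_model(rep(1, n_phases),
                                   seq_len(n_phases)),
                 rss = rss, dof = dof,
                 covariance = diag(2 * n_phases), weights = "unweighted",
                 data = data),
            class = "exp_fit")
}
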