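# SPECT VOI quantification: voxel-image container, triple-energy-window
# scatter correction, first-order Chang attenuation correction,
# adaptive-threshold volume delineation, block-27 uptake extrema and the
# count-rate -> activity conversion.

#' Voxel image container
#'
#' A 3-D numeric array with voxel sizes in mm, a value-unit tag and an
#' optional frame duration. 2-D input is promoted to a single-slice 3-D
#' array.
#'
#' @param data numeric array (2-D or 3-D) of voxel values, all finite.
#' @param voxel_mm voxel size per axis in mm (length 1 or 3, > 0).
#' @param units value-unit tag, e.g. `"cps"` or `"counts"`.
#' @param frame_duration_s acquisition duration per frame (s), if known.
#' @param corrections character vector of corrections already applied
#'   (provenance, prevents double correction), e.g. `"tew"`, `"chang"`.
#' @return an object of class `voxel_image`.
#' @export
voxel_image <- function(data, voxel_mm, units = "cps",
                        frame_duration_s = NA_real_,
                        corrections = character()) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 2-D or 3-D array")
  }
  if (any(!is.finite(data))) stop("voxel values must be finite")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0)) {
    stop("voxel_mm must be 1 or 3 positive values")
  }
  structure(list(data = data, voxel_mm = voxel_mm, units = units,
                 frame_duration_s = frame_duration_s,
                 corrections = corrections),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("Voxel image %s, voxels %.3g x %.3g x %.3g mm [%s]\n",
              paste(dim(x$data), collapse = " x "),
              x$voxel_mm[1L], x$voxel_mm[2L], x$voxel_mm[3L], x$units))
  if (length(x$corrections)) {
    cat("  corrections applied:", paste(x$corrections, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Voxel volume of an image, in ml
#'
#' @param image a [voxel_image()].
#' @return the volume of a single voxel in ml (mm^3 / 1000).
#' @export
voxel_volume_ml <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  prod(image$voxel_mm) / 1000
}

#' Read / write voxel images as NIfTI-1
#'
#' Thin wrappers around RNifti preserving voxel sizes. The value-unit tag
#' and frame duration are not representable in plain NIfTI and must be
#' supplied on read.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param image a [voxel_image()] (for writing).
#' @param units,frame_duration_s metadata for the returned image.
#' @return `read_voxel_image` returns a [voxel_image()];
#'   `write_voxel_image` returns `path` invisibly.
#' @export
read_voxel_image <- function(path, units = "cps",
                             frame_duration_s = NA_real_) {
  nii <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(nii)[1:3]
  arr <- as.array(nii)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  voxel_image(arr, vox, units = units, frame_duration_s = frame_duration_s)
}

#' @rdname read_voxel_image
#' @export
write_voxel_image <- function(image, path) {
  stopifnot(inherits(image, "voxel_image"))
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- image$voxel_mm
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Energy window set for triple-energy-window scatter correction
#'
#' Defaults follow standard 131I practice: a 20% window around the
#' 364 keV photopeak and 6% scatter windows immediately adjacent on
#' either side.
#'
#' @param peak_keV photopeak energy (keV).
#' @param peak_frac fractional width of the main window (0.15--0.20
#'   typical).
#' @param scatter_frac fractional width of each scatter window.
#' @return an object of class `energy_windows` with `peak`, `lower` and
#'   `upper` components, each `c(center, width)` in keV.
#' @export
energy_windows <- function(peak_keV = 364, peak_frac = 0.20,
                           scatter_frac = 0.06) {
  if (peak_keV <= 0 || peak_frac <= 0 || scatter_frac <= 0) {
    stop("all window parameters must be positive")
  }
  wp <- peak_frac * peak_keV
  ws <- scatter_frac * peak_keV
  win <- structure(list(
    peak = c(center = peak_keV, width = wp),
    lower = c(center = peak_keV - wp / 2 - ws / 2, width = ws),
    upper = c(center = peak_keV + wp / 2 + ws / 2, width = ws)),
    class = "energy_windows")
  validate_energy_windows(win)
  win
}

validate_energy_windows <- function(win) {
  if (any(c(win$peak["width"], win$lower["width"], win$upper["width"]) <= 0)) {
    stop("window widths must be positive")
  }
  if (!(win$lower["center"] < win$peak["center"] &&
        win$peak["center"] < win$upper["center"])) {
    stop("windows must be ordered lower < peak < upper")
  }
  lo_hi <- win$lower["center"] + win$lower["width"] / 2
  pk_lo <- win$peak["center"] - win$peak["width"] / 2
  pk_hi <- win$peak["center"] + win$peak["width"] / 2
  up_lo <- win$upper["center"] - win$upper["width"] / 2
  if (lo_hi > pk_lo + 1e-9 || up_lo < pk_hi - 1e-9) {
    stop("energy windows must not overlap")
  }
  invisible(win)
}

#' Triple-energy-window scatter correction
#'
#' `C_sc = C_peak - (W_peak / 2) * (C1 / W1 + C2 / W2)`, applied
#' element-wise and clamped at zero (counts are non-negative).
#'
#' @param c_peak counts in the main window (scalar, vector or array).
#' @param c_lower,c_upper counts in the lower/upper scatter windows,
#'   same shape as `c_peak`.
#' @param windows an [energy_windows()] set.
#' @return scatter-corrected counts, same shape as `c_peak`.
#' @examples
#' tew_correct(1000, 120, 60, energy_windows())  # 700
#' @export
tew_correct <- function(c_peak, c_lower, c_upper,
                        windows = energy_windows()) {
  if (!inherits(windows, "energy_windows")) {
    stop("windows must be an energy_windows object")
  }
  validate_energy_windows(windows)
  if (any(c_peak < 0) || any(c_lower < 0) || any(c_upper < 0)) {
    stop("counts must be non-negative")
  }
  est <- (windows$peak[["width"]] / 2) *
    (c_lower / windows$lower[["width"]] + c_upper / windows$upper[["width"]])
  pmax(c_peak - est, 0)
}

# --- Chang attenuation correction ------------------------------------------

# bilinear interpolation of a matrix at continuous voxel-centre coordinates
# (x = 1 at the centre of the first voxel); points outside return 0
bilinear_at <- function(mat, x, y) {
  nx <- nrow(mat)
  ny <- ncol(mat)
  out <- numeric(length(x))
  i0 <- floor(x)
  j0 <- floor(y)
  fx <- x - i0
  fy <- y - j0
  ok <- i0 >= 1 & i0 < nx & j0 >= 1 & j0 < ny
  # edge band: clamp to nearest voxel when within half a voxel of the border
  edge <- !ok & x >= 0.5 & x <= nx + 0.5 & y >= 0.5 & y <= ny + 0.5
  if (any(ok)) {
    i <- i0[ok]; j <- j0[ok]; ax <- fx[ok]; ay <- fy[ok]
    v00 <- mat[cbind(i, j)]
    v10 <- mat[cbind(i + 1L, j)]
    v01 <- mat[cbind(i, j + 1L)]
    v11 <- mat[cbind(i + 1L, j + 1L)]
    out[ok] <- v00 * (1 - ax) * (1 - ay) + v10 * ax * (1 - ay) +
      v01 * (1 - ax) * ay + v11 * ax * ay
  }
  if (any(edge)) {
    ii <- pmin(pmax(round(x[edge]), 1L), nx)
    jj <- pmin(pmax(round(y[edge]), 1L), ny)
    out[edge] <- mat[cbind(ii, jj)]
  }
  out
}

# In-mask path lengths (mm) from given voxel centres to the mask boundary
# along n_angles equally spaced in-plane rays. mask: numeric matrix (0/1);
# starts: matrix with columns (i, j) of voxel indices. Marching uses
# half-voxel steps with bilinear mask sampling, then bisects the exit
# interval for sub-step boundary localisation. Returns a matrix
# length(starts) x n_angles of path lengths.
chang_path_lengths <- function(mask, voxel_mm, starts, n_angles = 64L,
                               refine_iter = 8L) {
  theta <- (seq_len(n_angles) - 1L) / n_angles * 2 * pi
  ux <- cos(theta)
  uy <- sin(theta)
  h <- min(voxel_mm[1:2]) / 2            # step length, mm
  nx <- nrow(mask)
  ny <- ncol(mask)
  diag_mm <- sqrt((nx * voxel_mm[1L])^2 + (ny * voxel_mm[2L])^2)
  kmax <- ceiling(diag_mm / h) + 2L
  P <- nrow(starts)
  # ray grid: P voxels x n_angles, flattened
  x0 <- rep(starts[, 1L], times = n_angles)
  y0 <- rep(starts[, 2L], times = n_angles)
  dx <- rep(ux, each = P) * h / voxel_mm[1L]  # step in voxel units
  dy <- rep(uy, each = P) * h / voxel_mm[2L]
  n_rays <- P * n_angles
  lo <- numeric(n_rays)          # last step count known inside
  exited <- rep(FALSE, n_rays)
  active <- seq_len(n_rays)
  k <- 0L
  while (length(active) && k < kmax) {
    k <- k + 1L
    xs <- x0[active] + k * dx[active]
    ys <- y0[active] + k * dy[active]
    inside <- bilinear_at(mask, xs, ys) >= 0.5
    out_now <- !inside
    if (any(out_now)) {
      idx <- active[out_now]
      exited[idx] <- TRUE
      lo[idx] <- k - 1L
      active <- active[inside]
    }
  }
  lo[!exited] <- k  # ray never left the grid (mask touches border)
  d_lo <- lo * h
  d_hi <- pmin((lo + 1) * h, diag_mm)
  # bisection refinement of the boundary crossing
  ref <- which(exited)
  if (length(ref)) {
    a <- d_lo[ref]
    b <- d_hi[ref]
    for (i in seq_len(refine_iter)) {
      mid <- (a + b) / 2
      xs <- x0[ref] + mid / h * dx[ref]
      ys <- y0[ref] + mid / h * dy[ref]
      inside <- bilinear_at(mask, xs, ys) >= 0.5
      a[inside] <- mid[inside]
      b[!inside] <- mid[!inside]
    }
    d_lo[ref] <- (a + b) / 2
  }
  matrix(d_lo, nrow = P, ncol = n_angles)
}

#' Chang attenuation correction factors at voxel positions
#'
#' First-order Chang factor of a voxel:
#' `C(x) = 1 / mean_m(exp(-mu * d_m(x)))` with `d_m` the in-mask path
#' length (cm) to the body boundary along `n_angles` equally spaced
#' in-plane rays.
#'
#' @param mask_slice logical or 0/1 matrix (one transaxial slice).
#' @param voxel_mm in-plane voxel sizes (mm), length 1 or 2.
#' @param voxels matrix with columns (i, j): voxel indices to evaluate.
#' @param mu_per_cm linear attenuation coefficient (1/cm); 0.11 for
#'   364 keV photons in water.
#' @param n_angles number of rays (default 64).
#' @return numeric vector of correction factors (>= 1 for `mu > 0`).
#' @export
chang_factors <- function(mask_slice, voxel_mm, voxels, mu_per_cm = 0.11,
                          n_angles = 64L) {
  if (mu_per_cm < 0) stop("mu must be >= 0")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 2L)
  mask_num <- matrix(as.numeric(mask_slice), nrow = nrow(mask_slice))
  voxels <- matrix(as.numeric(voxels), ncol = 2L)
  if (mu_per_cm == 0) return(rep(1, nrow(voxels)))
  d_mm <- chang_path_lengths(mask_num, voxel_mm, voxels, n_angles)
  trans <- rowMeans(exp(-mu_per_cm * d_mm / 10))
  1 / trans
}

#' First-order Chang attenuation correction of a voxel image
#'
#' Every voxel inside the body mask is multiplied by its Chang correction
#' factor, computed slice by slice with in-plane rays (the method's
#' classical 2-D form). Voxels outside the mask are untouched; `mu = 0`
#' is the identity.
#'
#' @param image a [voxel_image()].
#' @param body_mask logical array on the same grid delineating the body
#'   outline.
#' @param mu_per_cm uniform linear attenuation coefficient (1/cm);
#'   default 0.11, water at 364 keV.
#' @param n_angles rays per voxel (default 64).
#' @return the corrected [voxel_image()] with `"chang"` appended to its
#'   corrections provenance.
#' @export
chang_attenuation_correct <- function(image, body_mask, mu_per_cm = 0.11,
                                      n_angles = 64L) {
  stopifnot(inherits(image, "voxel_image"))
  mask <- as.array(body_mask)
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (!identical(dim(mask), dim(image$data))) {
    stop("mask must be on the same grid as the image")
  }
  if (mu_per_cm < 0) stop("mu must be >= 0")
  if ("chang" %in% image$corrections) {
    warning("image already carries a Chang correction; applying again")
  }
  out <- image$data
  if (mu_per_cm > 0) {
    for (z in seq_len(dim(mask)[3L])) {
      msk <- mask[, , z] != 0
      if (!any(msk)) next
      vox <- which(msk, arr.ind = TRUE)
      f <- chang_factors(msk, image$voxel_mm[1:2], vox, mu_per_cm, n_angles)
      out[, , z][msk] <- image$data[, , z][msk] * f
    }
  }
  voxel_image(out, image$voxel_mm, units = image$units,
              frame_duration_s = image$frame_duration_s,
              corrections = c(image$corrections, "chang"))
}

#' VOI count rate and volume
#'
#' @param image a [voxel_image()] in cps units.
#' @param mask logical array on the image grid, non-empty.
#' @return a list with `rate_cps` (sum of in-mask voxel rates) and
#'   `volume_ml` (voxel count times voxel volume).
#' @export
voi_count_rate <- function(image, mask) {
  stopifnot(inherits(image, "voxel_image"))
  mask <- as.array(mask)
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (!identical(dim(mask), dim(image$data))) {
    stop("mask must be on the same grid as the image")
  }
  sel <- mask != 0
  if (!any(sel)) stop("empty mask")
  list(rate_cps = sum(image$data[sel]),
       volume_ml = sum(sel) * voxel_volume_ml(image))
}

# connected component of `sel` containing `seed_idx` (6-connectivity),
# by iterative frontier dilation
flood_select <- function(sel, seed_idx) {
  dims <- dim(sel)
  comp <- array(FALSE, dims)
  frontier <- array(FALSE, dims)
  frontier[seed_idx[1L], seed_idx[2L], seed_idx[3L]] <- TRUE
  if (!sel[seed_idx[1L], seed_idx[2L], seed_idx[3L]]) return(comp)
  shift <- function(a, d, axis) {
    out <- array(FALSE, dim(a))
    n <- dim(a)[axis]
    if (n < 2L) return(out)
    if (axis == 1L) {
      if (d == 1L) out[2:n, , ] <- a[1:(n - 1L), , ]
      else out[1:(n - 1L), , ] <- a[2:n, , ]
    } else if (axis == 2L) {
      if (d == 1L) out[, 2:n, ] <- a[, 1:(n - 1L), ]
      else out[, 1:(n - 1L), ] <- a[, 2:n, ]
    } else {
      if (d == 1L) out[, , 2:n] <- a[, , 1:(n - 1L)]
      else out[, , 1:(n - 1L)] <- a[, , 2:n]
    }
    out
  }
  while (any(frontier)) {
    comp <- comp | frontier
    grown <- shift(frontier, 1L, 1L) | shift(frontier, -1L, 1L) |
      shift(frontier, 1L, 2L) | shift(frontier, -1L, 2L)
    if (dims[3L] > 1L) {
      grown <- grown | shift(frontier, 1L, 3L) | shift(frontier, -1L, 3L)
    }
    frontier <- grown & sel & !comp
  }
  comp
}

#' Adaptive-threshold VOI delineation
#'
#' Bisection on the threshold (expressed as a fraction of the local
#' maximum around the seed) until the connected component containing the
#' seed matches the target volume to within half a voxel, or the
#' iteration budget is exhausted (the nearest bracketed volume is then
#' returned).
#'
#' @param image a [voxel_image()].
#' @param target_volume_ml target VOI volume (ml), larger than one voxel.
#' @param seed_point voxel index `c(i, j, k)` inside the object.
#' @param max_iter bisection iterations (default 50).
#' @return a logical array mask, with attributes `threshold_fraction`,
#'   `volume_ml` and `converged`.
#' @export
adaptive_threshold_mask <- function(image, target_volume_ml, seed_point,
                                    max_iter = 50L) {
  stopifnot(inherits(image, "voxel_image"))
  vv <- voxel_volume_ml(image)
  if (target_volume_ml <= vv) {
    stop("target volume must exceed one voxel volume")
  }
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L ||
      any(seed_point < 1L) || any(seed_point > dim(image$data))) {
    stop("seed_point must be a voxel index inside the image")
  }
  img <- image$data
  seed_val <- img[seed_point[1L], seed_point[2L], seed_point[3L]]
  if (seed_val <= 0) stop("seed point lies in background (non-positive value)")
  # local maximum: highest value in the component containing the seed at a
  # permissive threshold
  base <- flood_select(img > 0.01 * max(img), seed_point)
  if (!base[seed_point[1L], seed_point[2L], seed_point[3L]]) {
    stop("seed point lies in background")
  }
  local_max <- max(img[base])
  vol_at <- function(f) {
    comp <- flood_select(img >= f * local_max, seed_point)
    list(comp = comp, vol = sum(comp) * vv)
  }
  f_lo <- 1e-6   # largest volume
  f_hi <- 1
  v_lo <- vol_at(f_lo)
  v_hi <- vol_at(f_hi)
  if (v_lo$vol < target_volume_ml - vv / 2) {
    stop(sprintf(
      "target volume unreachable: object spans at most %.3g ml", v_lo$vol))
  }
  best <- v_lo
  best_f <- f_lo
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    f <- (f_lo + f_hi) / 2
    cur <- vol_at(f)
    if (abs(cur$vol - target_volume_ml) < abs(best$vol - target_volume_ml)) {
      best <- cur
      best_f <- f
    }
    if (abs(cur$vol - target_volume_ml) <= vv / 2) {
      converged <- TRUE
      best <- cur
      best_f <- f
      break
    }
    if (cur$vol > target_volume_ml) f_lo <- f else f_hi <- f
  }
  structure(best$comp, threshold_fraction = best_f,
            volume_ml = best$vol, converged = converged)
}

#' Extrema of 27-voxel block means inside a mask
#'
#' Means over 3x3x3 voxel blocks whose 27 voxels all lie inside the mask;
#' reports the maximum and minimum block means (sub-volume uptake
#' extrema, less noise-prone than single-voxel extremes).
#'
#' @param image a [voxel_image()].
#' @param mask logical array on the image grid.
#' @return a list with `max_block_mean`, `min_block_mean` and the block
#'   `centers` (voxel indices, one row each for max and min).
#' @export
block27_extrema <- function(image, mask) {
  stopifnot(inherits(image, "voxel_image"))
  mask <- as.array(mask)
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (!identical(dim(mask), dim(image$data))) {
    stop("mask must be on the same grid as the image")
  }
  d <- dim(mask)
  if (any(d < 3L)) stop("image too small for a 3x3x3 block")
  img <- image$data
  nin <- d - 2L  # dimensions of the valid block-centre grid
  sum_img <- array(0, nin)
  cnt_msk <- array(0L, nin)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    blk <- img[dx + seq_len(nin[1L]), dy + seq_len(nin[2L]),
               dz + seq_len(nin[3L]), drop = FALSE]
    mbk <- mask[dx + seq_len(nin[1L]), dy + seq_len(nin[2L]),
                dz + seq_len(nin[3L]), drop = FALSE]
    sum_img <- sum_img + blk
    cnt_msk <- cnt_msk + (mbk != 0)
  }
  valid <- cnt_msk == 27L
  if (!any(valid)) stop("mask admits no fully interior 3x3x3 block")
  means <- sum_img / 27
  means[!valid] <- NA
  imax <- which(means == max(means, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  imin <- which(means == min(means, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  list(max_block_mean = max(means, na.rm = TRUE),
       min_block_mean = min(means, na.rm = TRUE),
       centers = rbind(max = imax + 1L, min = imin + 1L))
}

#' Average projection count rate
#'
#' Mean over projections of counts divided by frame duration; the rate
#' entering the average dead-time correction of a SPECT acquisition.
#'
#' @param projection_counts either a vector of total counts per
#'   projection, or a 3-D array with projections along the third
#'   dimension (summed over the detector grid).
#' @param frame_duration_s frame duration(s) in seconds (scalar or one
#'   per projection, > 0).
#' @return average count rate in cps.
#' @export
average_projection_rate <- function(projection_counts, frame_duration_s) {
  if (any(frame_duration_s <= 0)) stop("durations must be positive")
  if (is.array(projection_counts) && length(dim(projection_counts)) == 3L) {
    projection_counts <- apply(projection_counts, 3L, sum)
  }
  mean(projection_counts / frame_duration_s)
}

#' Convert a VOI count rate to activity
#'
#' `A = C / (Q * R) * DTF`: the measured VOI count rate corrected for
#' sensitivity, partial-volume recovery and dead time.
#'
#' @param count_rate_cps VOI count rate (cps).
#' @param Q calibration factor (cps/MBq, > 0).
#' @param R recovery coefficient (0 < R, typically <= 1).
#' @param DTF dead-time correction factor (>= 1).
#' @return activity in MBq.
#' @examples
#' activity_from_voi(29.2, Q = 29.2, R = 0.5, DTF = 1.2)  # 2.4 MBq
#' @export
activity_from_voi <- function(count_rate_cps, Q, R = 1, DTF = 1) {
  if (Q <= 0) stop("Q must be positive")
  if (any(R <= 0)) stop("R must be positive")
  if (any(DTF < 1)) stop("DTF must be >= 1")
  count_rate_cps / (Q * R) * DTF
}

#' Full VOI measurement at one scan time
#'
#' Applies the camera model to a VOI count rate: selects the dead-time
#' mode from the average projection rate, evaluates the recovery curve at
#' the VOI volume and converts to activity.
#'
#' @param scan_time_h scan time post administration (hours).
#' @param count_rate_cps VOI count rate (cps).
#' @param voi_volume_ml VOI volume (ml).
#' @param camera a [camera_model()].
#' @param projection_rate_cps average projection count rate driving the
#'   dead-time correction; defaults to no dead-time correction when `NA`.
#' @param apply_recovery apply the camera's recovery curve (default TRUE
#'   when one is attached).
#' @return a data.frame row with `scan_time_h`, `rate_cps`, `volume_ml`,
#'   `DTF`, `R` and `activity_MBq` (the stored fields satisfy
#'   `activity = rate / (Q R) * DTF` exactly).
#' @export
voi_measurement <- function(scan_time_h, count_rate_cps, voi_volume_ml,
                            camera, projection_rate_cps = NA_real_,
                            apply_recovery = !is.null(camera$recovery)) {
  stopifnot(inherits(camera, "camera_model"))
  DTF <- if (is.na(projection_rate_cps)) 1 else {
    dead_time_factor(projection_rate_cps,
                     tau_for_rate(camera, projection_rate_cps))
  }
  R <- if (apply_recovery) {
    if (is.null(camera$recovery)) stop("camera has no recovery curve")
    interpolate_recovery(camera$recovery, voi_volume_ml)
  } else 1
  data.frame(scan_time_h = scan_time_h, rate_cps = count_rate_cps,
             volume_ml = voi_volume_ml, DTF = DTF, R = R,
             activity_MBq = activity_from_voi(count_rate_cps, camera$Q,
                                              R, DTF))
}
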