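#' Session-level denoising and quality control
#'
#' Implements the analysis-side preprocessing chain for already-aligned 4D
#' data: initial-volume discarding, CompCor tissue components, the
#' 12-parameter motion regressor expansion, motion/intensity scrubbing,
#' participant-level exclusion rules, simultaneous nuisance regression with
#' first-order detrending, zero-phase 0.01-0.1 Hz band-pass filtering, and
#' Gaussian smoothing of derived maps. The global signal is never removed.
#'
#' @name preprocess
NULL

#' Discard initial volumes
#'
#' Drops the first `n` volumes (T1-equilibration transients). The caller
#' must trim the motion trace identically.
#'
#' @param bold A [bold_series()].
#' @param n Number of leading volumes to drop (default 5).
#' @return The trimmed [bold_series()].
#' @export
discard_initial_volumes <- function(bold, n = 5L) {
  n <- as.integer(n)
  if (n < 0 || n >= bold$n_volumes) {
    stop("n must satisfy 0 <= n < n_volumes (", bold$n_volumes, "), got ", n)
  }
  if (n == 0L) return(bold)
  bold_series(bold$data[, , , (n + 1):bold$n_volumes, drop = FALSE],
              affine = bold$affine, tr_s = bold$tr_s)
}

#' CompCor nuisance components
#'
#' One PCA over the pooled white-matter + CSF voxel set: each voxel's series
#' is linearly detrended and standardized, then the top-`k` principal
#' component time courses (by singular value) are returned, each scaled to
#' unit variance.
#'
#' @param bold A [bold_series()] (post-discard).
#' @param wm_mask,csf_mask Logical 3D masks on the BOLD grid.
#' @param k Number of components (default 5).
#' @return T x k matrix of component time courses.
#' @export
compcor_components <- function(bold, wm_mask, csf_mask, k = 5L) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  mask <- wm_mask | csf_mask
  if (!any(mask)) stop("WM/CSF masks are empty")
  if (sum(mask) < k) stop("pooled tissue mask has fewer than k = ", k, " voxels")
  y <- .mask_matrix(bold, mask)                 # T x V
  n_t <- nrow(y)
  tt <- seq_len(n_t)
  y <- as.matrix(stats::resid(stats::lm.fit(cbind(1, tt), y)))
  s <- apply(y, 2, stats::sd)
  s[s == 0] <- 1
  y <- sweep(y, 2, s, "/")
  sv <- svd(y, nu = k, nv = 0)
  comp <- sv$u[, seq_len(k), drop = FALSE]
  sweep(comp, 2, apply(comp, 2, stats::sd), "/")
}

#' Expand a motion trace to 12 regressors
#'
#' The six rigid-body parameters plus their first backward differences (the
#' first difference row is zero).
#'
#' @param motion T x 6 matrix (mm translations, rad rotations), already
#'   trimmed to the retained volumes.
#' @return T x 12 matrix.
#' @export
motion_regressors <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp_d", 1:6))
  out
}

# composite framewise motion: translation step plus 65 mm arc-length of the
# rotation step (head-radius convention)
.composite_motion <- function(motion, radius_mm = 65) {
  d <- diff(as.matrix(motion))
  c(0, sqrt(rowSums(d[, 1:3, drop = FALSE]^2)) +
      radius_mm * sqrt(rowSums(d[, 4:6, drop = FALSE]^2)))
}

#' Flag artifact-corrupted volumes
#'
#' A volume is flagged if composite framewise motion exceeds
#' `motion_threshold_mm` or if the z-scored change of the global mean
#' intensity exceeds `global_z_threshold` in absolute value (the
#' "intermediate" artifact-detection setting).
#'
#' @param bold A [bold_series()] (post-discard).
#' @param motion T x 6 motion trace aligned with `bold`.
#' @param motion_threshold_mm Composite-motion threshold (default 0.9 mm).
#' @param global_z_threshold Global-signal-change z threshold (default 5).
#' @return Sorted unique 1-based volume indices.
#' @export
flag_bad_volumes <- function(bold, motion, motion_threshold_mm = 0.9,
                             global_z_threshold = 5) {
  motion <- as.matrix(motion)
  if (nrow(motion) != bold$n_volumes) {
    stop("motion trace (", nrow(motion), " rows) does not match ",
         bold$n_volumes, " volumes")
  }
  cm <- .composite_motion(motion)
  bad_motion <- which(cm > motion_threshold_mm)
  g <- colMeans(matrix(bold$data, ncol = bold$n_volumes))
  dg <- diff(g)
  # robust z of the global-signal change: spikes must not inflate the scale
  s <- stats::mad(dg)
  if (s == 0) s <- stats::sd(dg)
  z <- if (is.na(s) || s == 0) rep(0, length(dg)) else
    (dg - stats::median(dg)) / s
  bad_global <- which(abs(z) > global_z_threshold) + 1L
  sort(unique(c(bad_motion, bad_global)))
}

#' Participant/condition exclusion decision
#'
#' Excludes a session when flagged volumes exceed 30% of the time course or
#' any translation parameter exceeds 3 mm (strict inequalities). The maximum
#' absolute rotation is reported but does not trigger the millimetre rule.
#'
#' @param bad Indices from [flag_bad_volumes()].
#' @param n_retained Number of analyzed volumes.
#' @param motion T x 6 motion trace.
#' @param max_bad_fraction,max_translation_mm Exclusion thresholds
#'   (defaults 0.30 and 3 mm).
#' @return A `qc_report` list: `bad_volume_fraction`,
#'   `max_abs_translation_mm`, `max_abs_rotation`, `excluded`, `reason`.
#' @export
qc_exclusion <- function(bad, n_retained, motion, max_bad_fraction = 0.30,
                         max_translation_mm = 3) {
  stopifnot(n_retained > 0)
  motion <- as.matrix(motion)
  frac <- length(bad) / n_retained
  max_t <- max(abs(motion[, 1:3]))
  max_r <- max(abs(motion[, 4:6]))
  reasons <- character(0)
  if (frac > max_bad_fraction) {
    reasons <- c(reasons, sprintf("bad volumes %.1f%% > %.0f%%", 100 * frac,
                                  100 * max_bad_fraction))
  }
  if (max_t > max_translation_mm) {
    reasons <- c(reasons, sprintf("translation %.2f mm > %g mm", max_t,
                                  max_translation_mm))
  }
  structure(list(bad_volume_fraction = frac, max_abs_translation_mm = max_t,
                 max_abs_rotation = max_r, excluded = length(reasons) > 0,
                 reason = paste(reasons, collapse = "; ")),
            class = "qc_report")
}

#' Assemble the nuisance design matrix
#'
#' Columns: intercept, linear trend, 12 motion regressors, `k` CompCor
#' components — 19 columns at the defaults.
#'
#' @param compcor T x k component matrix from [compcor_components()].
#' @param motion12 T x 12 matrix from [motion_regressors()].
#' @return Labelled T x (2 + 12 + k) matrix.
#' @export
nuisance_matrix <- function(compcor, motion12) {
  n_t <- nrow(motion12)
  stopifnot(nrow(compcor) == n_t)
  trend <- seq_len(n_t) - (n_t + 1) / 2
  x <- cbind(intercept = 1, trend = trend / max(abs(trend)), motion12,
             compcor)
  colnames(x)[(ncol(x) - ncol(compcor) + 1):ncol(x)] <-
    paste0("compcor", seq_len(ncol(compcor)))
  if (any(!is.finite(x))) stop("nuisance matrix contains non-finite values")
  x
}

#' Nuisance regression, scrubbing and band-pass filtering
#'
#' Per voxel: one simultaneous least-squares regression on the nuisance
#' matrix augmented with a one-hot indicator per flagged volume
#' (scrubbing-by-regression, which zeroes the flagged volumes' influence),
#' then zero-phase Butterworth band-pass filtering of the residuals. With
#' `scrub_method = "delete"` flagged volumes are removed instead (temporal
#' spacing is then approximate for the filter).
#'
#' @param bold A [bold_series()] (post-discard).
#' @param nuisance T x p design from [nuisance_matrix()].
#' @param bad Flagged volume indices (possibly empty).
#' @param band Pass band in Hz, default `c(0.01, 0.1)`.
#' @param order Butterworth prototype order (default 2).
#' @param mask Optional logical 3D mask restricting computation; voxels
#'   outside are set to 0.
#' @param scrub_method `"regress"` (default) or `"delete"`.
#' @return A cleaned [bold_series()].
#' @export
clean_timeseries <- function(bold, nuisance, bad = integer(0),
                             band = c(0.01, 0.1), order = 2, mask = NULL,
                             scrub_method = c("regress", "delete")) {
  scrub_method <- match.arg(scrub_method)
  n_t <- bold$n_volumes
  stopifnot(nrow(nuisance) == n_t)
  if (band[1] >= band[2] || band[2] >= 1 / (2 * bold$tr_s)) {
    stop("band must satisfy f_lo < f_hi < Nyquist = ", 1 / (2 * bold$tr_s))
  }
  if (is.null(mask)) mask <- array(TRUE, dim = dim(bold$data)[1:3])
  y <- .mask_matrix(bold, mask)
  x <- nuisance
  bad <- sort(unique(as.integer(bad)))
  if (scrub_method == "regress" && length(bad) > 0) {
    spikes <- matrix(0, n_t, length(bad))
    spikes[cbind(bad, seq_along(bad))] <- 1
    colnames(spikes) <- paste0("scrub", bad)
    x <- cbind(x, spikes)
  }
  if (scrub_method == "delete" && length(bad) > 0) {
    keep <- setdiff(seq_len(n_t), bad)
    y <- y[keep, , drop = FALSE]
    x <- x[keep, , drop = FALSE]
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) stop("nuisance design is rank-deficient (rank ",
                                qr_x$rank, " < ", ncol(x), " columns)")
  res <- qr.resid(qr_x, y)
  filt <- butter_bandpass(band[1], band[2], fs = 1 / bold$tr_s, order = order)
  res <- filtfilt_bandpass(res, filt)
  bold_series(.matrix_to_vol4d(res, mask), affine = bold$affine,
              tr_s = bold$tr_s)
}

# 1D Gaussian kernel, truncated at 4 sigma, unit sum
.gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable 1D convolution along one axis of a 3D array, zero-padded
.convolve_axis <- function(vol, kernel, axis) {
  if (length(kernel) == 1) return(vol)
  half <- (length(kernel) - 1) / 2
  out <- array(0, dim = dim(vol))
  for (s in seq_along(kernel)) {
    shift <- s - 1 - half
    n <- dim(vol)[axis]
    src <- seq_len(n) + shift
    ok <- src >= 1 & src <= n
    if (!any(ok)) next
    idx_to <- which(ok)
    idx_from <- src[ok]
    if (axis == 1) {
      out[idx_to, , ] <- out[idx_to, , , drop = FALSE] +
        kernel[s] * vol[idx_from, , , drop = FALSE]
    } else if (axis == 2) {
      out[, idx_to, ] <- out[, idx_to, , drop = FALSE] +
        kernel[s] * vol[, idx_from, , drop = FALSE]
    } else {
      out[, , idx_to] <- out[, , idx_to, drop = FALSE] +
        kernel[s] * vol[, , idx_from, drop = FALSE]
    }
  }
  out
}

#' Gaussian smoothing of a derived 3D map
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis in voxel units, truncated at 4 sigma. Edge effects are corrected by
#' dividing by the smoothed all-ones volume, so constant maps are preserved
#' exactly. Intended for derived maps (gFCD, zFC), never raw time series.
#'
#' @param map3d 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm; 0 returns the input.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return Smoothed 3D array.
#' @export
smooth_map <- function(map3d, fwhm_mm = 8, voxel_size_mm = 3) {
  stopifnot(fwhm_mm >= 0, voxel_size_mm > 0)
  if (fwhm_mm == 0) return(map3d)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  k <- .gauss_kernel_1d(sigma_vox)
  sm <- map3d
  wt <- array(1, dim = dim(map3d))
  for (ax in 1:3) {
    sm <- .convolve_axis(sm, k, ax)
    wt <- .convolve_axis(wt, k, ax)
  }
  sm / wt
}

#' Run the full per-session preprocessing chain
#'
#' discard -> CompCor -> motion expansion -> scrub flagging -> QC decision ->
#' (if kept) simultaneous nuisance regression + band-pass.
#'
#' @param bold Raw [bold_series()].
#' @param motion Full-length T x 6 motion trace.
#' @param masks List with `wm`, `csf` logical masks (a `gm` entry, if
#'   present, restricts the cleaned output).
#' @param n_discard Leading volumes to drop (default 5).
#' @param compcor_k Number of CompCor components (default 5).
#' @param band Pass band in Hz (default `c(0.01, 0.1)`).
#' @param scrub_motion_mm,scrub_global_z Scrub thresholds (0.9 mm, z 5).
#' @param max_bad_fraction,max_translation_mm Exclusion thresholds (0.30, 3).
#' @return List with `cleaned` ([bold_series()] or `NULL` when excluded),
#'   `qc` (`qc_report`), `bad` (flagged indices, post-discard frame), and
#'   `n_retained`.
#' @export
preprocess_session <- function(bold, motion, masks, n_discard = 5L,
                               compcor_k = 5L, band = c(0.01, 0.1),
                               scrub_motion_mm = 0.9, scrub_global_z = 5,
                               max_bad_fraction = 0.30,
                               max_translation_mm = 3) {
  motion <- as.matrix(motion)
  if (nrow(motion) != bold$n_volumes) {
    stop("motion trace rows (", nrow(motion), ") != volumes (",
         bold$n_volumes, ")")
  }
  bold <- discard_initial_volumes(bold, n_discard)
  motion <- motion[(n_discard + 1):nrow(motion), , drop = FALSE]
  bad <- flag_bad_volumes(bold, motion, scrub_motion_mm, scrub_global_z)
  qc <- qc_exclusion(bad, bold$n_volumes, motion, max_bad_fraction,
                     max_translation_mm)
  cleaned <- NULL
  if (!qc$excluded) {
    cc <- compcor_components(bold, masks$wm, masks$csf, k = compcor_k)
    nuis <- nuisance_matrix(cc, motion_regressors(motion))
    cleaned <- clean_timeseries(bold, nuis, bad, band = band,
                                mask = masks$gm %||% NULL)
  }
  list(cleaned = cleaned, qc = qc, bad = bad, n_retained = bold$n_volumes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
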