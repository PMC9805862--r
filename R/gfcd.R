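#' Global functional connectivity density (gFCD)
#'
#' Per-voxel degree centrality over gray matter: the edge count
#' `K[i] = #{j != i : C_ij > r_threshold}` with `C` the Pearson correlation
#' between voxel time series, and the normalized density `K/K0` where `K0`
#' is the gray-matter mean of `K`. Negative correlations never count; ties
#' at the threshold are non-edges.
#'
#' @name gfcd
NULL

#' gFCD parameters
#'
#' @param r_threshold Positive correlation threshold in (0, 1); default 0.6,
#'   with 0.4 and 0.5 as the standard robustness settings.
#' @param block_size Voxels per block in the pairwise pass; memory scales as
#'   `block_size * n_voxels`.
#' @return A validated parameter list.
#' @export
gfcd_params <- function(r_threshold = 0.6, block_size = 2000L) {
  stopifnot(r_threshold > 0, r_threshold < 1, block_size >= 1)
  list(r_threshold = r_threshold, block_size = as.integer(block_size))
}

#' Compute a gFCD map
#'
#' Voxel series are standardized once; correlations are then inner products
#' computed blockwise, so the result is exact and independent of
#' `block_size`. Zero-variance voxels get `K = 0` with a warning and are not
#' counted as neighbours of any voxel.
#'
#' @param cleaned A preprocessed [bold_series()].
#' @param gm_mask Logical gray-matter mask.
#' @param params A [gfcd_params()] list.
#' @return A `gfcd_map`: `K` and `K_norm` 3D arrays (0 outside the mask),
#'   `K0` (mask mean of K), `mask`, `params`, `n_voxels`.
#' @export
compute_gfcd <- function(cleaned, gm_mask, params = gfcd_params()) {
  if (cleaned$n_volumes < 3) stop("need at least 3 retained volumes")
  y <- .mask_matrix(cleaned, gm_mask)               # T x V
  n_vox <- ncol(y)
  y <- sweep(y, 2, colMeans(y))
  nrm <- sqrt(colSums(y^2))
  zero_var <- nrm == 0
  if (all(zero_var)) stop("all voxels in the mask have zero variance")
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance voxel(s): K set to 0")
    nrm[zero_var] <- 1
  }
  y <- sweep(y, 2, nrm, "/")
  y[, zero_var] <- 0
  k <- integer(n_vox)
  thr <- params$r_threshold
  starts <- seq(1L, n_vox, by = params$block_size)
  for (s in starts) {
    idx <- s:min(s + params$block_size - 1L, n_vox)
    r_blk <- crossprod(y[, idx, drop = FALSE], y)   # nb x V
    k[idx] <- rowSums(r_blk > thr) - 1L             # remove self (r = 1)
  }
  k[zero_var] <- 0L                                 # self-corr 0, not counted
  k0 <- mean(k)
  k_norm <- if (k0 > 0) k / k0 else rep(0, n_vox)
  dims3 <- dim(gm_mask)
  k_vol <- array(0, dims3); k_vol[gm_mask] <- k
  kn_vol <- array(0, dims3); kn_vol[gm_mask] <- k_norm
  structure(list(K = k_vol, K_norm = kn_vol, K0 = k0, mask = gm_mask,
                 params = params, n_voxels = n_vox),
            class = "gfcd_map")
}

#' @export
print.gfcd_map <- function(x, ...) {
  cat(sprintf("<gfcd_map> %d voxels, threshold %.2g, K0 = %.3g\n",
              x$n_voxels, x$params$r_threshold, x$K0))
  invisible(x)
}

#' Smooth the normalized gFCD map
#'
#' Applies [smooth_map()] to `K_norm` (the map that enters statistics),
#' after normalization as the processing order requires.
#'
#' @param map A `gfcd_map`.
#' @param fwhm_mm,voxel_size_mm Smoothing kernel settings.
#' @return The `gfcd_map` with `K_norm` replaced by its smoothed version.
#' @export
smooth_gfcd_map <- function(map, fwhm_mm = 8, voxel_size_mm = 3) {
  map$K_norm <- smooth_map(map$K_norm, fwhm_mm, voxel_size_mm)
  map
}

#' Mean normalized gFCD over a region
#'
#' @param map A `gfcd_map` (smoothed or not) or a plain 3D array.
#' @param region_mask Logical mask; must intersect the gray-matter mask when
#'   `map` is a `gfcd_map`.
#' @return Arithmetic mean of `K_norm` over the region.
#' @export
gfcd_region_mean <- function(map, region_mask) {
  if (inherits(map, "gfcd_map")) {
    sel <- region_mask & map$mask
    if (!any(sel)) stop("region does not intersect the gray-matter mask")
    mean(map$K_norm[sel])
  } else {
    if (!any(region_mask)) stop("empty region")
    mean(map[region_mask])
  }
}
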