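#' Seed-based functional connectivity with Fisher z
#'
#' Correlates the mean preprocessed BOLD signal of a seed region with every
#' brain voxel and applies the variance-stabilizing Fisher transform
#' `z = atanh(r)`. Under the null, `z` is approximately normal with standard
#' deviation `1/sqrt(T - 3)` for `T` retained volumes.
#'
#' @name seedfc
NULL

#' Extract the seed time course
#'
#' @param cleaned A preprocessed [bold_series()].
#' @param seed_mask Logical 3D mask on the BOLD grid.
#' @return Unweighted mean series over seed voxels (length = volumes).
#' @export
extract_seed_timecourse <- function(cleaned, seed_mask) {
  rowMeans(.mask_matrix(cleaned, seed_mask))
}

#' Seed-based Fisher-z connectivity map
#'
#' `z[v] = atanh(r_v)` with `r_v` the Pearson correlation between the seed
#' mean and voxel `v`; `|r|` is clamped at `1 - 1e-7` so seed self-voxels
#' stay finite. Zero-variance voxels get `z = 0` with a warning.
#'
#' @param cleaned A preprocessed [bold_series()].
#' @param seed_mask Seed region mask.
#' @param brain_mask Optional analysis mask (default: all voxels).
#' @return An `fc_map`: `z` 3D array (0 outside the mask), `mask`,
#'   `seed_mask`, `n_volumes`.
#' @export
seed_fc_map <- function(cleaned, seed_mask, brain_mask = NULL) {
  if (cleaned$n_volumes < 3) stop("need at least 3 volumes")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dim(cleaned$data)[1:3])
  s <- extract_seed_timecourse(cleaned, seed_mask)
  s <- s - mean(s)
  s_norm <- sqrt(sum(s^2))
  if (s_norm == 0) stop("seed mean time course has zero variance")
  y <- .mask_matrix(cleaned, brain_mask)
  y <- sweep(y, 2, colMeans(y))
  nrm <- sqrt(colSums(y^2))
  zero_var <- nrm == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance voxel(s): z set to 0")
    nrm[zero_var] <- 1
  }
  r <- drop(crossprod(y, s)) / (nrm * s_norm)
  r[zero_var] <- 0
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  dims3 <- dim(brain_mask)
  z_vol <- array(0, dims3)
  z_vol[brain_mask] <- z
  structure(list(z = z_vol, mask = brain_mask, seed_mask = seed_mask,
                 n_volumes = cleaned$n_volumes),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("<fc_map> %d voxels, %d volumes, z range [%.3g, %.3g]\n",
              sum(x$mask), x$n_volumes, min(x$z[x$mask]), max(x$z[x$mask])))
  invisible(x)
}

#' Smooth a Fisher-z map
#'
#' Smoothing is applied to the z map before any statistics, matching the
#' map-processing order of the pipeline.
#'
#' @param map An `fc_map`.
#' @param fwhm_mm,voxel_size_mm Smoothing kernel settings.
#' @return The `fc_map` with `z` smoothed.
#' @export
smooth_fc_map <- function(map, fwhm_mm = 8, voxel_size_mm = 3) {
  map$z <- smooth_map(map$z, fwhm_mm, voxel_size_mm)
  map
}

#' Mean Fisher z over a region
#'
#' @param map An `fc_map` (smoothed or not) or a plain 3D array.
#' @param region_mask Nonempty logical mask.
#' @return Mean z over the region.
#' @export
fc_region_mean <- function(map, region_mask) {
  if (!any(region_mask)) stop("empty region")
  if (inherits(map, "fc_map")) mean(map$z[region_mask])
  else mean(map[region_mask])
}
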