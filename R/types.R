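#' BOLD series container
#'
#' Bundles one session's 4D BOLD signal with its spatial and temporal
#' metadata. `data` is indexed `[x, y, z, t]`.
#'
#' @param data 4D numeric array.
#' @param affine 4x4 voxel-to-mm matrix (RAS).
#' @param tr_s Repetition time in seconds.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine = diag(4), tr_s = 2) {
  dims <- dim(data)
  if (is.null(dims) || length(dims) != 4L) stop("data must be a 4D array")
  if (dims[4] < 1L) stop("at least one volume required")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  if (tr_s <= 0) stop("tr_s must be positive")
  structure(list(data = data, affine = affine, tr_s = tr_s,
                 n_volumes = dims[4]),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d grid, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

#' Build a rectangular region mask
#'
#' Axis-aligned box in 1-based voxel indices, inclusive on both ends.
#'
#' @param grid_shape Integer vector of length 3.
#' @param lo,hi Corner voxel indices (length-3 integer vectors).
#' @return Logical 3D array.
#' @export
box_mask <- function(grid_shape, lo, hi) {
  stopifnot(length(grid_shape) == 3, length(lo) == 3, length(hi) == 3)
  if (any(lo < 1) || any(hi > grid_shape) || any(lo > hi)) {
    stop("box [", paste(lo, collapse = ","), "]..[",
         paste(hi, collapse = ","), "] does not fit grid ",
         paste(grid_shape, collapse = "x"))
  }
  m <- array(FALSE, dim = grid_shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

# T x V matrix of the voxel time series under a logical mask
.mask_matrix <- function(bold, mask) {
  dims <- dim(bold$data)
  stopifnot(all(dim(mask) == dims[1:3]))
  v <- which(mask)
  if (length(v) == 0L) stop("mask is empty")
  n_vox <- prod(dims[1:3])
  mat <- matrix(bold$data, nrow = n_vox, ncol = dims[4])[v, , drop = FALSE]
  t(mat)
}

# write a T x V matrix back into a 4D array at masked locations
.matrix_to_vol4d <- function(mat, mask, fill = 0) {
  dims3 <- dim(mask)
  out <- array(fill, dim = c(dims3, nrow(mat)))
  idx <- which(mask)
  flat <- matrix(out, nrow = prod(dims3))
  flat[idx, ] <- t(mat)
  array(flat, dim = c(dims3, nrow(mat)))
}

# mm coordinates of voxel indices (rows of ijk, 1-based) under an affine
.voxel_to_mm <- function(ijk, affine) {
  ijk0 <- cbind(ijk - 1, 1)
  t(affine %*% t(ijk0))[, 1:3, drop = FALSE]
}
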