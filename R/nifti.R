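#' Minimal NIfTI-1 input/output
#'
#' Single-file NIfTI-1 (`.nii` or gzip-compressed `.nii.gz`) reader and writer
#' covering the needs of this pipeline: 3D/4D arrays, uint8 / int16 / int32 /
#' float32 / float64 storage, the sform affine, voxel sizes and repetition
#' time. Little-endian only on write; both endiannesses on read.
#'
#' @name nifti-io
#' @keywords internal
NULL

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, r = "uint8"),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  r = "int16"),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  r = "int32"),
  `16` = list(what = "double",  size = 4, signed = TRUE,  r = "float32"),
  `64` = list(what = "double",  size = 8, signed = TRUE,  r = "float64")
)

.nifti_open <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 image
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array, 3D or 4D), `affine`
#'   (4x4 voxel-to-mm matrix, sform if present otherwise diagonal from
#'   `pixdim`), `pixdim` (voxel sizes in mm), and `tr_s` (repetition time in
#'   seconds, `NA` for 3D images).
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  int16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2L * n)],
                                    "integer", n, size = 2, endian = endian)
  flt32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4L * n)],
                                    "double", n, size = 4, endian = endian)
  dim0 <- int16(40, 8)
  ndim <- dim0[1]
  if (ndim < 3 || ndim > 4) stop("only 3D/4D NIfTI supported, got ndim=", ndim)
  dims <- dim0[2:(1 + ndim)]
  datatype <- int16(70, 1)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- flt32(76, 8)
  vox_offset <- flt32(108, 1)
  scl_slope <- flt32(112, 1)
  scl_inter <- flt32(116, 1)
  sform_code <- int16(254, 1)
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1, ] <- flt32(280, 4)
    affine[2, ] <- flt32(296, 4)
    affine[3, ] <- flt32(312, 4)
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n_vals <- prod(dims)
  data <- readBin(con, dt$what, n = n_vals, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < n_vals) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  data <- array(as.double(data), dim = dims)
  list(data = data, affine = affine, pixdim = pixdim[2:4],
       tr_s = if (ndim == 4) pixdim[5] else NA_real_)
}

#' Write a NIfTI-1 image
#'
#' @param data 3D or 4D numeric/logical array.
#' @param path Output path; `.gz` suffix selects gzip compression.
#' @param affine 4x4 voxel-to-mm matrix stored as the sform (RAS convention).
#' @param tr_s Repetition time in seconds (stored in `pixdim[5]` for 4D data).
#' @param datatype Storage type: `"float32"`, `"float64"`, `"uint8"`,
#'   `"int16"` or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = NULL, tr_s = 0,
                        datatype = c("float32", "uint8", "int16", "int32",
                                     "float64")) {
  datatype <- match.arg(datatype)
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  dims <- dim(data)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L)) {
    stop("data must be a 3D or 4D array")
  }
  if (is.null(affine)) affine <- diag(4)
  stopifnot(all(dim(affine) == c(4, 4)))
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
  dt <- .nifti_datatypes[[as.character(code)]]
  bitpix <- as.integer(dt$size * 8L)
  pixdim <- c(1, sqrt(colSums(affine[1:3, 1:3]^2)),
              if (length(dims) == 4) tr_s else 0, 0, 0, 0)

  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                                   # sizeof_hdr
  w_raw(28)                                    # data_type, db_name
  w_i32(0); w_i16(0); w_raw(2)                 # extents, session_error, regular, dim_info
  w_i16(c(length(dims), dims, rep(1L, 7 - length(dims))))  # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)                  # intent_p1-3, intent_code
  w_i16(code); w_i16(bitpix); w_i16(0)         # datatype, bitpix, slice_start
  w_f32(pixdim)                                # pixdim[8]
  w_f32(352)                                   # vox_offset
  w_f32(1); w_f32(0)                           # scl_slope, scl_inter
  w_i16(0); w_raw(1)                           # slice_end, slice_code
  writeBin(as.raw(10L), con)                   # xyzt_units: mm | sec
  w_f32(c(0, 0, 0, 0))                         # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                               # glmax, glmin
  w_raw(104)                                   # descrip, aux_file
  w_i16(0); w_i16(2)                           # qform_code=0, sform_code=2
  w_f32(rep(0, 6))                             # quatern b,c,d; qoffset x,y,z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16)                                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  w_raw(4)                                     # extension flag

  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
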