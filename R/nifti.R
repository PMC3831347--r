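# Minimal NIfTI-1 I/O.
#
# No NIfTI-capable package is assumed; the format here is the plain
# single-file NIfTI-1 layout (348-byte header, magic "n+1", data at
# vox_offset).  Only what the pipeline needs is supported: 3-D (or 4-D with
# singleton trailing dims) scalar volumes, little- or big-endian, common
# datatypes, optional gzip.  Orientation handling is deliberately minimal:
# spacing comes from pixdim, origin from the sform translation (or qoffset),
# and the rotation part of the sform is passed through untouched.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3-D payload
#'   (trailing singleton dimensions are squeezed).
#' @param label if `TRUE`, return a [label_volume()]; codes are taken from
#'   the rounded data and named `class_<code>` unless `labels` is given.
#' @param labels optional named code table for `label = TRUE`.
#' @return an [mri_volume()] (or [label_volume()]).
#' @export
read_volume <- function(path, label = FALSE, labels = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_sz <- readBin(con, "integer", 1L, 4L, endian = endian)
  if (!identical(hdr_sz, 348L)) {
    endian <- "big"
    if (!identical(swap_int32(hdr_sz), 348L))
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  rd_i16 <- function(n) readBin(con, "integer", n, 2L, endian = endian)
  rd_i32 <- function(n) readBin(con, "integer", n, 4L, endian = endian)
  rd_f32 <- function(n) readBin(con, "double", n, 4L, endian = endian)
  skip <- function(n) invisible(readBin(con, "raw", n))

  skip(36L)                               # data_type..dim_info
  dims <- rd_i16(8L)
  skip(14L)                               # intent_p1..intent_code
  datatype <- rd_i16(1L)
  skip(4L)                                # bitpix, slice_start
  pixdim <- rd_f32(8L)
  vox_offset <- rd_f32(1L)
  scl_slope <- rd_f32(1L)
  scl_inter <- rd_f32(1L)
  skip(28L)                               # slice_end..glmin
  skip(104L)                              # descrip, aux_file
  qform_code <- rd_i16(1L)
  sform_code <- rd_i16(1L)
  skip(12L)                               # quatern_b, c, d
  qoffset <- rd_f32(3L)
  srow <- matrix(rd_f32(12L), nrow = 3L, byrow = TRUE)
  skip(16L)                               # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop("bad NIfTI magic in ", path)

  ndim <- dims[1L]
  if (ndim < 3L || ndim > 7L) stop("unsupported dimensionality: ", ndim)
  shape <- dims[2L:(1L + ndim)]
  if (ndim > 3L && any(shape[-(1:3)] != 1L))
    stop(sprintf("payload is %d-D with non-singleton trailing dimensions", ndim))
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)

  skip(as.integer(round(vox_offset)) - 348L)
  n <- prod(shape)
  raw_data <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                      endian = endian)
  if (length(raw_data) != n)
    stop("truncated NIfTI payload in ", path)
  x <- as.numeric(raw_data)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  n_bad <- sum(!is.finite(x))
  if (n_bad > 0L)
    stop(sprintf("load error: %d non-finite voxels in %s", n_bad, path))
  arr <- array(x, shape[1:3])
  spacing <- pixdim[2:4]
  origin <- if (sform_code > 0L) srow[, 4L] else qoffset
  if (label) {
    arr <- array(as.integer(round(arr)), dim(arr))
    if (is.null(labels)) {
      codes <- sort(unique(as.integer(arr)))
      labels <- stats::setNames(codes, paste0("class_", codes))
    }
    label_volume(arr, labels, spacing, origin)
  } else {
    mri_volume(arr, spacing, origin)
  }
}

#' Write a volume as NIfTI-1
#'
#' Scalar volumes are stored as float32, label volumes as int32; `.gz`
#' suffix selects gzip compression.  Spacing goes to `pixdim`, origin to the
#' sform translation (diagonal sform, code 1).
#'
#' @param vol an [mri_volume()] or [label_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mri_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  is_label <- inherits(vol, "label_volume")
  datatype <- if (is_label) 8L else 16L
  bitpix <- 32L
  d <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wr_i16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  wr_i32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  wr_f32 <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wr_pad <- function(n) writeBin(raw(n), con)

  wr_i32(348L)
  wr_pad(36L)                              # data_type..dim_info
  wr_i16(c(3L, d, 1L, 1L, 1L, 1L))         # dim[8]
  wr_f32(c(0, 0, 0)); wr_i16(0L)           # intent
  wr_i16(datatype); wr_i16(bitpix); wr_i16(0L)
  wr_f32(c(1, vol$spacing, 1, 1, 1, 1))    # pixdim (qfac = 1)
  wr_f32(352)                              # vox_offset
  wr_f32(1); wr_f32(0)                     # scl_slope / inter
  wr_i16(0L); wr_pad(2L)                   # slice_end, slice_code+xyzt_units
  wr_f32(c(0, 0, 0, 0))                    # cal_max..toffset
  wr_i32(c(0L, 0L))                        # glmax, glmin
  wr_pad(104L)                             # descrip, aux_file
  wr_i16(0L); wr_i16(1L)                   # qform_code, sform_code
  wr_f32(c(0, 0, 0))                       # quaternion
  wr_f32(vol$origin)                       # qoffset (mirrors sform)
  wr_f32(c(vol$spacing[1L], 0, 0, vol$origin[1L]))
  wr_f32(c(0, vol$spacing[2L], 0, vol$origin[2L]))
  wr_f32(c(0, 0, vol$spacing[3L], vol$origin[3L]))
  wr_pad(16L)                              # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  wr_pad(4L)                               # extension flag -> offset 352
  if (is_label) {
    writeBin(as.integer(vol$data), con, 4L, endian = "little")
  } else {
    writeBin(as.numeric(vol$data), con, 4L, endian = "little")
  }
  invisible(path)
}

swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), 4L, endian = "little")
  readBin(rev(b), "integer", 1L, 4L, endian = "little")
}
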