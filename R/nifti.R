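# Minimal NIfTI-1 I/O.
#
# Only the single-file (.nii / .nii.gz) variant is supported, which is all
# the pipeline emits and consumes. The writer stores float64 by default so
# write-then-read round trips are bit exact; the reader additionally accepts
# uint8/int16/int32/float32 with scl_slope/scl_inter scaling, little or big
# endian. Orientation comes from the sform when present, else the qform
# (quaternion), else the pixdim diagonal.

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE))

.open_read <- function(path) {
  con <- gzfile(path, "rb")  # transparently handles uncompressed files too
  con
}

.parse_header <- function(raw348, endian) {
  rd <- function(offset, what, n, size) {
    readBin(raw348[(offset + 1):length(raw348)], what = what, n = n,
            size = size, endian = endian)
  }
  list(
    sizeof_hdr = rd(0, "integer", 1, 4),
    dim        = rd(40, "integer", 8, 2),
    datatype   = rd(70, "integer", 1, 2),
    bitpix     = rd(72, "integer", 1, 2),
    pixdim     = rd(76, "double", 8, 4),
    vox_offset = rd(108, "double", 1, 4),
    scl_slope  = rd(112, "double", 1, 4),
    scl_inter  = rd(116, "double", 1, 4),
    qform_code = rd(252, "integer", 1, 2),
    sform_code = rd(254, "integer", 1, 2),
    quatern    = rd(256, "double", 3, 4),
    qoffset    = rd(268, "double", 3, 4),
    srow       = matrix(rd(280, "double", 12, 4), nrow = 3, byrow = TRUE),
    magic      = rawToChar(raw348[345:347]))
}

.qform_affine <- function(h) {
  b <- h$quatern[1]; c <- h$quatern[2]; d <- h$quatern[3]
  a2 <- 1 - b * b - c * c - d * d
  a <- sqrt(max(a2, 0))
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c),
    nrow = 3, byrow = TRUE)
  qfac <- if (h$pixdim[1] == -1) -1 else 1
  sc <- c(h$pixdim[2], h$pixdim[3], qfac * h$pixdim[4])
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% diag(sc)
  aff[1:3, 4] <- h$qoffset
  aff
}

#' Read a NIfTI-1 volume or 4-D series
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr repetition time override in seconds; by default taken from
#'   `pixdim[5]` (falling back to 2 s when the header leaves it unset).
#' @return An [fmri_volume()] for 3-D images or an [fmri_series()] for 4-D
#'   images (an ordered sequence of frames; see [as_volume_list()]).
#' @export
read_volume <- function(path, tr = NULL) {
  con <- .open_read(path)
  on.exit(close(con))
  raw348 <- readBin(con, "raw", n = 348)
  if (length(raw348) < 348) stop("truncated NIfTI file: ", path)
  endian <- "little"
  h <- .parse_header(raw348, endian)
  if (h$sizeof_hdr != 348L) {
    endian <- "big"
    h <- .parse_header(raw348, endian)
    if (h$sizeof_hdr != 348L) stop("malformed NIfTI header: ", path)
  }
  if (!h$magic %in% c("n+1", "ni1")) stop("malformed NIfTI magic: ", path)
  dt <- .nifti_dtypes[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", h$datatype)
  nd <- h$dim[1]
  if (nd < 3 || nd > 4) stop("only 3-D or 4-D NIfTI images are supported")
  dims <- h$dim[2:4]
  n_scan <- if (nd == 4) max(h$dim[5], 1L) else 1L
  # skip from end of header to vox_offset
  skip <- max(round(h$vox_offset), 348) - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n_val <- prod(dims) * n_scan
  vals <- readBin(con, what = dt$what, n = n_val, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_val) stop("truncated NIfTI data: ", path)
  vals <- as.double(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter

  if (h$sform_code > 0) {
    affine <- diag(4); affine[1:3, ] <- h$srow
  } else if (h$qform_code > 0) {
    affine <- .qform_affine(h)
  } else {
    affine <- diag(4)
    affine[cbind(1:3, 1:3)] <- h$pixdim[2:4]
  }
  if (!all(is.finite(affine))) stop("non-finite affine in NIfTI header")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (is.null(tr)) tr <- if (h$pixdim[5] > 0) h$pixdim[5] else 2
  grid <- acq_grid(dims, voxel_size = voxel_size, tr = tr, affine = affine)
  if (n_scan == 1L) {
    fmri_volume(array(vals, dim = dims), grid)
  } else {
    fmri_series(matrix(vals, nrow = prod(dims), ncol = n_scan), grid)
  }
}

#' Write a volume or 4-D series as NIfTI-1
#'
#' @param x an [fmri_volume()], [fmri_mask()] or [fmri_series()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param dtype `"float64"` (default, lossless for R numerics) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  grid <- x$grid
  if (inherits(x, "fmri_series")) {
    vals <- as.numeric(x$data); n_scan <- x$n_scan
  } else {
    vals <- as.numeric(x$values); n_scan <- 1L
  }
  code <- if (dtype == "float64") 64L else 16L
  size <- if (dtype == "float64") 8L else 4L
  nd <- if (n_scan > 1L) 4L else 3L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(value, what, size) {
    writeBin(value, con, size = size, endian = "little")
  }
  pad <- function(n) writeBin(raw(n), con)

  w(348L, "integer", 4)                                  # sizeof_hdr
  pad(36)                                                # unused through dim_info
  w(as.integer(c(nd, grid$dims, n_scan, 1, 1, 1)), "integer", 2)  # dim[8]
  w(c(0, 0, 0), "double", 4)                             # intent_p1..3
  w(0L, "integer", 2)                                    # intent_code
  w(code, "integer", 2)                                  # datatype
  w(as.integer(size * 8), "integer", 2)                  # bitpix
  w(0L, "integer", 2)                                    # slice_start
  w(c(1, grid$voxel_size, grid$tr, 0, 0, 0), "double", 4)  # pixdim[8]
  w(352, "double", 4)                                    # vox_offset
  w(c(1, 0), "double", 4)                                # scl_slope, scl_inter
  w(0L, "integer", 2)                                    # slice_end
  pad(1)                                                 # slice_code
  writeBin(as.raw(10L), con)                             # xyzt_units mm|sec
  w(c(0, 0, 0, 0), "double", 4)                          # cal_max..toffset
  w(c(0L, 0L), "integer", 4)                             # glmax, glmin
  pad(104)                                               # descrip, aux_file
  w(0L, "integer", 2)                                    # qform_code
  w(2L, "integer", 2)                                    # sform_code (aligned)
  w(rep(0, 6), "double", 4)                              # quatern, qoffset
  w(as.numeric(t(grid$affine[1:3, ])), "double", 4)      # srow_x/y/z
  pad(16)                                                # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)             # magic
  pad(4)                                                 # extension flag
  writeBin(vals, con, size = size, endian = "little")
  invisible(path)
}
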