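#' Scalar volume on an acquisition grid
#'
#' @param values numeric array whose dimensions equal `grid$dims`, or a
#'   vector of length `prod(grid$dims)` (column-major, x fastest).
#' @param grid an [acq_grid()].
#' @return An object of class `fmri_volume` with fields `values` (3-D array)
#'   and `grid`.
#' @export
fmri_volume <- function(values, grid) {
  stopifnot(inherits(grid, "acq_grid"))
  if (is.null(dim(values))) dim(values) <- grid$dims
  if (!identical(as.integer(dim(values)), grid$dims))
    stop("value array shape does not match grid dims")
  structure(list(values = values, grid = grid), class = "fmri_volume")
}

#' Boolean membership volume (mask)
#'
#' @param membership logical array matching `grid$dims` (or vector).
#' @inheritParams fmri_volume
#' @return An object of class `fmri_mask` (also an `fmri_volume`).
#' @export
fmri_mask <- function(membership, grid) {
  membership <- array(as.logical(membership), dim = grid$dims)
  v <- fmri_volume(membership, grid)
  class(v) <- c("fmri_mask", class(v))
  v
}

#' 4-D functional series on an acquisition grid
#'
#' Stored as an `n_vox x n_scan` matrix (voxels column-major, x fastest) to
#' keep the time-series algebra cheap; `as_volume_list()` recovers the
#' frame-wise view.
#'
#' @param data `n_vox x n_scan` numeric matrix.
#' @inheritParams fmri_volume
#' @export
fmri_series <- function(data, grid) {
  stopifnot(inherits(grid, "acq_grid"), is.matrix(data),
            nrow(data) == prod(grid$dims))
  structure(list(data = data, grid = grid, n_scan = ncol(data)),
            class = "fmri_series")
}

#' @export
print.fmri_series <- function(x, ...) {
  cat(sprintf("<fmri_series> %d scans on ", x$n_scan)); print(x$grid)
  invisible(x)
}

#' Split a 4-D series into an ordered list of volumes
#' @param series an [fmri_series()].
#' @export
as_volume_list <- function(series) {
  stopifnot(inherits(series, "fmri_series"))
  lapply(seq_len(series$n_scan),
         function(t) fmri_volume(series$data[, t], series$grid))
}

#' Gray-matter mask from a probability volume
#'
#' Thresholds a tissue-probability volume; the boundary is inclusive, so a
#' probability exactly equal to `threshold` is kept.
#'
#' @param prob an [fmri_volume()] with values in \[0, 1\].
#' @param threshold probability cut in \[0, 1\] (default 0.8, the
#'   segmentation intensity threshold used for the gray-matter mask).
#' @return An [fmri_mask()].
#' @export
gray_matter_mask <- function(prob, threshold = 0.8) {
  stopifnot(inherits(prob, "fmri_volume"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  v <- prob$values
  if (min(v) < 0 || max(v) > 1) stop("probability values must lie in [0, 1]")
  fmri_mask(v >= threshold, prob$grid)
}

# Elementwise helpers used across modules -----------------------------------

mask_and <- function(a, b) fmri_mask(a$values & b$values, a$grid)
mask_or  <- function(a, b) fmri_mask(a$values | b$values, a$grid)
mask_not <- function(a)    fmri_mask(!a$values, a$grid)

#' Number of member voxels in a mask
#' @param mask an [fmri_mask()].
#' @export
mask_size <- function(mask) sum(mask$values)

# Full-grid mask
full_mask <- function(grid) fmri_mask(array(TRUE, grid$dims), grid)
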