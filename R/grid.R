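#' Acquisition grid geometry
#'
#' An `acq_grid` bundles the lattice dimensions, voxel sizes, repetition time
#' and the 4x4 voxel-to-world affine (world coordinates are MNI millimetres).
#' Lattice coordinates are 0-based throughout the package; the affine maps
#' 0-based voxel indices to world mm.
#'
#' @param dims integer triple, voxels per axis (all >= 1).
#' @param voxel_size numeric triple, voxel edge lengths in mm (> 0).
#' @param tr repetition time in seconds.
#' @param affine 4x4 voxel-to-world transform; default centres the grid on
#'   the world origin with axes aligned to the lattice, which stands in for
#'   MNI alignment of spatially normalised data.
#' @return An object of class `acq_grid`.
#' @export
acq_grid <- function(dims, voxel_size = c(3.4375, 3.4375, 4), tr = 2,
                     affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(tr) == 1L, tr > 0)
  if (is.null(affine)) {
    affine <- diag(4)
    affine[cbind(1:3, 1:3)] <- voxel_size
    affine[1:3, 4] <- -voxel_size * (dims - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (!all(is.finite(affine))) stop("affine contains non-finite entries")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("affine is singular")
  structure(list(dims = dims, voxel_size = as.numeric(voxel_size),
                 tr = as.numeric(tr), affine = affine),
            class = "acq_grid")
}

#' @export
print.acq_grid <- function(x, ...) {
  cat(sprintf("<acq_grid> %d x %d x %d voxels, %.4g x %.4g x %.4g mm, TR %.3g s\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$tr))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims) && isTRUE(all.equal(a$affine, b$affine))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("objects do not share the same acquisition grid")
  invisible(TRUE)
}

#' Convert world (MNI mm) coordinates to continuous voxel coordinates
#'
#' @param grid an [acq_grid()].
#' @param xyz_mm numeric triple or n x 3 matrix of world coordinates.
#' @return Continuous 0-based lattice coordinates, same shape as the input.
#' @export
world_to_voxel <- function(grid, xyz_mm) {
  xyz <- rbind(t(matrix(as.numeric(xyz_mm), ncol = 3)), 1)
  v <- solve(grid$affine, xyz)[1:3, , drop = FALSE]
  if (is.matrix(xyz_mm)) t(v) else as.numeric(v)
}

#' Convert 0-based voxel coordinates to world (MNI mm) coordinates
#'
#' @inheritParams world_to_voxel
#' @param ijk numeric triple or n x 3 matrix of 0-based voxel coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  x <- rbind(t(matrix(as.numeric(ijk), ncol = 3)), 1)
  w <- (grid$affine %*% x)[1:3, , drop = FALSE]
  if (is.matrix(ijk)) t(w) else as.numeric(w)
}

# World mm coordinates of every voxel centre, as an n_vox x 3 matrix in
# column-major (x fastest) order matching the storage of volume arrays.
voxel_centers_mm <- function(grid) {
  d <- grid$dims
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(grid, ijk)
}
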