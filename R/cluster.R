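# Connected components, extent filtering, Gaussian smoothing and the
# Monte-Carlo cluster-extent threshold.

#' Label connected clusters of a mask
#'
#' @param mask an [fmri_mask()].
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+
#'   corners; the default, matching common Monte-Carlo cluster tools).
#' @param stat optional [fmri_volume()] used to locate each cluster's peak.
#' @return A `cluster_set`: `labels` (integer array, 0 background), `sizes`
#'   (voxel count per label), `peaks_mm` (per-label MNI coordinate of the
#'   maximal `stat`, or of an arbitrary member voxel when no stat is given),
#'   `grid`, `connectivity`.
#' @export
label_clusters <- function(mask, connectivity = 26, stat = NULL) {
  stopifnot(inherits(mask, "fmri_mask"))
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  lab <- .cpp_label_components(mask$values, mask$grid$dims,
                               as.integer(connectivity))
  k <- max(lab)
  sizes <- if (k > 0) tabulate(lab[lab > 0], nbins = k) else integer()
  peaks <- NULL
  if (k > 0) {
    sv <- if (is.null(stat)) NULL else as.numeric(stat$values)
    peaks <- t(vapply(seq_len(k), function(l) {
      idx <- which(lab == l)
      pick <- if (is.null(sv)) idx[1] else idx[which.max(abs(sv[idx]))]
      ijk <- arrayInd(pick, mask$grid$dims) - 1L
      voxel_to_world(mask$grid, as.numeric(ijk))
    }, numeric(3)))
    colnames(peaks) <- c("x", "y", "z")
  }
  structure(list(labels = lab, sizes = sizes, peaks_mm = peaks,
                 grid = mask$grid, connectivity = connectivity),
            class = "cluster_set")
}

#' Keep only clusters of at least k voxels
#'
#' @param clusters a `cluster_set` from [label_clusters()].
#' @param k minimum cluster extent in voxels (>= 1).
#' @return An [fmri_mask()] covering the surviving clusters.
#' @export
extent_filter <- function(clusters, k) {
  stopifnot(k >= 1)
  keep <- which(clusters$sizes >= k)
  fmri_mask(array(clusters$labels %in% keep, clusters$grid$dims),
            clusters$grid)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian with per-axis sigma `fwhm / sqrt(8 log 2) /
#' voxel_size`; edge taps are renormalised so a constant volume is
#' unchanged.
#'
#' @param volume an [fmri_volume()].
#' @param fwhm full width at half maximum in mm (>= 0; 0 is the identity).
#' @return Smoothed [fmri_volume()].
#' @export
smooth_gaussian <- function(volume, fwhm) {
  stopifnot(inherits(volume, "fmri_volume"))
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(volume)
  sig <- fwhm_to_sigma(fwhm) / volume$grid$voxel_size
  fmri_volume(.cpp_smooth3d(as.numeric(volume$values), volume$grid$dims, sig),
              volume$grid)
}

#' @rdname smooth_gaussian
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the family-wise probability of suprathreshold clusters of a
#' given extent under smooth Gaussian noise: per iteration the grid is
#' filled with unit Gaussian noise, smoothed to `fwhm`, restandardised to
#' zero mean and unit variance within the mask, thresholded at the
#' one-sided `voxel_p` z-cutoff, and the maximal cluster size is recorded.
#'
#' @param grid an [acq_grid()].
#' @param mask simulation mask; defaults to the full grid.
#' @param fwhm spatial smoothness in mm (default 8).
#' @param voxel_p one-sided voxel significance level (default 0.001).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed integer seed.
#' @param connectivity cluster connectivity (default 26).
#' @param alpha target family-wise level for `k_for_alpha` (default 0.001).
#' @return An `mc_result`: `null_max_sizes`, `n_supra` (suprathreshold voxel
#'   count per iteration), `alpha_for_k` (named vector of family-wise
#'   probabilities for extents 1..max), `k_for_alpha` (smallest extent
#'   achieving `alpha`, `Inf` if none), `n_iter`, `seed`, parameters.
#' @export
mc_extent_threshold <- function(grid, mask = NULL, fwhm = 8, voxel_p = 0.001,
                                n_iter = 10000, seed = 1L, connectivity = 26,
                                alpha = 0.001) {
  stopifnot(inherits(grid, "acq_grid"), n_iter >= 1,
            voxel_p > 0, voxel_p <= 1)
  if (is.null(mask)) mask <- full_mask(grid)
  stop_if_grid_mismatch(grid, mask$grid)
  if (mask_size(mask) == 0) stop("simulation mask is empty")
  sig <- if (fwhm > 0) fwhm_to_sigma(fwhm) / grid$voxel_size else c(0, 0, 0)
  zcut <- stats::qnorm(1 - voxel_p)
  sim <- with_seed(seed,
    .cpp_mc_max_cluster(grid$dims, sig, as.logical(mask$values), zcut,
                        as.integer(n_iter), as.integer(connectivity)))
  max_sizes <- sim[, 1]
  n_supra <- sim[, 2]
  kmax <- max(max_sizes, 1L)
  alpha_for_k <- vapply(seq_len(kmax), function(k) mean(max_sizes >= k),
                        numeric(1))
  names(alpha_for_k) <- seq_len(kmax)
  hit <- which(alpha_for_k <= alpha)
  structure(list(null_max_sizes = max_sizes, n_supra = n_supra,
                 alpha_for_k = alpha_for_k,
                 k_for_alpha = if (length(hit)) min(hit) else Inf,
                 n_iter = n_iter, seed = seed, fwhm = fwhm,
                 voxel_p = voxel_p, connectivity = connectivity,
                 alpha = alpha),
            class = "mc_result")
}

#' Family-wise probability of a cluster of at least k voxels
#' @param mc an `mc_result`.
#' @param k cluster extent in voxels.
#' @export
mc_alpha_for_k <- function(mc, k) mean(mc$null_max_sizes >= k)
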