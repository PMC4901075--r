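# Whole-brain spatial-correlation similarity of task response patterns.

#' Combine significance masks with the gray-matter mask
#'
#' @param sig_a,sig_b task significance masks (group-level suprathreshold
#'   voxels, no extent rule).
#' @param gray gray-matter mask.
#' @param combine `"union"` (default; keeps voxels significant in either
#'   task) or `"intersection"`.
#' @return An [fmri_mask()] with at least 3 voxels (error otherwise).
#' @export
similarity_mask <- function(sig_a, sig_b, gray,
                            combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  stop_if_grid_mismatch(sig_a$grid, sig_b$grid)
  stop_if_grid_mismatch(sig_a$grid, gray$grid)
  comb <- if (combine == "union") mask_or(sig_a, sig_b)
          else mask_and(sig_a, sig_b)
  out <- mask_and(gray, comb)
  if (mask_size(out) < 3)
    stop("similarity mask has fewer than 3 voxels")
  out
}

#' Masked voxelwise Pearson correlation of two maps
#'
#' @param map_a,map_b [fmri_volume()]s on one grid.
#' @param mask an [fmri_mask()] with >= 3 member voxels.
#' @return Pearson r over the masked voxels.
#' @export
spatial_correlation <- function(map_a, map_b, mask) {
  stop_if_grid_mismatch(map_a$grid, map_b$grid)
  stop_if_grid_mismatch(map_a$grid, mask$grid)
  idx <- which(mask$values)
  if (length(idx) < 3) stop("need at least 3 masked voxels")
  a <- as.numeric(map_a$values)[idx]
  b <- as.numeric(map_b$values)[idx]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance within the similarity mask")
  stats::cor(a, b)
}

#' Fisher Z transform
#'
#' `z = atanh(r) = 0.5 log((1 + r) / (1 - r))`; strictly increasing and odd.
#'
#' @param r correlation(s) with `|r| < 1`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' Per-subject task-pair similarity
#'
#' For each subject, correlates the two tasks' contrast maps within a
#' group-defined mask and Fisher-transforms the result.
#'
#' @param contrasts nested list `contrasts[[subject]][[task]][[phase]]`.
#' @param task_a,task_b task pair.
#' @param phase `"choice"` or `"feedback"`.
#' @param mask the similarity [fmri_mask()] (see [similarity_mask()]).
#' @return data.frame with `subject`, `pair`, `phase`, `n_voxels`, `r`, `z`.
#' @export
pair_similarity <- function(contrasts, task_a, task_b, phase, mask) {
  pair <- paste(task_a, task_b, sep = "-")
  do.call(rbind, lapply(names(contrasts), function(s) {
    r <- spatial_correlation(contrasts[[s]][[task_a]][[phase]],
                             contrasts[[s]][[task_b]][[phase]], mask)
    data.frame(subject = s, pair = pair, phase = phase,
               n_voxels = mask_size(mask), r = r, z = fisher_z(r),
               stringsAsFactors = FALSE)
  }))
}

#' Paired comparison of two similarity pairs
#'
#' Two-sided paired t-test across subjects on Fisher Z values, e.g. testing
#' whether Value-Mathematical similarity exceeds Value-Emotion similarity.
#'
#' @param res_a,res_b data.frames from [pair_similarity()] covering the same
#'   subjects.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
compare_pairs <- function(res_a, res_b) {
  a <- res_a$z[order(res_a$subject)]
  b <- res_b$z[order(res_b$subject)]
  if (length(a) != length(b) || length(a) < 2)
    stop("need matched z values from at least 2 subjects")
  d <- a - b
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  tval <- if (se == 0) 0 else mean(d) / se
  p <- if (se == 0) 1 else 2 * stats::pt(-abs(tval), n - 1)
  list(t = tval, df = n - 1L, p = p, mean_diff = mean(d), n = n)
}
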