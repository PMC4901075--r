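# Voxel-wise ordinary least squares, subject contrasts, group t-maps.

#' Fit a run's voxel-wise GLM
#'
#' Ordinary least squares of every masked voxel's time series on the design.
#' No prewhitening or high-pass filtering is applied; mild temporal
#' autocorrelation is treated as unmodelled noise (a deliberate
#' simplification documented in the methods vignette).
#'
#' @param run an [fmri_series()] (or `n_vox x n_scan` matrix).
#' @param design a `design_matrix` from [build_design()].
#' @param mask optional [fmri_mask()]; defaults to all voxels.
#' @return A `beta_maps` object: `beta` (regressors x voxels for masked
#'   voxels), `labels`, `resvar`, `df` (scans minus design rank), `mask`,
#'   `grid`, and `xtx_inv` for contrast variances.
#' @export
fit_run <- function(run, design, mask = NULL) {
  X <- design$X
  if (inherits(run, "fmri_series")) {
    grid <- run$grid
    data <- run$data
  } else stop("run must be an fmri_series")
  if (ncol(data) != nrow(X))
    stop("series has ", ncol(data), " frames but design has ", nrow(X), " rows")
  if (is.null(mask)) mask <- full_mask(grid)
  stop_if_grid_mismatch(grid, mask$grid)

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  midx <- which(mask$values)
  Y <- t(data[midx, , drop = FALSE])          # scans x voxels
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - qrx$rank
  resvar <- colSums(res^2) / df
  R <- qr.R(qrx)[, order(qrx$pivot), drop = FALSE]
  xtx_inv <- chol2inv(chol(crossprod(R[, , drop = FALSE])))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, labels = colnames(X),
                 task_columns = design$task_columns, resvar = resvar,
                 df = df, mask = mask, grid = grid, xtx_inv = xtx_inv),
            class = "beta_maps")
}

# Expand a named contrast over task columns to the full regressor vector.
.full_contrast <- function(bm, contrast) {
  if (is.null(names(contrast)))
    stop("contrast must be named by task column")
  missing <- setdiff(names(contrast), bm$labels)
  if (length(missing))
    stop("contrast references unknown columns: ",
         paste(missing, collapse = ", "))
  ct <- numeric(length(bm$labels))
  names(ct) <- bm$labels
  ct[names(contrast)] <- contrast
  ct
}

#' Per-run contrast t statistics
#'
#' @param bm a `beta_maps` from [fit_run()].
#' @param contrast named numeric vector over design columns.
#' @return Numeric vector of t values for masked voxels (df = `bm$df`).
#' @export
contrast_t <- function(bm, contrast) {
  ct <- .full_contrast(bm, contrast)
  est <- drop(crossprod(ct, bm$beta))
  se <- sqrt(bm$resvar * drop(t(ct) %*% bm$xtx_inv %*% ct))
  est / se
}

#' Run-weighted subject contrast
#'
#' Combines the per-run contrast values of one subject and task into a
#' single volume as a weighted mean; weights default to equal shares across
#' the runs contributing to the task (normalised to sum to 1), which
#' accounts for the different run counts per task.
#'
#' @param runs list of `beta_maps` sharing grid and labels.
#' @param contrast named numeric contrast over task columns.
#' @param weights optional per-run weights.
#' @return An [fmri_volume()] with `NA` outside the analysis mask.
#' @export
subject_contrast <- function(runs, contrast, weights = NULL) {
  stopifnot(length(runs) >= 1)
  if (is.null(weights)) weights <- rep(1 / length(runs), length(runs))
  if (length(weights) != length(runs))
    stop("weight vector length must match the number of runs")
  weights <- weights / sum(weights)
  grid <- runs[[1]]$grid
  out <- array(NA_real_, grid$dims)
  midx <- which(runs[[1]]$mask$values)
  acc <- numeric(length(midx))
  for (i in seq_along(runs)) {
    bm <- runs[[i]]
    stop_if_grid_mismatch(grid, bm$grid)
    ct <- .full_contrast(bm, contrast)
    acc <- acc + weights[i] * drop(crossprod(ct, bm$beta))
  }
  out[midx] <- acc
  fmri_volume(out, grid)
}

#' Group one-sample t-map
#'
#' Voxel-wise one-sample t statistic of the subject contrast values against
#' zero. This is the task-versus-baseline cell of the three-level task
#' factorial expressed as a per-task one-sample test; `df = n - 1`.
#' Zero-variance voxels (and voxels missing in any subject) are flagged
#' non-finite and excluded from downstream masks.
#'
#' @param contrasts list of per-subject contrast volumes (shared grid).
#' @param task,phase metadata labels carried on the map.
#' @return A `stat_map`: `values` ([fmri_volume()] of t), `df`, `task`,
#'   `phase`.
#' @export
group_tmap <- function(contrasts, task = NA_character_,
                       phase = NA_character_) {
  n <- length(contrasts)
  if (n < 2) stop("group t-map needs at least 2 subjects")
  grid <- contrasts[[1]]$grid
  mat <- vapply(contrasts, function(v) {
    stop_if_grid_mismatch(grid, v$grid)
    as.numeric(v$values)
  }, numeric(prod(grid$dims)))
  mu <- rowMeans(mat)
  sd <- sqrt(rowSums((mat - mu)^2) / (n - 1))
  t <- mu / (sd / sqrt(n))
  t[sd == 0] <- NA_real_
  stat_map(fmri_volume(t, grid), df = n - 1L, task = task, phase = phase)
}

#' Statistic map container
#'
#' @param values an [fmri_volume()] of t statistics.
#' @param df error degrees of freedom.
#' @param task,phase metadata labels.
#' @export
stat_map <- function(values, df, task = NA_character_,
                     phase = NA_character_) {
  stopifnot(inherits(values, "fmri_volume"), df >= 1)
  structure(list(values = values, df = df, task = task, phase = phase),
            class = "stat_map")
}
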