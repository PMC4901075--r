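# Regions of interest: conjunction-derived clusters and a-priori spheres.

#' Spherical ROI at an MNI coordinate
#'
#' Membership is by voxel-centre distance: a voxel belongs to the sphere
#' when its centre lies within `radius_mm` of `center_mm` (no
#' partial-volume weighting).
#'
#' @param center_mm MNI mm triple.
#' @param radius_mm sphere radius in mm (default 5, the a-priori convention).
#' @param grid an [acq_grid()].
#' @param name ROI label.
#' @return An `roi`: `name`, `source = "a_priori"`, `membership`
#'   ([fmri_mask()]), `center_mm`, `radius_mm`.
#' @export
sphere_roi <- function(center_mm, radius_mm = 5, grid, name = NULL) {
  centers <- voxel_centers_mm(grid)
  d2 <- (centers[, 1] - center_mm[1])^2 + (centers[, 2] - center_mm[2])^2 +
    (centers[, 3] - center_mm[3])^2
  inside <- d2 <= radius_mm^2
  if (!any(inside))
    stop("sphere at (", paste(center_mm, collapse = ", "),
         ") contains no voxel centre")
  structure(list(name = if (is.null(name))
                   sprintf("sphere_%g_%g_%g", center_mm[1], center_mm[2],
                           center_mm[3]) else name,
                 source = "a_priori", category = NA_character_,
                 membership = fmri_mask(inside, grid),
                 center_mm = as.numeric(center_mm), radius_mm = radius_mm),
            class = "roi")
}

#' A-priori ROI catalogue
#'
#' Meta-analytic coordinates for value (striatum, medial frontal),
#' mathematical (lateral frontal, superior/inferior parietal lobules) and
#' emotion processing (middle temporal gyrus, insula, amygdala, anterior
#' cingulate), shipped as a versioned JSON fixture.
#'
#' @return data.frame with `name`, `domain`, `x`, `y`, `z`.
#' @export
apriori_roi_catalog <- function() {
  path <- system.file("extdata", "apriori_rois.json", package = "conjfmri")
  tab <- jsonlite::fromJSON(path)$rois
  as.data.frame(tab, stringsAsFactors = FALSE)
}

#' Build the a-priori sphere ROIs
#' @param grid an [acq_grid()].
#' @param radius_mm sphere radius (default 5 mm).
#' @export
apriori_rois <- function(grid, radius_mm = 5) {
  tab <- apriori_roi_catalog()
  lapply(seq_len(nrow(tab)), function(i)
    sphere_roi(c(tab$x[i], tab$y[i], tab$z[i]), radius_mm, grid,
               name = tab$name[i]))
}

# dilate a mask by all lattice offsets within dist_mm (Euclidean, mm)
.dilate_mask <- function(mask, dist_mm) {
  if (dist_mm <= 0) return(mask)
  vs <- mask$grid$voxel_size
  rad <- floor(dist_mm / vs)
  offs <- expand.grid(dx = -rad[1]:rad[1], dy = -rad[2]:rad[2],
                      dz = -rad[3]:rad[3])
  keep <- with(offs, (dx * vs[1])^2 + (dy * vs[2])^2 + (dz * vs[3])^2
               <= dist_mm^2)
  offs <- offs[keep, , drop = FALSE]
  d <- mask$grid$dims
  idx <- which(mask$values, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (o in seq_len(nrow(offs))) {
    sh <- idx
    sh[, 1] <- sh[, 1] + offs$dx[o]
    sh[, 2] <- sh[, 2] + offs$dy[o]
    sh[, 3] <- sh[, 3] + offs$dz[o]
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    out[sh[ok, , drop = FALSE]] <- TRUE
  }
  fmri_mask(out, mask$grid)
}

#' ROIs from conjunction clusters
#'
#' Each surviving suprathreshold cluster of each conjunction category
#' becomes one ROI. Two exclusion rules apply: clusters overlapping
#' `excluded_structures` (e.g. visual/somatosensory/motor territory) are
#' dropped entirely; and voxels of a more-exclusive category (more `~`
#' terms) lying within `dilation_mm` of a more-inclusive category's
#' clusters are removed as residual-smoothing periphery, with ROIs emptied
#' by the rule dropped.
#'
#' @param categories named list of `conjunction_map`s (see
#'   [partition_conjunctions()]).
#' @param excluded_structures optional [fmri_mask()].
#' @param dilation_mm periphery distance in mm (default 4, about one voxel).
#' @param connectivity cluster connectivity.
#' @return List of `roi` objects (`source = "conjunction"`).
#' @export
rois_from_conjunctions <- function(categories, excluded_structures = NULL,
                                   dilation_mm = 4, connectivity = 26) {
  grid <- categories[[1]]$membership$grid
  n_excl <- vapply(categories, function(cm) length(cm$spec$exclude),
                   integer(1))
  ord <- order(n_excl)
  # periphery guard: dilated union of every strictly-more-inclusive category
  guards <- list()
  acc <- fmri_mask(array(FALSE, grid$dims), grid)
  for (lev in sort(unique(n_excl))) {
    guards[[as.character(lev)]] <- acc
    for (i in which(n_excl == lev))
      acc <- mask_or(acc, categories[[i]]$membership)
    acc <- acc  # union grows with inclusiveness level
  }
  guard_dilated <- lapply(guards, .dilate_mask, dist_mm = dilation_mm)

  rois <- list()
  for (i in ord) {
    cm <- categories[[i]]
    cl <- cm$clusters
    if (length(cl$sizes) == 0) next
    guard <- guard_dilated[[as.character(n_excl[i])]]
    for (lab in seq_along(cl$sizes)) {
      memb <- array(cl$labels == lab, grid$dims)
      if (!is.null(excluded_structures) &&
          any(memb & excluded_structures$values)) next
      memb <- memb & !guard$values
      if (!any(memb)) next
      rois[[length(rois) + 1]] <- structure(
        list(name = sprintf("%s_cluster%d", gsub(" ", "", cm$spec$label), lab),
             source = "conjunction", category = cm$spec$label,
             membership = fmri_mask(memb, grid),
             center_mm = NULL, radius_mm = NULL),
        class = "roi")
    }
  }
  rois
}

#' Extract mean ROI responses per subject, task and phase
#'
#' @param contrasts nested list `contrasts[[subject]][[task]][[phase]]` of
#'   contrast [fmri_volume()]s (as produced by [fit_cohort_glm()]).
#' @param rois list of `roi` objects.
#' @return data.frame with one row per subject x task x phase x roi and
#'   column `mean_response`.
#' @export
extract_responses <- function(contrasts, rois) {
  rows <- list()
  for (s in names(contrasts)) {
    for (task in names(contrasts[[s]])) {
      for (phase in names(contrasts[[s]][[task]])) {
        vol <- contrasts[[s]][[task]][[phase]]
        vals <- as.numeric(vol$values)
        for (r in rois) {
          stop_if_grid_mismatch(vol$grid, r$membership$grid)
          idx <- which(r$membership$values)
          v <- vals[idx]
          v <- v[is.finite(v)]
          if (!length(v)) stop("ROI '", r$name, "' is empty after masking")
          rows[[length(rows) + 1]] <- data.frame(
            subject = s, task = task, phase = phase, roi = r$name,
            mean_response = mean(v), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Paired comparison of two tasks' responses within an ROI
#'
#' Two-sided paired t-test across subjects of the task difference, with the
#' 95 percent confidence interval of the within-subject difference.
#'
#' @param table a response table from [extract_responses()].
#' @param roi,phase,task_a,task_b selectors.
#' @return List with `t`, `df`, `p`, `ci` (length 2), `mean_diff`, `n`.
#' @export
roi_compare <- function(table, roi, phase, task_a, task_b) {
  pick <- function(task) {
    sub <- table[table$roi == roi & table$phase == phase &
                   table$task == task, ]
    sub$mean_response[order(sub$subject)]
  }
  a <- pick(task_a); b <- pick(task_b)
  if (length(a) != length(b) || length(a) < 2)
    stop("need matched responses from at least 2 subjects")
  d <- a - b
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  tval <- if (se == 0) 0 else mean(d) / se
  p <- if (se == 0) 1 else 2 * stats::pt(-abs(tval), n - 1)
  ci <- mean(d) + c(-1, 1) * stats::qt(0.975, n - 1) * se
  list(t = tval, df = n - 1L, p = p, ci = ci, mean_diff = mean(d), n = n)
}
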