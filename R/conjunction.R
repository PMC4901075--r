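# Minimal-t-statistic conjunction analysis.
#
# A voxel belongs to a conjunction such as V ∩ M ∩ ~E when its t statistic
# passes the one-sided voxel threshold in every included task and fails it
# in every excluded task; the voxel's summary statistic is the minimum over
# the included tasks (the minimal t). The seven include/exclude
# combinations of three tasks partition the suprathreshold territory.

.tasks3 <- c("Value", "Mathematical", "Emotion")

#' Conjunction specification
#'
#' @param include nonempty subset of the task names.
#' @param exclude complementary subset (defaults to all remaining tasks).
#' @param sign `"positive"` or `"negative"` response direction.
#' @param voxel_p one-sided voxel significance level (default 0.001).
#' @param extent_k minimum cluster size in voxels (default 50).
#' @param tasks full task universe (default Value/Mathematical/Emotion).
#' @return A `conjunction_spec`.
#' @export
conjunction_spec <- function(include, exclude = NULL,
                             sign = c("positive", "negative"),
                             voxel_p = 0.001, extent_k = 50,
                             tasks = .tasks3) {
  sign <- match.arg(sign)
  if (is.null(exclude)) exclude <- setdiff(tasks, include)
  stopifnot(length(include) >= 1, all(include %in% tasks),
            all(exclude %in% tasks),
            length(intersect(include, exclude)) == 0,
            setequal(union(include, exclude), tasks),
            voxel_p > 0, voxel_p < 1, extent_k >= 1)
  label <- paste(c(include, paste0("~", exclude))[match(tasks,
            c(include, exclude))], collapse = " & ")
  structure(list(include = include, exclude = exclude, sign = sign,
                 voxel_p = voxel_p, extent_k = extent_k, tasks = tasks,
                 label = label),
            class = "conjunction_spec")
}

#' One-sided critical t value
#'
#' @param df error degrees of freedom (>= 1).
#' @param p one-sided significance level in (0, 1).
#' @param sign `"positive"` returns the upper critical value, `"negative"`
#'   its mirror.
#' @export
t_threshold <- function(df, p = 0.001, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  stopifnot(df >= 1)
  crit <- stats::qt(1 - p, df)
  if (sign == "negative") -crit else crit
}

#' Conjunction of task t-maps under one include/exclude rule
#'
#' @param maps named list of `stat_map`s (one per task, shared grid and df).
#' @param spec a [conjunction_spec()]. The `extent_k` cluster rule is
#'   applied per conjunction via [label_clusters()]/[extent_filter()];
#'   `connectivity` controls the neighbourhood.
#' @param connectivity cluster connectivity for the extent rule.
#' @return A `conjunction_map`: `membership` ([fmri_mask()] after extent
#'   filtering), `min_t` ([fmri_volume()], `NA` outside membership), `spec`,
#'   `clusters` (a `cluster_set` of the surviving clusters).
#' @export
conjoin <- function(maps, spec, connectivity = 26) {
  missing <- setdiff(spec$tasks, names(maps))
  if (length(missing))
    stop("no stat map supplied for task(s): ", paste(missing, collapse = ", "))
  grid <- maps[[1]]$values$grid
  df <- maps[[1]]$df
  for (m in maps) stop_if_grid_mismatch(grid, m$values$grid)
  crit <- t_threshold(df, spec$voxel_p, spec$sign)
  pass <- lapply(maps[spec$tasks], function(m) {
    t <- m$values$values
    ok <- if (spec$sign == "positive") t >= crit else t <= crit
    ok & is.finite(t)
  })
  member <- Reduce(`&`, pass[spec$include])
  for (ex in spec$exclude) member <- member & !pass[[ex]]

  tin <- vapply(maps[spec$include], function(m) as.numeric(m$values$values),
                numeric(prod(grid$dims)))
  # sign-adjusted minimum: the included statistic closest to the threshold
  cols <- lapply(seq_len(ncol(tin)), function(j) tin[, j])
  min_t <- if (spec$sign == "positive") do.call(pmin, cols)
           else do.call(pmax, cols)
  min_t[!member] <- NA_real_

  mask0 <- fmri_mask(member, grid)
  stat_vol <- fmri_volume(min_t, grid)
  cl <- label_clusters(mask0, connectivity, stat = stat_vol)
  mask <- if (spec$extent_k > 1) extent_filter(cl, spec$extent_k) else mask0
  min_t[!mask$values] <- NA_real_
  cl <- label_clusters(mask, connectivity, stat = fmri_volume(min_t, grid))
  structure(list(membership = mask, min_t = fmri_volume(min_t, grid),
                 spec = spec, clusters = cl, df = df),
            class = "conjunction_map")
}

#' Names of the seven conjunction categories
#' @param tasks task universe.
#' @return Character vector of labels in canonical order.
#' @export
conjunction_categories <- function(tasks = .tasks3) {
  combos <- .category_combos(tasks)
  vapply(combos, function(inc)
    conjunction_spec(inc, tasks = tasks, extent_k = 1)$label, character(1))
}

.category_combos <- function(tasks = .tasks3) {
  list(tasks, tasks[c(1, 2)], tasks[c(1, 3)], tasks[c(2, 3)],
       tasks[1], tasks[2], tasks[3])
}

#' Seven-way conjunction partition of three task maps
#'
#' Runs [conjoin()] for every nonempty include subset of the three tasks.
#' Before extent filtering the seven memberships are pairwise disjoint and
#' their union is exactly the set of voxels suprathreshold in at least one
#' task.
#'
#' @inheritParams conjoin
#' @param sign response direction.
#' @param voxel_p one-sided voxel significance level.
#' @param extent_k minimum cluster size in voxels.
#' @return Named list of seven `conjunction_map`s.
#' @export
partition_conjunctions <- function(maps, sign = "positive", voxel_p = 0.001,
                                   extent_k = 50, connectivity = 26) {
  tasks <- intersect(.tasks3, names(maps))
  if (length(tasks) != 3) tasks <- names(maps)
  out <- lapply(.category_combos(tasks), function(inc) {
    conjoin(maps, conjunction_spec(inc, sign = sign, voxel_p = voxel_p,
                                   extent_k = extent_k, tasks = tasks),
            connectivity = connectivity)
  })
  names(out) <- vapply(out, function(cm) cm$spec$label, character(1))
  out
}
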