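# End-to-end pipeline: simulate -> glm -> threshold -> conjunction -> roi ->
# similarity -> behaviour -> report.

#' Group significance mask from a stat map
#'
#' Voxels passing the one-sided voxel threshold (no extent rule).
#'
#' @param map a `stat_map`.
#' @param voxel_p one-sided significance level.
#' @param sign `"positive"` or `"negative"`.
#' @export
sig_mask <- function(map, voxel_p = 0.001, sign = "positive") {
  crit <- t_threshold(map$df, voxel_p, sign)
  t <- map$values$values
  ok <- if (sign == "positive") t >= crit else t <= crit
  fmri_mask(ok & is.finite(t), map$values$grid)
}

#' Fit the cohort GLM and form subject contrasts and group t-maps
#'
#' For every subject and task, builds run designs (condition regressors plus
#' six motion covariates and an intercept), fits the voxel-wise OLS, and
#' combines runs into run-weighted subject contrasts for the choice and
#' feedback phases; then computes per-task group one-sample t-maps.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param phases phases to analyse.
#' @return List with `contrasts` (`[[subject]][[task]][[phase]]` volumes)
#'   and `group` (`[[task]][[phase]]` `stat_map`s).
#' @export
fit_cohort_glm <- function(cohort, phases = c("choice", "feedback")) {
  grid <- cohort$grid
  contrasts <- list()
  for (s in names(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    contrasts[[s]] <- list()
    for (task in names(sub$runs)) {
      grouping <- condition_grouping(task)
      fits <- lapply(seq_along(sub$runs[[task]]), function(r) {
        run <- sub$runs[[task]][[r]]
        design <- build_design(sub$schedules[[task]][[r]],
                               n_scan = run$series$n_scan, tr = grid$tr,
                               motion = run$motion, grouping = grouping)
        fit_run(run$series, design)
      })
      contrasts[[s]][[task]] <- lapply(stats::setNames(phases, phases),
        function(ph) {
          ct <- task_contrast(fits[[1]]$task_columns, ph)
          subject_contrast(fits, ct[ct != 0])
        })
    }
  }
  tasks <- names(cohort$subjects[[1]]$runs)
  group <- lapply(stats::setNames(tasks, tasks), function(task) {
    lapply(stats::setNames(phases, phases), function(ph) {
      group_tmap(lapply(contrasts, function(sc) sc[[task]][[ph]]),
                 task = task, phase = ph)
    })
  })
  list(contrasts = contrasts, group = group)
}

#' Pipeline configuration
#'
#' All thresholds default to the study's: voxel p = 0.001, cluster extent
#' 50 voxels, 10,000 Monte-Carlo iterations, 8 mm FWHM, gray-matter
#' threshold 0.8, 5 mm a-priori spheres, 20 subjects on the 64 x 64 x 38
#' acquisition grid.
#'
#' @param n_subjects,grid,atlas,noise cohort settings (see
#'   [generate_cohort()]).
#' @param voxel_p,extent_k,connectivity conjunction thresholds.
#' @param mc_iter Monte-Carlo iterations for the extent threshold; 0 skips
#'   the simulation and uses `extent_k` as given.
#' @param gm_threshold gray-matter probability cut.
#' @param sphere_radius a-priori ROI radius (mm).
#' @param similarity_combine `"union"` or `"intersection"` significance
#'   masking for the spatial correlation.
#' @param signs response directions to partition.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 20, grid = acq_grid(c(64, 64, 38)),
                            atlas = default_truth_atlas(),
                            noise = noise_model(), voxel_p = 0.001,
                            extent_k = 50, connectivity = 26,
                            mc_iter = 10000, gm_threshold = 0.8,
                            sphere_radius = 5,
                            similarity_combine = "union",
                            signs = c("positive", "negative"), seed = 1L) {
  structure(list(n_subjects = n_subjects, grid = grid, atlas = atlas,
                 noise = noise, voxel_p = voxel_p, extent_k = extent_k,
                 connectivity = connectivity, mc_iter = mc_iter,
                 gm_threshold = gm_threshold, sphere_radius = sphere_radius,
                 similarity_combine = similarity_combine, signs = signs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Reduced-scale demonstration configuration
#'
#' A 28 x 28 x 18 grid (same voxel size and TR) with the synthetic
#' scaled-down atlas, no Monte-Carlo stage and a 10-voxel extent rule: a
#' hard-edged 8 mm planted sphere spans only ~45 voxels at this voxel size,
#' below the 50-voxel rule that is calibrated for whole-brain correction of
#' smooth real activations, so recovery studies assess the partition at a
#' smaller extent.
#'
#' @param n_subjects cohort size (default 20).
#' @param seed master seed.
#' @export
demo_config <- function(n_subjects = 20, seed = 1L) {
  grid <- acq_grid(c(28, 28, 18))
  pipeline_config(n_subjects = n_subjects, grid = grid,
                  atlas = demo_truth_atlas(grid), extent_k = 10,
                  mc_iter = 0, seed = seed)
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order on a synthetic cohort and
#' returns a report bundle; identical config and seed give identical
#' results. With `out_dir`, writes the dataset, cluster tables, ROI
#' response tables and similarity summaries (every file embeds the seed and
#' a config hash).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param phases phases to analyse.
#' @return A `pipeline_report` list: `cohort`, `glm`, `mc`, `partitions`
#'   (per sign), `cluster_table`, `rois`, `responses`, `similarity`,
#'   `behavior`, `config_hash`, `seed`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL,
                         phases = c("choice", "feedback")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cfg_hash <- config_hash(config)

  cohort <- stage("simulate",
    generate_cohort(config$n_subjects, atlas = config$atlas,
                    noise = config$noise, grid = config$grid,
                    seed = config$seed))
  glm <- stage("glm", fit_cohort_glm(cohort, phases))
  gm <- gray_matter_mask(cohort$gm_prob, config$gm_threshold)

  mc <- NULL
  extent_k <- config$extent_k
  if (config$mc_iter > 0) {
    mc <- stage("mc-threshold",
      mc_extent_threshold(config$grid, fwhm = config$noise$fwhm,
                          voxel_p = config$voxel_p,
                          n_iter = config$mc_iter, seed = config$seed,
                          connectivity = config$connectivity))
  }

  partitions <- stage("conjoin", {
    out <- list()
    for (ph in phases) {
      maps <- lapply(glm$group, function(g) g[[ph]])
      for (sg in config$signs)
        out[[ph]][[sg]] <- partition_conjunctions(
          maps, sign = sg, voxel_p = config$voxel_p, extent_k = extent_k,
          connectivity = config$connectivity)
    }
    out
  })

  cluster_table <- stage("report-clusters", {
    rows <- list()
    for (ph in names(partitions)) for (sg in names(partitions[[ph]])) {
      for (cm in partitions[[ph]][[sg]]) {
        cl <- cm$clusters
        if (length(cl$sizes) == 0) next
        mt <- as.numeric(cm$min_t$values)
        for (lab in seq_along(cl$sizes)) {
          idx <- which(cl$labels == lab)
          rows[[length(rows) + 1]] <- data.frame(
            phase = ph, sign = sg, conjunction = cm$spec$label,
            region = sprintf("cluster%d", lab), size = cl$sizes[lab],
            x = cl$peaks_mm[lab, 1], y = cl$peaks_mm[lab, 2],
            z = cl$peaks_mm[lab, 3],
            t = mt[idx][which.max(abs(mt[idx]))],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  rois <- stage("roi-build",
    rois_from_conjunctions(partitions[[phases[1]]][["positive"]],
                           excluded_structures = cohort$excluded,
                           connectivity = config$connectivity))
  responses <- stage("roi-extract",
    if (length(rois)) extract_responses(glm$contrasts, rois) else NULL)

  similarity <- stage("similarity", {
    out <- list()
    for (ph in phases) {
      sigs <- lapply(glm$group, function(g)
        sig_mask(g[[ph]], config$voxel_p, "positive"))
      m_vm <- similarity_mask(sigs$Value, sigs$Mathematical, gm,
                              config$similarity_combine)
      m_ve <- similarity_mask(sigs$Value, sigs$Emotion, gm,
                              config$similarity_combine)
      res_vm <- pair_similarity(glm$contrasts, "Value", "Mathematical", ph,
                                m_vm)
      res_ve <- pair_similarity(glm$contrasts, "Value", "Emotion", ph, m_ve)
      out[[ph]] <- list(vm = res_vm, ve = res_ve,
                        test = compare_pairs(res_vm, res_ve))
    }
    out
  })

  behavior <- stage("behavior", list(
    table = cohort$behavior,
    anova_accuracy = anova_tasks(cohort$behavior, "accuracy"),
    anova_rt = anova_tasks(cohort$behavior, "mean_rt"),
    tukey_accuracy = tukey_posthoc(cohort$behavior, "accuracy"),
    tukey_rt = tukey_posthoc(cohort$behavior, "mean_rt")))

  report <- structure(list(cohort = cohort, glm = glm, mc = mc,
                           partitions = partitions,
                           cluster_table = cluster_table, rois = rois,
                           responses = responses, similarity = similarity,
                           behavior = behavior, config_hash = cfg_hash,
                           seed = config$seed),
                      class = "pipeline_report")
  if (!is.null(out_dir)) stage("write-report",
    write_report(report, out_dir))
  report
}

#' Stable hash of a pipeline configuration
#' @param config a [pipeline_config()].
#' @export
config_hash <- function(config) {
  cfg <- config
  cfg$atlas <- cfg$atlas$regions
  cfg$grid <- list(cfg$grid$dims, cfg$grid$voxel_size, cfg$grid$tr,
                   cfg$grid$affine)
  txt <- paste(deparse(cfg), collapse = "")
  # small Fowler-Noll-Vo style rolling hash; stability, not cryptography
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write the report bundle
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = report$seed, config_hash = report$config_hash)
  if (!is.null(report$cluster_table))
    utils::write.table(cbind(report$cluster_table,
                             seed = report$seed,
                             config_hash = report$config_hash),
                       file.path(out_dir, "cluster_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(report$responses))
    utils::write.table(cbind(report$responses, seed = report$seed,
                             config_hash = report$config_hash),
                       file.path(out_dir, "roi_responses.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  sim <- lapply(report$similarity, function(ph)
    list(mean_z_vm = mean(ph$vm$z), mean_z_ve = mean(ph$ve$z),
         test = ph$test))
  jsonlite::write_json(c(stamp, list(similarity = sim,
                                     behavior = report$behavior[-1],
                                     mc_k = if (!is.null(report$mc))
                                       report$mc$k_for_alpha else NULL)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
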