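# BOLD simulation: planted signal + smooth AR(1) Gaussian noise.

#' Noise model for simulated runs
#'
#' @param sigma temporal noise SD in signal (percent) units (default 1).
#' @param fwhm spatial smoothness of the noise in mm (default 8, mimicking
#'   data smoothed with an 8 mm FWHM kernel).
#' @param ar1 lag-1 temporal autocorrelation in \[0, 1) (default 0.2).
#' @return A `noise_model`.
#' @export
noise_model <- function(sigma = 1, fwhm = 8, ar1 = 0.2) {
  stopifnot(sigma >= 0, fwhm >= 0, ar1 >= 0, ar1 < 1)
  structure(list(sigma = sigma, fwhm = fwhm, ar1 = ar1),
            class = "noise_model")
}

# smooth small-amplitude motion drift (mm / radians)
.simulate_motion <- function(n_scan, amplitude = 0.05) {
  drift <- apply(matrix(stats::rnorm(n_scan * 6, sd = amplitude / 4), n_scan),
                 2, cumsum)
  as.matrix(stats::filter(drift, rep(1 / 9, 9), sides = 2, circular = TRUE))
}

#' Simulate one functional run
#'
#' The signal at each voxel is the planted effect amplitude times the
#' HRF-convolved condition regressors of the schedule (choice events at full
#' amplitude, feedback events scaled by `feedback_scale`), on top of a flat
#' baseline. Noise is Gaussian, spatially smoothed to the stated FWHM and
#' temporally AR(1), scaled so the marginal voxel SD is `noise$sigma`.
#'
#' @param events per-run event table from [generate_schedule()].
#' @param effect the task's planted effect [fmri_volume()] (percent signal
#'   change during choice).
#' @param noise a [noise_model()].
#' @param grid an [acq_grid()].
#' @param task task name selecting the [condition_grouping()].
#' @param n_scan scans in the run.
#' @param seed integer seed.
#' @param feedback_scale feedback amplitude relative to choice (default 0.5).
#' @param baseline flat baseline signal level (default 100).
#' @param hrf an [hrf_params()].
#' @return List with `series` (an [fmri_series()]) and `motion`
#'   (`n_scan x 6`).
#' @export
simulate_run <- function(events, effect, noise, grid, task, n_scan,
                         seed = 1L, feedback_scale = 0.5, baseline = 100,
                         hrf = hrf_params()) {
  stopifnot(inherits(effect, "fmri_volume"), inherits(noise, "noise_model"))
  if (n_scan <= 0) stop("run length must be positive")
  stop_if_grid_mismatch(grid, effect$grid)
  design <- build_design(events, n_scan, tr = grid$tr, hrf = hrf,
                         grouping = condition_grouping(task))
  tc <- design$task_columns
  colamp <- ifelse(grepl("^choice", tc), 1, feedback_scale)
  s_t <- as.numeric(design$X[, tc, drop = FALSE] %*% colamp)
  signal <- outer(as.numeric(effect$values), s_t)

  with_seed(seed, {
    data <- baseline + signal
    if (noise$sigma > 0) {
      sig_vox <- if (noise$fwhm > 0) fwhm_to_sigma(noise$fwhm) / grid$voxel_size
                 else c(0, 0, 0)
      data <- data + .cpp_noise_run(grid$dims, sig_vox, noise$sigma,
                                    noise$ar1, as.integer(n_scan))
    }
    motion <- .simulate_motion(n_scan)
    list(series = fmri_series(data, grid), motion = motion)
  })
}

#' Simulate one subject
#'
#' Draws the subject's regional responsiveness (Gaussian multipliers around
#' 1 with SD `subject_sd`, shared across the tasks a region serves), task
#' accuracies and response times, then generates schedules and runs for all
#' tasks.
#'
#' @param specs named list of [task_spec()]s.
#' @param atlas a [truth_atlas()].
#' @param noise a [noise_model()].
#' @param grid an [acq_grid()].
#' @param seed integer seed.
#' @param subject_sd between-subject SD of region amplitude multipliers
#'   (default 0.3, i.e. 30 percent of the effect).
#' @param accuracy_sd,rt_means,rt_sd behavioural population parameters; the
#'   defaults follow the observed task means/SDs (accuracy SDs 5.4/7.0/14.3
#'   percent; response times 1982(436)/2447(280)/1759(375) ms).
#' @return A `subject_sim`: `schedules`, `runs` (per task: list of
#'   [simulate_run()] results), `effects`, `region_scale`, `behavior` row.
#' @export
simulate_subject <- function(specs, atlas, noise, grid, seed = 1L,
                             subject_sd = 0.3,
                             accuracy_sd = c(Value = 5.4, Mathematical = 7.0,
                                             Emotion = 14.3),
                             rt_means = c(Value = 1982, Mathematical = 2447,
                                          Emotion = 1759),
                             rt_sd = c(Value = 436, Mathematical = 280,
                                       Emotion = 375)) {
  n_reg <- nrow(atlas$regions)
  draws <- with_seed(seed, list(
    scale = stats::rnorm(n_reg, mean = 1, sd = subject_sd),
    acc_jit = stats::rnorm(length(specs)),
    rt = stats::rnorm(length(specs)),
    subseeds = sample.int(.Machine$integer.max - 1, length(specs))))
  effects <- plant_truth(atlas, grid, scale = draws$scale)

  schedules <- list()
  runs <- list()
  behavior <- NULL
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    acc <- min(1, max(0, sp$accuracy +
                        draws$acc_jit[i] * accuracy_sd[[sp$name]] / 100))
    sched <- generate_schedule(sp, seed = draws$subseeds[i], accuracy = acc,
                               tr = grid$tr)
    schedules[[sp$name]] <- sched
    runs[[sp$name]] <- lapply(seq_along(sched), function(r) {
      simulate_run(sched[[r]], effects[[sp$name]], noise, grid,
                   task = sp$name, n_scan = sp$volumes_per_run,
                   seed = draws$subseeds[i] %% 100000L + r)
    })
    obs_acc <- mean(unlist(lapply(sched, function(ev)
      ev$outcome[grepl("^choice", ev$condition)] == "correct"))) * 100
    behavior <- rbind(behavior, data.frame(
      task = sp$name, accuracy = obs_acc,
      mean_rt = max(200, rt_means[[sp$name]] + draws$rt[i] * rt_sd[[sp$name]]),
      stringsAsFactors = FALSE))
  }
  structure(list(schedules = schedules, runs = runs, effects = effects,
                 region_scale = draws$scale, behavior = behavior,
                 grid = grid),
            class = "subject_sim")
}

# Smooth-edged ellipsoidal "brain" gray-matter probability volume.
.gm_probability <- function(grid) {
  centers <- voxel_centers_mm(grid)
  mid <- voxel_to_world(grid, (grid$dims - 1) / 2)
  semi <- 0.46 * grid$voxel_size * grid$dims
  r <- sqrt(((centers[, 1] - mid[1]) / semi[1])^2 +
              ((centers[, 2] - mid[2]) / semi[2])^2 +
              ((centers[, 3] - mid[3]) / semi[3])^2)
  fmri_volume(pmin(1, pmax(0, (1.05 - r) / 0.1)), grid)
}

#' Generate a synthetic cohort
#'
#' Simulates `n_subjects` subjects under one truth atlas and noise model.
#' With `out_dir` set, writes per-subject NIfTI runs, event and motion TSVs,
#' the gray-matter probability volume, the excluded-structures mask (union
#' of atlas regions flagged `exclude_structure`) and a JSON manifest; the
#' in-memory cohort is returned either way.
#'
#' @param n_subjects number of subjects (default 20).
#' @param specs named list of [task_spec()]s.
#' @param atlas a [truth_atlas()]; defaults to [default_truth_atlas()].
#' @param noise a [noise_model()].
#' @param grid an [acq_grid()]; defaults to the 64 x 64 x 38 acquisition
#'   lattice at 3.4375 x 3.4375 x 4 mm, TR 2 s.
#' @param seed integer master seed; all randomness flows from it.
#' @param out_dir optional output directory.
#' @return A `cohort`: `subjects` (list of `subject_sim`), `gm_prob`,
#'   `excluded`, `atlas`, `grid`, `noise`, `seed`, `behavior` table.
#' @export
generate_cohort <- function(n_subjects = 20, specs = default_task_specs(),
                            atlas = default_truth_atlas(),
                            noise = noise_model(),
                            grid = acq_grid(c(64, 64, 38)), seed = 1L,
                            out_dir = NULL) {
  subseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_subjects))
  subjects <- lapply(seq_len(n_subjects), function(s)
    simulate_subject(specs, atlas, noise, grid, seed = subseeds[s]))
  names(subjects) <- sprintf("sub%02d", seq_len(n_subjects))
  behavior <- do.call(rbind, lapply(names(subjects), function(s)
    cbind(subject = s, subjects[[s]]$behavior)))
  gm <- .gm_probability(grid)
  excl_idx <- which(atlas$regions$exclude_structure)
  excluded <- if (length(excl_idx)) atlas_mask(atlas, grid, excl_idx)
              else fmri_mask(array(FALSE, grid$dims), grid)
  cohort <- structure(list(subjects = subjects, gm_prob = gm,
                           excluded = excluded, atlas = atlas, grid = grid,
                           noise = noise, seed = seed, behavior = behavior),
                      class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort to disk
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cohort$seed,
                   grid = list(dims = cohort$grid$dims,
                               voxel_size = cohort$grid$voxel_size,
                               tr = cohort$grid$tr),
                   noise = unclass(cohort$noise), subjects = list())
  write_volume(cohort$gm_prob, file.path(out_dir, "gm_prob.nii.gz"))
  write_volume(cohort$excluded, file.path(out_dir, "excluded.nii.gz"))
  for (s in names(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    sdir <- file.path(out_dir, s)
    dir.create(sdir, showWarnings = FALSE)
    files <- list()
    for (task in names(sub$runs)) {
      for (r in seq_along(sub$runs[[task]])) {
        base <- sprintf("%s_run%d", tolower(task), r)
        write_volume(sub$runs[[task]][[r]]$series,
                     file.path(sdir, paste0(base, ".nii.gz")),
                     dtype = "float32")
        write_events(sub$schedules[[task]][[r]],
                     file.path(sdir, paste0(base, "_events.tsv")))
        write_motion(sub$runs[[task]][[r]]$motion,
                     file.path(sdir, paste0(base, "_motion.tsv")))
        files[[base]] <- paste0(s, "/", base, c(".nii.gz", "_events.tsv",
                                                "_motion.tsv"))
      }
    }
    manifest$subjects[[s]] <- files
  }
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  utils::write.table(cohort$behavior, file.path(out_dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
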