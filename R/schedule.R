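# Trial-schedule generation for the three decision tasks.
#
# Timing per trial: 4 s choice, 2 s feedback, then a variable fixation
# inter-trial interval in [1, 5] s with mean 1.5 s; every run opens and
# closes with 20 s fixation. Predetermined-outcome categories follow the
# printed design: the higher-expected-value option wins in "higher" trials,
# the lower one in "lower" trials, any choice wins in "either" trials and
# none in "neither" trials.

# Run code with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Task specification
#'
#' Captures one task's run structure, trial counts, outcome schedule and
#' timing. Ready-made constructors [value_task_spec()], [math_task_spec()]
#' and [emotion_task_spec()] encode the study design (Value: 2 runs of 200
#' volumes, 5 difficulty levels x 16 trials; Mathematical: 1 run of 224
#' volumes, 3 levels x 15 trials; Emotion: 1 run of 108 volumes, 20 trials).
#'
#' @param name task label.
#' @param n_runs number of runs.
#' @param volumes_per_run scans per run.
#' @param difficulty_levels number of difficulty levels.
#' @param trials_per_level trials per level (totals = levels x per-level).
#' @param outcome_schedule named integer vector of predetermined-outcome
#'   category counts summing to the total trial count. Categories are
#'   `higher`, `lower`, `either`, `neither`, or `actual` for tasks whose
#'   feedback follows the response with no predetermined outcome.
#' @param accuracy probability of a correct choice used when simulating
#'   responses; defaults are the observed task means.
#' @param choice_duration,feedback_duration event durations in seconds.
#' @param iti_range,iti_mean inter-trial fixation interval range and mean (s).
#' @param lead_fixation fixation before the first and after the last trial (s).
#' @return A `task_spec` object.
#' @export
task_spec <- function(name, n_runs, volumes_per_run, difficulty_levels,
                      trials_per_level, outcome_schedule, accuracy,
                      choice_duration = 4, feedback_duration = 2,
                      iti_range = c(1, 5), iti_mean = 1.5,
                      lead_fixation = 20) {
  n_trials <- difficulty_levels * trials_per_level
  stopifnot(sum(outcome_schedule) == n_trials,
            iti_mean >= iti_range[1], iti_mean <= iti_range[2],
            n_runs >= 1, volumes_per_run >= 1,
            accuracy >= 0, accuracy <= 1)
  structure(list(name = name, n_runs = as.integer(n_runs),
                 volumes_per_run = as.integer(volumes_per_run),
                 difficulty_levels = as.integer(difficulty_levels),
                 trials_per_level = as.integer(trials_per_level),
                 n_trials = as.integer(n_trials),
                 outcome_schedule = outcome_schedule, accuracy = accuracy,
                 choice_duration = choice_duration,
                 feedback_duration = feedback_duration,
                 iti_range = iti_range, iti_mean = iti_mean,
                 lead_fixation = lead_fixation),
            class = "task_spec")
}

#' @rdname task_spec
#' @export
value_task_spec <- function() {
  task_spec("Value", n_runs = 2, volumes_per_run = 200,
            difficulty_levels = 5, trials_per_level = 16,
            outcome_schedule = c(higher = 50, lower = 8, either = 12,
                                 neither = 10),
            accuracy = 0.634)
}

#' @rdname task_spec
#' @export
math_task_spec <- function() {
  task_spec("Mathematical", n_runs = 1, volumes_per_run = 224,
            difficulty_levels = 3, trials_per_level = 15,
            outcome_schedule = c(actual = 45), accuracy = 0.781)
}

#' @rdname task_spec
#' @export
emotion_task_spec <- function() {
  task_spec("Emotion", n_runs = 1, volumes_per_run = 108,
            difficulty_levels = 1, trials_per_level = 20,
            outcome_schedule = c(higher = 10, lower = 2, either = 5,
                                 neither = 3),
            accuracy = 0.568)
}

#' Default task specifications for the three-task design
#' @return Named list of [task_spec()] objects (Value, Mathematical, Emotion).
#' @export
default_task_specs <- function() {
  list(Value = value_task_spec(), Mathematical = math_task_spec(),
       Emotion = emotion_task_spec())
}

# Rate of the shifted truncated exponential on [lo, hi] whose mean is m.
.iti_rate <- function(lo, hi, m) {
  span <- hi - lo
  target <- m - lo
  if (abs(target - span / 2) < 1e-12) return(0)  # uniform limit
  f <- function(l) 1 / l - span * exp(-span * l) / (1 - exp(-span * l)) - target
  stats::uniroot(f, c(1e-8, 1e3), tol = 1e-12)$root
}

#' Draw inter-trial intervals
#'
#' ITIs follow a shifted exponential truncated to `range`, with the rate
#' calibrated so the distribution mean equals `mean` (default: \[1, 5\] s
#' with mean 1.5 s). Draws are iid via inverse-CDF sampling.
#'
#' @param n number of draws.
#' @param range length-2 interval in seconds.
#' @param mean target mean in seconds.
#' @return Numeric vector of `n` ITIs, all within `range`.
#' @export
sample_iti <- function(n, range = c(1, 5), mean = 1.5) {
  lam <- .iti_rate(range[1], range[2], mean)
  span <- range[2] - range[1]
  u <- stats::runif(n)
  if (lam == 0) return(range[1] + u * span)
  range[1] - log(1 - u * (1 - exp(-span * lam))) / lam
}

# Balanced allocation of outcome-category counts across difficulty levels:
# category labels are dealt to levels round-robin, so every level holds
# exactly trials_per_level trials and each category is spread as evenly as
# possible (in particular every level keeps sure-win "either" and sure-loss
# "neither" trials, so no feedback regressor cell is empty).
.allocate_categories <- function(counts, levels) {
  labels <- rep(names(counts), counts)
  lev <- rep_len(seq_len(levels), length(labels))
  out <- matrix(0L, nrow = levels, ncol = length(counts),
                dimnames = list(NULL, names(counts)))
  tab <- table(factor(lev, levels = seq_len(levels)),
               factor(labels, levels = names(counts)))
  out[] <- as.integer(tab)
  out
}

#' Generate per-run event tables for a task
#'
#' Produces one event table per run with choice and feedback rows, onsets
#' starting after the lead-in fixation, balanced allocation of difficulty
#' levels and outcome categories across runs, simulated choice correctness,
#' and realised gain/no-gain (or correct/incorrect) feedback. Deterministic
#' for a fixed seed.
#'
#' @param task a [task_spec()].
#' @param seed integer seed.
#' @param accuracy optional override of the simulated probability of a
#'   correct choice.
#' @param tr repetition time in seconds, fixing the run duration
#'   `volumes_per_run * tr` the schedule must fit.
#' @return A list of `n_runs` event data.frames (columns `onset_s`,
#'   `duration_s`, `condition`, `outcome`), with attribute `task`.
#' @export
generate_schedule <- function(task, seed = 1L, accuracy = task$accuracy,
                              tr = 2) {
  stopifnot(inherits(task, "task_spec"))
  with_seed(seed, {
    lv <- task$difficulty_levels
    per_level_cat <- .allocate_categories(task$outcome_schedule, lv)
    trials <- do.call(rbind, lapply(seq_len(lv), function(l) {
      data.frame(level = l,
                 category = rep(colnames(per_level_cat), per_level_cat[l, ]),
                 stringsAsFactors = FALSE)
    }))
    # strict global alternation: runs get equal trial totals (80 -> 40/40)
    # and every within-level category block of >= n_runs trials spans all runs
    trials$run <- rep_len(seq_len(task$n_runs), nrow(trials))
    trials$correct <- stats::runif(nrow(trials)) < accuracy
    predet <- !identical(names(task$outcome_schedule), "actual")
    if (predet) {
      trials$gain <- trials$category == "either" |
        (trials$category == "higher" & trials$correct) |
        (trials$category == "lower" & !trials$correct)
      trials$fb <- ifelse(trials$gain, "gain", "nogain")
    } else {
      trials$fb <- ifelse(trials$correct, "correct", "incorrect")
    }

    runs <- vector("list", task$n_runs)
    run_dur <- task$volumes_per_run * tr
    for (r in seq_len(task$n_runs)) {
      tr_r <- trials[trials$run == r, , drop = FALSE]
      tr_r <- tr_r[sample.int(nrow(tr_r)), , drop = FALSE]  # pseudo-random order
      n <- nrow(tr_r)
      iti <- sample_iti(n, task$iti_range, task$iti_mean)
      trial_len <- task$choice_duration + task$feedback_duration
      onset <- task$lead_fixation +
        c(0, cumsum(trial_len + iti[-n]))
      run_end <- onset[n] + trial_len + task$lead_fixation
      if (run_end > run_dur)
        stop(sprintf("schedule does not fit run %d: needs %.1f s, run is %.0f s",
                     r, run_end, run_dur))
      runs[[r]] <- data.frame(
        onset_s = c(rbind(onset, onset + task$choice_duration)),
        duration_s = rep(c(task$choice_duration, task$feedback_duration), n),
        condition = c(rbind(paste0("choice_L", tr_r$level),
                            paste0("feedback_L", tr_r$level))),
        outcome = c(rbind(ifelse(tr_r$correct, "correct", "incorrect"),
                          tr_r$fb)),
        stringsAsFactors = FALSE)
      attr(runs[[r]], "iti") <- iti
    }
    attr(runs, "task") <- task$name
    runs
  })
}
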