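# Design-matrix construction.
#
# Condition regressors are boxcars (4 s choice, 2 s feedback) convolved with
# the canonical HRF on a microtime grid and sampled at scan onsets. Each
# regressor is scaled so that an isolated event of its duration peaks at 1;
# a GLM coefficient is then directly the peak signal change attributable to
# one event, which keeps planted effect sizes and recovered betas on the
# same scale.

# causal convolution y[i] = sum_j h[j] x[i - j + 1] via C-level filtering
.conv_causal <- function(x, h) {
  nh <- length(h)
  y <- stats::filter(c(rep(0, nh - 1), x), h, method = "convolution",
                     sides = 1)
  as.numeric(y[(nh - 1) + seq_along(x)])
}

#' Condition-grouping rules
#'
#' A grouping rule maps each event (condition, outcome) to a regressor
#' label, and declares which labels are nuisance rather than task columns.
#' The task defaults reproduce the study's models: Value groups events into
#' 5 difficulty levels x (choice, gain feedback, no-gain feedback) = 15 task
#' regressors; Mathematical into 3 levels x (choice of correct trials,
#' correct feedback, incorrect feedback) = 9 task regressors with
#' incorrect-trial choices kept as one nuisance regressor so all scans stay
#' modelled; Emotion into choice, gain feedback and no-gain feedback = 3.
#'
#' @param task `"Value"`, `"Mathematical"` or `"Emotion"`.
#' @return A function `(condition, outcome) -> label` with attribute
#'   `nuisance` (labels to treat as nuisance conditions).
#' @export
condition_grouping <- function(task) {
  level_of <- function(condition) sub("^[a-z]+_L", "", condition)
  phase_of <- function(condition) sub("_L[0-9]+$", "", condition)
  f <- switch(task,
    Value = function(condition, outcome) {
      ifelse(phase_of(condition) == "choice",
             paste0("choice_L", level_of(condition)),
             paste0("fb_", ifelse(outcome == "gain", "gain", "nogain"),
                    "_L", level_of(condition)))
    },
    Mathematical = function(condition, outcome) {
      ifelse(phase_of(condition) == "choice",
             ifelse(outcome == "correct",
                    paste0("choice_L", level_of(condition)),
                    "choice_incorrect"),
             paste0("fb_", outcome, "_L", level_of(condition)))
    },
    Emotion = function(condition, outcome) {
      ifelse(phase_of(condition) == "choice", "choice",
             paste0("fb_", ifelse(outcome == "gain", "gain", "nogain")))
    },
    stop("unknown task: ", task))
  attr(f, "nuisance") <- if (task == "Mathematical") "choice_incorrect"
                         else character()
  f
}

#' Build a run design matrix
#'
#' @param events per-run event table (see [generate_schedule()]).
#' @param n_scan number of scans in the run.
#' @param tr repetition time (s).
#' @param hrf an [hrf_params()].
#' @param motion optional `n_scan x 6` motion-parameter matrix, appended as
#'   nuisance columns.
#' @param grouping grouping rule from [condition_grouping()]; every event
#'   condition must be covered by the rule.
#' @return A `design_matrix`: list with `X` (scans x regressors, labelled),
#'   `task_columns`, `nuisance_columns`, `tr`, `n_scan`.
#' @export
build_design <- function(events, n_scan, tr = 2, hrf = hrf_params(),
                         motion = NULL, grouping) {
  stopifnot(is.data.frame(events) || nrow(events) == 0)
  if (!is.null(motion) && nrow(motion) != n_scan)
    stop("motion table must have one row per scan")
  run_dur <- n_scan * tr
  if (nrow(events) > 0 && any(events$onset_s + events$duration_s > run_dur))
    stop("event extends beyond the run")

  h <- canonical_hrf(hrf)
  dt <- hrf$dt
  nt <- ceiling(run_dur / dt) + 1L

  task_cols <- list()
  nuis_cond_cols <- list()
  if (nrow(events) > 0) {
    labels <- grouping(events$condition, events$outcome)
    if (anyNA(labels))
      stop("grouping rule does not cover conditions: ",
           paste(unique(events$condition[is.na(labels)]), collapse = ", "))
    # per-duration peak of an isolated event response, for scaling
    peak_for <- vapply(unique(events$duration_s), function(d) {
      nb <- ceiling(d / dt) + length(h)
      box <- as.numeric(seq(0, by = dt, length.out = nb) < d)
      max(.conv_causal(box, h))
    }, numeric(1))
    names(peak_for) <- as.character(unique(events$duration_s))

    scan_idx <- round((seq_len(n_scan) - 1) * tr / dt) + 1L
    # the convolution is only needed at scan times: gather the lagged boxcar
    # values into an n_scan x n_lag matrix once and take its product with h
    lag_idx <- outer(scan_idx, seq_along(h) - 1L, `-`)
    lag_idx <- pmax(lag_idx, 0L) + 1L          # index 1 of box0 is a zero pad
    for (lab in sort(unique(labels))) {
      sel <- which(labels == lab)
      box0 <- numeric(nt + 1L)
      for (i in sel) {
        a <- floor(events$onset_s[i] / dt) + 1L
        b <- min(nt, ceiling((events$onset_s[i] + events$duration_s[i]) / dt))
        box0[(a:b) + 1L] <- 1
      }
      conv_at_scans <- drop(matrix(box0[lag_idx], nrow = n_scan) %*% h)
      reg <- conv_at_scans /
        peak_for[[as.character(events$duration_s[sel[1]])]]
      if (all(reg == 0)) {
        warning("dropping all-zero regressor: ", lab)
        next
      }
      if (lab %in% attr(grouping, "nuisance")) nuis_cond_cols[[lab]] <- reg
      else task_cols[[lab]] <- reg
    }
  } else {
    warning("empty schedule: design contains only nuisance columns")
  }

  nuis <- nuis_cond_cols
  if (!is.null(motion)) {
    for (j in 1:6) nuis[[paste0("motion", j)]] <- motion[, j]
  }
  nuis[["intercept"]] <- rep(1, n_scan)

  X <- do.call(cbind, c(task_cols, nuis))
  colnames(X) <- c(names(task_cols), names(nuis))
  if (anyDuplicated(colnames(X))) stop("duplicate regressor labels")
  structure(list(X = X, task_columns = names(task_cols),
                 nuisance_columns = names(nuis), tr = tr, n_scan = n_scan),
            class = "design_matrix")
}

#' Averaging contrast over a phase's task regressors
#'
#' Builds the contrast vector that averages the choice-phase (or
#' feedback-phase) condition coefficients of a design, i.e. the task-mean
#' response used for the task-versus-baseline maps.
#'
#' @param design a `design_matrix` (or character vector of task labels).
#' @param phase `"choice"` or `"feedback"`.
#' @return Named numeric contrast over the task columns.
#' @export
task_contrast <- function(design, phase = c("choice", "feedback")) {
  phase <- match.arg(phase)
  labels <- if (is.character(design)) design else design$task_columns
  pick <- if (phase == "choice") grepl("^choice", labels)
          else grepl("^fb_", labels)
  if (!any(pick)) stop("no task columns for phase ", phase)
  ct <- numeric(length(labels))
  names(ct) <- labels
  ct[pick] <- 1 / sum(pick)
  ct
}
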