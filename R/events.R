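# Event tables and motion-parameter tables.
#
# Event tables are tab-separated with a header row and exactly the columns
# onset_s, duration_s, condition, outcome; one row per modelled event
# (choice and feedback phases are separate rows). Motion tables are
# tab-separated with six columns (tx, ty, tz in mm; rx, ry, rz in radians)
# and one row per scan.

.event_cols <- c("onset_s", "duration_s", "condition", "outcome")

#' Read a per-run event table
#' @param path TSV file with columns onset_s, duration_s, condition, outcome.
#' @return A data.frame ordered by onset.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(.event_cols %in% names(ev)))
    stop("event table must have columns: ", paste(.event_cols, collapse = ", "))
  ev <- ev[order(ev$onset_s), .event_cols]
  rownames(ev) <- NULL
  ev
}

#' Write a per-run event table
#' @param events data.frame as produced by [generate_schedule()].
#' @param path output TSV path.
#' @export
write_events <- function(events, path) {
  stopifnot(all(.event_cols %in% names(events)))
  utils::write.table(events[, .event_cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a six-column motion-parameter table
#' @param path TSV path, one row per scan.
#' @return A numeric matrix with 6 columns.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.delim(path))
  if (ncol(m) != 6) stop("motion table must have exactly 6 columns")
  storage.mode(m) <- "double"
  m
}

#' Write a motion-parameter table
#' @param motion numeric matrix, n_scan x 6.
#' @param path output TSV path.
#' @export
write_motion <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  utils::write.table(motion, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
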