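# Stopping-threshold picking (STP).
#
# For every (parent, child) pair, one threshold T is chosen from the
# cross-validated training confidences of that parent's classifier:
#   a = the smallest candidate threshold whose constrained accuracy (among
#       records retained at that threshold) strictly exceeds the accuracy
#       target, 1.0 if none does;
#   b = the mean confidence of the correctly classified records, 0 if none;
#   T = max(a, b) - variability.
# Records enter a pair's selection by their PREDICTED child: at
# classification time only the predicted child is known, and T gates
# exactly those events.  T below 0 means "never stop"; the conservative
# fallbacks (a = 1, b = 0) make a pair with no usable evidence almost
# always yield "uncertain".

#' Configuration of the stopping-threshold picker
#'
#' @param candidate_grid ascending candidate thresholds in `[0, 1]`.
#' @param accuracy_target constrained accuracy must strictly exceed this
#'   (default 0.90).
#' @param variability amount subtracted from `max(a, b)` (default 0.05),
#'   slackening the threshold against sampling variability of the training
#'   confidences.
#' @return Object of class `stp_config`.
#' @export
stp_config <- function(candidate_grid = seq(0, 1, by = 0.01),
                       accuracy_target = 0.90, variability = 0.05) {
  stopifnot(is.unsorted(candidate_grid) == FALSE,
            all(candidate_grid >= 0), all(candidate_grid <= 1),
            accuracy_target >= 0, accuracy_target <= 1, variability >= 0)
  # snap grid values generated by seq() to their decimal intent so that a
  # confidence printed as 0.70 is retained at the candidate 0.70
  candidate_grid <- round(candidate_grid, 10)
  structure(list(candidate_grid = candidate_grid,
                 accuracy_target = accuracy_target,
                 variability = variability),
            class = "stp_config")
}

#' Constrained accuracy at a confidence threshold
#'
#' Among records with confidence at least `t`, the fraction whose predicted
#' child equals the true child; `NA` when no record is retained.
#'
#' @param records data frame with columns `truth`, `predicted`,
#'   `confidence`.
#' @param t threshold.
#' @return Accuracy in `[0, 1]`, or `NA` for an empty retained set.
#' @export
constrained_accuracy_at <- function(records, t) {
  keep <- records$confidence >= t
  if (!any(keep)) return(NA_real_)
  mean(records$predicted[keep] == records$truth[keep])
}

#' Pick the stopping threshold for one (parent, child) pair
#'
#' @param records cross-validation records whose predicted child is this
#'   pair's child (columns `truth`, `predicted`, `confidence`).
#' @param cfg an [stp_config()].
#' @return Named numeric vector with elements `a`, `b`, `T` and
#'   `n_records`.
#' @export
pick_threshold <- function(records, cfg = stp_config()) {
  if (nrow(records) == 0L) {
    a <- 1; b <- 0
  } else {
    acc <- vapply(cfg$candidate_grid, constrained_accuracy_at,
                  numeric(1), records = records)
    hit <- which(!is.na(acc) & acc > cfg$accuracy_target)
    a <- if (length(hit)) cfg$candidate_grid[hit[1]] else 1
    correct <- records$predicted == records$truth
    b <- if (any(correct)) mean(records$confidence[correct]) else 0
  }
  c(a = a, b = b, T = max(a, b) - cfg$variability,
    n_records = nrow(records))
}

#' Build the stopping-threshold table of a trained hierarchy
#'
#' One threshold per (parent, child) pair of every multi-child parent;
#' single-child parents need no thresholds (the novelty classifier's
#' outlier verdict plays that role).
#'
#' @param taxonomy a `hiertax_taxonomy`.
#' @param cv_by_parent named list: parent node id (as character) ->
#'   cross-validation record data frame from [crossval_confidences()].
#' @param cfg an [stp_config()].
#' @param skip_missing silently skip multi-child parents without records
#'   (used when node failures were collected instead of aborting)?
#' @return Data frame with columns `parent`, `child`, `a`, `b`, `T`,
#'   `n_records`.
#' @export
build_threshold_table <- function(taxonomy, cv_by_parent,
                                  cfg = stp_config(), skip_missing = FALSE) {
  rows <- list()
  for (pid in taxonomy_internal_ids(taxonomy)) {
    kids <- taxonomy_children(taxonomy, pid)
    if (length(kids) < 2L) next
    cv <- cv_by_parent[[as.character(pid)]]
    if (is.null(cv)) {
      if (skip_missing) next
      stop("no cross-validation records for multi-child parent '",
           taxonomy_node_name(taxonomy, pid), "'", call. = FALSE)
    }
    for (kid in kids) {
      child <- taxonomy_node_name(taxonomy, kid)
      sel <- pick_threshold(cv[cv$predicted == child, , drop = FALSE], cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(parent = taxonomy_node_name(taxonomy, pid),
                   parent_id = pid, child = child,
                   a = sel[["a"]], b = sel[["b"]], T = sel[["T"]],
                   n_records = sel[["n_records"]],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(parent = character(0), parent_id = integer(0),
                      child = character(0), a = numeric(0), b = numeric(0),
                      T = numeric(0), n_records = integer(0)))
  do.call(rbind, rows)
}
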