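#' Ground-truth primitive sequence of a trial
#'
#' @param trial a trial (list with `labels`).
#' @return integer class-code sequence (run-length collapse of the track).
#' @export
trial_gt_sequence <- function(trial) collapse_to_sequence(trial$labels)

#' Evaluate per-window sequence predictions against labeled trials
#'
#' The end-to-end evaluation path shared by the sequence model and the
#' baselines: per trial, the per-window predicted sequences are merged by
#' the boundary-deduplicating counter into one predicted stream, which is
#' Levenshtein-aligned with the ground-truth sequence; alignments are
#' aggregated into classification metrics, confusion matrix and counting
#' reports.
#'
#' @param trials list of labeled trials (`labels`, `segments`, `subject`,
#'   `activity`).
#' @param window_seqs_by_trial list (same length) of per-window predicted
#'   sequences.
#' @return list with `metrics` ([metrics_report()]), `alignments`,
#'   `per_trial` (outcome tallies for bootstrap), `counts`
#'   (`predicted`/`true` per class), `count_error` (per-class
#'   [counting_error()]), `activity_counts` and `activity_error`
#'   (per-activity), and `subject_error` ([subject_counting_error()]).
#' @export
evaluate_sequence_predictions <- function(trials, window_seqs_by_trial) {
  stopifnot(length(trials) == length(window_seqs_by_trial))
  gt_seqs <- lapply(trials, trial_gt_sequence)
  streams <- lapply(window_seqs_by_trial, function(ws) dedup_and_count(ws)$stream)
  alignments <- Map(align_sequences, gt_seqs, streams)

  pred_counts <- Reduce(`+`, lapply(streams, function(s) tabulate(s, 5L)))
  names(pred_counts) <- PRIMITIVE_CLASSES
  tru_counts <- true_counts(trials)

  acts <- vapply(trials, `[[`, "", "activity")
  act_pred <- tapply(vapply(streams, length, 0L), acts, sum)
  act_true <- tapply(vapply(trials, function(t) nrow(t$segments), 0L), acts, sum)

  subj <- vapply(trials, `[[`, "", "subject")
  by_subj <- function(x) {
    out <- lapply(split(seq_along(subj), subj), function(ii) {
      cnt <- Reduce(`+`, lapply(x[ii], function(s) tabulate(s, 5L)))
      names(cnt) <- PRIMITIVE_CLASSES
      cnt
    })
    out
  }
  pred_by_subj <- by_subj(streams)
  true_by_subj <- by_subj(lapply(trials, function(t) class_to_code(t$segments$klass)))

  trial_ids <- paste(subj, acts, vapply(trials, `[[`, "", "trial_id"), sep = "/")
  list(metrics = metrics_report(alignments),
       alignments = alignments,
       per_trial = per_trial_outcomes(gt_seqs, streams, trial_ids),
       counts = list(predicted = pred_counts, true = tru_counts),
       count_error = counting_error(pred_counts, tru_counts),
       activity_counts = list(predicted = act_pred, true = act_true),
       activity_error = counting_error(
         stats::setNames(as.numeric(act_pred), names(act_pred)),
         stats::setNames(as.numeric(act_true), names(act_true))),
       subject_error = subject_counting_error(pred_by_subj, true_by_subj))
}

#' Oracle window predictions (ground-truth core sequences)
#'
#' Replaces the model with an oracle that emits each test core's true
#' collapsed sequence — used to verify that windowing plus deduplicating
#' counting is exact.
#'
#' @param trial a labeled trial.
#' @param core_s core length in seconds.
#' @return list of integer sequences, one per 4-s test core.
#' @export
oracle_window_sequences <- function(trial, core_s = 4) {
  n <- length(trial$labels)
  clen <- as.integer(round(core_s * trial$recording$sample_rate))
  starts <- seq.int(0L, max(0L, ceiling(n / clen) - 1L) * clen, by = clen)
  lapply(starts, function(cs)
    collapse_to_sequence(trial$labels, cs, min(cs + clen, n)))
}
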