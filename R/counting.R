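#' Boundary-deduplicating primitive counting
#'
#' Concatenates the per-window predicted sequences (in temporal core order)
#' into one stream, merging the single primitive that can straddle each
#' boundary between non-overlapping 4-s cores: whenever the last element of
#' one window equals the first element of the next, the two are counted as
#' one instance. Duplicates *within* a window are genuine repetitions and
#' are never merged; a primitive spanning three or more cores merges
#' pairwise across every boundary it crosses and is counted once. The merge
#' is class-equality based, so two genuinely distinct same-class primitives
#' meeting exactly at a core boundary are (incorrectly) merged — an inherent
#' limit of timing-free sequences.
#'
#' @param window_sequences list of primitive sequences (codes or characters),
#'   one per window in temporal order.
#' @return a `count_report` list: `counts` (named per-class tally), `stream`
#'   (the merged code sequence), `n_merges`, `total`.
#' @export
dedup_and_count <- function(window_sequences) {
  seqs <- lapply(window_sequences, class_to_code)
  stream <- integer(0)
  n_merges <- 0L
  for (s in seqs) {
    if (length(s) == 0L) next
    if (length(stream) > 0L && stream[length(stream)] == s[1L]) {
      s <- s[-1L]
      n_merges <- n_merges + 1L
    }
    stream <- c(stream, s)
  }
  tab <- tabulate(stream, nbins = 5L)
  names(tab) <- PRIMITIVE_CLASSES
  structure(list(counts = tab, stream = stream, n_merges = n_merges,
                 total = sum(tab)), class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("<count_report>", x$total, "primitives (", x$n_merges, "boundary merges ):\n")
  print(x$counts)
  invisible(x)
}

#' Counting error relative to ground truth
#'
#' Per cell (class or activity): percent error
#' `100 * (predicted - true) / true` and percent-of-true
#' `100 * predicted / true`. Cells with zero true count cannot be
#' normalized; they are excluded with a warning rather than producing a
#' division failure.
#'
#' @param predicted,true named non-negative count vectors over the same
#'   cells.
#' @return data.frame with columns `cell`, `predicted`, `true`,
#'   `percent_error`, `percent_of_true`; excluded zero-truth cells are
#'   absent.
#' @export
counting_error <- function(predicted, true) {
  cells <- names(true)
  if (is.null(cells)) cells <- as.character(seq_along(true))
  predicted <- predicted[cells]
  zero <- true == 0
  if (any(zero)) {
    warning("excluding zero-truth cells: ", paste(cells[zero], collapse = ", "))
  }
  keep <- !zero
  data.frame(cell = cells[keep],
             predicted = as.numeric(predicted[keep]),
             true = as.numeric(true[keep]),
             percent_error = 100 * (predicted[keep] - true[keep]) / true[keep],
             percent_of_true = 100 * predicted[keep] / true[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-subject counting-error summary
#'
#' Computes each subject's total-count percent error and returns the
#' per-subject values with their mean and standard deviation, mirroring
#' single-subject counting-error reporting (means over subjects can wash
#' out offsetting under- and over-counts).
#'
#' @param predicted_by_subject,true_by_subject named lists (by subject) of
#'   per-class count vectors.
#' @return list with `per_subject` data.frame (`subject`, `percent_error`)
#'   and `mean`, `sd` of the per-subject errors.
#' @export
subject_counting_error <- function(predicted_by_subject, true_by_subject) {
  subjects <- names(true_by_subject)
  pe <- vapply(subjects, function(s) {
    tot_true <- sum(true_by_subject[[s]])
    if (tot_true == 0) return(NA_real_)
    100 * (sum(predicted_by_subject[[s]]) - tot_true) / tot_true
  }, 0)
  list(per_subject = data.frame(subject = subjects, percent_error = pe,
                                row.names = NULL, stringsAsFactors = FALSE),
       mean = mean(pe, na.rm = TRUE), sd = stats::sd(pe[!is.na(pe)]))
}
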