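#' Levenshtein alignment of predicted vs. ground-truth primitive sequences
#'
#' Computes a unit-cost minimal edit alignment between a ground-truth and a
#' predicted primitive sequence and returns the full edit script. Each
#' alignment operation is one of `match` (same class on both sides),
#' `substitution` (a ground-truth primitive predicted as another class),
#' `deletion` (a ground-truth primitive absent from the prediction) or
#' `insertion` (a predicted primitive with no ground-truth counterpart).
#' Among equal-cost alignments the backtrace deterministically prefers
#' match over substitution over deletion over insertion.
#'
#' @param gt,pred integer code or character primitive sequences (either may
#'   be empty).
#' @return a `seq_alignment`: list with `ops` (data.frame with columns `op`,
#'   `gt` and `pred` class codes, `NA` where a side is absent) and
#'   `distance` (the minimal edit distance).
#' @export
align_sequences <- function(gt, pred) {
  gt0 <- class_to_code(gt); pred0 <- class_to_code(pred)
  # DP on the reversed sequences so that the backtrace (which walks from the
  # DP corner) applies the tie preference from the START of the originals:
  # the earliest divergence is explained as a substitution when possible
  gt <- rev(gt0); pred <- rev(pred0)
  n <- length(gt); m <- length(pred)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  if (n > 0L && m > 0L) {
    for (i in 1:n) {
      for (j in 1:m) {
        sub <- d[i, j] + (gt[i] != pred[j])
        d[i + 1L, j + 1L] <- min(sub, d[i, j + 1L] + 1L, d[i + 1L, j] + 1L)
      }
    }
  }
  # backtrace with fixed preference: match > substitution > deletion > insertion
  ops <- vector("list", n + m)
  k <- 0L; i <- n; j <- m
  while (i > 0L || j > 0L) {
    k <- k + 1L
    if (i > 0L && j > 0L && gt[i] == pred[j] && d[i + 1L, j + 1L] == d[i, j]) {
      ops[[k]] <- list(op = "match", gt = gt[i], pred = pred[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && j > 0L && d[i + 1L, j + 1L] == d[i, j] + 1L) {
      ops[[k]] <- list(op = "substitution", gt = gt[i], pred = pred[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && d[i + 1L, j + 1L] == d[i, j + 1L] + 1L) {
      ops[[k]] <- list(op = "deletion", gt = gt[i], pred = NA_integer_)
      i <- i - 1L
    } else {
      ops[[k]] <- list(op = "insertion", gt = NA_integer_, pred = pred[j])
      j <- j - 1L
    }
  }
  ops <- ops[seq_len(k)]
  # ops were collected walking from the reversed corner, i.e. already in the
  # original forward order
  df <- data.frame(
    op = vapply(ops, `[[`, "", "op"),
    gt = vapply(ops, function(o) as.integer(o$gt), 0L),
    pred = vapply(ops, function(o) as.integer(o$pred), 0L),
    stringsAsFactors = FALSE)
  structure(list(ops = df, distance = d[n + 1L, m + 1L],
                 n_gt = n, n_pred = m),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> |gt| = %d, |pred| = %d, distance = %d\n",
              x$n_gt, x$n_pred, x$distance))
  invisible(x)
}

#' @rdname align_sequences
#' @details `edit_distance()` computes only the minimal unit-cost edit
#'   distance (no edit script), which is cheaper when alignments are not
#'   needed.
#' @export
edit_distance <- function(gt, pred) {
  gt <- class_to_code(gt); pred <- class_to_code(pred)
  n <- length(gt); m <- length(pred)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in 1:n) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in 1:m) {
      cur[j + 1L] <- min(prev[j] + (gt[i] != pred[j]), prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Four-way error taxonomy of an alignment
#'
#' Tallies the alignment operations into the prediction-outcome taxonomy:
#' matches are true positives of their class; a deletion is a false negative
#' of the ground-truth class where nothing was predicted; a substitution
#' `(c, c')` is simultaneously a swap-out false negative of `c` and a
#' swap-in false positive of `c'`; an insertion is a false positive of the
#' predicted class with no ground-truth counterpart. By construction
#' `FN = deletions + swap-outs` and `FP = insertions + swap-ins`.
#'
#' @param alignment a `seq_alignment` or list of them.
#' @return an `outcome_tally`: data.frame with one row per class and columns
#'   `class`, `gt_count`, `tp`, `deletion`, `swap_out`, `insertion`,
#'   `swap_in`, `fn`, `fp`, plus a `substitutions` 5 x 5 count matrix
#'   attribute (rows ground truth, columns predicted).
#' @export
classify_outcomes <- function(alignment) {
  if (inherits(alignment, "seq_alignment")) alignment <- list(alignment)
  ops <- do.call(rbind, lapply(alignment, `[[`, "ops"))
  tal <- data.frame(class = PRIMITIVE_CLASSES, gt_count = 0L, tp = 0L,
                    deletion = 0L, swap_out = 0L, insertion = 0L, swap_in = 0L,
                    stringsAsFactors = FALSE)
  subm <- matrix(0L, 5L, 5L, dimnames = list(PRIMITIVE_CLASSES, PRIMITIVE_CLASSES))
  if (!is.null(ops) && nrow(ops)) {
    cnt <- function(cls, sel) as.integer(tabulate(cls[sel], nbins = 5L))
    tal$tp <- cnt(ops$gt, ops$op == "match")
    tal$deletion <- cnt(ops$gt, ops$op == "deletion")
    tal$swap_out <- cnt(ops$gt, ops$op == "substitution")
    tal$insertion <- cnt(ops$pred, ops$op == "insertion")
    tal$swap_in <- cnt(ops$pred, ops$op == "substitution")
    tal$gt_count <- cnt(ops$gt, !is.na(ops$gt))
    sub <- ops[ops$op == "substitution", , drop = FALSE]
    if (nrow(sub)) {
      for (r in seq_len(nrow(sub))) subm[sub$gt[r], sub$pred[r]] <- subm[sub$gt[r], sub$pred[r]] + 1L
    }
  }
  tal$fn <- tal$deletion + tal$swap_out
  tal$fp <- tal$insertion + tal$swap_in
  structure(tal, substitutions = subm, class = c("outcome_tally", "data.frame"))
}

#' Classification metrics over primitive predictions
#'
#' `sensitivity()` is the proportion of ground-truth primitives correctly
#' predicted, `TP / (TP + FN)`. `fdr()` is the proportion of predicted
#' primitives that are spurious, `FP / (TP + FP)` — the overcount measure.
#' `f1()` is the harmonic mean of sensitivity and precision (`1 - FDR`),
#' `2 s (1 - f) / (s + (1 - f))`, which on consistent tallies equals
#' `2 TP / (2 TP + FN + FP)`. `aer()` is the Action Error Rate: the minimal
#' number of edits turning the prediction into the ground truth, normalized
#' by ground-truth length (it may exceed 1). Undefined cases (empty
#' denominators) return `NA`.
#'
#' @param tp,fn,fp non-negative tallies.
#' @param sens,fdr values in `[0, 1]`.
#' @param gt,pred primitive sequences (for `aer`).
#' @return a numeric scalar.
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn <= 0) return(NA_real_)
  tp / (tp + fn)
}

#' @rdname sensitivity
#' @export
fdr <- function(tp, fp) {
  if (tp + fp <= 0) return(NA_real_)
  fp / (tp + fp)
}

#' @rdname sensitivity
#' @export
f1 <- function(sens, fdr) {
  prec <- 1 - fdr
  if (is.na(sens) || is.na(prec) || sens + prec <= 0) return(NA_real_)
  2 * sens * prec / (sens + prec)
}

#' @rdname sensitivity
#' @export
aer <- function(gt, pred) {
  gt <- class_to_code(gt); pred <- class_to_code(pred)
  if (length(gt) == 0L) return(NA_real_)
  align_sequences(gt, pred)$distance / length(gt)
}

#' Aggregate metrics report from alignments
#'
#' Aggregates per-trial alignments into overall and per-class tallies,
#' sensitivity, FDR, F1, mean AER and the normalized confusion matrix.
#'
#' @param alignments list of `seq_alignment` (one per trial).
#' @return a `metrics_report` list: `overall` (tp/fn/fp, sensitivity, fdr,
#'   f1, aer), `per_class` (an `outcome_tally` with added frequency and
#'   metric columns) and `confusion` (see [confusion_matrix()]).
#' @export
metrics_report <- function(alignments) {
  if (inherits(alignments, "seq_alignment")) alignments <- list(alignments)
  tal <- classify_outcomes(alignments)
  tp <- sum(tal$tp); fn <- sum(tal$fn); fp <- sum(tal$fp)
  s <- sensitivity(tp, fn); f <- fdr(tp, fp)
  aers <- vapply(alignments, function(a)
    if (a$n_gt > 0L) a$distance / a$n_gt else NA_real_, 0)
  per_class <- tal
  per_class$sensitivity <- ifelse(tal$tp + tal$fn > 0, tal$tp / (tal$tp + tal$fn), NA)
  per_class$fdr <- ifelse(tal$tp + tal$fp > 0, tal$fp / (tal$tp + tal$fp), NA)
  gt <- pmax(tal$gt_count, 1L)
  per_class$deletion_freq <- ifelse(tal$gt_count > 0, tal$deletion / gt, NA)
  per_class$swap_out_freq <- ifelse(tal$gt_count > 0, tal$swap_out / gt, NA)
  per_class$insertion_freq <- ifelse(tal$gt_count > 0, tal$insertion / gt, NA)
  per_class$swap_in_freq <- ifelse(tal$gt_count > 0, tal$swap_in / gt, NA)
  structure(list(
    overall = list(tp = tp, fn = fn, fp = fp, sensitivity = s, fdr = f,
                   f1 = f1(s, f), aer = mean(aers, na.rm = TRUE)),
    per_class = per_class,
    confusion = confusion_matrix(alignments)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<metrics_report> TP %d FN %d FP %d | sensitivity %.3f, FDR %.3f, F1 %.3f, AER %.3f\n",
              o$tp, o$fn, o$fp, o$sensitivity, o$fdr, o$f1, o$aer))
  invisible(x)
}

#' Normalized confusion matrix with deletion and insertion margins
#'
#' Rows are ground-truth classes, columns predicted classes; entries are
#' normalized by the ground-truth count of the row class, so the diagonal is
#' the per-class sensitivity and each row (diagonal, off-diagonal swap-outs,
#' deletion margin) sums to 1. The insertion margin (predicted primitives
#' with no ground-truth counterpart, normalized by the ground-truth count of
#' the predicted class) is reported as an extra row and is not part of the
#' row-sum identity. Classes absent from the ground truth yield `NA` rows.
#'
#' @param alignments list of `seq_alignment`.
#' @return a 6 x 6 numeric matrix: 5 class rows plus `insertion` row; 5
#'   class columns plus `deletion` column.
#' @export
confusion_matrix <- function(alignments) {
  tal <- classify_outcomes(alignments)
  subm <- attr(tal, "substitutions")
  out <- matrix(NA_real_, 6L, 6L,
                dimnames = list(c(PRIMITIVE_CLASSES, "insertion"),
                                c(PRIMITIVE_CLASSES, "deletion")))
  for (r in 1:5) {
    gtc <- tal$gt_count[r]
    if (gtc > 0L) {
      out[r, 1:5] <- subm[r, ] / gtc
      out[r, r] <- tal$tp[r] / gtc
      out[r, 6L] <- tal$deletion[r] / gtc
    }
  }
  out[6L, 1:5] <- ifelse(tal$gt_count > 0, tal$insertion / tal$gt_count, NA)
  out
}

#' Bootstrap comparison of model classification performance
#'
#' Compares models from their per-trial prediction outcomes on a common set
#' of trials. Each replicate subsamples `subsample` trials with replacement
#' (the same trials for every model), aggregates the tallies and computes
#' sensitivity, FDR and F1 per model. The first model is the reference; each
#' rival is compared with unpaired two-tailed equal-variance t-tests on the
#' replicate distributions (degrees of freedom `2 n_replicates - 2`) with
#' Bonferroni correction over the number of rivals.
#'
#' @param per_trial list of data.frames, one per model (named), each with
#'   columns `trial`, `tp`, `fn`, `fp` over the same trials.
#' @param n_replicates number of bootstrap sets (default 250).
#' @param subsample trials drawn per set with replacement (default 81).
#' @return a `bootstrap_result`: `replicates` (long data.frame of per-model,
#'   per-replicate metrics), `df` (t-test degrees of freedom) and `tests`
#'   (data.frame with model, metric, t, p, p_bonferroni, mean difference).
#' @export
bootstrap_compare <- function(per_trial, n_replicates = 250L, subsample = 81L) {
  if (length(per_trial) < 2L) stop("bootstrap comparison needs at least 2 models")
  if (is.null(names(per_trial)) || any(names(per_trial) == "")) {
    names(per_trial) <- paste0("model", seq_along(per_trial))
  }
  ref_trials <- sort(per_trial[[1L]]$trial)
  for (m in per_trial) {
    if (!identical(sort(m$trial), ref_trials)) stop("models must share the same trial set")
  }
  per_trial <- lapply(per_trial, function(m) m[order(m$trial), , drop = FALSE])
  n_trials <- length(ref_trials)
  models <- names(per_trial)

  mets <- array(NA_real_, c(n_replicates, length(models), 3L),
                dimnames = list(NULL, models, c("sensitivity", "fdr", "f1")))
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(n_trials, subsample, replace = TRUE)
    for (mi in seq_along(models)) {
      t <- per_trial[[mi]][idx, , drop = FALSE]
      s <- sensitivity(sum(t$tp), sum(t$fn)); f <- fdr(sum(t$tp), sum(t$fp))
      mets[b, mi, ] <- c(s, f, f1(s, f))
    }
  }
  df <- 2L * n_replicates - 2L
  tests <- list()
  for (mi in seq_along(models)[-1L]) {
    for (metric in dimnames(mets)[[3L]]) {
      a <- mets[, 1L, metric]; bvals <- mets[, mi, metric]
      tt <- stats::t.test(a, bvals, var.equal = TRUE)
      tests[[length(tests) + 1L]] <- data.frame(
        reference = models[1L], model = models[mi], metric = metric,
        mean_reference = mean(a), mean_model = mean(bvals),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_bonferroni <- pmin(1, tests$p * (length(models) - 1L))
  reps <- do.call(rbind, lapply(models, function(m) data.frame(
    model = m, replicate = seq_len(n_replicates),
    sensitivity = mets[, m, "sensitivity"], fdr = mets[, m, "fdr"],
    f1 = mets[, m, "f1"], stringsAsFactors = FALSE)))
  structure(list(replicates = reps, df = df, tests = tests,
                 n_replicates = n_replicates, subsample = subsample),
            class = "bootstrap_result")
}

#' Per-trial prediction outcomes for bootstrap comparison
#'
#' @param gt_seqs,pred_seqs lists of primitive sequences, aligned per trial.
#' @param trial_ids optional trial identifiers.
#' @return data.frame with columns `trial`, `tp`, `fn`, `fp`.
#' @export
per_trial_outcomes <- function(gt_seqs, pred_seqs, trial_ids = seq_along(gt_seqs)) {
  stopifnot(length(gt_seqs) == length(pred_seqs))
  rows <- lapply(seq_along(gt_seqs), function(i) {
    tal <- classify_outcomes(align_sequences(gt_seqs[[i]], pred_seqs[[i]]))
    data.frame(trial = trial_ids[i], tp = sum(tal$tp), fn = sum(tal$fn),
               fp = sum(tal$fp), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
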