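#' Per-channel statistical features
#'
#' Five statistics per channel — mean, maximum, minimum, standard deviation
#' and root mean square — concatenated in channel order (population
#' convention for sd and RMS, so `RMS^2 = mean^2 + sd^2`).
#'
#' @param window numeric matrix (samples x channels), non-empty.
#' @return numeric vector of length `5 * ncol(window)` in channel-major
#'   order (`mean, max, min, sd, rms` per channel).
#' @export
extract_features <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) == 0L) stop("empty feature window")
  n <- nrow(window)
  mu <- colMeans(window)
  mx <- apply(window, 2L, max)
  mn <- apply(window, 2L, min)
  msq <- colMeans(window^2)
  sdv <- sqrt(pmax(0, msq - mu^2))
  rms <- sqrt(msq)
  as.vector(rbind(mu, mx, mn, sdv, rms))
}

# features for every stride-spaced center of a recording: one row per
# prediction step, on a centered sub-window clipped at the edges
pointwise_features <- function(samples, sub_window_s = 1, stride_s = 0.1,
                               sample_rate = 100) {
  n <- nrow(samples)
  half <- as.integer(round(sub_window_s * sample_rate / 2))
  step <- max(1L, as.integer(round(stride_s * sample_rate)))
  centers <- seq.int(1L, n, by = step)
  feats <- t(vapply(centers, function(c) {
    lo <- max(1L, c - half); hi <- min(n, c + half)
    extract_features(samples[lo:hi, , drop = FALSE])
  }, numeric(5L * ncol(samples))))
  list(features = feats, centers = centers, step = step, n = n)
}

#' Train a pointwise random-forest primitive classifier
#'
#' A probability random forest over per-channel statistical features of
#' sliding sub-windows (default 1 s, stride 0.1 s) centered on each
#' prediction step; it emits a class-probability vector per step, which is
#' repeated to the 10-ms sample grid.
#'
#' @param trials list of training trials (`recording`, `labels`).
#' @param stats [channel_stats()] used to normalize inputs.
#' @param n_trees number of trees.
#' @param sub_window_s,stride_s feature sub-window length and stride (s).
#' @param seed RNG seed for the forest.
#' @return an `rf_pointwise` model.
#' @export
train_pointwise_rf <- function(trials, stats, n_trees = 100L, sub_window_s = 1,
                               stride_s = 0.1, seed = 1L) {
  X <- list(); y <- list()
  for (t in trials) {
    recn <- zscore_normalize(t$recording, stats)
    pf <- pointwise_features(recn$samples, sub_window_s, stride_s, recn$sample_rate)
    X[[length(X) + 1L]] <- pf$features
    y[[length(y) + 1L]] <- t$labels[pf$centers]
  }
  X <- do.call(rbind, X)
  y <- unlist(y)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.class <- factor(y, levels = 1:5)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = n_trees, probability = TRUE,
                        seed = seed, num.threads = 1L)
  structure(list(fit = fit, stats = stats, sub_window_s = sub_window_s,
                 stride_s = stride_s), class = "rf_pointwise")
}

#' Pointwise class probabilities for a recording
#'
#' @param model an `rf_pointwise` model.
#' @param rec an unnormalized [imu_recording()].
#' @return numeric matrix, one row per 10-ms sample, five columns of class
#'   probabilities summing to 1.
#' @export
predict_pointwise <- function(model, rec) {
  recn <- zscore_normalize(rec, model$stats)
  pf <- pointwise_features(recn$samples, model$sub_window_s, model$stride_s,
                           recn$sample_rate)
  df <- as.data.frame(pf$features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  pr <- stats::predict(model$fit, data = df, num.threads = 1L)$predictions
  out <- matrix(0, nrow(pr), 5L)
  out[, as.integer(colnames(pr))] <- pr
  # nearest-center upsampling from the stride grid to the sample grid
  idx <- pmin(length(pf$centers),
              pmax(1L, round((seq_len(pf$n) - 1L) / pf$step) + 1L))
  full <- out[idx, , drop = FALSE]
  colnames(full) <- PRIMITIVE_CLASSES
  full
}

# Kaiser shape parameter from relative sidelobe attenuation (dB), the
# standard window-design relation
kaiser_beta <- function(atten_db) {
  if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  else 0
}

#' Kaiser-window smoothing of pointwise predictions
#'
#' Weighted running average of each class-probability track with a
#' normalized Kaiser window (weights sum to 1); edges use reflection
#' padding, and the smoothed probability vectors are renormalized to sum
#' to 1. Window size 1 is the identity.
#'
#' @param probs matrix of per-sample class probabilities.
#' @param window_size odd kernel length in samples.
#' @param atten_db relative sidelobe attenuation in dB (sets the Kaiser
#'   shape parameter).
#' @return smoothed probability matrix of the same shape.
#' @export
kaiser_smooth <- function(probs, window_size, atten_db = 50) {
  window_size <- as.integer(window_size)
  if (window_size < 1L || window_size %% 2L == 0L) {
    stop("window_size must be an odd positive integer")
  }
  if (window_size == 1L) return(probs)
  n <- nrow(probs)
  kern <- signal::kaiser(window_size, kaiser_beta(atten_db))
  kern <- kern / sum(kern)
  half <- (window_size - 1L) %/% 2L
  pad_top <- probs[pmin(n, (half + 1L):2L), , drop = FALSE]
  pad_bot <- probs[pmax(1L, (n - 1L):(n - half)), , drop = FALSE]
  xp <- rbind(pad_top, probs, pad_bot)
  sm <- apply(xp, 2L, function(col) {
    y <- stats::filter(col, kern, method = "convolution", sides = 2L)
    y[(half + 1L):(half + n)]
  })
  sm <- pmax(sm, 0)
  sm / rowSums(sm)
}

#' Convert smoothed pointwise predictions to a primitive sequence
#'
#' Per-sample argmax followed by run-length collapse over the half-open
#' region `[start, end)`.
#'
#' @param probs per-sample class-probability matrix.
#' @param start,end 0-based sample region (defaults: whole track).
#' @return integer class-code sequence.
#' @export
pointwise_to_sequence <- function(probs, start = 0L, end = nrow(probs)) {
  cls <- max.col(probs, ties.method = "first")
  collapse_to_sequence(cls, start, end)
}

#' Select Kaiser smoother parameters on validation data
#'
#' Grid search over window sizes and sidelobe attenuations maximizing
#' sequence-level validation F1 (per-trial Levenshtein alignment of the
#' smoothed, collapsed predictions against ground truth). Ties are broken
#' toward the smallest window, then the smallest attenuation.
#'
#' @param probs_by_trial list of pointwise probability matrices.
#' @param gt_seqs list of ground-truth primitive sequences, one per trial.
#' @param window_grid,atten_grid candidate window sizes (odd) and
#'   attenuations (dB).
#' @return list with `window_size`, `atten_db` and the search `grid`
#'   data.frame (with validation `f1` per candidate).
#' @export
select_smoother <- function(probs_by_trial, gt_seqs,
                            window_grid = c(1L, 5L, 11L, 21L, 41L, 81L),
                            atten_grid = c(30, 50, 70)) {
  grid <- expand.grid(window_size = sort(window_grid), atten_db = sort(atten_grid))
  grid <- grid[order(grid$window_size, grid$atten_db), , drop = FALSE]
  grid$f1 <- vapply(seq_len(nrow(grid)), function(g) {
    tp <- fn <- fp <- 0L
    for (i in seq_along(probs_by_trial)) {
      sm <- kaiser_smooth(probs_by_trial[[i]], grid$window_size[g], grid$atten_db[g])
      tal <- classify_outcomes(align_sequences(gt_seqs[[i]], pointwise_to_sequence(sm)))
      tp <- tp + sum(tal$tp); fn <- fn + sum(tal$fn); fp <- fp + sum(tal$fp)
    }
    s <- sensitivity(tp, fn); f <- fdr(tp, fp)
    v <- f1(s, f)
    if (is.na(v)) -Inf else v
  }, 0)
  best <- which.max(grid$f1)  # first maximum = smallest window, attenuation
  list(window_size = grid$window_size[best], atten_db = grid$atten_db[best],
       grid = grid)
}

#' Random-forest baseline trial predictions
#'
#' Full baseline path for one recording: pointwise probabilities, Kaiser
#' smoothing, then per-core argmax-collapse at the 4-s test partition so the
#' baseline is evaluated through exactly the same windowed-sequence and
#' counting machinery as the sequence model.
#'
#' @param model an `rf_pointwise` model.
#' @param rec an [imu_recording()].
#' @param window_size,atten_db smoother parameters (from [select_smoother()]).
#' @param core_s test core length in seconds.
#' @return list of integer sequences, one per 4-s core.
#' @export
rf_predict_sequences <- function(model, rec, window_size, atten_db, core_s = 4) {
  probs <- predict_pointwise(model, rec)
  sm <- kaiser_smooth(probs, window_size, atten_db)
  n <- nrow(sm)
  clen <- as.integer(round(core_s * rec$sample_rate))
  starts <- seq.int(0L, max(0L, ceiling(n / clen) - 1L) * clen, by = clen)
  lapply(starts, function(cs) pointwise_to_sequence(sm, cs, min(cs + clen, n)))
}
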