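# Adam optimizer state over a named list of parameter matrices
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(clip_norm) && gn > clip_norm) {
    grads <- lapply(grads, function(g) g * (clip_norm / gn))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# validation metrics of greedy decoding against window targets: mean AER over
# windows plus aggregate sensitivity/FDR from per-window alignments
validate_windows <- function(params, config, windows, chunk = 256L) {
  model <- structure(list(params = params, config = config), class = "seq2seq_model")
  tp <- fn <- fp <- 0L
  aers <- numeric(0)
  for (start in seq.int(1L, length(windows), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(windows))
    ws <- windows[idx]
    feats <- encode_windows(model, ws)
    preds <- decode_greedy(list(model), list(feats), config$max_decode_len)
    for (i in seq_along(ws)) {
      gt <- ws[[i]]$target
      al <- align_sequences(gt, preds[[i]])
      tal <- classify_outcomes(al)
      tp <- tp + sum(tal$tp); fn <- fn + sum(tal$fn); fp <- fp + sum(tal$fp)
      if (length(gt) > 0L) aers <- c(aers, al$distance / length(gt))
    }
  }
  list(aer = mean(aers), sensitivity = sensitivity(tp, fn), fdr = fdr(tp, fp))
}

#' Train the GRU encoder-decoder on labeled windows
#'
#' Minimizes teacher-forced token cross-entropy (PAD positions masked, EOS
#' appended to every target) with Adam at the configured learning rate.
#' After every epoch the model greedily decodes the validation windows and
#' logs validation AER, sensitivity and FDR. Checkpoint selection prioritizes
#' the overcounting constraint: among epochs with validation FDR below
#' `fdr_ceiling` the maximum-sensitivity epoch is kept; if no epoch
#' qualifies, the minimum-AER epoch is kept. Training stops once `patience`
#' epochs pass without the selected checkpoint improving.
#'
#' @param train_windows,val_windows lists of windows from [make_windows()]
#'   (normalized data, non-`NULL` targets), from disjoint subjects.
#' @param config a [seq2seq_config()].
#' @param stats the [channel_stats()] used to normalize the windows; stored
#'   with the model for prediction-time preprocessing.
#' @param verbose print per-epoch progress.
#' @return a `seq2seq_model`: list with `params` (selected checkpoint),
#'   `config`, `stats` and `history` (per-epoch data.frame with `epoch`,
#'   `loss`, `val_aer`, `val_sensitivity`, `val_fdr`, `selected`).
#' @export
train_seq2seq <- function(train_windows, val_windows, config = seq2seq_config(),
                          stats = NULL, verbose = FALSE) {
  if (length(train_windows) == 0L) stop("empty training window set")
  for (w in train_windows) {
    if (is.null(w$target)) stop("training windows must carry target sequences")
  }
  set.seed(config$seed)
  params <- init_params(config)
  opt <- adam_init(params)
  n <- length(train_windows)
  bs <- min(config$batch_size, n)

  # inverse-frequency class weights counter the idle-heavy token distribution
  # (rare classes would otherwise lose ambiguous calls to frequent ones);
  # clipped so no class dominates, reserved tokens at weight 1
  tok_w <- rep(1, config$vocab)
  if (isTRUE(config$class_weighting)) {
    cnt <- tabulate(unlist(lapply(train_windows, `[[`, "target")), nbins = N_CLASSES)
    wc <- mean(cnt[cnt > 0]) / pmax(cnt, 1L)
    tok_w[seq_len(N_CLASSES)] <- pmin(pmax(wc, 0.5), 2.5)
  }

  best <- list(params = params, qualifies = FALSE, sens = -Inf, aer = Inf, epoch = 0L)
  history <- list()
  epochs_since_best <- 0L

  lr_decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
  for (epoch in seq_len(config$max_epochs)) {
    cur_lr <- config$lr * lr_decay^(epoch - 1L)
    ord <- sample.int(n)
    total_loss <- 0; total_tok <- 0
    for (start in seq.int(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      ws <- train_windows[idx]
      toks <- decoder_teacher_tokens(lapply(ws, `[[`, "target"), config$max_decode_len)
      cube <- windows_to_cube(ws, config$time_stride)
      if (config$input_noise_sd > 0) {
        # training-only jitter on the normalized channels: regularizes against
        # overfitting the finite window set (validation/test inputs are clean)
        cube <- cube + array(stats::rnorm(length(cube), sd = config$input_noise_sd),
                             dim(cube))
      }
      res <- cpp_seq2seq_loss_grad(params, cube,
                                   toks$dec_in - 1L, toks$dec_tgt - 1L,
                                   config$enc_layers, TOK_PAD - 1L, TRUE, tok_w)
      upd <- adam_step(params, res$grads, opt, cur_lr)
      params <- upd$params; opt <- upd$state
      total_loss <- total_loss + res$loss * res$n_tokens
      total_tok <- total_tok + res$n_tokens
    }
    val <- if (length(val_windows)) {
      validate_windows(params, config, val_windows)
    } else list(aer = NA_real_, sensitivity = NA_real_, fdr = NA_real_)

    qualifies <- !is.na(val$fdr) && val$fdr < config$fdr_ceiling
    is_best <- if (qualifies) {
      !best$qualifies || (!is.na(val$sensitivity) && val$sensitivity > best$sens)
    } else {
      !best$qualifies && !is.na(val$aer) && val$aer < best$aer
    }
    if (length(val_windows) == 0L) is_best <- TRUE  # no validation: keep latest
    if (is_best) {
      best <- list(params = params, qualifies = qualifies,
                   sens = if (is.na(val$sensitivity)) -Inf else val$sensitivity,
                   aer = if (is.na(val$aer)) Inf else val$aer, epoch = epoch)
      epochs_since_best <- 0L
    } else {
      epochs_since_best <- epochs_since_best + 1L
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, loss = total_loss / max(total_tok, 1),
      val_aer = val$aer, val_sensitivity = val$sensitivity, val_fdr = val$fdr,
      selected = is_best)
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  val AER %.3f  sens %.3f  FDR %.3f%s",
                      epoch, total_loss / max(total_tok, 1), val$aer,
                      val$sensitivity, val$fdr, if (is_best) "  *" else ""))
    }
    if (epochs_since_best >= config$patience) break
  }
  structure(list(params = best$params, config = config, stats = stats,
                 history = do.call(rbind, history), best_epoch = best$epoch),
            class = "seq2seq_model")
}

# windows (normalized, with targets) for a set of trials at a given slide
trials_to_windows <- function(trials, stats, config, slide_s,
                              drop_partial_cores = slide_s < config$core_s) {
  out <- list()
  for (t in trials) {
    recn <- zscore_normalize(t$recording, stats)
    w <- make_windows(recn, labels = t$labels, window_s = config$window_s,
                      core_s = config$core_s, slide_s = slide_s,
                      drop_partial_cores = drop_partial_cores,
                      target_min_overlap_s = config$target_min_overlap_s)
    out <- c(out, w)
  }
  out
}

#' Cross-validated ensemble training
#'
#' Splits the training subjects into `k` folds by seeded rotation; each fold
#' trains one model on the other folds' subjects (about 75/25 train/val for
#' `k = 4`) and validates on its own. The `k` selected checkpoints form the
#' ensemble whose step-wise averaged probabilities drive prediction.
#' Channel statistics are estimated once on all training-split recordings
#' (never on test data) and shared by the members so ensemble members see
#' identical inputs.
#'
#' @param trials list of training trials, each with `recording`, `labels`
#'   and `subject`.
#' @param k number of folds / ensemble members (default 4).
#' @param config a [seq2seq_config()].
#' @param verbose print per-epoch progress.
#' @return a `seq2seq_ensemble`: list with `models`, `stats`, `folds`
#'   (data.frame of subject fold assignments) and `config`.
#' @export
cross_validated_train <- function(trials, k = 4L, config = seq2seq_config(),
                                  verbose = FALSE) {
  if (k < 2L) stop("k must be at least 2")
  subjects <- unique(vapply(trials, `[[`, "", "subject"))
  if (length(subjects) < k) stop("need at least k subjects for k folds")
  set.seed(config$seed)
  shuffled <- sample(subjects)
  fold_of <- sort(rep(seq_len(k), length.out = length(shuffled)))
  names(fold_of) <- shuffled
  stats <- channel_stats(lapply(trials, `[[`, "recording"))

  models <- vector("list", k)
  for (fold in seq_len(k)) {
    val_subj <- names(fold_of)[fold_of == fold]
    tr_trials <- Filter(function(t) !(t$subject %in% val_subj), trials)
    va_trials <- Filter(function(t) t$subject %in% val_subj, trials)
    cfg <- config
    cfg$seed <- config$seed + fold
    tw <- trials_to_windows(tr_trials, stats, cfg, cfg$train_slide_s)
    vw <- trials_to_windows(va_trials, stats, cfg, cfg$val_slide_s)
    if (verbose) message("fold ", fold, ": ", length(tw), " train windows, ",
                         length(vw), " val windows (val subjects: ",
                         paste(val_subj, collapse = ", "), ")")
    models[[fold]] <- train_seq2seq(tw, vw, cfg, stats = stats, verbose = verbose)
    rm(tw, vw); gc(verbose = FALSE)
  }
  folds <- data.frame(subject = names(fold_of), fold = unname(fold_of),
                      stringsAsFactors = FALSE)
  structure(list(models = models, stats = stats, folds = folds, config = config),
            class = "seq2seq_ensemble")
}
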