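#' Sequence model configuration
#'
#' Architecture and optimization settings for the GRU encoder-decoder. The
#' encoder is a 3-layer bidirectional GRU of width `hidden` per direction;
#' the decoder is a single-layer GRU whose width is `2 * hidden`, matching
#' the concatenated final forward/backward encoder states that form the
#' feature vector and the decoder's initial state. The reference full-scale
#' configuration uses `hidden = 3072` (decoder 6144) with learning rate
#' 5e-4; the desk-scale defaults (`hidden = 64`, `lr = 5e-3`) were selected
#' on validation Action Error Rate. Training uses teacher-forced
#' cross-entropy (optionally inverse-frequency class-weighted) with Adam,
#' 6-s windows with 4-s cores, a 0.5-s training slide
#' and a 4-s test slide. Early stopping selects, among epoch checkpoints
#' with validation FDR below `fdr_ceiling`, the one with maximum validation
#' sensitivity (overcounting mistrains patients, so FDR is constrained
#' first); if no epoch qualifies, the minimum-AER epoch is used.
#'
#' @param hidden encoder hidden width per direction.
#' @param ... overrides of the remaining fields: `enc_layers`, `lr`,
#'   `batch_size`, `max_epochs`, `patience`, `window_s`, `core_s`,
#'   `train_slide_s`, `val_slide_s`, `test_slide_s`, `max_decode_len`,
#'   `fdr_ceiling`, `sample_rate`, `seed`; plus the desk-scale training
#'   choices `time_stride` (encoder input subsampling: 5 gives a 20-Hz
#'   effective rate, 1 restores full resolution), `target_min_overlap_s`
#'   (drop sub-threshold boundary slivers from training targets),
#'   `lr_decay` (per-epoch multiplicative learning-rate decay; 1 disables),
#'   `input_noise_sd` (training-only Gaussian jitter on the normalized
#'   channels, a regularizer; 0 disables) and `class_weighting`
#'   (inverse-frequency token weights in the loss, clipped to `[0.5, 2.5]`,
#'   so rare classes do not lose ambiguous calls to frequent ones).
#' @return a `seq2seq_config` list.
#' @export
seq2seq_config <- function(hidden = 64L, ...) {
  cfg <- list(hidden = as.integer(hidden), enc_layers = 3L, n_channels = N_CHANNELS,
              vocab = VOCAB_SIZE, time_stride = 5L, lr = 5e-3, lr_decay = 0.93,
              batch_size = 32L, max_epochs = 20L,
              patience = 6L, window_s = 6, core_s = 4, train_slide_s = 0.5,
              val_slide_s = 2, test_slide_s = 4, max_decode_len = 13L,
              fdr_ceiling = 0.2, target_min_overlap_s = 0.15,
              input_noise_sd = 0, class_weighting = FALSE,
              sample_rate = 100, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown seq2seq_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$hidden <= 0L) stop("hidden width must be positive")
  if (cfg$core_s > cfg$window_s) stop("core_s must not exceed window_s")
  structure(cfg, class = "seq2seq_config")
}

# parameter initialization: uniform(-k, k) with k = 1/sqrt(fan-in-side width),
# the customary recurrent-layer scheme
init_params <- function(config) {
  H <- config$hidden; D <- 2L * H; V <- config$vocab
  k_enc <- 1 / sqrt(H); k_dec <- 1 / sqrt(D)
  u <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  p <- list()
  for (l in seq_len(config$enc_layers)) {
    n_in <- if (l == 1L) config$n_channels else D
    for (d in c("f", "b")) {
      p[[sprintf("enc_W_%d_%s", l, d)]] <- u(n_in, 3L * H, k_enc)
      p[[sprintf("enc_U_%d_%s", l, d)]] <- u(H, 3L * H, k_enc)
      p[[sprintf("enc_b_%d_%s", l, d)]] <- matrix(stats::runif(3L * H, -k_enc, k_enc), 1L)
    }
  }
  # decoder input = one-hot previous token + the 2H feature vector, which
  # conditions every decode step (not only the initial hidden state)
  p$dec_W <- u(V + D, 3L * D, k_dec)
  p$dec_U <- u(D, 3L * D, k_dec)
  p$dec_b <- matrix(stats::runif(3L * D, -k_dec, k_dec), 1L)
  p$out_W <- u(D, V, k_dec)
  p$out_b <- matrix(0, 1L, V)
  p
}

# stack a list of windows into the (batch x channels x time) cube the
# compiled core consumes; time_stride subsamples the window before the
# recurrence (primitive durations are >= 0.3 s, so a 20-50 Hz effective rate
# keeps the kinematic signal while shortening backpropagation through time)
windows_to_cube <- function(windows, time_stride = 1L) {
  B <- length(windows)
  keep <- seq.int(max(1L, (time_stride + 1L) %/% 2L),
                  nrow(windows[[1L]]$data), by = time_stride)
  C <- ncol(windows[[1L]]$data)
  arr <- array(0, c(B, C, length(keep)))
  for (b in seq_len(B)) arr[b, , ] <- t(windows[[b]]$data[keep, , drop = FALSE])
  arr
}

# teacher-forcing token matrices: decoder input (SOS + target) and target
# (target + EOS), PAD-filled to the longest target in the batch
decoder_teacher_tokens <- function(targets, max_decode_len) {
  targets <- lapply(targets, function(t) t[seq_len(min(length(t), max_decode_len - 1L))])
  L <- max(vapply(targets, length, 0L)) + 1L
  B <- length(targets)
  dec_in <- matrix(TOK_PAD, B, L)
  dec_tgt <- matrix(TOK_PAD, B, L)
  for (b in seq_len(B)) {
    tg <- targets[[b]]
    dec_in[b, seq_len(length(tg) + 1L)] <- c(TOK_SOS, tg)
    dec_tgt[b, seq_len(length(tg) + 1L)] <- c(tg, TOK_EOS)
  }
  list(dec_in = dec_in, dec_tgt = dec_tgt)
}

#' Encode windows into feature vectors
#'
#' Runs the bidirectional encoder stack over a batch of normalized windows
#' and returns one feature vector per window: the concatenation of the final
#' forward and final backward top-layer states (length `2 * hidden`).
#'
#' @param model a `seq2seq_model` (see [train_seq2seq()]).
#' @param windows list of windows from [make_windows()], each with exactly
#'   `window_s * sample_rate` rows.
#' @return numeric matrix, one row per window, `2 * hidden` columns.
#' @export
encode_windows <- function(model, windows) {
  wlen <- as.integer(round(model$config$window_s * model$config$sample_rate))
  for (w in windows) {
    if (nrow(w$data) != wlen) {
      stop("window has ", nrow(w$data), " rows; encoder requires ", wlen)
    }
  }
  cpp_encode(model$params, windows_to_cube(windows, model$config$time_stride),
             model$config$enc_layers)
}

#' Greedy ensemble decoding with token feedback
#'
#' Decodes feature vectors autoregressively. At each step the per-class
#' probability vectors of all ensemble members are averaged; the argmax
#' token is emitted (ties broken by fixed class order: reach, reposition,
#' transport, stabilization, idle) and fed back as the previous-token input
#' to every member's decoder at the next step. Decoding starts from the
#' start-of-sequence token and stops at end-of-sequence or `max_len`;
#' reserved tokens never appear in the returned sequences.
#'
#' @param models list of `seq2seq_model`s (one entry gives plain greedy
#'   decoding of that model).
#' @param feats list of feature matrices, one per model, same batch rows.
#' @param max_len maximum emitted tokens per window.
#' @return list of integer class-code sequences, one per batch row.
#' @export
decode_greedy <- function(models, feats, max_len) {
  B <- nrow(feats[[1L]])
  if (max_len <= 0L || B == 0L) return(rep(list(integer(0)), B))
  hs <- feats
  prev <- rep(TOK_SOS, B)
  emitted <- matrix(TOK_PAD, B, max_len)
  for (t in seq_len(max_len)) {
    probs <- 0
    for (m in seq_along(models)) {
      step <- cpp_decoder_step(models[[m]]$params, hs[[m]], as.integer(prev - 1L),
                               feats[[m]])
      probs <- probs + step$probs
      hs[[m]] <- step$h
    }
    probs <- probs / length(models)
    tok <- max.col(probs, ties.method = "first")
    emitted[, t] <- tok
    prev <- tok
  }
  lapply(seq_len(B), function(b) {
    s <- emitted[b, ]
    eos <- which(s == TOK_EOS)
    if (length(eos)) s <- s[seq_len(eos[1L] - 1L)]
    s[s <= N_CLASSES]
  })
}

#' Predict the primitive sequences of a recording
#'
#' Normalizes the recording with the model's stored training-split channel
#' statistics, tiles it into 6-s windows at the 4-s test slide (cores
#' partition the recording) and greedily decodes one primitive sequence per
#' core, in temporal order. Accepts a single trained model or an ensemble.
#'
#' @param model a `seq2seq_model` or `seq2seq_ensemble`.
#' @param rec an unnormalized [imu_recording()].
#' @return list of integer class-code sequences, one per core.
#' @export
predict_recording <- function(model, rec) {
  models <- if (inherits(model, "seq2seq_ensemble")) model$models else list(model)
  cfg <- models[[1L]]$config
  if (length(models) > 1L) {
    for (m in models[-1L]) {
      if (m$config$vocab != cfg$vocab || m$config$hidden != cfg$hidden ||
          m$config$window_s != cfg$window_s || m$config$core_s != cfg$core_s) {
        stop("ensemble members must share vocabulary and window geometry")
      }
    }
  }
  if (!isTRUE(all.equal(rec$sample_rate, cfg$sample_rate))) {
    stop("recording sample rate ", rec$sample_rate, " does not match model (",
         cfg$sample_rate, ")")
  }
  recn <- zscore_normalize(rec, model$stats)
  windows <- make_windows(recn, window_s = cfg$window_s, core_s = cfg$core_s,
                          slide_s = cfg$test_slide_s, drop_partial_cores = FALSE)
  if (length(windows) == 0L) return(list())
  feats <- lapply(models, encode_windows, windows = windows)
  decode_greedy(models, feats, cfg$max_decode_len)
}

#' @rdname predict_recording
#' @param recs list of recordings.
#' @return `predict_trials()` returns a list of per-recording lists of
#'   sequences.
#' @export
predict_trials <- function(model, recs) lapply(recs, function(r) predict_recording(model, r))

#' Save and load model checkpoints
#'
#' Checkpoints bundle parameters, configuration, normalization statistics
#' and training history with a format version; a reloaded checkpoint
#' reproduces predictions bit-identically.
#'
#' @param model a `seq2seq_model` or `seq2seq_ensemble`.
#' @param path checkpoint file path.
#' @return `load_model()` returns the restored object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seq2seq_model") || inherits(model, "seq2seq_ensemble"))
  obj <- list(format_version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported checkpoint format")
  }
  obj$model
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat(sprintf("<seq2seq_model> H = %d (decoder %d), %d encoder layers, %d epochs trained\n",
              x$config$hidden, 2L * x$config$hidden, x$config$enc_layers,
              if (is.null(x$history)) 0L else nrow(x$history)))
  invisible(x)
}

#' @export
print.seq2seq_ensemble <- function(x, ...) {
  cat(sprintf("<seq2seq_ensemble> %d members, H = %d\n",
              length(x$models), x$models[[1L]]$config$hidden))
  invisible(x)
}
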