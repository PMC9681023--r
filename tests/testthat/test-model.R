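# tiny-model fixtures: H = 4, 2 encoder layers, short windows
tiny_config <- function(...) {
  base <- list(hidden = 4L, enc_layers = 2L, time_stride = 1L,
               window_s = 0.4, core_s = 0.2, sample_rate = 100)
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(seq2seq_config, base)
}

tiny_params <- function(cfg, seed = 1) {
  set.seed(seed)
  imuseq:::init_params(cfg)
}

tiny_batch <- function(B, T, seed = 2) {
  set.seed(seed)
  array(rnorm(B * 77 * T, sd = 0.5), c(B, 77, T))
}

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()
  p <- tiny_params(cfg, seed = 5)
  X <- tiny_batch(2L, 8L, seed = 6)
  tk <- imuseq:::decoder_teacher_tokens(list(c(1L, 3L), 2L), cfg$max_decode_len)
  res <- imuseq:::cpp_seq2seq_loss_grad(p, X, tk$dec_in - 1L, tk$dec_tgt - 1L,
                                        cfg$enc_layers, 7L, TRUE)
  lossfn <- function(pp) imuseq:::cpp_seq2seq_loss_grad(
    pp, X, tk$dec_in - 1L, tk$dec_tgt - 1L, cfg$enc_layers, 7L, FALSE)$loss
  eps <- 1e-6
  set.seed(7)
  for (nm in names(p)) {
    g <- res$grads[[nm]]
    for (i in sample(length(p[[nm]]), min(4L, length(p[[nm]])))) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps; lp <- lossfn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; lm <- lossfn(pp)
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(fd - g[i]), 1e-4 * max(1, abs(fd)) + 1e-7)
    }
  }
})

test_that("teacher-forced loss equals a direct token cross-entropy summation", {
  cfg <- tiny_config()
  p <- tiny_params(cfg, seed = 8)
  X <- tiny_batch(3L, 6L, seed = 9)
  targets <- list(c(1L, 2L), c(4L), c(5L, 3L, 1L))
  tk <- imuseq:::decoder_teacher_tokens(targets, cfg$max_decode_len)
  res <- imuseq:::cpp_seq2seq_loss_grad(p, X, tk$dec_in - 1L, tk$dec_tgt - 1L,
                                        cfg$enc_layers, 7L, FALSE)

  # oracle: replay encoder + decoder step-by-step through the public step API
  model <- structure(list(params = p, config = cfg), class = "seq2seq_model")
  feat <- imuseq:::cpp_encode(p, X, cfg$enc_layers)
  h <- feat
  total <- 0; ntok <- 0
  for (t in seq_len(ncol(tk$dec_in))) {
    step <- imuseq:::cpp_decoder_step(p, h, as.integer(tk$dec_in[, t] - 1L), feat)
    h <- step$h
    for (b in 1:3) {
      tgt <- tk$dec_tgt[b, t]
      if (tgt != 8L) {  # PAD
        total <- total - log(step$probs[b, tgt])
        ntok <- ntok + 1
      }
    }
  }
  expect_equal(res$loss, total / ntok, tolerance = 1e-12)
  expect_equal(res$n_tokens, ntok)
})

test_that("encoding is deterministic, shape-correct and input-sensitive", {
  for (H in c(8L, 16L)) {
    cfg <- seq2seq_config(hidden = H, enc_layers = 2L, time_stride = 1L,
                          window_s = 0.3, core_s = 0.1)
    p <- tiny_params(cfg, seed = H)
    model <- structure(list(params = p, config = cfg), class = "seq2seq_model")
    mk <- function(data) list(data = data, core_start = 0L, core_end = 10L)
    zero <- mk(matrix(0, 30, 77))
    burst <- mk(matrix(rnorm(30 * 77), 30, 77))
    f <- encode_windows(model, list(zero, burst, burst))
    expect_equal(dim(f), c(3L, 2L * H))
    expect_identical(f[2, ], f[3, ])            # determinism
    expect_gt(max(abs(f[1, ] - f[2, ])), 0)     # non-constancy
    expect_error(encode_windows(model, list(mk(matrix(0, 10, 77)))), "rows")
  }
})

test_that("decoder probabilities are normalized and decoding respects the vocabulary", {
  cfg <- tiny_config()
  p <- tiny_params(cfg, seed = 11)
  model <- structure(list(params = p, config = cfg), class = "seq2seq_model")
  X <- tiny_batch(4L, 40L, seed = 12)
  feat <- imuseq:::cpp_encode(p, X, cfg$enc_layers)
  step <- imuseq:::cpp_decoder_step(p, feat, rep(5L, 4L), feat)
  expect_equal(rowSums(step$probs), rep(1, 4), tolerance = 1e-6)

  seqs <- decode_greedy(list(model), list(feat), max_len = 12L)
  for (s in seqs) expect_true(all(s %in% 1:5))
  expect_identical(decode_greedy(list(model), list(feat), 0L),
                   rep(list(integer(0)), 4))
  # greedy decoding is deterministic
  expect_identical(seqs, decode_greedy(list(model), list(feat), 12L))
})

test_that("an ensemble of four copies reproduces single-model greedy decoding", {
  cfg <- tiny_config()
  p <- tiny_params(cfg, seed = 13)
  model <- structure(list(params = p, config = cfg), class = "seq2seq_model")
  X <- tiny_batch(3L, 40L, seed = 14)
  feat <- imuseq:::cpp_encode(p, X, cfg$enc_layers)
  single <- decode_greedy(list(model), list(feat), 10L)
  quad <- decode_greedy(rep(list(model), 4), rep(list(feat), 4), 10L)
  expect_identical(single, quad)
})

test_that("averaged ensemble probabilities stay normalized", {
  cfg <- tiny_config()
  models <- lapply(1:4, function(i)
    structure(list(params = tiny_params(cfg, seed = i), config = cfg),
              class = "seq2seq_model"))
  X <- tiny_batch(2L, 40L, seed = 15)
  feats <- lapply(models, function(m) imuseq:::cpp_encode(m$params, X, cfg$enc_layers))
  probs <- 0
  hs <- feats
  for (i in 1:4) {
    st <- imuseq:::cpp_decoder_step(models[[i]]$params, hs[[i]], rep(5L, 2L),
                                    feats[[i]])
    probs <- probs + st$probs
  }
  expect_equal(rowSums(probs / 4), rep(1, 2), tolerance = 1e-6)
})

test_that("a single window is memorized by a few hundred training steps", {
  cfg <- tiny_config(hidden = 16L, lr = 5e-3, lr_decay = 1, batch_size = 1L,
                     max_epochs = 300L, patience = 300L, seed = 16L)
  set.seed(16)
  w <- list(data = matrix(rnorm(40 * 77), 40, 77), core_start = 10L,
            core_end = 30L, target = c(1L, 3L))
  m <- train_seq2seq(list(w), list(), cfg)
  expect_lt(m$history$loss[nrow(m$history)], 0.05)
})

test_that("training is reproducible and checkpoints round-trip bit-identically", {
  cfg <- tiny_config(hidden = 8L, max_epochs = 3L, seed = 21L)
  set.seed(22)
  ws <- lapply(1:6, function(i)
    list(data = matrix(rnorm(40 * 77), 40, 77), core_start = 10L,
         core_end = 30L, target = random_sequence(2)))
  m1 <- train_seq2seq(ws[1:4], ws[5:6], cfg)
  m2 <- train_seq2seq(ws[1:4], ws[5:6], cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m1, path)
  m3 <- load_model(path)
  X <- tiny_batch(2L, 40L, seed = 23)
  f1v <- imuseq:::cpp_encode(m1$params, X, cfg$enc_layers)
  f3v <- imuseq:::cpp_encode(m3$params, X, cfg$enc_layers)
  expect_identical(f1v, f3v)
  expect_identical(decode_greedy(list(m1), list(f1v), 8L),
                   decode_greedy(list(m3), list(f3v), 8L))
})

test_that("empty training sets and degenerate configs are rejected", {
  cfg <- tiny_config()
  expect_error(train_seq2seq(list(), list(), cfg), "empty")
  expect_error(seq2seq_config(hidden = 0L), "positive")
  expect_error(seq2seq_config(window_s = 2, core_s = 4), "core_s")
  expect_error(cross_validated_train(list(), k = 1L), "at least 2")
})

test_that("cross-validation folds rotate subjects disjointly and reproducibly", {
  ds <- get_small_dataset()
  trials <- Filter(function(t) t$split != "test", ds$trials)
  # 3 train subjects, k = 3: each subject validates exactly one fold
  cfg <- tiny_config(hidden = 4L, max_epochs = 1L, seed = 31L)
  ens1 <- cross_validated_train(trials, k = 3L, config = cfg)
  ens2 <- cross_validated_train(trials, k = 3L, config = cfg)
  expect_identical(ens1$folds, ens2$folds)
  expect_identical(sort(ens1$folds$subject), sort(unique(vapply(trials, `[[`, "", "subject"))))
  expect_identical(anyDuplicated(ens1$folds$subject), 0L)
  expect_length(ens1$models, 3L)
})

test_that("predict_recording tiles a 14-s recording into 4 core sequences", {
  cfg <- tiny_config(hidden = 4L, window_s = 6, core_s = 4, time_stride = 5L,
                     max_epochs = 1L)
  set.seed(41)
  tr <- small_trial(duration_s = 14)
  stats <- channel_stats(list(tr$recording))
  model <- structure(list(params = tiny_params(cfg, 41), config = cfg,
                          stats = stats), class = "seq2seq_model")
  out <- predict_recording(model, tr$recording)
  expect_length(out, 4L)
  bad <- tr$recording; bad$sample_rate <- 50
  expect_error(predict_recording(model, bad), "sample rate")
})
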