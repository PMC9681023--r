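test_that("statistical features have their closed forms on constant windows", {
  w <- matrix(-2, 10, 3)
  f <- extract_features(w)
  expect_length(f, 15L)
  # per channel: mean, max, min, sd, rms
  expect_equal(f[1:5], c(-2, -2, -2, 0, 2))
  expect_error(extract_features(matrix(0, 0, 3)), "empty")
})

test_that("RMS^2 = mean^2 + sd^2 under the population convention", {
  set.seed(81)
  for (rep in 1:20) {
    w <- matrix(rnorm(60), 20, 3)
    f <- matrix(extract_features(w), nrow = 5)
    expect_equal(f[5, ]^2, f[1, ]^2 + f[4, ]^2, tolerance = 1e-9)
  }
})

test_that("feature vectors have fixed channel-major layout", {
  w <- cbind(1:4, rep(7, 4))
  f <- extract_features(w)
  expect_length(f, 10L)
  expect_equal(f[6:10], c(7, 7, 7, 0, 7))
})

test_that("kaiser smoothing: identity, constancy and flip removal", {
  set.seed(82)
  probs <- matrix(runif(200 * 5), 200, 5)
  probs <- probs / rowSums(probs)
  expect_identical(kaiser_smooth(probs, 1L), probs)
  expect_error(kaiser_smooth(probs, 4L), "odd")

  const <- matrix(rep(c(0.6, 0.1, 0.1, 0.1, 0.1), each = 100), 100, 5)
  sm <- kaiser_smooth(const, 11L, 50)
  expect_equal(sm, const, tolerance = 1e-12)

  # isolated 1-sample flip inside a long run disappears after smoothing
  cls <- rep(1L, 101); cls[51] <- 2L
  onehot <- matrix(0, 101, 5); onehot[cbind(1:101, cls)] <- 1
  sm <- kaiser_smooth(onehot, 5L, 50)
  expect_true(all(max.col(sm) == 1L))
  # smoothed vectors remain normalized
  expect_equal(rowSums(sm), rep(1, 101), tolerance = 1e-9)
})

test_that("pointwise-to-sequence collapses argmax tracks", {
  onehot <- matrix(0, 30, 5)
  onehot[cbind(1:30, rep(c(2L, 4L), each = 15))] <- 1
  expect_identical(pointwise_to_sequence(onehot), c(2L, 4L))
  expect_identical(pointwise_to_sequence(onehot, 0L, 15L), 2L)
  # collapse never emits adjacent duplicates
  set.seed(83)
  noisy <- matrix(runif(150), 30, 5)
  s <- pointwise_to_sequence(noisy / rowSums(noisy))
  expect_true(all(diff(s) != 0 | length(s) <= 1))
})

test_that("the oracle one-hot pipeline reproduces the ground-truth sequence", {
  set.seed(84)
  tr <- small_trial(duration_s = 10)
  onehot <- matrix(0, length(tr$labels), 5)
  onehot[cbind(seq_along(tr$labels), tr$labels)] <- 1
  expect_identical(pointwise_to_sequence(onehot), trial_gt_sequence(tr))
})

test_that("smoother selection prefers the identity on noiseless one-hot input", {
  set.seed(85)
  trs <- replicate(3, small_trial(duration_s = 8), simplify = FALSE)
  probs <- lapply(trs, function(t) {
    oh <- matrix(0, length(t$labels), 5)
    oh[cbind(seq_along(t$labels), t$labels)] <- 1
    oh
  })
  gts <- lapply(trs, trial_gt_sequence)
  sel <- select_smoother(probs, gts, window_grid = c(1L, 11L, 41L), atten_grid = c(30, 60))
  expect_equal(sel$window_size, 1L)
  expect_equal(sel$atten_db, 30)
  expect_equal(max(sel$grid$f1), sel$grid$f1[sel$grid$window_size == 1][1])
  # single-candidate grid returns that candidate
  one <- select_smoother(probs, gts, window_grid = 21L, atten_grid = 50)
  expect_equal(one$window_size, 21L)
})

test_that("random forest separates linearly separable classes and is seeded", {
  set.seed(86)
  ds <- get_small_dataset()
  trials <- Filter(function(t) t$split == "train", ds$trials)
  stats <- channel_stats(lapply(trials, `[[`, "recording"))
  rf1 <- train_pointwise_rf(trials[1:4], stats, n_trees = 50L, seed = 9L)
  rf2 <- train_pointwise_rf(trials[1:4], stats, n_trees = 50L, seed = 9L)
  test_rec <- trials[[5]]$recording
  p1 <- predict_pointwise(rf1, test_rec)
  p2 <- predict_pointwise(rf2, test_rec)
  expect_identical(p1, p2)                                  # seeded
  expect_equal(rowSums(p1), rep(1, nrow(p1)), tolerance = 1e-9)
  # pointwise accuracy on burst-vs-quiescent structure is high on clean data
  acc <- mean(max.col(p1) == trials[[5]]$labels)
  expect_gte(acc, 0.8)

  # single-class data are rejected
  one_class <- trials[[1]]
  one_class$labels <- rep(5L, length(one_class$labels))
  expect_error(train_pointwise_rf(list(one_class), stats), "single class")
})
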