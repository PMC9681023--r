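test_that("sampled segments tile the requested duration exactly", {
  set.seed(51)
  for (dur in c(5, 12.34, 20)) {
    segs <- sample_segments(default_grammar(), dur)
    n <- as.integer(round(dur * 100))
    expect_equal(segs$start[1], 0L)
    expect_equal(segs$end[nrow(segs)], n)
    if (nrow(segs) > 1) expect_equal(segs$start[-1], segs$end[-nrow(segs)])
  }
})

test_that("a degenerate grammar produces a single-class tiling", {
  tr <- matrix(0, 5, 5); tr[, 5] <- 1   # every class jumps to idle
  g <- list(transition = tr, initial = c(0, 0, 0, 0, 1))
  set.seed(52)
  segs <- sample_segments(g, 10)
  expect_true(all(segs$klass == "idle"))
})

test_that("segment sampling is deterministic under a fixed seed", {
  set.seed(53); a <- sample_segments(default_grammar(), 15)
  set.seed(53); b <- sample_segments(default_grammar(), 15)
  expect_identical(a, b)
})

test_that("empirical transition frequencies match the grammar", {
  g <- default_grammar()
  set.seed(54)
  # sample many transitions directly through the segment sampler
  segs <- sample_segments(g, 12000)  # ~10,000 segments of >= 0.3 s
  cls <- class_to_code(segs$klass)
  from <- cls[-length(cls)]; to <- cls[-1]
  for (i in 1:5) {
    sel <- from == i
    n_i <- sum(sel)
    if (n_i < 50) next
    emp <- tabulate(to[sel], 5) / n_i
    se <- sqrt(g$transition[i, ] * (1 - g$transition[i, ]) / n_i)
    expect_true(all(abs(emp - g$transition[i, ]) <= pmax(3 * se, 1e-12)),
                label = paste("row", i))
  }
})

test_that("rendering realizes the phenotypes", {
  set.seed(55)
  ph <- default_phenotypes()
  cfg <- synthetic_config(noise_g = 0, noise_deg = 0, noise_quat_rad = 0)
  segs <- segments("reach", 0L, 100L)
  out <- render_recording(segs, ph, cfg, paretic_side = "right")
  hand_x <- out$recording$samples[, which(imu_channel_names() == "acc_r_hand_x")]
  bell <- ph$reach$amp_g * imuseq:::mj_bell(100)
  expect_equal(hand_x, bell, tolerance = 1e-12)      # closed-form minimum jerk
  expect_length(out$labels, 100L)                    # labels match duration

  set.seed(56)
  trial <- small_trial(duration_s = 20)
  burst <- trial$labels %in% 1:3
  energy <- rowMeans(abs(trial$recording$samples[, 1:27]))
  expect_gt(mean(energy[burst]), mean(energy[!burst]))
})

test_that("burst and quiescent samples are separable by a smoothed-energy oracle", {
  set.seed(57)
  ds <- generate_dataset(synthetic_config(n_subjects = 3L, trials_per_subject = 2L,
                                          split = c(train = 3L, val = 0L, test = 0L),
                                          seed = 57L))
  acc <- 0; lab <- 0
  correct <- 0; total <- 0
  for (t in ds$trials) {
    e <- rowMeans(t$recording$samples[, 1:27]^2)
    ma <- stats::filter(e, rep(1 / 31, 31), sides = 2)
    ma[is.na(ma)] <- e[is.na(ma)]
    burst <- t$labels %in% 1:3
    thr <- stats::quantile(ma, mean(!burst))  # oracle threshold at the class split
    correct <- correct + sum((ma > thr) == burst)
    total <- total + length(burst)
  }
  expect_gte(correct / total, 0.95)
})

test_that("dataset splits are disjoint by subject and the seed fixes the manifest", {
  ds <- get_small_dataset()
  by_split <- split(ds$manifest$subject, ds$manifest$split)
  pairs <- utils::combn(names(by_split), 2)
  for (k in seq_len(ncol(pairs))) {
    expect_length(intersect(by_split[[pairs[1, k]]], by_split[[pairs[2, k]]]), 0)
  }
  ds2 <- generate_dataset(ds$config)
  expect_identical(ds$manifest, ds2$manifest)
  # per-class totals equal the sum over trials
  per_trial <- vapply(ds$trials, function(t) true_counts(list(t)), integer(5))
  expect_equal(true_counts(ds$trials), rowSums(per_trial), ignore_attr = TRUE)
  # default self-transitions are zero: no adjacent duplicate segments
  for (t in ds$trials) expect_true(all(diff(class_to_code(t$segments$klass)) != 0))
})

test_that("config validation rejects impossible splits", {
  expect_error(generate_dataset(synthetic_config(n_subjects = 2L,
                                                 split = c(train = 1L, val = 0L, test = 1L))),
               "at least 3")
  expect_error(generate_dataset(synthetic_config(n_subjects = 5L,
                                                 split = c(train = 2L, val = 1L, test = 1L))),
               "sum to n_subjects")
  expect_error(synthetic_config(bogus_field = 1), "unknown")
})

test_that("datasets round-trip through disk", {
  ds <- get_small_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$manifest$subject, ds$manifest$subject)
  expect_equal(back$trials[[1]]$recording$samples, ds$trials[[1]]$recording$samples,
               tolerance = 1e-12)
  expect_identical(back$trials[[1]]$labels, ds$trials[[1]]$labels)
  expect_identical(back$trials[[1]]$segments, ds$trials[[1]]$segments)
})
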