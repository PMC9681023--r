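rc <- function(...) class_to_code(c(...))

# independent brute-force edit distance by exhaustive recursion
brute_distance <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  min(brute_distance(a[-1], b[-1]) + (a[1] != b[1]),
      brute_distance(a[-1], b) + 1,
      brute_distance(a, b[-1]) + 1)
}

test_that("alignment of identical sequences is all matches at distance 0", {
  al <- align_sequences(rc("reach", "transport"), rc("reach", "transport"))
  expect_equal(al$distance, 0)
  expect_true(all(al$ops$op == "match"))
})

test_that("a substitution plus an insertion are recovered from a mixed pair", {
  al <- align_sequences(rc("transport", "stabilization", "reach"),
                        rc("transport", "idle", "reach", "reach"))
  expect_equal(al$distance, 2)
  expect_equal(sum(al$ops$op == "substitution"), 1L)
  expect_equal(sum(al$ops$op == "insertion"), 1L)
  sub <- al$ops[al$ops$op == "substitution", ]
  expect_equal(code_to_class(sub$gt), "stabilization")
  expect_equal(code_to_class(sub$pred), "idle")
})

test_that("empty-side alignments are pure insertions/deletions", {
  al <- align_sequences(integer(0), rc("idle"))
  expect_equal(al$distance, 1)
  expect_equal(al$ops$op, "insertion")
  al <- align_sequences(rc("reach", "idle"), integer(0))
  expect_equal(al$distance, 2)
  expect_true(all(al$ops$op == "deletion"))
})

test_that("alignment distance matches brute-force recursion on short sequences", {
  set.seed(71)
  for (rep in 1:60) {
    a <- random_sequence(sample(0:4, 1))
    b <- random_sequence(sample(0:4, 1))
    expect_equal(align_sequences(a, b)$distance, brute_distance(a, b))
  }
})

test_that("alignment op counts satisfy the length identities on random pairs", {
  set.seed(72)
  for (rep in 1:100) {
    a <- random_sequence(sample(0:8, 1))
    b <- random_sequence(sample(0:8, 1))
    al <- align_sequences(a, b)
    n <- table(factor(al$ops$op, c("match", "substitution", "deletion", "insertion")))
    expect_equal(unname(n["match"] + n["substitution"] + n["deletion"]), length(a))
    expect_equal(unname(n["match"] + n["substitution"] + n["insertion"]), length(b))
    expect_equal(al$distance, unname(n["substitution"] + n["deletion"] + n["insertion"]))
  }
})

test_that("edit distance is symmetric and satisfies the triangle inequality", {
  set.seed(73)
  d <- function(a, b) align_sequences(a, b)$distance
  for (rep in 1:40) {
    a <- random_sequence(sample(0:6, 1))
    b <- random_sequence(sample(0:6, 1))
    cc <- random_sequence(sample(0:6, 1))
    expect_equal(d(a, b), d(b, a))
    expect_lte(d(a, cc), d(a, b) + d(b, cc))
  }
})

test_that("outcome taxonomy: FN and FP decompositions hold and match a direct pass", {
  set.seed(74)
  for (rep in 1:50) {
    al <- align_sequences(random_sequence(sample(1:8, 1)), random_sequence(sample(0:8, 1)))
    tal <- classify_outcomes(al)
    expect_equal(tal$fn, tal$deletion + tal$swap_out)
    expect_equal(tal$fp, tal$insertion + tal$swap_in)
    # independent tallies straight off the op list
    ops <- al$ops
    for (k in 1:5) {
      expect_equal(tal$tp[k], sum(ops$op == "match" & ops$gt == k))
      expect_equal(tal$deletion[k], sum(ops$op == "deletion" & ops$gt == k))
      expect_equal(tal$swap_out[k], sum(ops$op == "substitution" & ops$gt == k))
      expect_equal(tal$swap_in[k], sum(ops$op == "substitution" & ops$pred == k, na.rm = TRUE))
      expect_equal(tal$insertion[k], sum(ops$op == "insertion" & ops$pred == k, na.rm = TRUE))
    }
    # a substitution is one swap-out AND one swap-in
    expect_equal(sum(tal$swap_out), sum(tal$swap_in))
  }
})

test_that("single substitution yields paired swap-out/swap-in with FN = FP = 1", {
  tal <- classify_outcomes(align_sequences(rc("reach"), rc("idle")))
  expect_equal(tal$swap_out[tal$class == "reach"], 1L)
  expect_equal(tal$swap_in[tal$class == "idle"], 1L)
  expect_equal(sum(tal$fn), 1L)
  expect_equal(sum(tal$fp), 1L)
})

test_that("sensitivity, FDR and F1 formulas", {
  expect_equal(sensitivity(8, 2), 0.8)
  expect_equal(sensitivity(5, 0), 1.0)
  expect_equal(sensitivity(0, 5), 0.0)
  expect_true(is.na(sensitivity(0, 0)))
  expect_equal(fdr(8, 2), 0.2)
  expect_equal(fdr(8, 0), 0.0)
  expect_equal(fdr(0, 5), 1.0)
  expect_equal(f1(1, 0), 1.0)
  # formula form agrees with the count form on integer tallies
  set.seed(75)
  for (rep in 1:50) {
    tp <- sample(0:50, 1); fn <- sample(0:20, 1); fp <- sample(0:20, 1)
    if (tp + fn == 0 || tp + fp == 0 || 2 * tp + fn + fp == 0) next
    s <- sensitivity(tp, fn); f <- fdr(tp, fp)
    if (s + (1 - f) == 0) next  # harmonic-mean form undefined at (0, 1)
    expect_equal(f1(s, f), 2 * tp / (2 * tp + fn + fp), tolerance = 1e-12)
  }
})

test_that("AER equals brute-force distance normalized by ground-truth length", {
  expect_equal(aer(rc("reach", "idle"), rc("reach", "idle")), 0)
  expect_equal(aer(random_sequence(4), integer(0)), 1)
  expect_true(is.na(aer(integer(0), rc("reach"))))
  set.seed(76)
  for (rep in 1:30) {
    a <- random_sequence(sample(1:5, 1))
    b <- random_sequence(sample(0:6, 1))
    expect_equal(aer(a, b), brute_distance(a, b) / length(a))
  }
  # one substitution in a length-4 sequence
  gt <- rc("reach", "transport", "idle", "reach")
  pr <- gt; pr[2] <- class_to_code("idle")
  expect_equal(aer(gt, pr), 0.25)
})

test_that("confusion matrix rows conserve mass and match a brute-force pass", {
  set.seed(77)
  als <- lapply(1:30, function(i)
    align_sequences(random_sequence(sample(1:8, 1)), random_sequence(sample(0:8, 1))))
  cm <- confusion_matrix(als)
  tal <- classify_outcomes(als)
  for (k in 1:5) {
    if (tal$gt_count[k] == 0) next
    expect_equal(sum(cm[k, ]), 1, tolerance = 1e-12)          # row conservation
    expect_equal(cm[k, k], tal$tp[k] / tal$gt_count[k])       # diagonal = sensitivity
  }
  # perfect predictions give an identity diagonal
  perfect <- lapply(1:10, function(i) {
    s <- random_sequence(6)
    align_sequences(s, s)
  })
  cmp <- confusion_matrix(perfect)
  expect_true(all(diag(cmp[1:5, 1:5])[classify_outcomes(perfect)$gt_count > 0] == 1))
})

test_that("bootstrap comparison: df, determinism and the identical-models null", {
  set.seed(78)
  pt <- data.frame(trial = 1:100,
                   tp = rpois(100, 8), fn = rpois(100, 2), fp = rpois(100, 2))
  res <- bootstrap_compare(list(a = pt, b = pt), n_replicates = 250L, subsample = 81L)
  expect_equal(res$df, 498L)
  expect_true(all(res$tests$df == 498))
  expect_true(all(res$tests$p_bonferroni > 0.9))
  expect_true(all(abs(res$tests$mean_reference - res$tests$mean_model) < 1e-3))

  set.seed(99); r1 <- bootstrap_compare(list(a = pt, b = pt), 50L, 30L)
  set.seed(99); r2 <- bootstrap_compare(list(a = pt, b = pt), 50L, 30L)
  expect_identical(r1$replicates, r2$replicates)

  pt2 <- pt; pt2$trial <- pt2$trial + 1000
  expect_error(bootstrap_compare(list(a = pt, b = pt2)), "same trial set")
  expect_error(bootstrap_compare(list(a = pt)), "at least 2")
})

test_that("bootstrap detects a genuinely better model", {
  set.seed(79)
  good <- data.frame(trial = 1:100, tp = rpois(100, 9), fn = rpois(100, 1),
                     fp = rpois(100, 1))
  bad <- data.frame(trial = 1:100, tp = rpois(100, 6), fn = rpois(100, 4),
                    fp = rpois(100, 4))
  res <- bootstrap_compare(list(good = good, bad = bad), 100L, 50L)
  sens_row <- res$tests[res$tests$metric == "sensitivity", ]
  expect_lt(sens_row$p_bonferroni, 0.001)
  expect_gt(sens_row$mean_reference, sens_row$mean_model)
})
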