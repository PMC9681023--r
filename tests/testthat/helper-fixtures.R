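# shared fixtures, built in code

# minimal valid 77-channel sample matrix (all quaternion vector parts zero)
blank_samples <- function(n, paretic = 1) {
  m <- matrix(0, n, 77L)
  m[, 77L] <- paretic
  m
}

# small random primitive sequence over the 5-class alphabet
random_sequence <- function(len) sample.int(5L, len, replace = TRUE)

# one small synthetic trial (seeded by the caller)
small_trial <- function(duration_s = 12, paretic_side = "right") {
  cfg <- synthetic_config(duration_s = duration_s)
  segs <- sample_segments(default_grammar(), duration_s, sample_rate = cfg$sample_rate)
  render_recording(segs, config = cfg, paretic_side = paretic_side)
}

# memoized small synthetic dataset shared across test files
.fixture_env <- new.env(parent = emptyenv())

get_small_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(
      synthetic_config(n_subjects = 4L, trials_per_subject = 2L,
                       split = c(train = 3L, val = 0L, test = 1L),
                       duration_s = 12, seed = 77L))
  }
  .fixture_env$ds
}

# memoized full-scale trained ensemble used by the end-to-end checks; built
# once under the default study conditions
get_trained_ensemble <- function() {
  if (is.null(.fixture_env$ens)) {
    ds <- get_default_dataset()
    train_trials <- Filter(function(t) t$split == "train", ds$trials)
    .fixture_env$ens <- cross_validated_train(train_trials, k = 4L,
                                              config = seq2seq_config(seed = 101L))
  }
  .fixture_env$ens
}

get_default_dataset <- function() {
  if (is.null(.fixture_env$default_ds)) {
    .fixture_env$default_ds <- generate_dataset()
  }
  .fixture_env$default_ds
}
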