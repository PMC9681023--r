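#' Default kinematic phenotypes for the five primitives
#'
#' The generator gives each primitive class a distinct kinematic phenotype on
#' the 77-channel layout. The three motion primitives (reach, reposition,
#' transport) render minimum-jerk velocity bells on class-specific sensor
#' signatures: reach is hand/forearm dominant at the largest amplitude,
#' reposition forearm dominant at the smallest, transport hand/arm dominant
#' with trunk involvement. The two minimal-motion primitives render sensor
#' noise only, except that stabilization (and transport, which conveys an
#' object) carries a small constant offset on the paretic-hand acceleration
#' channels as a surrogate for grasp — the real sensor array has no finger
#' channels, which is exactly why stabilization and idle are confusable.
#' Durations are log-normal, truncated to `[0.3, 5]` s. Amplitudes are in g
#' (accelerations), degrees (joint angles) and radians (orientation
#' excursions).
#'
#' @return a named list, one phenotype per class, each with fields
#'   `profile` (`"burst"` or `"quiescent"`), `amp_g`, `ang_amp_deg`,
#'   `quat_amp_rad`, `grasp_g`, `dur_median_s`, `dur_sdlog`,
#'   `sensor_w` (length-9 paretic-side sensor weights) and `ang_channels`.
#' @export
default_phenotypes <- function() {
  w <- function(...) {
    v <- numeric(9L); named <- list(...)
    v[match(names(named), IMU_SENSORS)] <- unlist(named)
    v
  }
  list(
    reach = list(profile = "burst", amp_g = 1.0, ang_amp_deg = 30,
                 quat_amp_rad = 0.40, grasp_g = 0, dur_median_s = 1.0,
                 dur_sdlog = 0.30,
                 sensor_w = w(r_hand = 1.0, r_forearm = 0.8, r_arm = 0.5),
                 ang_channels = 1:4),
    reposition = list(profile = "burst", amp_g = 0.65, ang_amp_deg = 20,
                      quat_amp_rad = 0.30, grasp_g = 0, dur_median_s = 1.0,
                      dur_sdlog = 0.30,
                      sensor_w = w(r_forearm = 1.0, r_arm = 0.6, r_hand = 0.3),
                      ang_channels = 5:8),
    transport = list(profile = "burst", amp_g = 0.85, ang_amp_deg = 25,
                     quat_amp_rad = 0.35, grasp_g = 0.12, dur_median_s = 1.4,
                     dur_sdlog = 0.30,
                     sensor_w = w(r_hand = 0.9, r_arm = 0.9, c7 = 0.3),
                     ang_channels = 9:12),
    stabilization = list(profile = "quiescent", amp_g = 0, ang_amp_deg = 0,
                         quat_amp_rad = 0, grasp_g = 0.12, dur_median_s = 1.6,
                         dur_sdlog = 0.35, sensor_w = numeric(9L),
                         ang_channels = integer(0)),
    idle = list(profile = "quiescent", amp_g = 0, ang_amp_deg = 0,
                quat_amp_rad = 0, grasp_g = 0, dur_median_s = 1.2,
                dur_sdlog = 0.35, sensor_w = numeric(9L),
                ang_channels = integer(0))
  )
}

#' First-order primitive grammars
#'
#' Synthetic activities string primitives together under a first-order
#' Markov grammar. Rows are the current class, columns the next; rows sum to
#' one and the diagonal defaults to zero so the sampled ground truth never
#' contains back-to-back same-class segments (which a timing-free sequence
#' could not distinguish from a single long primitive). The two default
#' activities differ in how object-bound they are: `"act_table"` favours
#' reach-transport-stabilize cycles, `"act_sort"` favours repositioning.
#'
#' @param activity one of `"act_table"`, `"act_sort"`.
#' @return a list with `transition` (5 x 5 row-stochastic matrix, zero
#'   diagonal) and `initial` (length-5 probability vector).
#' @export
default_grammar <- function(activity = "act_table") {
  cls <- PRIMITIVE_CLASSES
  if (activity == "act_table") {
    tr <- rbind(c(0.00, 0.10, 0.60, 0.15, 0.15),
                c(0.35, 0.00, 0.20, 0.10, 0.35),
                c(0.15, 0.15, 0.00, 0.40, 0.30),
                c(0.30, 0.15, 0.35, 0.00, 0.20),
                c(0.40, 0.25, 0.25, 0.10, 0.00))
    init <- c(0.30, 0.10, 0.10, 0.10, 0.40)
  } else if (activity == "act_sort") {
    tr <- rbind(c(0.00, 0.30, 0.40, 0.10, 0.20),
                c(0.30, 0.00, 0.25, 0.10, 0.35),
                c(0.20, 0.30, 0.00, 0.25, 0.25),
                c(0.25, 0.30, 0.25, 0.00, 0.20),
                c(0.30, 0.35, 0.25, 0.10, 0.00))
    init <- c(0.25, 0.25, 0.10, 0.10, 0.30)
  } else stop("unknown synthetic activity: ", activity)
  dimnames(tr) <- list(cls, cls)
  list(transition = tr, initial = stats::setNames(init, cls))
}

validate_grammar <- function(grammar) {
  tr <- grammar$transition
  if (!all(dim(tr) == c(5L, 5L))) stop("transition matrix must be 5 x 5")
  if (any(abs(rowSums(tr) - 1) > 1e-9)) stop("transition rows must sum to 1")
  if (any(tr < 0)) stop("transition probabilities must be non-negative")
  if (abs(sum(grammar$initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  invisible(grammar)
}

#' Default synthetic dataset configuration
#'
#' The defaults define the study conditions used throughout the package's
#' experiments: 10 synthetic subjects (8 training, 2 held-out test), 5
#' trials per subject split over two activities, 20-s trials at 100 Hz,
#' acceleration noise at 5% of the largest burst amplitude, and balanced
#' paretic sides.
#'
#' @param ... named overrides of the default fields.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(n_subjects = 10L, trials_per_subject = 5L,
              activities = c("act_table", "act_sort"),
              split = c(train = 8L, val = 0L, test = 2L),
              duration_s = 20, sample_rate = 100,
              noise_g = 0.05, noise_deg = 1.0, noise_quat_rad = 0.005,
              drift_deg_min = 0, seed = 20260101L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown synthetic_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "synthetic_config")
}

#' Sample a primitive segment tiling from a grammar
#'
#' Draws a realization of the first-order grammar: classes follow the Markov
#' chain, durations are truncated log-normal per the phenotypes, and the last
#' segment is cut so the segments tile `[0, total_duration_s)` exactly.
#' Randomness comes from the R session RNG; callers seed it.
#'
#' @param grammar a grammar from [default_grammar()].
#' @param total_duration_s trial duration in seconds.
#' @param phenotypes phenotype list from [default_phenotypes()].
#' @param sample_rate sampling rate in Hz.
#' @return a segment table tiling `[0, total_duration_s * sample_rate)`.
#' @export
sample_segments <- function(grammar, total_duration_s, phenotypes = default_phenotypes(),
                            sample_rate = 100) {
  validate_grammar(grammar)
  n <- as.integer(round(total_duration_s * sample_rate))
  kl <- integer(0); len <- integer(0); total <- 0L
  cur <- sample.int(5L, 1L, prob = grammar$initial)
  while (total < n) {
    ph <- phenotypes[[cur]]
    dur <- stats::rlnorm(1L, meanlog = log(ph$dur_median_s), sdlog = ph$dur_sdlog)
    dur <- min(max(dur, 0.3), 5)
    k <- max(1L, as.integer(round(dur * sample_rate)))
    kl <- c(kl, cur); len <- c(len, k); total <- total + k
    cur <- sample.int(5L, 1L, prob = grammar$transition[cur, ])
  }
  end <- pmin(cumsum(len), n)
  keep <- c(TRUE, end[-length(end)] < n)[seq_along(end)]
  end <- end[keep]; kl <- kl[keep]
  start <- c(0L, end[-length(end)])
  segments(code_to_class(kl), start, end)
}

# normalized minimum-jerk velocity bell on k samples, peak 1
mj_bell <- function(k) {
  tau <- (seq_len(k) - 0.5) / k
  16 * tau^2 * (1 - tau)^2
}

# fixed per-sensor rotation axes (unit vectors) for orientation excursions
sensor_axes <- function() {
  ax <- rbind(c(1, 0.4, 0.2), c(0.3, 1, 0.1), c(0.2, 0.3, 1),
              c(1, 0.2, 0.5), c(1, 0.2, 0.5), c(0.5, 1, 0.3),
              c(0.5, 1, 0.3), c(0.2, 0.5, 1), c(0.2, 0.5, 1))
  ax / sqrt(rowSums(ax^2))
}

# map right-side-referenced sensor weights onto the paretic side, keeping a
# 30% contralateral component so motion is visible on both arms
side_weights <- function(sensor_w, paretic_side) {
  right <- c("r_hand", "r_arm", "r_forearm")
  left <- c("l_hand", "l_arm", "l_forearm")
  out <- sensor_w
  names(out) <- IMU_SENSORS
  if (paretic_side == "left") {
    out[left] <- sensor_w[match(right, IMU_SENSORS)]
    out[right] <- 0
  }
  contra <- if (paretic_side == "left") right else left
  ipsi <- if (paretic_side == "left") left else right
  out[contra] <- 0.3 * out[ipsi]
  out
}

#' Render a labeled synthetic IMU recording from segments
#'
#' Produces a 77-channel recording realizing the given segment tiling: burst
#' classes add minimum-jerk velocity bells on their signature acceleration
#' channels, joint-angle excursions on class-specific angle channels and
#' orientation excursions (rotations about fixed per-sensor axes) on the
#' quaternion channels; object-carrying classes add the constant grasp
#' offset on the paretic-hand acceleration channels; every continuous
#' channel receives Gaussian noise. The label track equals the segments.
#'
#' @param segs segment table tiling the trial.
#' @param phenotypes phenotype list.
#' @param config a [synthetic_config()].
#' @param paretic_side `"left"` or `"right"`.
#' @param subject_id,activity_id,trial_id,ue_fma recording metadata.
#' @return list with `recording` ([imu_recording()]) and `labels`
#'   (integer code track).
#' @export
render_recording <- function(segs, phenotypes = default_phenotypes(),
                             config = synthetic_config(), paretic_side = "right",
                             subject_id = "s1", activity_id = "a1", trial_id = "t1",
                             ue_fma = NA_integer_) {
  n <- segs$end[nrow(segs)]
  rate <- config$sample_rate
  axis_w <- c(1, 0.6, 0.3)
  m <- matrix(0, n, N_CHANNELS)

  # noise first: accelerations, angles, and orientation-angle jitter
  m[, ACC_COLS] <- stats::rnorm(n * 27L, sd = config$noise_g)
  m[, ANG_COLS] <- stats::rnorm(n * 22L, sd = config$noise_deg)
  theta <- matrix(stats::rnorm(n * 9L, sd = config$noise_quat_rad), n, 9L)

  hand <- if (paretic_side == "right") "r_hand" else "l_hand"
  hand_acc <- ACC_COLS[(match(hand, IMU_SENSORS) - 1L) * 3L + 1:3]

  for (i in seq_len(nrow(segs))) {
    ph <- phenotypes[[segs$klass[i]]]
    rows <- (segs$start[i] + 1L):segs$end[i]
    k <- length(rows)
    if (ph$profile == "burst") {
      bell <- mj_bell(k)
      sw <- side_weights(ph$sensor_w, paretic_side)
      for (s in which(sw > 0)) {
        acc_cols <- ACC_COLS[(s - 1L) * 3L + 1:3]
        m[rows, acc_cols] <- m[rows, acc_cols] +
          outer(bell, ph$amp_g * sw[s] * axis_w)
        theta[rows, s] <- theta[rows, s] + ph$quat_amp_rad * sw[s] * bell
      }
      if (length(ph$ang_channels)) {
        m[rows, ANG_COLS[ph$ang_channels]] <-
          m[rows, ANG_COLS[ph$ang_channels], drop = FALSE] +
          outer(bell, rep(ph$ang_amp_deg, length(ph$ang_channels)))
      }
    }
    if (ph$grasp_g > 0) {
      m[rows, hand_acc] <- m[rows, hand_acc] +
        matrix(ph$grasp_g * axis_w, k, 3L, byrow = TRUE)
    }
  }

  if (config$drift_deg_min > 0) {
    drift <- config$drift_deg_min * (seq_len(n) / rate) / 60
    m[, ANG_COLS] <- m[, ANG_COLS] + drift
  }

  ax <- sensor_axes()
  for (s in 1:9) {
    v <- outer(sin(theta[, s] / 2), ax[s, ])
    m[, QUAT_COLS[(s - 1L) * 3L + 1:3]] <- v
  }
  m[, FLAG_COL] <- if (paretic_side == "right") 1 else 0

  rec <- imu_recording(m, subject_id = subject_id, activity_id = activity_id,
                       trial_id = trial_id, sample_rate = rate, ue_fma = ue_fma)
  list(recording = rec, labels = segments_to_labels(segs, n), segments = segs)
}

#' Generate a full labeled synthetic dataset with subject-level splits
#'
#' Draws `n_subjects` synthetic subjects with balanced paretic sides,
#' renders `trials_per_subject` trials each (activities cycled), and assigns
#' whole subjects to the train/val/test splits so no subject leaks across
#' splits. The seed in the config fully determines the output.
#'
#' @param config a [synthetic_config()].
#' @param phenotypes phenotype list.
#' @return a `synthetic_dataset` list with `trials` (each holding
#'   `recording`, `labels`, `segments`, `subject`, `activity`, `trial_id`,
#'   `split`), a `manifest` data.frame and the `config`.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             phenotypes = default_phenotypes()) {
  if (config$n_subjects < 3L) stop("n_subjects must be at least 3")
  if (sum(config$split) != config$n_subjects) {
    stop("split sizes (", paste(config$split, collapse = "/"),
         ") must sum to n_subjects (", config$n_subjects, ")")
  }
  set.seed(config$seed)
  subjects <- sprintf("subj%02d", seq_len(config$n_subjects))
  sides <- rep(c("right", "left"), length.out = config$n_subjects)
  fma <- sample(20:66, config$n_subjects, replace = TRUE)
  split_of <- rep(names(config$split), times = config$split)

  grammars <- lapply(config$activities, default_grammar)
  names(grammars) <- config$activities

  trials <- list()
  for (i in seq_along(subjects)) {
    for (j in seq_len(config$trials_per_subject)) {
      act <- config$activities[((j - 1L) %% length(config$activities)) + 1L]
      segs <- sample_segments(grammars[[act]], config$duration_s, phenotypes,
                              config$sample_rate)
      tr <- render_recording(segs, phenotypes, config, paretic_side = sides[i],
                             subject_id = subjects[i], activity_id = act,
                             trial_id = sprintf("trial%02d", j), ue_fma = fma[i])
      tr$subject <- subjects[i]; tr$activity <- act
      tr$trial_id <- sprintf("trial%02d", j); tr$split <- split_of[i]
      trials[[length(trials) + 1L]] <- tr
    }
  }
  manifest <- data.frame(
    subject = vapply(trials, `[[`, "", "subject"),
    activity = vapply(trials, `[[`, "", "activity"),
    trial = vapply(trials, `[[`, "", "trial_id"),
    split = vapply(trials, `[[`, "", "split"),
    n_samples = vapply(trials, function(t) nrow(t$recording$samples), 0L),
    paretic_side = vapply(trials, function(t)
      if (t$recording$samples[1L, FLAG_COL] == 1) "right" else "left", ""),
    n_primitives = vapply(trials, function(t) nrow(t$segments), 0L),
    seed = config$seed,
    stringsAsFactors = FALSE)
  structure(list(trials = trials, manifest = manifest, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d trials, %d subjects (%s), seed %d\n",
              nrow(x$manifest), length(unique(x$manifest$subject)),
              paste(names(table(x$manifest$split)), table(x$manifest$split),
                    sep = ":", collapse = " "),
              x$config$seed))
  invisible(x)
}

#' Write / read a synthetic dataset as plain-text files
#'
#' Each trial becomes a channel table, a YAML metadata sidecar and a segment
#' label table; `manifest.csv` and `config.yaml` index the dataset.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset()` invisibly returns `dir`; `read_dataset()`
#'   rebuilds the `synthetic_dataset` from disk.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in dataset$trials) {
    stem <- file.path(dir, paste(t$subject, t$activity, t$trial_id, sep = "_"))
    write_recording(t$recording, paste0(stem, "_channels.csv"),
                    paste0(stem, "_meta.yaml"))
    write_segments(t$segments, paste0(stem, "_segments.csv"),
                   t$recording$sample_rate)
  }
  data.table::fwrite(dataset$manifest, file.path(dir, "manifest.csv"))
  yaml::write_yaml(unclass(dataset$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- as.data.frame(data.table::fread(file.path(dir, "manifest.csv")))
  config <- do.call(synthetic_config, yaml::read_yaml(file.path(dir, "config.yaml")))
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    stem <- file.path(dir, paste(r$subject, r$activity, r$trial, sep = "_"))
    rec <- read_recording(paste0(stem, "_channels.csv"), paste0(stem, "_meta.yaml"))
    segs <- read_segments(paste0(stem, "_segments.csv"), rec$sample_rate)
    list(recording = rec, labels = segments_to_labels(segs, nrow(rec$samples)),
         segments = segs, subject = r$subject, activity = r$activity,
         trial_id = r$trial, split = r$split)
  })
  structure(list(trials = trials, manifest = manifest, config = config),
            class = "synthetic_dataset")
}

#' Ground-truth primitive counts of a set of trials
#'
#' @param trials list of trials (elements of `synthetic_dataset$trials`).
#' @return named integer vector of per-class primitive counts.
#' @export
true_counts <- function(trials) {
  tab <- table(factor(unlist(lapply(trials, function(t) t$segments$klass)),
                      levels = PRIMITIVE_CLASSES))
  out <- as.integer(tab)
  names(out) <- PRIMITIVE_CLASSES
  out
}
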