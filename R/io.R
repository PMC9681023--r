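#' Canonical IMU channel layout
#'
#' Nine sensors (cervical and thoracic spine, pelvis, both hands, arms and
#' forearms) each contribute 3 acceleration axes (g) and the 3 vector
#' components of a sensor-orientation unit quaternion (the scalar part is
#' implied non-negative), followed by 22 upper-body joint angles (degrees)
#' and one paretic-side flag (0 = left, 1 = right), for 77 channels per
#' 10-ms time step.
#'
#' @return character vector of the 77 canonical channel names, in order:
#'   27 accelerations, 27 quaternion components, 22 angles, `paretic_side`.
#' @export
imu_channel_names <- function() {
  sensors <- c("c7", "t10", "pelvis", "l_hand", "r_hand",
               "l_arm", "r_arm", "l_forearm", "r_forearm")
  axes <- c("x", "y", "z")
  c(paste0("acc_", rep(sensors, each = 3L), "_", axes),
    paste0("quat_", rep(sensors, each = 3L), "_", axes),
    sprintf("ang_%02d", 1:22),
    "paretic_side")
}

IMU_SENSORS <- c("c7", "t10", "pelvis", "l_hand", "r_hand",
                 "l_arm", "r_arm", "l_forearm", "r_forearm")
N_CHANNELS <- 77L
ACC_COLS <- 1:27
QUAT_COLS <- 28:54
ANG_COLS <- 55:76
FLAG_COL <- 77L

#' Construct a validated IMU recording
#'
#' @param samples numeric matrix, one row per 10-ms time step, 77 columns in
#'   the canonical order of [imu_channel_names()].
#' @param subject_id,activity_id,trial_id identifiers.
#' @param sample_rate sampling rate in Hz (default 100).
#' @param ue_fma upper-extremity Fugl-Meyer score, 0-66, or `NA`.
#' @param validate check channel count, constant paretic flag and quaternion
#'   vector norms (`|v| <= 1 + 1e-3`).
#' @return an object of class `imu_recording`: a list with elements
#'   `samples`, `sample_rate`, `subject_id`, `activity_id`, `trial_id`,
#'   `ue_fma`.
#' @export
imu_recording <- function(samples, subject_id = "s1", activity_id = "a1",
                          trial_id = "t1", sample_rate = 100, ue_fma = NA_integer_,
                          validate = TRUE) {
  samples <- as.matrix(samples)
  if (validate) {
    if (ncol(samples) != N_CHANNELS) {
      stop("recording must have ", N_CHANNELS, " channels, got ", ncol(samples))
    }
    if (nrow(samples) > 0L) {
      flag <- samples[, FLAG_COL]
      if (any(flag != flag[1L])) stop("paretic-side flag must be constant")
      if (!all(flag[1L] %in% c(0, 1))) stop("paretic-side flag must be 0 or 1")
      vnorm <- quat_vector_norms(samples)
      if (any(vnorm > 1 + 1e-3)) {
        stop("quaternion vector components exceed unit norm (max |v| = ",
             format(max(vnorm)), ")")
      }
    }
  }
  colnames(samples) <- imu_channel_names()
  structure(list(samples = samples, sample_rate = sample_rate,
                 subject_id = subject_id, activity_id = activity_id,
                 trial_id = trial_id, ue_fma = ue_fma),
            class = "imu_recording")
}

# per-row, per-sensor norms of the stored quaternion vector parts -> n x 9
quat_vector_norms <- function(samples) {
  q <- samples[, QUAT_COLS, drop = FALSE]
  out <- matrix(0, nrow(samples), 9L)
  for (s in 1:9) {
    cols <- (s - 1L) * 3L + 1:3
    out[, s] <- sqrt(rowSums(q[, cols, drop = FALSE]^2))
  }
  out
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s/%s/%s: %d samples @ %g Hz (%.1f s), paretic side %s\n",
              x$subject_id, x$activity_id, x$trial_id, nrow(x$samples),
              x$sample_rate, nrow(x$samples) / x$sample_rate,
              if (x$samples[1L, FLAG_COL] == 1) "right" else "left"))
  invisible(x)
}

#' Read and write IMU recordings
#'
#' A recording is stored as two text files: a comma-delimited channel table
#' whose header names all 77 canonical channels (one row per 10-ms step),
#' and a YAML metadata sidecar with keys `subject`, `activity`, `trial`,
#' `paretic_side`, `sample_rate_hz` and optional `ue_fma`.
#'
#' @param channel_table_path path to the delimited channel table.
#' @param metadata_path path to the YAML sidecar.
#' @param rec an `imu_recording`.
#' @return `read_recording()` returns a validated [imu_recording()];
#'   `write_recording()` invisibly returns the two paths written.
#' @export
read_recording <- function(channel_table_path, metadata_path) {
  dt <- data.table::fread(channel_table_path, sep = ",", header = TRUE,
                          colClasses = "numeric", showProgress = FALSE)
  want <- imu_channel_names()
  have <- names(dt)
  if (!identical(have, want)) {
    missing <- setdiff(want, have)
    extra <- setdiff(have, want)
    msg <- "channel table schema mismatch"
    if (length(missing)) msg <- paste0(msg, "; missing: ", paste(missing, collapse = ", "))
    if (length(extra)) msg <- paste0(msg, "; unexpected: ", paste(extra, collapse = ", "))
    if (!length(missing) && !length(extra)) msg <- paste0(msg, "; columns out of order")
    stop(msg)
  }
  m <- as.matrix(dt)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1L]
    stop("non-numeric or missing cell in channel table at row ", bad)
  }
  meta <- yaml::read_yaml(metadata_path)
  for (key in c("subject", "activity", "trial", "sample_rate_hz")) {
    if (is.null(meta[[key]])) stop("metadata sidecar missing key: ", key)
  }
  imu_recording(m,
                subject_id = as.character(meta$subject),
                activity_id = as.character(meta$activity),
                trial_id = as.character(meta$trial),
                sample_rate = as.numeric(meta$sample_rate_hz),
                ue_fma = if (is.null(meta$ue_fma)) NA_integer_ else as.integer(meta$ue_fma))
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, channel_table_path, metadata_path) {
  stopifnot(inherits(rec, "imu_recording"))
  dt <- data.table::as.data.table(rec$samples)
  data.table::fwrite(dt, channel_table_path, sep = ",")
  meta <- list(subject = rec$subject_id, activity = rec$activity_id,
               trial = rec$trial_id,
               paretic_side = if (rec$samples[1L, FLAG_COL] == 1) "right" else "left",
               sample_rate_hz = rec$sample_rate)
  if (!is.na(rec$ue_fma)) meta$ue_fma <- rec$ue_fma
  yaml::write_yaml(meta, metadata_path)
  invisible(c(channel_table_path, metadata_path))
}

#' Read and write primitive segment label tables
#'
#' Delimited text with columns `klass,start_ms,end_ms` (end exclusive);
#' times are converted to 0-based sample indices at the given rate.
#'
#' @param path file path.
#' @param segs segment table from [segments()].
#' @param sample_rate sampling rate in Hz used for the ms/sample conversion.
#' @return `read_segments()` returns a segment table in sample units.
#' @export
read_segments <- function(path, sample_rate = 100) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, showProgress = FALSE)
  need <- c("klass", "start_ms", "end_ms")
  if (!all(need %in% names(dt))) {
    stop("segment table must have columns klass,start_ms,end_ms")
  }
  fac <- sample_rate / 1000
  segments(dt$klass, round(dt$start_ms * fac), round(dt$end_ms * fac))
}

#' @rdname read_segments
#' @export
write_segments <- function(segs, path, sample_rate = 100) {
  fac <- 1000 / sample_rate
  dt <- data.table::data.table(klass = segs$klass,
                               start_ms = as.integer(segs$start * fac),
                               end_ms = as.integer(segs$end * fac))
  data.table::fwrite(dt, path, sep = ",")
  invisible(path)
}
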