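# quaternion helpers ---------------------------------------------------------
# quaternions are (w, x, y, z) rows; the channel table stores only (x, y, z)
# with w = sqrt(1 - |v|^2) >= 0 implied.

quat_complete <- function(v) {
  # v: n x 3 vector parts -> n x 4 unit quaternions with non-negative w
  w2 <- pmax(0, 1 - rowSums(v^2))
  cbind(sqrt(w2), v)
}

quat_conjugate <- function(q) cbind(q[, 1L], -q[, 2L], -q[, 3L], -q[, 4L])

quat_multiply <- function(a, b) {
  # Hamilton product, row-wise; a or b may be a single row
  if (is.null(dim(a))) a <- matrix(a, 1L)
  if (is.null(dim(b))) b <- matrix(b, 1L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

quat_to_matrix <- function(q) {
  # single quaternion (w,x,y,z) -> 3x3 rotation matrix
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Sensor-centric quaternion transformation
#'
#' Re-expresses each sensor's orientation stream relative to a reference
#' (calibration) pose, so that the stored quaternions describe the rotation
#' of each sensor about its own axes rather than about the global frame:
#' `q_rel(t) = reference^-1 (x) q(t)` (Hamilton product). By default the
#' reference is each sensor's orientation at the first sample, so the
#' transformed stream starts at the identity rotation. Acceleration, joint
#' angle and flag channels pass through unchanged; output quaternions remain
#' unit-norm, stored as vector parts with non-negative implied scalar part.
#'
#' @param rec an [imu_recording()].
#' @param reference optional 9 x 4 matrix of unit reference quaternions
#'   (rows `(w, x, y, z)`, one per sensor in canonical sensor order).
#'   Defaults to the first sample of each sensor.
#' @return the transformed `imu_recording`.
#' @export
sensor_centric_transform <- function(rec, reference = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  m <- rec$samples
  if (nrow(m) == 0L) return(rec)
  if (is.null(reference)) {
    reference <- quat_complete(matrix(m[1L, QUAT_COLS], 9L, 3L, byrow = TRUE))
  } else {
    reference <- as.matrix(reference)
    if (!all(dim(reference) == c(9L, 4L))) stop("reference must be a 9 x 4 quaternion matrix")
    nrm <- sqrt(rowSums(reference^2))
    if (any(nrm < 1e-8)) stop("zero-norm reference quaternion for sensor ", which(nrm < 1e-8)[1L])
    reference <- reference / nrm
  }
  for (s in 1:9) {
    cols <- QUAT_COLS[(s - 1L) * 3L + 1:3]
    q <- quat_complete(m[, cols, drop = FALSE])
    rel <- quat_multiply(quat_conjugate(reference[s, , drop = FALSE]), q)
    # renormalize and fix sign convention w >= 0 (q and -q are one rotation)
    rel <- rel / sqrt(rowSums(rel^2))
    flip <- rel[, 1L] < 0
    rel[flip, ] <- -rel[flip, , drop = FALSE]
    m[, cols] <- rel[, 2:4, drop = FALSE]
  }
  rec$samples <- m
  rec
}

#' Per-channel normalization statistics
#'
#' Estimates per-channel means and standard deviations over the pooled rows
#' of the training-split recordings only; the statistics are stored with the
#' trained model and re-applied verbatim at validation and test time so no
#' test information leaks into preprocessing. Standard deviations of
#' constant channels are floored at `eps`.
#'
#' @param recordings a list of [imu_recording()] (the training split).
#' @param eps floor replacing zero standard deviations.
#' @return an object of class `channel_stats`: list with numeric vectors
#'   `mean` and `sd` of length 77.
#' @export
channel_stats <- function(recordings, eps = 1e-8) {
  if (inherits(recordings, "imu_recording")) recordings <- list(recordings)
  m <- do.call(rbind, lapply(recordings, function(r) r$samples))
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < eps] <- eps
  structure(list(mean = mu, sd = sdv, eps = eps), class = "channel_stats")
}

#' Z-score normalization of a recording
#'
#' Standardizes the 76 continuous channels with training-split statistics;
#' the paretic-side flag channel passes through unchanged.
#' `zscore_denormalize()` inverts the map with the same statistics.
#'
#' @param rec an [imu_recording()].
#' @param stats a [channel_stats()] object.
#' @return the (de)normalized `imu_recording`.
#' @export
zscore_normalize <- function(rec, stats) {
  stopifnot(inherits(rec, "imu_recording"), inherits(stats, "channel_stats"))
  m <- rec$samples
  cont <- seq_len(N_CHANNELS - 1L)
  m[, cont] <- sweep(sweep(m[, cont, drop = FALSE], 2L, stats$mean[cont], "-"),
                     2L, stats$sd[cont], "/")
  rec$samples <- m
  rec$normalized <- TRUE
  rec
}

#' @rdname zscore_normalize
#' @export
zscore_denormalize <- function(rec, stats) {
  stopifnot(inherits(rec, "imu_recording"), inherits(stats, "channel_stats"))
  m <- rec$samples
  cont <- seq_len(N_CHANNELS - 1L)
  m[, cont] <- sweep(sweep(m[, cont, drop = FALSE], 2L, stats$sd[cont], "*"),
                     2L, stats$mean[cont], "+")
  rec$samples <- m
  rec$normalized <- NULL
  rec
}
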