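#' Tile a recording into overlapping windows with prediction cores
#'
#' The model consumes fixed 6-s windows and predicts the primitive sequence
#' of the middle 4-s core; the flanking 1 s on each side provides temporal
#' context only. At the training slide (0.5 s) cores overlap heavily, which
#' multiplies training windows and exposes primitive boundaries at many
#' offsets. At the test slide (4 s) the cores partition the recording: core
#' starts are 0, 4, 8, ... and the final core is truncated at the recording
#' end, so every time step belongs to exactly one core. Window data outside
#' the recording (the 1-s flanks at the edges, and any truncated tail) is
#' zero-padded so each window has exactly `window_s * sample_rate` rows.
#'
#' @param rec an [imu_recording()] (normalized for model use).
#' @param labels optional dense label track (codes or characters) of the same
#'   length; when given, each window carries the run-length-collapsed target
#'   sequence of its core.
#' @param window_s,core_s window and core lengths in seconds (6 and 4).
#' @param slide_s core-to-core slide in seconds: 0.5 for training, 4 for
#'   testing (the default).
#' @param drop_partial_cores if `TRUE` (the training convention) only full
#'   `core_s` cores are produced; if `FALSE` (the test convention) a final
#'   truncated core covers the recording tail.
#' @param target_min_overlap_s when building target sequences, drop label
#'   runs that overlap the core by less than this many seconds (0 disables).
#'   Primitives last at least 0.3 s, so only slivers of primitives that
#'   barely graze a core boundary are affected; such a primitive lies
#'   substantially inside the neighbouring core and is represented there.
#'   Filtering them makes decoder targets consistent across window offsets
#'   instead of depending on sub-0.1-s boundary placement.
#' @return a list of windows, each a list with elements `data`
#'   (`window_s * rate` x 77 matrix), `core_start`, `core_end` (0-based
#'   half-open sample interval in recording coordinates) and `target`
#'   (integer code sequence or `NULL`).
#' @export
make_windows <- function(rec, labels = NULL, window_s = 6, core_s = 4,
                         slide_s = 4, drop_partial_cores = slide_s < core_s,
                         target_min_overlap_s = 0) {
  stopifnot(inherits(rec, "imu_recording"))
  if (core_s > window_s) stop("core_s must not exceed window_s")
  if (slide_s <= 0) stop("slide_s must be positive")
  rate <- rec$sample_rate
  n <- nrow(rec$samples)
  if (n == 0L) return(list())
  wlen <- as.integer(round(window_s * rate))
  clen <- as.integer(round(core_s * rate))
  step <- as.integer(round(slide_s * rate))
  flank <- (wlen - clen) %/% 2L
  if (!is.null(labels)) {
    labels <- class_to_code(labels)
    if (length(labels) != n) stop("label track length must equal recording length")
  }
  if (drop_partial_cores && n < clen) return(list())
  starts <- if (drop_partial_cores) {
    seq.int(0L, n - clen, by = step)
  } else {
    seq.int(0L, as.integer(max(0, ceiling(n / step) - 1)) * step, by = step)
  }
  lapply(as.integer(starts), function(cs) {
    ce <- min(cs + clen, n)
    ws <- cs - flank
    idx <- ws + seq_len(wlen) - 1L       # 0-based sample indices of the window
    inside <- idx >= 0L & idx < n
    data <- matrix(0, wlen, ncol(rec$samples))
    data[inside, ] <- rec$samples[idx[inside] + 1L, , drop = FALSE]
    colnames(data) <- colnames(rec$samples)
    list(data = data, core_start = cs, core_end = ce,
         target = if (is.null(labels)) NULL else {
           collapse_region_filtered(labels, cs, ce,
                                    as.integer(round(target_min_overlap_s * rate)))
         })
  })
}

# run-length collapse of [start, end) dropping runs shorter than min_len
# samples (boundary slivers); adjacent same-class runs created by a drop are
# merged; the dominant run is always kept so the sequence is never empty
collapse_region_filtered <- function(labels, start, end, min_len) {
  if (min_len <= 1L) return(collapse_to_sequence(labels, start, end))
  if (start == end) return(integer(0))
  r <- rle(class_to_code(labels)[(start + 1L):end])
  keep <- r$lengths >= min_len
  if (!any(keep)) keep[which.max(r$lengths)] <- TRUE
  rle(r$values[keep])$values
}
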