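#' Functional primitive classes
#'
#' The five substantive functional primitives of upper-extremity motion:
#' `reach` (motion to make contact with a target object), `reposition`
#' (motion near an object without conveying it), `transport` (motion
#' conveying an object), `stabilization` (minimal motion holding an object
#' still) and `idle` (minimal motion at the ready). The decoder vocabulary
#' additionally carries the reserved sequence tokens `SOS`, `EOS` and `PAD`,
#' which never appear in segments, counts or metrics.
#'
#' @format `PRIMITIVE_CLASSES` is a character vector of length 5;
#'   `DECODER_VOCAB` appends the three reserved tokens.
#' @export
PRIMITIVE_CLASSES <- c("reach", "reposition", "transport", "stabilization", "idle")

#' @rdname PRIMITIVE_CLASSES
#' @export
DECODER_VOCAB <- c(PRIMITIVE_CLASSES, "SOS", "EOS", "PAD")

# token integer codes (1-based); classes occupy 1..5 in fixed tie-break order
TOK_SOS <- 6L
TOK_EOS <- 7L
TOK_PAD <- 8L
N_CLASSES <- 5L
VOCAB_SIZE <- 8L

#' Encode / decode primitive class labels
#'
#' Primitive sequences are represented internally as integer vectors with
#' codes 1..5 in the fixed class order of [PRIMITIVE_CLASSES]; these helpers
#' convert between character labels and codes.
#'
#' @param x character vector of class labels, or integer vector of codes.
#' @return `class_to_code()` returns an integer vector; `code_to_class()` a
#'   character vector.
#' @export
class_to_code <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  code <- match(x, PRIMITIVE_CLASSES)
  if (anyNA(code)) {
    stop("unknown primitive class: ", paste(unique(x[is.na(code)]), collapse = ", "))
  }
  code
}

#' @rdname class_to_code
#' @export
code_to_class <- function(x) PRIMITIVE_CLASSES[as.integer(x)]

#' Primitive segment tables
#'
#' A segment table records the ground-truth decomposition of one recording:
#' one row per primitive instance with its class and half-open sample
#' interval `[start, end)` (0-based, end exclusive). Segments must be
#' ordered, non-overlapping and tile their recording without gaps when they
#' originate from a dense label track.
#'
#' @param klass character or integer vector of primitive classes.
#' @param start,end integer sample indices, 0-based, `start < end`, half-open.
#' @return a `data.frame` with columns `klass` (character), `start`, `end`.
#' @export
segments <- function(klass, start, end) {
  klass <- code_to_class(class_to_code(klass))
  start <- as.integer(start); end <- as.integer(end)
  if (length(klass) != length(start) || length(start) != length(end)) {
    stop("klass, start, end must have equal length")
  }
  if (any(start >= end)) stop("segments require start < end")
  if (length(start) > 1L) {
    if (any(diff(start) <= 0)) stop("segments must be ordered by start")
    if (any(start[-1L] < end[-length(end)])) stop("segments must not overlap")
  }
  data.frame(klass = klass, start = start, end = end, stringsAsFactors = FALSE)
}

#' Convert between segments and dense label tracks
#'
#' A label track assigns one primitive class per 10-ms time step. The two
#' forms round-trip losslessly except that adjacent same-class segments
#' merge when recovered from a track (the track cannot represent their
#' boundary).
#'
#' @param segs a segment table from [segments()]; must tile `[0, n)`.
#' @param n recording length in samples.
#' @param labels integer (codes) or character vector, one class per sample.
#' @return `segments_to_labels()` returns an integer code vector of length
#'   `n`; `labels_to_segments()` returns a segment table.
#' @export
segments_to_labels <- function(segs, n) {
  if (nrow(segs) == 0L) {
    if (n > 0L) stop("empty segment table cannot tile a non-empty recording")
    return(integer(0))
  }
  if (segs$start[1L] != 0L || segs$end[nrow(segs)] != n ||
      (nrow(segs) > 1L && any(segs$start[-1L] != segs$end[-nrow(segs)]))) {
    stop("segments must tile [0, n) exactly")
  }
  rep(class_to_code(segs$klass), times = segs$end - segs$start)
}

#' @rdname segments_to_labels
#' @export
labels_to_segments <- function(labels) {
  labels <- class_to_code(labels)
  if (length(labels) == 0L) {
    return(segments(character(0), integer(0), integer(0)))
  }
  r <- rle(labels)
  end <- cumsum(r$lengths)
  segments(code_to_class(r$values), c(0L, end[-length(end)]), end)
}

#' Run-length collapse of a label-track region into a primitive sequence
#'
#' Collapses the labels in the half-open region `[start, end)` of a dense
#' label track into the timing-free ordered class sequence that the decoder
#' emits and the counter consumes: consecutive identical classes become one
#' element; order is preserved. An empty region yields an empty sequence.
#'
#' @param labels integer code or character label track.
#' @param start,end 0-based half-open sample region; defaults to the whole
#'   track.
#' @return integer vector of class codes (possibly empty).
#' @export
collapse_to_sequence <- function(labels, start = 0L, end = length(labels)) {
  labels <- class_to_code(labels)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end > length(labels) || start > end) {
    stop("region [", start, ", ", end, ") out of bounds for track of length ",
         length(labels))
  }
  if (start == end) return(integer(0))
  rle(labels[(start + 1L):end])$values
}
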