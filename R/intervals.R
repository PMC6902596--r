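#' Circular genome intervals
#'
#' An interval on a circular sequence of length `genome_length`, stored
#' 0-based half-open: `start` is the first base (0-based, inclusive), `end`
#' the base after the last (exclusive).  The interval wraps across the
#' origin iff `start >= end`; `start == end` denotes the whole circle
#' (span equal to `genome_length`), which is permitted for rotations but
#' not for annotated features.
#'
#' @param start 0-based inclusive start, in `[0, genome_length)`.
#' @param end 0-based exclusive end, in `[0, genome_length]`.
#' @param genome_length Length of the circle in bp.
#' @return An object of class `circ_interval`.
#' @export
#' @examples
#' iv <- circ_interval(95, 5, 100)   # wraps the origin
#' interval_span(iv)                 # 10
circ_interval <- function(start, end, genome_length) {
  start <- as.integer(start); end <- as.integer(end)
  L <- as.integer(genome_length)
  if (is.na(L) || L <= 0L) stop("genome_length must be a positive integer", call. = FALSE)
  if (is.na(start) || start < 0L || start >= L)
    stop("interval start ", start, " outside [0, ", L, ")", call. = FALSE)
  if (is.na(end) || end < 0L || end > L)
    stop("interval end ", end, " outside [0, ", L, "]", call. = FALSE)
  structure(list(start = start, end = end, genome_length = L,
                 wraps = start >= end),
            class = "circ_interval")
}

#' @rdname circ_interval
#' @param x A `circ_interval`.
#' @export
interval_span <- function(x) {
  m <- (x$end - x$start) %% x$genome_length
  if (m == 0L) x$genome_length else m
}

# 1-based inclusive linear segments covering the interval (1 or 2 rows)
interval_segments <- function(x) {
  L <- x$genome_length
  if (!x$wraps) return(matrix(c(x$start + 1L, x$end), nrow = 1L))
  if (x$end == x$start) return(matrix(c(1L, L), nrow = 1L))  # whole circle
  segs <- matrix(c(x$start + 1L, L), nrow = 1L)
  if (x$end > 0L) segs <- rbind(segs, c(1L, x$end))
  segs
}

#' Shared bases of two circular intervals
#'
#' Number of bases of the circle covered by both intervals.  Symmetric.
#'
#' @param a,b `circ_interval` objects on the same circle.
#' @return Integer number of shared bases.
#' @export
interval_overlap <- function(a, b) {
  if (a$genome_length != b$genome_length)
    stop("intervals are on circles of different length", call. = FALSE)
  sa <- interval_segments(a); sb <- interval_segments(b)
  tot <- 0L
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
    tot <- tot + max(0L, min(sa[i, 2L], sb[j, 2L]) - max(sa[i, 1L], sb[j, 1L]) + 1L)
  }
  tot
}

# is b entirely inside a?
interval_contains <- function(a, b) {
  interval_overlap(a, b) == interval_span(b)
}

# interval from 0-based start and span, normalising the end
interval_from_span <- function(start0, span, L) {
  s <- ((start0 %% L) + L) %% L
  e <- s + span
  if (e > L) e <- e - L
  circ_interval(s, e, L)
}

#' @export
print.circ_interval <- function(x, ...) {
  cat(sprintf("<circ_interval [%d, %d) span=%d on %d bp circle%s>\n",
              x$start, x$end, interval_span(x), x$genome_length,
              if (x$wraps) ", wraps origin" else ""))
  invisible(x)
}
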