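#' Genomic interval (0-based, half-open)
#'
#' Lightweight container for a genomic interval. All coordinates in the
#' package are 0-based, half-open (`[start, end)`), i.e. the BED convention.
#' Printed 1-based inclusive coordinates (the usual way loci are quoted in
#' articles and browsers) must be converted on ingestion by subtracting 1
#' from the start.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end exclusive end; must satisfy `start < end` unless
#'   `zero_width = TRUE` (used for insertion anchors).
#' @param zero_width allow `start == end`.
#' @return an object of class `"gi"`.
#' @examples
#' gi("chr2", 74400000, 74760000)
#' @export
gi <- function(chrom, start, end, zero_width = FALSE) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (start < 0) stop("interval start must be >= 0")
  if (zero_width) {
    if (end < start) stop("interval end must be >= start")
  } else if (end <= start) {
    stop("interval must satisfy start < end (half-open convention)")
  }
  structure(list(chrom = chrom, start = start, end = end), class = "gi")
}

#' @export
print.gi <- function(x, ...) {
  cat(sprintf("%s:%s-%s [0-based, half-open; width %s]\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","),
              format(gi_width(x), big.mark = ",")))
  invisible(x)
}

#' @rdname gi
#' @param x a `gi` object.
#' @export
gi_width <- function(x) x$end - x$start

#' Convert a printed 1-based inclusive span to a `gi`
#'
#' @inheritParams gi
#' @param first,last 1-based inclusive coordinates as printed.
#' @export
gi_from_1based <- function(chrom, first, last) gi(chrom, first - 1, last)

is_gi <- function(x) inherits(x, "gi")

gi_midpoint <- function(x) floor((x$start + x$end) / 2)

# vectorised half-open overlap test: any shared base
overlaps_any <- function(start1, end1, start2, end2) {
  start1 < end2 & end1 > start2
}

# vectorised membership of point positions in [start, end)
point_in <- function(pos, start, end) pos >= start & pos < end
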