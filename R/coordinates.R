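# Internal coordinate convention: 0-based half-open [start, end), like BED.
# External tables (CNV TSV, VCF POS, CADD pos) are 1-based inclusive and are
# converted at the I/O boundary, never inside the analysis code.

#' Convert 1-based inclusive coordinates to the internal 0-based half-open form
#'
#' @param start,end Integer vectors of 1-based inclusive positions.
#' @return A list with elements `start` and `end` (0-based half-open).
#' @examples
#' coords_to_internal(101, 200) # start 100, end 200, length 100
#' @export
coords_to_internal <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert internal 0-based half-open coordinates back to 1-based inclusive
#'
#' Inverse of [coords_to_internal()]: `coords_to_external(coords_to_internal(s, e))`
#' reproduces `s, e` exactly.
#'
#' @param start,end Integer vectors of 0-based half-open positions.
#' @return A list with elements `start` and `end` (1-based inclusive).
#' @export
coords_to_external <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

# Overlap of half-open intervals [a1,a2) and [b1,b2), vectorized over b.
overlaps_halfopen <- function(a1, a2, b1, b2) {
  a1 < b2 & b1 < a2
}

# Validate a set of half-open intervals; `what` names the offending table in
# error messages.
check_intervals <- function(chrom, start, end, what = "interval") {
  if (any(is.na(chrom) | !nzchar(chrom))) {
    stop(sprintf("%s: chromosome label must be non-empty", what), call. = FALSE)
  }
  if (any(start < 0L)) {
    stop(sprintf("%s: start must be >= 0", what), call. = FALSE)
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("%s: end must exceed start (row %d: start=%d end=%d)",
                 what, bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}
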