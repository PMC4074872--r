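## Small shared helpers: rounding and coordinate conventions.

#' Round half away from zero
#'
#' Decimal rounding with halves moving away from zero (so 0.25 -> 0.3 at one
#' digit, -0.25 -> -0.3), the convention used for reported phenotype tables;
#' base `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Convert between 1-based inclusive and BED (0-based half-open) intervals
#'
#' Genomic coordinates are 1-based inclusive throughout the package (the
#' VCF/GFF3 convention); BED files are 0-based half-open. These two
#' converters are exact inverses.
#'
#' @param start,end 1-based inclusive interval bounds.
#' @return `toBedCoords`: data.frame with `start` and `end` on the BED
#'   scale; `fromBedCoords`: data.frame on the 1-based inclusive scale.
#' @examples
#' toBedCoords(1001, 2000)   # -> 1000, 2000
#' fromBedCoords(1000, 2000) # -> 1001, 2000
#' @export
toBedCoords <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  data.frame(start = start - 1L, end = end)
}

#' @rdname toBedCoords
#' @export
fromBedCoords <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  data.frame(start = start + 1L, end = end)
}

## Empirical top-quantile threshold: value of the k-th largest entry with
## k = ceiling(n * quantile), so that exactly k values (plus ties) are >= it.
topQuantileThreshold <- function(values, quantile) {
  stopifnot(length(values) >= 1, quantile > 0, quantile < 1)
  k <- max(1L, ceiling(length(values) * quantile))
  sort(values, decreasing = TRUE)[k]
}

## Distance from a point to a 1-based inclusive interval: 0 inside,
## otherwise the absolute offset to the nearest bound.
pointIntervalDistance <- function(pos, start, end) {
  pmax(0, pmax(start - pos, pos - end))
}
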