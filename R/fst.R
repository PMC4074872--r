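## Nei FST: per-site values, a genome-wide summary, and the 20-kb/2-kb
## sliding-window scan.

#' Per-site Nei FST
#'
#' Gene-diversity based fixation index for two populations without
#' sample-size correction: with `pbar = (p1 + p2)/2`,
#' `HT = 2 pbar (1 - pbar)` and `HS = p1(1-p1) + p2(1-p2)`,
#' `FST = (HT - HS)/HT`, defined as 0 for monomorphic sites (`HT = 0`).
#' Values lie in \[0, 1\], are symmetric in the populations, and are 0 iff
#' `p1 == p2` at polymorphic sites.
#'
#' @param p1,p2 allele frequencies in the two populations (vectorized;
#'   `NA` for masked sites propagates).
#' @return numeric vector of FST values.
#' @examples
#' fstPerSite(0.2, 0.8)  # 0.36
#' fstPerSite(0, 1)      # 1
#' @export
fstPerSite <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- p1 * (1 - p1) + p2 * (1 - p2)
  ifelse(ht == 0, 0, (ht - hs) / ht)
}

#' Genome-wide Nei FST
#'
#' Multi-locus Nei GST: the ratio of summed heterozygosity components,
#' `sum(HT - HS) / sum(HT)` over unmasked polymorphic sites. Averaging
#' components before taking the ratio (rather than averaging per-site
#' ratios) is the standard multi-locus estimator and is what converges to
#' the generating differentiation level.
#'
#' @param freqs `GRanges` from [alleleFrequencies()] (or any object with
#'   `p1`/`p2` metadata columns), or a data.frame with `p1`, `p2`.
#' @return a single FST value.
#' @export
fstGenomeWide <- function(freqs) {
  m <- if (is.data.frame(freqs)) freqs else as.data.frame(S4Vectors::mcols(freqs))
  keep <- !is.na(m$p1) & !is.na(m$p2)
  p1 <- m$p1[keep]; p2 <- m$p2[keep]
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- p1 * (1 - p1) + p2 * (1 - p2)
  sum(ht - hs) / sum(ht)
}

#' Sliding-window average of a per-site statistic
#'
#' Tiles windows of `window` bp every `step` bp from position 1 of each
#' chromosome and averages the site statistic over the SNPs each window
#' contains (unweighted mean). Windows containing no SNP are omitted.
#'
#' @param siteStats `GRanges` of SNP positions with a numeric metadata
#'   column named by `column`; must be sorted by position within
#'   chromosome.
#' @param window,step window size and slide step in bp (defaults 20 kb /
#'   2 kb).
#' @param column name of the metadata column to average.
#' @return `GRanges` of windows with metadata `value` (window mean) and
#'   `nSnps`.
#' @export
windowScan <- function(siteStats, window = 20000, step = 2000,
                       column = "value") {
  stopifnot(column %in% names(S4Vectors::mcols(siteStats)))
  v <- S4Vectors::mcols(siteStats)[[column]]
  keep <- !is.na(v)
  siteStats <- siteStats[keep]
  v <- v[keep]
  chroms <- split(seq_along(siteStats),
                  as.character(GenomicRanges::seqnames(siteStats)))
  res <- lapply(names(chroms), function(ch) {
    idx <- chroms[[ch]]
    pos <- BiocGenerics::start(siteStats)[idx]
    if (is.unsorted(pos)) stop("site positions must be sorted within chromosome")
    maxPos <- max(pos)
    starts <- seq(1L, maxPos, by = step)
    wr <- IRanges::IRanges(starts, width = window)
    hits <- IRanges::findOverlaps(IRanges::IRanges(pos, width = 1L), wr)
    if (!length(hits)) return(NULL)
    wi <- S4Vectors::subjectHits(hits)
    si <- S4Vectors::queryHits(hits)
    means <- tapply(v[idx][si], wi, mean)
    counts <- tapply(si, wi, length)
    w <- sort(unique(wi))
    GenomicRanges::GRanges(ch, wr[w],
                           value = as.numeric(means[as.character(w)]),
                           nSnps = as.integer(counts[as.character(w)]))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(GenomicRanges::GRanges(value = numeric(), nSnps = integer()))
  out <- suppressWarnings(do.call(c, res))
  S4Vectors::metadata(out)$window <- window
  S4Vectors::metadata(out)$step <- step
  out
}

#' Windowed Nei FST scan
#'
#' Convenience wrapper: computes per-site Nei FST from a frequency table
#' (masked sites skipped) and averages it in sliding windows via
#' [windowScan()].
#'
#' @param freqs `GRanges` from [alleleFrequencies()].
#' @param window,step window size and step in bp.
#' @return `GRanges` of windows with `value` (mean FST) and `nSnps`.
#' @export
fstWindowScan <- function(freqs, window = 20000, step = 2000) {
  gr <- freqs
  S4Vectors::mcols(gr)$value <- fstPerSite(freqs$p1, freqs$p2)
  windowScan(gr, window = window, step = step, column = "value")
}
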