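## Top-quantile region calling, intersection into ecotype differentiated
## regions (EDRs), EDS identification, and gene assignment.

#' Call top-quantile regions from a window or grid-point scan
#'
#' The threshold is the empirical top-`quantile` value: the k-th largest
#' statistic with `k = ceiling(n * quantile)`, so that exactly k entries
#' (plus any ties at the threshold) are selected -- tie handling is
#' deterministic and permutation-invariant. Selected windows or grid
#' points are converted to intervals (grid points are first expanded by
#' `expand` bp on each side) and merged when they overlap, abut, or are
#' separated by at most `mergeGap` bp.
#'
#' @param stats `GRanges` of windows or grid points with a numeric
#'   metadata column named by `column`.
#' @param quantile upper tail mass (default 0.005, i.e. the top 5 per
#'   mille). A warning is raised when fewer than `1/quantile` entries are
#'   available; the threshold still comes from the full sort.
#' @param mergeGap maximum gap (bp) between merged intervals; for a
#'   sliding-window scan use the step size, for a grid scan a small
#'   multiple of the grid spacing.
#' @param expand half-width (bp) by which point ranges are grown before
#'   merging (0 for window scans).
#' @param column metadata column holding the statistic.
#' @return `GRanges` of merged regions; the threshold is stored in
#'   `metadata(x)$threshold`.
#' @export
callTopRegions <- function(stats, quantile = 0.005, mergeGap = 2000,
                           expand = 0, column = "value") {
  v <- S4Vectors::mcols(stats)[[column]]
  stopifnot(!is.null(v))
  if (length(v) < 1 / quantile)
    warning("fewer than 1/quantile entries; threshold from full sort")
  thr <- topQuantileThreshold(v, quantile)
  hot <- stats[v >= thr]
  if (expand > 0)
    hot <- GenomicRanges::resize(hot, BiocGenerics::width(hot) + 2 * expand,
                                 fix = "center")
  out <- GenomicRanges::reduce(hot, min.gapwidth = mergeGap + 1L)
  BiocGenerics::start(out) <- pmax(1L, BiocGenerics::start(out))
  S4Vectors::metadata(out)$threshold <- thr
  out
}

#' Intersect FST and cross-population scan regions into EDRs
#'
#' Ecotype differentiated regions are the interval intersection of the
#' top-quantile windowed-FST regions and the top-quantile
#' cross-population composite-likelihood regions; empty intersections are
#' dropped. When a frequency table is supplied, the number of member SNPs
#' per EDR is attached.
#'
#' @param fstRegions,xpclrRegions merged `GRanges` from
#'   [callTopRegions()].
#' @param freqs optional `GRanges` of SNPs (e.g. from
#'   [alleleFrequencies()]).
#' @return `GRanges` of EDRs with `nSnps` when `freqs` is given.
#' @export
intersectToEdrs <- function(fstRegions, xpclrRegions, freqs = NULL) {
  edrs <- GenomicRanges::intersect(fstRegions, xpclrRegions,
                                   ignore.strand = TRUE)
  edrs <- edrs[BiocGenerics::width(edrs) > 0]
  if (!is.null(freqs))
    edrs$nSnps <- GenomicRanges::countOverlaps(edrs, freqs)
  edrs
}

#' Identify ecotype differentiated SNPs (EDSs)
#'
#' An EDS is a SNP inside an EDR whose between-population allele-frequency
#' difference is strictly greater than `minDiff` (default 0.6, i.e.
#' larger than 60%). SNPs masked in either population are excluded.
#'
#' @param freqs `GRanges` from [alleleFrequencies()].
#' @param edrs `GRanges` of EDRs.
#' @param minDiff strict lower bound on `|p1 - p2|`.
#' @return `GRanges` of EDSs with metadata `p1`, `p2` and `diff`.
#' @export
identifyEds <- function(freqs, edrs, minDiff = 0.6) {
  inEdr <- IRanges::overlapsAny(freqs, edrs)
  d <- abs(freqs$p1 - freqs$p2)
  sel <- inEdr & !is.na(d) & d > minDiff
  out <- freqs[sel]
  out$diff <- d[sel]
  out
}

#' Assign ecotype differentiated genes (EDGs)
#'
#' An EDG is a gene whose interval overlaps an EDR (any overlap). Each
#' EDG is classified by its nearest EDS: `"genic"` when an EDS lies within
#' the gene body, `"flank"` when the nearest EDS is within `flank` bp of
#' either gene end (strand ignored), `"none"` otherwise.
#'
#' @param edrs `GRanges` of EDRs.
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param eds `GRanges` of EDSs from [identifyEds()].
#' @param flank flank width in bp (default 1000).
#' @return `GRanges` of EDGs with `gene_id` and `edsClass`.
#' @export
assignEdgs <- function(edrs, genes, eds, flank = 1000) {
  stopifnot("gene_id" %in% names(S4Vectors::mcols(genes)))
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  known <- unique(as.character(GenomicRanges::seqnames(edrs)))
  if (length(known) && !any(gChrom %in% known) && length(edrs))
    stop("no shared chromosome names between genes and EDRs: genes on ",
         paste(unique(gChrom), collapse = ","))
  edgs <- genes[IRanges::overlapsAny(genes, edrs)]
  if (!length(edgs)) {
    edgs$edsClass <- character(0)
    return(edgs)
  }
  cls <- vapply(seq_along(edgs), function(i) {
    g <- edgs[i]
    onChrom <- eds[as.character(GenomicRanges::seqnames(eds)) ==
                     as.character(GenomicRanges::seqnames(g))]
    if (!length(onChrom)) return("none")
    dd <- pointIntervalDistance(BiocGenerics::start(onChrom),
                                BiocGenerics::start(g), BiocGenerics::end(g))
    dmin <- min(dd)
    if (dmin == 0) "genic" else if (dmin <= flank) "flank" else "none"
  }, character(1))
  edgs$edsClass <- cls
  edgs
}
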