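## Single-population composite likelihood ratio sweep scan based on the
## site frequency spectrum (SFS). The genome-wide empirical spectrum is
## the background model; around a putative sweep the spectrum of nearby
## sites is distorted toward the extreme (rare / near-fixed, i.e. low
## minor-allele) classes, with the distortion decaying with distance.

#' Genome-wide empirical site frequency spectrum
#'
#' Bins the (by default folded) allele-frequency spectrum of a single
#' population into `nBins` equal-width bins over (0, 0.5\] (folded) or
#' (0, 1) (unfolded), with a small pseudocount so every bin has positive
#' probability.
#'
#' @param p numeric vector of allele frequencies (reference-allele scale;
#'   `NA`s dropped). At least 100 SNPs are required.
#' @param nBins number of frequency bins.
#' @param folded fold the spectrum to minor-allele frequencies (default;
#'   the ancestral state is typically unknown).
#' @return list with `breaks`, `prob` (sums to 1), `nBins`, `folded`.
#' @export
backgroundSfs <- function(p, nBins = 10, folded = TRUE) {
  p <- p[!is.na(p)]
  p <- p[p > 0 & p < 1]
  if (length(p) < 100)
    stop("at least 100 unmasked polymorphic SNPs are required")
  f <- if (folded) pmin(p, 1 - p) else p
  top <- if (folded) 0.5 else 1
  breaks <- seq(0, top, length.out = nBins + 1)
  bin <- pmin(pmax(findInterval(f, breaks, left.open = TRUE), 1L), nBins)
  counts <- tabulate(bin, nBins) + 0.5
  list(breaks = breaks, prob = counts / sum(counts),
       nBins = nBins, folded = folded)
}

## Bin index of frequencies under an SFS object.
.sfsBin <- function(p, sfs) {
  f <- if (sfs$folded) pmin(p, 1 - p) else p
  pmin(pmax(findInterval(f, sfs$breaks, left.open = TRUE), 1L), sfs$nBins)
}

#' Single-population composite likelihood ratio sweep scan
#'
#' For each grid point (every `gridStep` bp) the SNPs within `windowBp`
#' contribute `log P(bin | model)` under the background spectrum and
#' under a sweep-distorted spectrum
#' `q(alpha, d) = e * bg + (1 - e) * spike`, where
#' `e = 1 - exp(-d / alpha)` is the probability that a lineage at
#' distance `d` escapes a sweep of scale `alpha` (bp) and `spike` is a
#' geometric spectrum concentrated on the extreme-frequency classes. The
#' score is `2 * (max_alpha CL(alpha) - CL(background))`, maximized over
#' a log-spaced `alphaGrid` that includes the null limit `alpha -> 0`
#' (escape everywhere), so scores are non-negative.
#'
#' @param freqs `GRanges` with a single population's frequencies in the
#'   metadata column `p` (or supply `column`).
#' @param background SFS from [backgroundSfs()]. A degenerate background
#'   with all mass in one bin is refused.
#' @param gridStep grid spacing in bp (default 1 kb).
#' @param windowBp half-window in bp around each grid point.
#' @param alphaGrid sweep-scale grid in bp.
#' @param spikeDecay geometric decay of the sweep spectrum over bins.
#' @param column name of the frequency column.
#' @return `GRanges` of grid points with `score` and `nSnps`.
#' @export
clrScan <- function(freqs, background, gridStep = 1000, windowBp = 50000,
                    alphaGrid = 10^seq(2, 4.5, length.out = 10),
                    spikeDecay = 0.3, column = "p") {
  if (max(background$prob) > 0.9)
    stop("degenerate background spectrum: refusing to scan")
  p <- S4Vectors::mcols(freqs)[[column]]
  usable <- !is.na(p) & p > 0 & p < 1
  fr <- freqs[usable]
  p <- p[usable]
  bin <- .sfsBin(p, background)
  logBg <- log(background$prob)[bin]
  spike <- spikeDecay^(seq_len(background$nBins) - 1)
  spike <- spike / sum(spike)
  logMix <- function(e, b) log(e * background$prob[b] + (1 - e) * spike[b])
  chroms <- split(seq_along(fr), as.character(GenomicRanges::seqnames(fr)))
  res <- lapply(names(chroms), function(ch) {
    idx <- chroms[[ch]]
    pos <- BiocGenerics::start(fr)[idx]
    if (max(pos) < gridStep %/% 2) return(NULL)
    gridPos <- seq(gridStep %/% 2, max(pos), by = gridStep)
    scores <- rep(NA_real_, length(gridPos))
    nS <- integer(length(gridPos))
    for (g in seq_along(gridPos)) {
      d <- abs(pos - gridPos[g])
      sel <- which(d <= windowBp)
      if (length(sel) < 2) next
      j <- idx[sel]; dj <- d[sel]
      ll0 <- sum(logBg[j])
      llA <- vapply(alphaGrid, function(a) {
        e <- 1 - exp(-dj / a)
        sum(logMix(e, bin[j]))
      }, numeric(1))
      scores[g] <- 2 * max(0, max(llA) - ll0)
      nS[g] <- length(sel)
    }
    ok <- !is.na(scores)
    if (!any(ok)) return(NULL)
    GenomicRanges::GRanges(ch, IRanges::IRanges(gridPos[ok], width = 1L),
                           score = scores[ok], nSnps = nS[ok])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(GenomicRanges::GRanges(score = numeric(), nSnps = integer()))
  out <- suppressWarnings(do.call(c, res))
  S4Vectors::metadata(out)$gridStep <- gridStep
  out
}

#' Call sweep regions and select nearby genes
#'
#' Takes the top-`quantile` grid points of a [clrScan()] (threshold as in
#' [callTopRegions()]), merges consecutive significant grid points lying
#' within `mergeGridSteps` grid steps of one another into sweep regions,
#' and selects every gene whose interval lies within `geneFlank` bp of a
#' significant grid point (distance 0 when the point falls inside the
#' gene).
#'
#' @param scores `GRanges` of grid points from [clrScan()].
#' @param quantile upper tail mass (default 0.05, the top 5%).
#' @param geneFlank maximum gene-to-grid-point distance in bp (default
#'   10 kb).
#' @param genes `GRanges` with `gene_id`.
#' @param mergeGridSteps merge significant grid points within this many
#'   grid steps.
#' @return list with `regions` (`GRanges`), `genes` (character vector of
#'   selected gene ids) and `threshold`.
#' @export
callSweepRegions <- function(scores, quantile = 0.05, geneFlank = 10000,
                             genes = NULL, mergeGridSteps = 2) {
  v <- scores$score
  thr <- topQuantileThreshold(v, quantile)
  hot <- scores[v >= thr]
  gridStep <- S4Vectors::metadata(scores)$gridStep
  if (is.null(gridStep)) gridStep <- 1000
  regions <- GenomicRanges::reduce(hot,
                                   min.gapwidth = mergeGridSteps * gridStep + 1L)
  selected <- character()
  if (!is.null(genes) && length(hot)) {
    stopifnot("gene_id" %in% names(S4Vectors::mcols(genes)))
    sel <- vapply(seq_along(genes), function(i) {
      g <- genes[i]
      same <- as.character(GenomicRanges::seqnames(hot)) ==
        as.character(GenomicRanges::seqnames(g))
      if (!any(same)) return(FALSE)
      dd <- pointIntervalDistance(BiocGenerics::start(hot)[same],
                                  BiocGenerics::start(g),
                                  BiocGenerics::end(g))
      min(dd) <= geneFlank
    }, logical(1))
    selected <- genes$gene_id[sel]
  }
  list(regions = regions, genes = selected, threshold = thr)
}

#' Assign EDGs to the population(s) in which they were selected
#'
#' Partitions a set of ecotype differentiated genes by membership in the
#' per-population selected-gene sets: `upland_only`, `irrigated_only`,
#' `both`, or `unassigned` (in neither). The labels are exhaustive and
#' mutually exclusive.
#'
#' @param edgIds character vector of EDG gene ids.
#' @param uplandGenes,irrigatedGenes gene ids selected in each
#'   population's sweep scan.
#' @return data.frame with `gene_id` and `label` (factor with the four
#'   levels above).
#' @export
assignEdgPopulation <- function(edgIds, uplandGenes, irrigatedGenes) {
  inU <- edgIds %in% uplandGenes
  inI <- edgIds %in% irrigatedGenes
  label <- ifelse(inU & inI, "both",
           ifelse(inU, "upland_only",
           ifelse(inI, "irrigated_only", "unassigned")))
  data.frame(gene_id = edgIds,
             label = factor(label, levels = c("upland_only",
                                              "irrigated_only",
                                              "both", "unassigned")))
}
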