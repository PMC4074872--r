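## Cross-population composite-likelihood sweep scan. At each grid point the
## objective population's allele frequencies are modeled, site by site,
## around the reference population's frequencies: neutrally as drift with
## genome-wide variance inflation omega, and under a sweep as a mixture in
## which a lineage at recombination distance r from the swept site is
## dragged to the ancestral haplotype's allele with probability
## 1 - c(r, s), c = 1 - exp(-r/s). Dragging inflates the conditional
## variance toward p(1-p); the score is twice the maximized composite
## log-likelihood ratio over the sweep scale s, so it is 0 when the null
## fits best and grows with coordinated multi-SNP frequency differentials.
## This is a normal-approximation reimplementation (no LD down-weighting)
## with the published window/grid/SNP-count parameters as defaults.

#' Cross-population composite likelihood ratio scan
#'
#' Scans grid points every `gridStep` bp. For each grid point, the SNPs
#' within a `windowCM`-centimorgan window (at most `maxSnps`, nearest
#' first) contribute a composite log-likelihood of the objective
#' population's frequencies (`p1`) given the reference population's
#' (`p2`). Under neutral drift `p1 ~ N(p2, (omega + 1/(2 n1)) v)` with
#' `v = p2(1 - p2)`; under a sweep of scale `s` centered at the grid
#' point, a site at map distance `r` keeps its drift variance with
#' probability `c = 1 - exp(-r/s)` and is otherwise dragged, giving
#' variance `v (c^2 omega + (1 - c)^2 + 1/(2 n1))`. The score is
#' `2 * (max_s CL(s) - CL(null))`, maximized over a log-spaced grid of
#' `s` that includes the null, so scores are non-negative.
#'
#' The drift inflation `omega` is estimated genome-wide by the method of
#' moments from `(p1 - p2)^2 / v` over intermediate-frequency sites.
#'
#' @param freqs `GRanges` from [alleleFrequencies()]; `p1` is the
#'   objective (swept-candidate) population.
#' @param gridStep grid spacing in bp (default 2 kb).
#' @param windowCM window size in centimorgans (default 0.1).
#' @param maxSnps maximum SNPs per window (default 150).
#' @param recRate constant recombination rate in cM/Mb used when no map is
#'   supplied (default 4, a rice-scale genome average).
#' @param geneticMap optional data.frame (`chrom`, `pos`, `cM`) mapping
#'   physical to genetic positions; linearly interpolated.
#' @param sGrid sweep-scale grid in Morgans over which the likelihood is
#'   maximized.
#' @param siteCap cap on each site's absolute log-likelihood-ratio
#'   contribution; bounds the influence of single extreme sites on the
#'   composite score (the role LD down-weighting plays in the full
#'   model). `Inf` disables the cap.
#' @return `GRanges` of grid points (width 1) with `score` and `nSnps`.
#'   Grid points with fewer than 2 usable SNPs are skipped.
#' @export
xpclrScan <- function(freqs, gridStep = 2000, windowCM = 0.1, maxSnps = 150,
                      recRate = 4, geneticMap = NULL,
                      sGrid = 10^seq(-6, -1.5, length.out = 12),
                      siteCap = 5) {
  m <- S4Vectors::mcols(freqs)
  usable <- !is.na(m$p1) & !is.na(m$p2)
  fr <- freqs[usable]
  p1 <- fr$p1; p2 <- fr$p2
  n1 <- if ("n1" %in% names(S4Vectors::mcols(fr))) fr$n1 else rep(Inf, length(fr))
  # variance scale with a floor: reference frequencies are treated as
  # bounded away from fixation so single ill-conditioned sites cannot
  # dominate the composite score
  v <- pmax(p2 * (1 - p2), 0.01)
  mid <- p2 > 0.05 & p2 < 0.95
  omega <- mean((p1[mid] - p2[mid])^2 / v[mid])
  sampVar <- ifelse(is.finite(n1) & n1 > 0, 1 / (2 * pmax(n1, 1)), 0)
  chroms <- split(seq_along(fr), as.character(GenomicRanges::seqnames(fr)))
  halfWinM <- windowCM / 2 / 100            # half window in Morgans
  res <- lapply(names(chroms), function(ch) {
    idx <- chroms[[ch]]
    pos <- BiocGenerics::start(fr)[idx]
    cm <- .geneticPosition(ch, pos, recRate, geneticMap)   # Morgans
    if (max(pos) < gridStep %/% 2) return(NULL)
    gridPos <- seq(gridStep %/% 2, max(pos), by = gridStep)
    gridCm <- .geneticPosition(ch, gridPos, recRate, geneticMap)
    scores <- rep(NA_real_, length(gridPos))
    nS <- integer(length(gridPos))
    for (g in seq_along(gridPos)) {
      r <- abs(cm - gridCm[g])
      sel <- which(r <= halfWinM)
      if (length(sel) > maxSnps)
        sel <- sel[order(r[sel])][seq_len(maxSnps)]
      if (length(sel) < 2) next
      j <- idx[sel]
      rj <- r[sel]
      var0 <- (omega + sampVar[j]) * v[j]
      ll0 <- dnorm(p1[j], p2[j], sqrt(var0), log = TRUE)
      lrS <- vapply(sGrid, function(s) {
        cc <- if (s <= 0) rep(1, length(rj)) else 1 - exp(-rj / s)
        varS <- v[j] * (cc^2 * omega + (1 - cc)^2 + sampVar[j])
        lr <- dnorm(p1[j], p2[j], sqrt(varS), log = TRUE) - ll0
        sum(pmin(pmax(lr, -siteCap), siteCap))
      }, numeric(1))
      scores[g] <- 2 * max(0, max(lrS))
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
  S4Vectors::metadata(out)$omega <- omega
  out
}

## Physical position -> genetic position in Morgans; constant rate unless a
## per-chromosome map (chrom, pos, cM) is supplied.
.geneticPosition <- function(chrom, pos, recRate, geneticMap) {
  if (is.null(geneticMap))
    return(pos * recRate * 1e-8)            # cM/Mb -> Morgans/bp
  gm <- geneticMap[geneticMap$chrom == chrom, ]
  if (nrow(gm) < 2) stop("genetic map needs >= 2 points for ", chrom)
  stats::approx(gm$pos, gm$cM, xout = pos, rule = 2)$y / 100
}
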