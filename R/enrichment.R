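## Chi-square contingency enrichment of gene categories among EDGs versus
## the genome-wide background.

#' Chi-square enrichment of a gene category in an EDG set
#'
#' From the four counts -- `a` category genes among the `b` EDGs, `c`
#' category genes among the `d` genome genes -- builds the 2x2 table
#' `[[a, b - a], [c - a, (d - b) - (c - a)]]` and applies Pearson's
#' chi-square test without continuity correction. The enrichment fold is
#' `(a/b) / (c/d)`. A warning is logged when any expected cell is below 1.
#'
#' @param a category genes in the EDG set.
#' @param b EDG set size.
#' @param c category genes genome-wide.
#' @param d genome gene total.
#' @return data.frame with `a`, `b`, `c`, `d`, `statistic`, `p`, `fold`.
#' @examples
#' chisqEnrichment(10, 154, 100, 30000)
#' @export
chisqEnrichment <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= a, c >= a, d >= b, d >= c)
  tab <- matrix(c(a, b - a, c - a, (d - b) - (c - a)), 2, 2, byrow = TRUE)
  if (any(tab < 0)) stop("negative derived cell; check the four counts")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    warning("expected cell below 1; chi-square approximation is poor")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  fold <- (a / b) / (c / d)
  data.frame(a = a, b = b, c = c, d = d,
             statistic = unname(ct$statistic), p = ct$p.value, fold = fold)
}

#' Enrichment of every category among a gene set
#'
#' Runs [chisqEnrichment()] for each category label over an EDG id set
#' against the genome background. Each gene counts once per category
#' regardless of how many differentiated SNPs it carries.
#'
#' @param edgIds character vector of EDG gene ids.
#' @param categories data.frame with `gene_id`, `category` (a gene may
#'   appear in several categories).
#' @param allGeneIds character vector of all genome gene ids.
#' @param adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, reporting raw
#'   P values.
#' @return data.frame, one row per category, with counts, statistic, `p`
#'   (and `pAdjusted` when requested) and `fold`.
#' @export
enrichmentTest <- function(edgIds, categories, allGeneIds,
                           adjust = "none") {
  stopifnot(all(c("gene_id", "category") %in% names(categories)))
  edgIds <- unique(edgIds)
  allGeneIds <- unique(allGeneIds)
  b <- length(edgIds)
  d <- length(allGeneIds)
  out <- do.call(rbind, lapply(unique(categories$category), function(cat) {
    catGenes <- unique(categories$gene_id[categories$category == cat])
    catGenes <- intersect(catGenes, allGeneIds)
    res <- chisqEnrichment(length(intersect(catGenes, edgIds)), b,
                           length(catGenes), d)
    cbind(category = cat, res)
  }))
  if (adjust != "none")
    out$pAdjusted <- stats::p.adjust(out$p, method = adjust)
  out[order(out$p), ]
}
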