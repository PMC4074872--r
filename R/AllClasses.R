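#' @import methods
#' @importFrom stats dnorm pchisq pnorm pt qnorm quantile rbeta rbinom rnorm
#'   runif sd setNames var cor complete.cases rmultinom cor.test t.test
#'   chisq.test as.dist
#' @importFrom utils read.delim write.table head tail
#' @importFrom BiocGenerics start end width strand
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData
NULL

#' GenotypeExperiment: biallelic SNP dosages with population labels
#'
#' A thin extension of [SummarizedExperiment::RangedSummarizedExperiment-class]
#' holding one assay, `"dosage"`, the per-site per-sample count of
#' reference alleles in \{0, 1, 2, NA\}. Row ranges carry the site
#' coordinates (1-based, width 1) with `ref` and `alt` alleles; column data
#' carries the sample-to-population assignment in `population`.
#'
#' @slot .nothing no additional slots; the class exists for validity checks
#'   and method dispatch.
#'
#' @seealso [GenotypeExperiment()] for the constructor,
#'   [dosage()], [populations()] for accessors.
#' @export
setClass("GenotypeExperiment",
  contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    if (!all(c("ref", "alt") %in% names(S4Vectors::mcols(rr))))
      msg <- c(msg, "rowRanges must carry 'ref' and 'alt' alleles")
    if (any(BiocGenerics::width(rr) != 1L))
      msg <- c(msg, "sites must have width 1")
    # strictly increasing positions within chromosome
    sp <- split(BiocGenerics::start(rr), as.character(GenomicRanges::seqnames(rr)))
    if (any(vapply(sp, function(x) is.unsorted(x, strictly = TRUE), logical(1))))
      msg <- c(msg, "site positions must be strictly increasing within chromosome")
  }
  if (!"population" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry 'population'")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param dosage integer matrix (sites x samples) of reference-allele
#'   dosages in \{0, 1, 2\} with `NA` for missing genotypes.
#' @param chrom,pos site coordinates (1-based positions).
#' @param ref,alt single-character reference and alternate alleles.
#' @param population character or factor of population labels, one per
#'   sample (e.g. `"upland"` / `"irrigated"`).
#' @param sampleNames optional sample identifiers; defaults to the dosage
#'   column names or `S1..Sn`.
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' ge <- GenotypeExperiment(
#'   dosage = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'   ref = c("A", "C"), alt = c("G", "T"),
#'   population = c("upland", "irrigated"))
#' dosage(ge)
#' @export
GenotypeExperiment <- function(dosage, chrom, pos, ref, alt, population,
                               sampleNames = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sampleNames))
    sampleNames <- colnames(dosage)
  if (is.null(sampleNames))
    sampleNames <- paste0("S", seq_len(ncol(dosage)))
  colnames(dosage) <- sampleNames
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = as.character(ref),
                               alt = as.character(alt))
  names(rr) <- paste(chrom, pos, sep = ":")
  rownames(dosage) <- names(rr)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(population = as.character(population),
                                   row.names = sampleNames))
  new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment Extract the dosage assay.
#' @param x a `GenotypeExperiment`.
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeExperiment Sample population labels (named character).
#' @export
populations <- function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$population),
           colnames(x))
}

#' @describeIn GenotypeExperiment Site coordinates and alleles as `GRanges`.
#' @export
sites <- function(x) SummarizedExperiment::rowRanges(x)

setMethod("show", "GenotypeExperiment", function(object) {
  pops <- table(populations(object))
  d <- dosage(object)
  cat("GenotypeExperiment:", nrow(object), "biallelic sites x",
      ncol(object), "samples\n")
  cat("  populations:",
      paste(names(pops), pops, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * mean(is.na(d))))
})

#' Admixture model fit
#'
#' Result of [admixtureEM()]: per-sample ancestry fractions `Q`
#' (samples x K, rows on the simplex), per-ancestry allele frequencies `F`
#' (K x sites, reference-allele scale) and the log-likelihood trace, which
#' is non-decreasing by construction of the EM updates.
#'
#' @slot Q numeric matrix of ancestry proportions.
#' @slot F numeric matrix of ancestral allele frequencies.
#' @slot loglik numeric vector, one entry per EM iteration.
#' @slot iterations integer, iterations used by the best start.
#' @slot converged logical.
#' @export
setClass("AdmixtureFit",
  representation(Q = "matrix", F = "matrix", loglik = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("AdmixtureFit", function(object) {
  msg <- character()
  if (any(object@Q < -1e-12) ||
      any(abs(rowSums(object@Q) - 1) > 1e-8))
    msg <- c(msg, "Q rows must be non-negative and sum to 1")
  if (any(object@F < -1e-12 | object@F > 1 + 1e-12))
    msg <- c(msg, "F entries must lie in [0, 1]")
  if (is.unsorted(object@loglik - 1e-8 * abs(object@loglik)))
    msg <- c(msg, "log-likelihood trace must be non-decreasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AdmixtureFit", function(object) {
  cat("AdmixtureFit: K =", ncol(object@Q), ",", nrow(object@Q), "samples,",
      ncol(object@F), "sites\n")
  cat("  log-likelihood:", tail(object@loglik, 1),
      "after", object@iterations, "iterations",
      if (object@converged) "(converged)" else "(max iterations)", "\n")
})

#' @describeIn AdmixtureFit Ancestry proportion matrix Q.
#' @param x an `AdmixtureFit`.
#' @export
ancestryQ <- function(x) x@Q

#' @describeIn AdmixtureFit Ancestral allele-frequency matrix F.
#' @export
ancestryF <- function(x) x@F

#' @describeIn AdmixtureFit Log-likelihood trace.
#' @export
loglikTrace <- function(x) x@loglik
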