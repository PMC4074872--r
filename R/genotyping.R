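## Site filters, low-coverage genotype decision rules, allele-frequency
## estimation with missing-data thresholds, and the high-call-rate SNP
## subset used for population-structure inference.

#' Filter SNP sites on quality, copy number and depth
#'
#' A site is kept iff `siteQuality >= 15`, `copyNumber <= 1.5` and
#' `6 <= depth <= 300` (boundary depths 6 and 300 are kept; only strict
#' violations are removed). Records with any of the three fields missing
#' are rejected with reason `"incomplete"`.
#'
#' @param siteTable data.frame with columns `siteQuality`, `copyNumber`,
#'   `depth` (one row per site; extra columns are carried through).
#' @param minQuality,maxCopyNumber,depthRange filter thresholds.
#' @return list with `kept` (the retained rows) and `log` (data.frame of
#'   rejected rows with a `reason` column: `"quality"`, `"copy_number"`,
#'   `"depth"` or `"incomplete"`; the first failing rule is reported).
#' @examples
#' tab <- data.frame(siteQuality = c(30, 14), copyNumber = 1, depth = 50)
#' filterSites(tab)$log$reason
#' @export
filterSites <- function(siteTable, minQuality = 15, maxCopyNumber = 1.5,
                        depthRange = c(6, 300)) {
  req <- c("siteQuality", "copyNumber", "depth")
  stopifnot(all(req %in% names(siteTable)))
  incomplete <- !complete.cases(siteTable[req])
  badQ <- !incomplete & siteTable$siteQuality < minQuality
  badC <- !incomplete & !badQ & siteTable$copyNumber > maxCopyNumber
  badD <- !incomplete & !badQ & !badC &
    (siteTable$depth < depthRange[1] | siteTable$depth > depthRange[2])
  reason <- rep(NA_character_, nrow(siteTable))
  reason[incomplete] <- "incomplete"
  reason[badQ] <- "quality"
  reason[badC] <- "copy_number"
  reason[badD] <- "depth"
  rejected <- !is.na(reason)
  log <- siteTable[rejected, , drop = FALSE]
  log$reason <- reason[rejected]
  list(kept = siteTable[!rejected, , drop = FALSE], log = log)
}

## IUPAC ambiguity decoding for consensus genotypes, via Biostrings' map.
.decodeIupac <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  ifelse(is.na(code) | !code %in% names(map), NA_character_, map[code])
}

#' Call a genotype from per-sample base-call evidence
#'
#' Implements the quality decision rules for low-coverage consensus calls,
#' using the Phred-scale average quality of the best base (`qBest`), of the
#' second-best base (`qSecond`) and of the consensus genotype
#' (`qConsensus`), with the score-20 threshold (error rate at most 1%):
#'
#' * `qBest >= 20` and `qSecond < 20`: homozygous best base;
#' * `qBest >= 20` and `qSecond >= 20`: heterozygous best/second;
#' * both `< 20` but `qConsensus >= 20`: the consensus genotype (an IUPAC
#'   code, decoded to a homozygote or heterozygote);
#' * otherwise: missing.
#'
#' The called genotype is then mapped to a reference-allele dosage given
#' the site's `ref`/`alt` pair; calls involving a base outside that pair
#' (or an inconsistent IUPAC code) are returned missing.
#'
#' @param qBest,qSecond,qConsensus numeric quality vectors.
#' @param bestBase,secondBase,consensusBase base calls (consensus may be an
#'   IUPAC ambiguity code).
#' @param ref,alt site alleles.
#' @return integer vector of dosages (0, 1, 2 or `NA`), vectorized over
#'   sites/records.
#' @export
callGenotype <- function(qBest, qSecond, qConsensus,
                         bestBase, secondBase, consensusBase, ref, alt) {
  n <- length(qBest)
  bestBase <- rep_len(bestBase, n)
  secondBase <- rep_len(secondBase, n)
  consensusBase <- rep_len(consensusBase, n)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  dosageOf <- function(b1, b2) {
    # dosage = number of reference alleles in the unordered pair (b1, b2)
    ok <- (b1 == ref | b1 == alt) & (b2 == ref | b2 == alt)
    ifelse(ok, (b1 == ref) + (b2 == ref), NA_integer_)
  }
  homBest <- qBest >= 20 & qSecond < 20
  het <- qBest >= 20 & qSecond >= 20
  cons <- qBest < 20 & qSecond < 20 & qConsensus >= 20
  out <- rep(NA_integer_, n)
  out[homBest] <- dosageOf(bestBase, bestBase)[homBest]
  out[het] <- dosageOf(bestBase, secondBase)[het]
  if (any(cons, na.rm = TRUE)) {
    dec <- .decodeIupac(consensusBase)
    b1 <- substr(dec, 1, 1)
    b2 <- ifelse(nchar(dec) == 2, substr(dec, 2, 2), b1)
    consDos <- ifelse(is.na(dec) | nchar(dec) > 2, NA_integer_,
                      dosageOf(b1, b2))
    out[cons] <- consDos[cons]
  }
  as.integer(out)
}

#' Build a GenotypeExperiment from raw call records
#'
#' Applies [callGenotype()] to a long table of per-(site, sample) call
#' records (the layout produced by [simulateGenotypeMatrix()] with
#' `records = TRUE`) and assembles the dosage matrix.
#'
#' @param records data.frame with columns `chrom`, `pos`, `sample`, `ref`,
#'   `alt`, `bestBase`, `secondBase`, `qBest`, `qSecond`, `consensusBase`,
#'   `qConsensus`.
#' @param population named character of population labels per sample.
#' @return a [GenotypeExperiment-class].
#' @export
genotypesFromRecords <- function(records, population) {
  d <- callGenotype(records$qBest, records$qSecond, records$qConsensus,
                    records$bestBase, records$secondBase,
                    records$consensusBase, records$ref, records$alt)
  key <- paste(records$chrom, records$pos, sep = ":")
  siteKeys <- unique(key)
  sampleIds <- unique(records$sample)
  mat <- matrix(NA_integer_, length(siteKeys), length(sampleIds),
                dimnames = list(siteKeys, sampleIds))
  mat[cbind(match(key, siteKeys), match(records$sample, sampleIds))] <- d
  first <- !duplicated(key)
  GenotypeExperiment(mat,
                     chrom = records$chrom[first], pos = records$pos[first],
                     ref = records$ref[first], alt = records$alt[first],
                     population = population[sampleIds],
                     sampleNames = sampleIds)
}

#' Per-population reference-allele frequencies with masking
#'
#' For each site and population, `p` is the allele-counting frequency
#' `sum(dosage) / (2 n)` over non-missing genotypes (heterozygotes
#' contribute 1), and `n` the number of called individuals. A site is
#' masked for a population unless strictly more than `minCalled`
#' individuals are called there; masked frequencies are `NA` and are
#' excluded from all frequency-based statistics.
#'
#' @param ge a [GenotypeExperiment-class] with exactly two population
#'   labels.
#' @param minCalled masking threshold; sites are kept when
#'   `n > minCalled` (default 10).
#' @return `GRanges` of sites with metadata `p1`, `n1`, `mask1`, `p2`,
#'   `n2`, `mask2`; populations are ordered by first appearance in the
#'   sample table and recorded in the `populations` attribute of the
#'   metadata.
#' @export
alleleFrequencies <- function(ge, minCalled = 10) {
  pop <- populations(ge)
  lv <- unique(pop)
  stopifnot(length(lv) == 2)
  d <- dosage(ge)
  out <- sites(ge)
  for (i in 1:2) {
    di <- d[, pop == lv[i], drop = FALSE]
    n <- rowSums(!is.na(di))
    p <- ifelse(n > 0, rowSums(di, na.rm = TRUE) / (2 * n), NA_real_)
    mask <- n <= minCalled
    p[mask] <- NA_real_
    S4Vectors::mcols(out)[[paste0("p", i)]] <- p
    S4Vectors::mcols(out)[[paste0("n", i)]] <- n
    S4Vectors::mcols(out)[[paste0("mask", i)]] <- mask
  }
  S4Vectors::metadata(out)$populations <- lv
  out
}

#' Select the high-call-rate SNP subset for structure inference
#'
#' Retains sites whose total number of non-missing genotypes across all
#' samples is strictly greater than `minTotalCalled` (default 100),
#' preserving site order.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param minTotalCalled strict lower bound on called samples per site.
#' @return the subsetted `GenotypeExperiment`.
#' @export
selectStructureSnps <- function(ge, minTotalCalled = 100) {
  called <- rowSums(!is.na(dosage(ge)))
  ge[called > minTotalCalled, ]
}
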