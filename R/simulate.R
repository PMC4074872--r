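## Synthetic two-population SNP data with planted selective sweeps and
## recorded ground truth. The generator emulates the study design it is
## meant to exercise: two rice ecotype panels (84 upland + 82 irrigated
## accessions), heavy genotype missingness from low-coverage sequencing
## (67% per accession on average), per-site read depths between 6 and 300,
## weak genome-wide differentiation (Nei FST about 0.06), and a handful of
## strongly differentiated sweep loci with skewed site frequency spectra.

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator. Defaults are the
#' study conditions the package is designed around: 84 + 82 samples, 67%
#' missing genotypes, read depths in \[6, 300\], background Nei FST 0.06,
#' and a 96.4% genotype-call concordance. Genome size defaults are
#' desk-scale (2 chromosomes of 1 Mb, 10,000 SNPs).
#'
#' @slot nPop1,nPop2 sample counts for population 1 (upland) and 2
#'   (irrigated).
#' @slot nChrom,chromLength,nSnps genome layout.
#' @slot fstBackground target realized between-population Nei FST of
#'   background sites, in \[0, 1).
#' @slot sweeps data.frame with columns `chrom`, `center`, `width`,
#'   `differential` (target |p1 - p2|, in \[0, 1\]) and `sfsSkew` (> 0;
#'   larger values push the swept population's derived alleles toward
#'   fixation).
#' @slot missingRate fraction of missing genotypes, in \[0, 1).
#' @slot depthRange integer min/max read depth.
#' @slot concordance fraction of determinable genotype calls whose quality
#'   scores encode the true genotype.
#' @slot seed integer random seed; identical seeds give identical output.
#' @export
setClass("SimConfig", representation(
  nPop1 = "integer", nPop2 = "integer",
  nChrom = "integer", chromLength = "integer", nSnps = "integer",
  fstBackground = "numeric", sweeps = "data.frame",
  missingRate = "numeric", depthRange = "integer",
  concordance = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@fstBackground < 0 || object@fstBackground >= 1)
    msg <- c(msg, "fstBackground must be in [0, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (object@concordance <= 0 || object@concordance > 1)
    msg <- c(msg, "concordance must be in (0, 1]")
  if (nrow(object@sweeps)) {
    s <- object@sweeps
    if (any(s$differential < 0 | s$differential > 1))
      msg <- c(msg, "sweep differential must be in [0, 1]")
    if (any(s$sfsSkew <= 0))
      msg <- c(msg, "sfsSkew must be > 0")
    if (any(s$width >= object@chromLength))
      msg <- c(msg, "sweep widths must be smaller than chromLength")
    if (any(s$chrom < 1 | s$chrom > object@nChrom))
      msg <- c(msg, "sweep chrom out of range")
  }
  if (length(object@depthRange) != 2 || object@depthRange[1] > object@depthRange[2] ||
      object@depthRange[1] < 0)
    msg <- c(msg, "depthRange must be an ordered non-negative pair")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nPop1,nPop2,nChrom,chromLength,nSnps,fstBackground,sweeps,missingRate,depthRange,concordance,seed
#'   see the class slots.
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- simConfig(nSnps = 1000, seed = 7)
#' @export
simConfig <- function(nPop1 = 84, nPop2 = 82, nChrom = 2,
                      chromLength = 1e6, nSnps = 10000,
                      fstBackground = 0.06,
                      sweeps = data.frame(chrom = integer(), center = integer(),
                                          width = integer(),
                                          differential = numeric(),
                                          sfsSkew = numeric()),
                      missingRate = 0.67, depthRange = c(6, 300),
                      concordance = 0.964, seed = 1L) {
  new("SimConfig",
      nPop1 = as.integer(nPop1), nPop2 = as.integer(nPop2),
      nChrom = as.integer(nChrom), chromLength = as.integer(chromLength),
      nSnps = as.integer(nSnps), fstBackground = fstBackground,
      sweeps = as.data.frame(sweeps), missingRate = missingRate,
      depthRange = as.integer(depthRange), concordance = concordance,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nPop1, "+", object@nPop2, "samples,",
      object@nChrom, "x", object@chromLength, "bp,", object@nSnps, "SNPs\n")
  cat("  background FST", object@fstBackground, "| missing", object@missingRate,
      "| depth", paste(object@depthRange, collapse = "-"),
      "|", nrow(object@sweeps), "sweep loci | seed", object@seed, "\n")
})

#' Simulate per-site population allele frequencies
#'
#' Background sites follow a Balding-Nichols model: an ancestral
#' reference-allele frequency is drawn from Uniform(0.05, 0.95) and each
#' population's frequency from a Beta distribution around it. The Beta
#' dispersion is set to `2*F/(1+F)` (with `F = fstBackground`) so that the
#' realized between-population Nei FST of the background equals
#' `fstBackground`: two demes drawn independently with dispersion `c` show
#' a between-deme Nei FST of `(c/2)/(1 - c/2)`, and this choice inverts
#' that relation.
#'
#' Sites inside a sweep interval are forced to the configured allele
#' frequency differential: the irrigated population keeps a low derived
#' frequency `q ~ Uniform(0, 1 - differential)` while the swept (upland)
#' population gets `q + differential`, then skewed toward fixation via
#' `p -> p^(1/sfsSkew)`; the reported reference-allele frequency is
#' `1 - derived`. All sweep sites therefore satisfy
#' `|p1 - p2| >= differential` in truth.
#'
#' @param config a [SimConfig-class].
#' @return list with `freqs`, a `GRanges` of site positions carrying true
#'   reference-allele frequencies `p1`, `p2` and `inSweep`; and `truth`,
#'   a list with the sweep intervals (`GRanges`) and the config.
#' @export
simulateFrequencies <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nC <- config@nChrom
  # even split of sites over chromosomes, unique sorted positions
  per <- diff(round(seq(0, config@nSnps, length.out = nC + 1)))
  chrom <- rep(paste0("chr", seq_len(nC)), per)
  pos <- unlist(lapply(per, function(n) {
    sort(sample.int(config@chromLength, n))
  }), use.names = FALSE)
  F <- config@fstBackground
  n <- config@nSnps
  panc <- runif(n, 0.05, 0.95)
  if (F > 0) {
    cdisp <- 2 * F / (1 + F)
    a <- panc * (1 - cdisp) / cdisp
    b <- (1 - panc) * (1 - cdisp) / cdisp
    p1 <- rbeta(n, a, b)
    p2 <- rbeta(n, a, b)
  } else {
    p1 <- p2 <- panc
  }
  sweepGr <- GenomicRanges::GRanges()
  inSweep <- rep(FALSE, n)
  if (nrow(config@sweeps)) {
    s <- config@sweeps
    sweepGr <- GenomicRanges::GRanges(
      paste0("chr", s$chrom),
      IRanges::IRanges(pmax(1, round(s$center - s$width / 2)),
                       pmin(config@chromLength, round(s$center + s$width / 2))),
      differential = s$differential, sfsSkew = s$sfsSkew)
    siteGr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
    hits <- GenomicRanges::findOverlaps(siteGr, sweepGr)
    idx <- S4Vectors::queryHits(hits)
    sw <- S4Vectors::subjectHits(hits)
    inSweep[idx] <- TRUE
    d <- s$differential[sw]
    skew <- s$sfsSkew[sw]
    qlow <- runif(length(idx), 0, 1 - d)        # derived freq, irrigated
    qhigh <- (qlow + d)^(1 / skew)              # derived freq, swept upland
    p1[idx] <- 1 - qhigh                        # reference-allele scale
    p2[idx] <- 1 - qlow
  }
  freqs <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                  p1 = p1, p2 = p2, inSweep = inSweep)
  names(freqs) <- paste(chrom, pos, sep = ":")
  list(freqs = freqs,
       truth = list(sweeps = sweepGr, config = config))
}

## Base pairs used for ref/alt: transitions twice as likely as
## transversions, loosely mirroring real SNP spectra.
.refAltPair <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  isTs <- runif(n) < 2 / 3
  alt <- ifelse(isTs, ts[ref],
                vapply(ref, function(r) sample(tv[[r]], 1), character(1)))
  data.frame(ref = ref, alt = alt)
}

#' Simulate a genotype matrix (and optional raw call records)
#'
#' Genotypes are drawn per sample as Binomial(2, p) on the reference-allele
#' scale, then masked missing at `missingRate`. With `records = TRUE`, a
#' per-(site, sample) table of raw call evidence (best/second base average
#' qualities, consensus genotype and quality, depth) is emitted, built so
#' that the genotype decision rules of [callGenotype()] recover the true
#' genotype for a `concordance` fraction of determinable calls.
#'
#' @param sim output of [simulateFrequencies()].
#' @param records logical; also emit the raw `SiteCallRecord` table
#'   (intended for small configurations).
#' @return list with `genotypes` (a [GenotypeExperiment-class]) and
#'   `records` (data.frame or `NULL`).
#' @export
simulateGenotypeMatrix <- function(sim, records = FALSE) {
  config <- sim$truth$config
  set.seed(config@seed + 1L)
  fr <- sim$freqs
  n <- length(fr)
  n1 <- config@nPop1; n2 <- config@nPop2
  p <- cbind(matrix(rep(fr$p1, n1), n, n1),
             matrix(rep(fr$p2, n2), n, n2))
  g <- matrix(rbinom(length(p), 2L, p), n, n1 + n2)
  miss <- matrix(runif(length(g)) < config@missingRate, n, n1 + n2)
  gObs <- g
  gObs[miss] <- NA_integer_
  ra <- .refAltPair(n)
  pop <- c(rep("upland", n1), rep("irrigated", n2))
  samp <- c(paste0("UP", seq_len(n1)), paste0("IR", seq_len(n2)))
  ge <- GenotypeExperiment(gObs,
                           chrom = as.character(GenomicRanges::seqnames(fr)),
                           pos = BiocGenerics::start(fr),
                           ref = ra$ref, alt = ra$alt,
                           population = pop, sampleNames = samp)
  rec <- NULL
  if (records)
    rec <- .simulateCallRecords(g, miss, ra, fr, samp, config)
  list(genotypes = ge, records = rec, truthDosage = g)
}

## Quality-score triples consistent with the three genotype decision rules.
## Truth dosage g (ref alleles): 2 = hom ref, 1 = het, 0 = hom alt.
.simulateCallRecords <- function(g, miss, ra, fr, samp, config) {
  n <- nrow(g); m <- ncol(g)
  chrom <- rep(as.character(GenomicRanges::seqnames(fr)), m)
  pos <- rep(BiocGenerics::start(fr), m)
  ref <- rep(ra$ref, m); alt <- rep(ra$alt, m)
  sampleId <- rep(samp, each = n)
  gv <- as.vector(g); missv <- as.vector(miss)
  # encoded dosage: truth, or a corrupted value for 1 - concordance of calls
  enc <- gv
  corrupt <- runif(n * m) >= config@concordance
  shift <- sample(1:2, n * m, replace = TRUE)
  enc[corrupt] <- (gv[corrupt] + shift[corrupt]) %% 3L
  qhi <- function(k) sample(20:40, k, replace = TRUE)
  qlo <- function(k) sample(0:19, k, replace = TRUE)
  N <- n * m
  qBest <- qhi(N); qSecond <- qlo(N); qCons <- qlo(N)
  bestBase <- ifelse(enc >= 1, ref, alt)
  secondBase <- ifelse(enc >= 1, alt, ref)
  consBase <- rep(NA_character_, N)
  # a third of determinable calls take the consensus route
  consensusRoute <- !missv & runif(N) < 1 / 3
  het <- enc == 1L
  qSecond[het & !consensusRoute] <- qhi(sum(het & !consensusRoute))
  qBest[consensusRoute] <- qlo(sum(consensusRoute))
  qCons[consensusRoute] <- qhi(sum(consensusRoute))
  iupacHet <- setNames(c("M", "R", "W", "S", "Y", "K"),
                       c("AC", "AG", "AT", "CG", "CT", "GT"))
  hetCode <- iupacHet[paste0(pmin(ref, alt), pmax(ref, alt))]
  consBase[consensusRoute] <- ifelse(het[consensusRoute],
                                     hetCode[consensusRoute],
                                     bestBase[consensusRoute])
  # missing: nothing reaches quality 20
  qBest[missv] <- qlo(sum(missv)); qSecond[missv] <- qlo(sum(missv))
  qCons[missv] <- qlo(sum(missv))
  data.frame(chrom = chrom, pos = pos, sample = sampleId,
             ref = ref, alt = alt,
             bestBase = bestBase, secondBase = secondBase,
             qBest = qBest, qSecond = qSecond,
             consensusBase = consBase, qConsensus = qCons,
             depth = sample(config@depthRange[1]:config@depthRange[2],
                            N, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate an admixed genotype panel with known ancestry
#'
#' Generates a two-source admixture scenario for testing ancestry
#' estimation: two strongly diverged source gene pools (Balding-Nichols
#' Beta draws with dispersion `sourceDivergence` around a common
#' ancestral frequency), a set of anchor individuals pure for each
#' source, and a set of admixed individuals with mixing proportion
#' `mixing`. Genotypes are Binomial(2, q' F) draws.
#'
#' @param nAnchor1,nAnchor2 pure individuals per source.
#' @param nAdmixed admixed individuals.
#' @param mixing ancestry fraction of source 1 in admixed individuals
#'   (default 0.7).
#' @param nSnps number of SNPs (default 5000).
#' @param sourceDivergence Beta dispersion of the source pools (default
#'   0.4, a deeply diverged pair such as distinct subspecies).
#' @param seed integer seed.
#' @return list with `genotypes` (a [GenotypeExperiment-class] with
#'   population labels `source1`/`source2`/`admixed`), `Q` (true
#'   ancestry matrix) and `F` (true source frequencies, 2 x sites).
#' @export
simulateAdmixedPanel <- function(nAnchor1 = 25, nAnchor2 = 25,
                                 nAdmixed = 30, mixing = 0.7,
                                 nSnps = 5000, sourceDivergence = 0.4,
                                 seed = 1) {
  set.seed(seed)
  panc <- runif(nSnps, 0.05, 0.95)
  a <- panc * (1 - sourceDivergence) / sourceDivergence
  b <- (1 - panc) * (1 - sourceDivergence) / sourceDivergence
  F <- rbind(rbeta(nSnps, a, b), rbeta(nSnps, a, b))
  Q <- rbind(cbind(rep(1, nAnchor1), 0),
             cbind(rep(0, nAnchor2), 1),
             cbind(rep(mixing, nAdmixed), 1 - mixing))
  P <- Q %*% F
  n <- nrow(Q)
  G <- matrix(rbinom(n * nSnps, 2L, P), n, nSnps)
  ra <- .refAltPair(nSnps)
  ge <- GenotypeExperiment(t(G),
                           chrom = "chr1", pos = seq_len(nSnps) * 100L,
                           ref = ra$ref, alt = ra$alt,
                           population = c(rep("source1", nAnchor1),
                                          rep("source2", nAnchor2),
                                          rep("admixed", nAdmixed)))
  list(genotypes = ge, Q = Q, F = F)
}

#' Simulate a gene annotation with category labels
#'
#' Tiles non-overlapping gene intervals over the chromosomes and assigns a
#' fraction of genes to a focal category; genes inside sweep intervals are
#' assigned to the category at `fold` times the background rate (capped at
#' probability 1), so that downstream enrichment has planted signal.
#'
#' @param config a [SimConfig-class].
#' @param nGenes total number of genes.
#' @param geneLength,minGap gene length and minimum intergenic gap (bp).
#' @param categoryFraction background fraction of genes in the focal
#'   category.
#' @param fold category enrichment fold inside sweep intervals (1 = none).
#' @param sweeps optional `GRanges` of sweep intervals (from
#'   [simulateFrequencies()] truth).
#' @return list with `genes` (`GRanges` with `gene_id`) and `categories`
#'   (data.frame `gene_id`, `category`).
#' @export
simulateGenesAndCategories <- function(config, nGenes = 200,
                                       geneLength = 2000, minGap = 500,
                                       categoryFraction = 0.1, fold = 1,
                                       sweeps = GenomicRanges::GRanges()) {
  set.seed(config@seed + 2L)
  per <- diff(round(seq(0, nGenes, length.out = config@nChrom + 1)))
  grl <- lapply(seq_len(config@nChrom), function(i) {
    k <- per[i]
    if (k == 0) return(GenomicRanges::GRanges())
    slot <- floor(config@chromLength / k)
    stopifnot(slot >= geneLength + minGap)
    starts <- (seq_len(k) - 1L) * slot +
      sample.int(slot - geneLength, k, replace = TRUE)
    GenomicRanges::GRanges(paste0("chr", i),
                           IRanges::IRanges(starts + 1L, width = geneLength))
  })
  genes <- suppressWarnings(do.call(c, grl))
  genes$gene_id <- sprintf("G%04d", seq_along(genes))
  names(genes) <- genes$gene_id
  inSweep <- IRanges::overlapsAny(genes, sweeps)
  pIn <- pmin(1, categoryFraction * fold)
  inCat <- ifelse(inSweep, runif(length(genes)) < pIn,
                  runif(length(genes)) < categoryFraction)
  categories <- data.frame(gene_id = genes$gene_id,
                           category = ifelse(inCat, "focal", "other"),
                           stringsAsFactors = FALSE)
  list(genes = genes, categories = categories)
}

#' Default phenotype generator parameters
#'
#' Group means and standard deviations for eight traits of upland and
#' irrigated rice scored under irrigated and rainfed-upland conditions
#' (e.g. plant height 89.5 +/- 16.0 cm for irrigated vs 116.1 +/- 22.1 cm
#' for upland accessions under the irrigated environment). These are the
#' generator's defaults; any subset can be overridden.
#'
#' @return data.frame with `trait`, `environment`, `ecotype`, `mean`, `sd`.
#' @export
phenotypeDefaults <- function() {
  tr <- c("plant_height", "tiller_number", "root_weight", "root_length",
          "grain_weight_1000", "productive_panicles",
          "filled_grain_per_panicle", "empty_grain_per_panicle")
  irr <- data.frame(
    trait = tr, environment = "irrigated",
    irrigated_mean = c(89.5, 9.8, 12.8, 24.1, 23.8, 11.0, 124.2, 31.0),
    irrigated_sd   = c(16.0, 3.1, 5.7, 2.5, 2.9, 3.1, 27.6, 21.1),
    upland_mean    = c(116.1, 8.7, 17.2, 27.2, 25.9, 9.6, 129.8, 31.4),
    upland_sd      = c(22.1, 2.7, 7.1, 4.1, 4.3, 2.7, 35.3, 15.4))
  upl <- data.frame(
    trait = tr[-6], environment = "upland",
    irrigated_mean = c(81.2, 1.5, 1.8, 23.5, 23.4, 33.3, 26.3),
    irrigated_sd   = c(12.6, 0.6, 0.9, 4.0, 4.7, 16.6, 10.1),
    upland_mean    = c(103.9, 1.3, 2.4, 29.9, 25.6, 40.5, 18.9),
    upland_sd      = c(15.4, 0.5, 1.0, 6.1, 4.4, 16.9, 9.8))
  wide <- rbind(irr, upl)
  long <- rbind(
    data.frame(trait = wide$trait, environment = wide$environment,
               ecotype = "irrigated", mean = wide$irrigated_mean,
               sd = wide$irrigated_sd),
    data.frame(trait = wide$trait, environment = wide$environment,
               ecotype = "upland", mean = wide$upland_mean,
               sd = wide$upland_sd))
  long[order(long$environment, long$trait, long$ecotype), ]
}

#' Simulate an ecotype-structured phenotype table
#'
#' Trait values are drawn Normal(mean, sd) per (trait, environment,
#' ecotype) cell of `params`, for `nPop1` upland and `nPop2` irrigated
#' accessions.
#'
#' @param config a [SimConfig-class].
#' @param params parameter table in the format of [phenotypeDefaults()].
#' @return data.frame with `accession`, `ecotype`, `environment`, `trait`,
#'   `value`.
#' @export
simulatePhenotypes <- function(config, params = phenotypeDefaults()) {
  set.seed(config@seed + 3L)
  acc <- data.frame(
    accession = c(paste0("UP", seq_len(config@nPop1)),
                  paste0("IR", seq_len(config@nPop2))),
    ecotype = c(rep("upland", config@nPop1),
                rep("irrigated", config@nPop2)))
  out <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    a <- acc[acc$ecotype == p$ecotype, ]
    data.frame(accession = a$accession, ecotype = p$ecotype,
               environment = p$environment, trait = p$trait,
               value = rnorm(nrow(a), p$mean, p$sd))
  }))
  rownames(out) <- NULL
  out
}
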