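# Site filters, genotype decision rules, allele frequencies and the
# structure-SNP subset.

test_that("site filters apply the quality/copy-number/depth rules with correct boundaries", {
  tab <- data.frame(
    siteQuality = c(30, 14, 15, 30, 30, 30, 30, 30, NA),
    copyNumber  = c(1.0, 1.0, 1.0, 1.6, 1.5, 1.0, 1.0, 1.0, 1.0),
    depth       = c(50, 50, 50, 50, 50, 5, 301, 6, 50))
  res <- filterSites(tab)
  # kept: rows 1 (clean), 3 (quality exactly 15), 5 (copy exactly 1.5),
  # 8 (depth exactly 6)
  expect_equal(nrow(res$kept), 4)
  expect_equal(res$log$reason,
               c("quality", "copy_number", "depth", "depth", "incomplete"))
  tab300 <- data.frame(siteQuality = 20, copyNumber = 1, depth = 300)
  expect_equal(nrow(filterSites(tab300)$kept), 1)
})

# Scalar reference implementation of the three decision rules, written
# directly from their verbal statement; used as the truth table.
oracleCall <- function(qb, qs, qc, best, second, cons, ref, alt) {
  dos <- function(b1, b2) {
    if (!(b1 %in% c(ref, alt)) || !(b2 %in% c(ref, alt))) return(NA_integer_)
    as.integer((b1 == ref) + (b2 == ref))
  }
  if (qb >= 20 && qs < 20) return(dos(best, best))
  if (qb >= 20 && qs >= 20) return(dos(best, second))
  if (qb < 20 && qs < 20 && qc >= 20) {
    dec <- Biostrings::IUPAC_CODE_MAP[cons]
    if (is.na(dec) || nchar(dec) > 2) return(NA_integer_)
    b1 <- substr(dec, 1, 1)
    b2 <- if (nchar(dec) == 2) substr(dec, 2, 2) else b1
    return(dos(b1, b2))
  }
  NA_integer_
}

test_that("genotype rules match the truth table on a quality grid", {
  grid <- expand.grid(qb = seq(0, 40, by = 4), qs = seq(0, 40, by = 4),
                      qc = seq(0, 40, by = 4))
  # ref/alt A/G; consensus is the A/G heterozygote code R
  got <- callGenotype(grid$qb, grid$qs, grid$qc,
                      bestBase = "A", secondBase = "G", consensusBase = "R",
                      ref = "A", alt = "G")
  want <- vapply(seq_len(nrow(grid)), function(i)
    oracleCall(grid$qb[i], grid$qs[i], grid$qc[i], "A", "G", "R", "A", "G"),
    integer(1))
  expect_identical(got, want)
})

test_that("genotype rule worked examples behave as specified", {
  # strong best base only -> homozygous best
  expect_identical(callGenotype(30, 5, 0, "A", "G", NA, "A", "G"), 2L)
  # both bases credible -> heterozygous
  expect_identical(callGenotype(25, 22, 0, "A", "G", NA, "A", "G"), 1L)
  # weak bases, credible consensus het -> dosage 1
  expect_identical(callGenotype(10, 8, 25, "A", "G", "R", "A", "G"), 1L)
  # weak everything -> missing
  expect_identical(callGenotype(10, 8, 15, "A", "G", "R", "A", "G"),
                   NA_integer_)
  # consensus homozygote code
  expect_identical(callGenotype(5, 5, 30, "A", "G", "G", "A", "G"), 0L)
  # consensus IUPAC inconsistent with the ref/alt pair -> missing
  expect_identical(callGenotype(5, 5, 30, "A", "G", "S", "A", "G"),
                   NA_integer_)
  # best base outside ref/alt -> missing
  expect_identical(callGenotype(30, 5, 0, "T", "G", NA, "A", "G"),
                   NA_integer_)
})

test_that("allele frequencies equal a naive recount and masking is strict", {
  for (seed in 1:3) {
    d <- randomDosage(40, 30, missing = 0.4, seed = seed)
    ge <- GenotypeExperiment(d, chrom = "chr1", pos = seq_len(40) * 10L,
                             ref = rep("A", 40), alt = rep("G", 40),
                             population = rep(c("upland", "irrigated"),
                                              each = 15))
    fr <- alleleFrequencies(ge, minCalled = 5)
    for (i in sample(40, 10)) {
      x <- d[i, 1:15]
      n <- sum(!is.na(x))
      if (n > 5) expect_equal(unname(fr$p1[i]), sum(x, na.rm = TRUE) / (2 * n))
      else expect_true(is.na(fr$p1[i]) && fr$mask1[i])
    }
  }
})

test_that("masking threshold is 'more than minCalled' exactly", {
  # site called in exactly 10 vs 11 of one population
  d <- matrix(NA_integer_, 2, 30)
  d[1, 1:10] <- 1L    # 10 called in pop1 -> masked
  d[2, 1:11] <- 1L    # 11 called -> kept
  d[, 16:30] <- 2L    # pop2 fully called
  ge <- GenotypeExperiment(d, chrom = "chr1", pos = c(10L, 20L),
                           ref = c("A", "A"), alt = c("G", "G"),
                           population = rep(c("upland", "irrigated"),
                                            each = 15))
  fr <- alleleFrequencies(ge, minCalled = 10)
  expect_true(fr$mask1[1])
  expect_false(fr$mask1[2])
  expect_equal(unname(fr$p2), c(1, 1))
  # all-missing site masks in both populations
  d2 <- rbind(d, NA)
  ge2 <- GenotypeExperiment(rbind(d, matrix(NA_integer_, 1, 30)),
                            chrom = "chr1", pos = c(10L, 20L, 30L),
                            ref = rep("A", 3), alt = rep("G", 3),
                            population = rep(c("upland", "irrigated"),
                                             each = 15))
  fr2 <- alleleFrequencies(ge2, minCalled = 10)
  expect_true(fr2$mask1[3] && fr2$mask2[3])
})

test_that("structure-SNP selection keeps sites called in more than the threshold", {
  d <- randomDosage(60, 120, missing = 0.2, seed = 9)
  ge <- GenotypeExperiment(d, chrom = "chr1", pos = seq_len(60) * 5L,
                           ref = rep("A", 60), alt = rep("C", 60),
                           population = rep(c("upland", "irrigated"), 60))
  sub <- selectStructureSnps(ge, minTotalCalled = 100)
  # independent recount oracle
  counts <- apply(d, 1, function(x) sum(!is.na(x)))
  expect_identical(BiocGenerics::start(sites(sub)),
                   (seq_len(60) * 5L)[counts > 100])
  # boundary: exactly 100 called is dropped, 101 retained
  d2 <- matrix(NA_integer_, 2, 120)
  d2[1, 1:100] <- 1L
  d2[2, 1:101] <- 1L
  ge2 <- GenotypeExperiment(d2, chrom = "chr1", pos = c(5L, 10L),
                            ref = c("A", "A"), alt = c("C", "C"),
                            population = rep(c("upland", "irrigated"), 60))
  expect_equal(nrow(selectStructureSnps(ge2, 100)), 1L)
  # fully-called matrix retains everything
  d3 <- matrix(1L, 3, 120)
  ge3 <- GenotypeExperiment(d3, chrom = "chr1", pos = c(5L, 10L, 15L),
                            ref = rep("A", 3), alt = rep("C", 3),
                            population = rep(c("upland", "irrigated"), 60))
  expect_equal(nrow(selectStructureSnps(ge3, 100)), 3L)
})
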