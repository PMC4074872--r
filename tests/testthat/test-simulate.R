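# Synthetic-data generator: determinism, frequency model, missingness,
# planted sweeps, genes and phenotypes.

test_that("generation is bit-identical under a fixed seed", {
  cfg <- simConfig(nSnps = 500, nChrom = 2, chromLength = 1e5, seed = 11)
  a <- simulateFrequencies(cfg)
  b <- simulateFrequencies(cfg)
  expect_identical(a$freqs, b$freqs)
  ga <- simulateGenotypeMatrix(a)
  gb <- simulateGenotypeMatrix(b)
  expect_identical(dosage(ga$genotypes), dosage(gb$genotypes))
  cfg2 <- simConfig(nSnps = 500, nChrom = 2, chromLength = 1e5, seed = 12)
  expect_false(identical(simulateFrequencies(cfg2)$freqs$p1, a$freqs$p1))
})

test_that("fstBackground = 0 gives identical population frequencies", {
  cfg <- simConfig(nSnps = 300, fstBackground = 0, nChrom = 1,
                   chromLength = 1e5, seed = 2)
  sim <- simulateFrequencies(cfg)
  expect_equal(sim$freqs$p1, sim$freqs$p2)
  expect_equal(fstGenomeWide(data.frame(p1 = sim$freqs$p1,
                                        p2 = sim$freqs$p2)), 0)
})

test_that("realized background FST matches the configured level", {
  for (f in c(0.06, 0.13)) {
    cfg <- simConfig(nSnps = 8000, nChrom = 2, chromLength = 1e6,
                     fstBackground = f, seed = 21)
    sim <- simulateFrequencies(cfg)
    got <- fstGenomeWide(data.frame(p1 = sim$freqs$p1, p2 = sim$freqs$p2))
    expect_lt(abs(got - f), 0.02)
  }
})

test_that("sweep sites honor the configured differential and SFS skew", {
  cfg <- simConfig(nSnps = 2000, nChrom = 1, chromLength = 1e6,
                   sweeps = data.frame(chrom = 1, center = 5e5, width = 1e5,
                                       differential = 0.9, sfsSkew = 3),
                   seed = 5)
  sim <- simulateFrequencies(cfg)
  sw <- sim$freqs[sim$freqs$inSweep]
  expect_gt(length(sw), 50)
  d <- abs(sw$p1 - sw$p2)
  expect_true(all(d >= 0.6))            # and in fact >= the differential
  expect_true(all(d >= 0.9 - 1e-9))
  # skew pushes the swept population's derived allele toward fixation
  expect_lt(median(sw$p1), 0.1)         # reference allele nearly lost
  # sweep interval inside chromosome bounds
  expect_true(all(BiocGenerics::start(sim$truth$sweeps) >= 1 &
                  BiocGenerics::end(sim$truth$sweeps) <= 1e6))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simConfig(fstBackground = 1), "fstBackground")
  expect_error(simConfig(missingRate = 1), "missingRate")
  expect_error(simConfig(sweeps = data.frame(chrom = 1, center = 100,
                                             width = 10, differential = 1.2,
                                             sfsSkew = 1)),
               "differential")
  expect_error(simConfig(nChrom = 1, chromLength = 1000,
                         sweeps = data.frame(chrom = 1, center = 100,
                                             width = 2000,
                                             differential = 0.5,
                                             sfsSkew = 1)),
               "width")
})

test_that("missingness hits the configured rate and fixed alleles give dosage 2", {
  cfg <- simConfig(nSnps = 1000, nChrom = 1, chromLength = 1e6,
                   missingRate = 0.67, seed = 8)
  sim <- simulateFrequencies(cfg)
  gm <- simulateGenotypeMatrix(sim)
  d <- dosage(gm$genotypes)             # 1000 x 166 > 1e5 entries
  expect_lt(abs(mean(is.na(d)) - 0.67), 0.02)
  # fixed reference allele in both populations
  fix <- sim
  fix$freqs$p1 <- 1; fix$freqs$p2 <- 1
  gm2 <- simulateGenotypeMatrix(fix)
  d2 <- dosage(gm2$genotypes)
  expect_true(all(d2[!is.na(d2)] == 2L))
})

test_that("call records decode to the true genotype at the configured concordance", {
  cfg <- simConfig(nPop1 = 10, nPop2 = 10, nSnps = 300, nChrom = 1,
                   chromLength = 1e5, missingRate = 0.2,
                   concordance = 0.964, seed = 13)
  sim <- simulateFrequencies(cfg)
  gm <- simulateGenotypeMatrix(sim, records = TRUE)
  ge <- genotypesFromRecords(gm$records, populations(gm$genotypes))
  truth <- gm$truthDosage
  called <- dosage(ge)
  det <- !is.na(called)
  acc <- mean(called[det] == truth[det])
  expect_gt(acc, 0.94)
  expect_lt(acc, 0.985)
  # missing pattern agrees with the direct dosage matrix
  expect_equal(is.na(called), is.na(dosage(gm$genotypes)),
               ignore_attr = TRUE)
})

test_that("gene models are sorted, non-overlapping and category-taggable", {
  cfg <- simConfig(nChrom = 2, chromLength = 1e6, seed = 3)
  gn <- simulateGenesAndCategories(cfg, nGenes = 100,
                                   categoryFraction = 0.1, fold = 1)
  genes <- gn$genes
  for (ch in unique(as.character(GenomicRanges::seqnames(genes)))) {
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == ch]
    expect_false(is.unsorted(BiocGenerics::start(g), strictly = TRUE))
    expect_true(all(BiocGenerics::start(g)[-1] > BiocGenerics::end(g)[-length(g)]))
  }
  expect_setequal(gn$categories$gene_id, genes$gene_id)
})

test_that("phenotypes track their configured cell means", {
  cfg <- simConfig(seed = 4)
  ph <- simulatePhenotypes(cfg)
  defs <- phenotypeDefaults()
  # every cell mean within 2 standard errors of the configured mean
  for (i in seq_len(nrow(defs))) {
    cell <- defs[i, ]
    v <- ph$value[ph$trait == cell$trait & ph$environment == cell$environment &
                    ph$ecotype == cell$ecotype]
    se <- cell$sd / sqrt(length(v))
    expect_lt(abs(mean(v) - cell$mean), 3 * se)
  }
  # sd = 0 gives exact means
  defs0 <- defs
  defs0$sd <- 0
  ph0 <- simulatePhenotypes(cfg, params = defs0)
  g <- ph0[ph0$trait == "plant_height" & ph0$environment == "irrigated", ]
  expect_equal(unique(g$value[g$ecotype == "upland"]), 116.1)
  expect_equal(unique(g$value[g$ecotype == "irrigated"]), 89.5)
})
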