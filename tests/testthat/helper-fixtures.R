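# Shared fixtures built in code.

# A tiny deterministic genotype table: 4 sites x 4 samples, two populations.
makeTinyGe <- function() {
  d <- matrix(c(2L, 1L, 0L, NA,
                2L, 2L, 1L, 0L,
                0L, 0L, NA, 1L,
                1L, 1L, 2L, 2L), nrow = 4, byrow = TRUE)
  GenotypeExperiment(d,
                     chrom = rep("chr1", 4), pos = c(100L, 200L, 300L, 400L),
                     ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
                     population = c("upland", "upland", "irrigated", "irrigated"),
                     sampleNames = c("u1", "u2", "i1", "i2"))
}

# Random dosage matrix with controlled missingness.
randomDosage <- function(nSites, nSamples, missing = 0.3, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, nSites * nSamples, replace = TRUE),
              nSites, nSamples)
  d[matrix(runif(nSites * nSamples) < missing, nSites, nSamples)] <- NA
  storage.mode(d) <- "integer"
  d
}

# Does the (possibly rooted) tree contain the bipartition grp | rest?
# Re-roots at a tip outside grp so clade representation is well defined.
hasBipartition <- function(tree, grp) {
  out <- setdiff(tree$tip.label, grp)[1]
  tr <- ape::root(ape::unroot(tree), outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(tr, grp)
}

# Printed phenotype-differentiation table used for the arithmetic
# regression: group means plus the expected difference/percentage cells.
phenotypeEcotypeCells <- function() {
  df <- read.table(header = TRUE, text = "
trait env irr upl diff percent
plant_height irrigated 89.5 116.1 26.6 29.7
tiller_number irrigated 9.8 8.7 1.1 11.2
root_weight irrigated 12.8 17.2 4.4 34.4
root_length irrigated 24.1 27.2 3.1 12.9
grain_weight irrigated 23.8 25.9 2.1 8.8
panicles irrigated 11.0 9.6 1.4 12.7
filled_grain irrigated 124.2 129.8 5.6 4.5
empty_grain irrigated 31.0 31.4 0.4 1.3
plant_height upland 81.2 103.9 22.7 28.0
tiller_number upland 1.5 1.3 0.2 13.3
root_weight upland 1.8 2.4 0.6 33.3
root_length upland 23.5 29.9 6.4 27.2
grain_weight upland 23.4 25.6 2.2 9.4
filled_grain upland 33.3 40.5 7.2 21.6
empty_grain upland 26.3 18.9 7.4 28.1
")
  df
}

# Between-environment cells (irrigated condition -> dry-land condition),
# per ecotype, with the printed signed difference and percentage.
phenotypeEnvironmentCells <- function() {
  read.table(header = TRUE, text = "
trait ecotype env1 env2 diff percent
plant_height irrigated 89.5 81.2 -8.3 -9.3
plant_height upland 116.1 103.9 -12.2 -10.5
tiller_number irrigated 9.8 1.5 -8.3 -84.7
tiller_number upland 8.7 1.3 -7.4 -85.1
root_weight irrigated 12.8 1.8 -11.0 -85.9
root_weight upland 17.2 2.4 -14.8 -86.0
root_length irrigated 24.1 23.5 -0.6 -2.5
root_length upland 27.2 29.9 2.7 9.9
grain_weight irrigated 23.8 23.4 -0.4 -1.7
grain_weight upland 25.9 25.6 -0.3 -1.2
panicles irrigated 11.0 1.5 -9.5 -86.4
filled_grain irrigated 124.2 33.3 -90.9 -73.2
filled_grain upland 129.8 40.5 -89.3 -68.8
empty_grain irrigated 31.0 26.3 -4.7 -15.2
empty_grain upland 31.4 18.9 -12.5 -39.8
")
}
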