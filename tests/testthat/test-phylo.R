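# F84 distances, neighbor joining and bootstrap consensus.

# Build a hom-only pair of "sequences" in dosage encoding from two base
# vectors: ref = first sequence's base, alt = the other base where they
# differ (arbitrary different base where they agree).
pairToDosage <- function(seq1, seq2) {
  n <- length(seq1)
  ref <- seq1
  alt <- ifelse(seq1 == seq2,
                vapply(seq1, function(b)
                  sample(setdiff(c("A", "C", "G", "T"), b), 1), ""),
                seq2)
  list(d1 = rep(2L, n), d2 = ifelse(seq1 == seq2, 2L, 0L),
       ref = ref, alt = alt)
}

test_that("identical sequences have distance zero; small divergence is near p", {
  set.seed(1)
  s <- sample(c("A", "C", "G", "T"), 1000, TRUE)
  pd <- pairToDosage(s, s)
  expect_equal(f84Distance(pd$d1, pd$d2, pd$ref, pd$alt)$distance, 0)
  # 1% divergence: F84 distance within 5% of the p-distance
  s2 <- s
  idx <- sample(1000, 10)
  s2[idx] <- vapply(s[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  pd2 <- pairToDosage(s, s2)
  d <- f84Distance(pd2$d1, pd2$d2, pd2$ref, pd2$alt)$distance
  expect_lt(abs(d - 0.01) / 0.01, 0.05)
})

test_that("F84 distance agrees exactly with the reference implementation in ape", {
  set.seed(3)
  for (rep in 1:3) {
    s1 <- sample(c("A", "C", "G", "T"), 1500, TRUE)
    s2 <- s1
    idx <- sample(1500, 120)
    s2[idx] <- vapply(s1[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    pd <- pairToDosage(s1, s2)
    own <- f84Distance(pd$d1, pd$d2, pd$ref, pd$alt)$distance
    bin <- ape::as.DNAbin(rbind(a = tolower(s1), b = tolower(s2)))
    ref <- as.numeric(ape::dist.dna(bin, model = "F84",
                                    pairwise.deletion = TRUE))
    expect_equal(own, ref, tolerance = 1e-10)
  }
})

test_that("sequences evolved under F84 at distance 0.1 are estimated within 0.02", {
  # independent simulate-then-estimate oracle: build the F84 rate matrix,
  # exponentiate to the transition matrix at the target distance, sample.
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  pi <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  kappa <- 2
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) for (j in bases) {
    if (i == j) next
    ts <- (i %in% c("A", "G") && j %in% c("A", "G")) ||
      (i %in% c("C", "T") && j %in% c("C", "T"))
    grp <- if (j %in% c("A", "G")) piR else piY
    Q[i, j] <- pi[j] * (1 + if (ts) kappa / grp else 0)
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  P <- as.matrix(Matrix::expm(Q * 0.1))
  n <- 20000
  s1 <- sample(bases, n, TRUE, prob = pi)
  s2 <- vapply(s1, function(b) sample(bases, 1, prob = P[b, ]), "")
  pd <- pairToDosage(s1, s2)
  d <- f84Distance(pd$d1, pd$d2, pd$ref, pd$alt)$distance
  expect_lt(abs(d - 0.1), 0.02)
})

test_that("heterozygotes contribute fractionally to the mismatch proportions", {
  # one sample hom ref, the other het at every site: expected mismatch 1/2
  n <- 400
  ref <- rep("A", n); alt <- rep("G", n)
  r <- f84Distance(rep(2L, n), rep(1L, n), ref, alt)
  expect_equal(r$P + r$Q, 0.5)
})

test_that("zero shared sites yields a flagged undefined distance", {
  r <- f84Distance(c(NA, NA, 2L), c(1L, 1L, NA),
                   rep("A", 3), rep("G", 3))
  expect_true(is.na(r$distance))
  expect_equal(r$nShared, 0)
})

test_that("NJ recovers additive four-taxon matrices exactly", {
  # quartet ((a:2,b:3):3,(c:4,d:4)) -> hand-solved additive distances
  dm <- matrix(c(0, 5, 9, 9,
                 5, 0, 10, 10,
                 9, 10, 0, 8,
                 9, 10, 8, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(dm)
  expect_setequal(round(tr$edge.length, 10), c(2, 3, 3, 4, 4))
  # topology: a and b form a cherry
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  cherries <- lapply(pp, function(x) sort(labs[x]))
  hasCherry <- function(pair)
    any(vapply(cherries, function(x) identical(x, pair), logical(1)))
  expect_true(hasCherry(c("a", "b")) || hasCherry(c("c", "d")))
  # tree distances reproduce the input exactly (additivity)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[letters[1:4], letters[1:4]],
               dm, tolerance = 1e-10)
})

test_that("three taxa give the closed-form star and small inputs error", {
  dm <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- njTree(dm)
  # closed form: x = (d_xy + d_xz - d_yz)/2 = 1, y = 3, z = 5
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("x", "y", "z")]), c(1, 3, 5))
  expect_error(njTree(dm[1:2, 1:2]), "at least 3")
})

test_that("identical samples form a zero-length cherry", {
  d <- randomDosage(80, 5, missing = 0, seed = 2)
  d <- cbind(d, d[, 5])                          # duplicate the last sample
  colnames(d) <- paste0("s", 1:6)
  ge <- GenotypeExperiment(d, chrom = "chr1", pos = seq_len(80) * 10L,
                           ref = rep("A", 80), alt = rep("G", 80),
                           population = rep("upland", 6))
  dm <- f84DistanceMatrix(ge)
  expect_equal(dm["s5", "s6"], 0)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
})

test_that("bootstrap consensus recovers a clear population split with high support", {
  cfg <- simConfig(nPop1 = 8, nPop2 = 8, nSnps = 400, nChrom = 1,
                   chromLength = 1e5, fstBackground = 0.5,
                   missingRate = 0.1, seed = 31)
  sim <- simulateFrequencies(cfg)
  gm <- simulateGenotypeMatrix(sim)
  bc <- bootstrapConsensus(gm$genotypes, replicates = 50, seed = 5)
  expect_true(all(bc$consensus$node.label <= 100))
  # the upland/irrigated bipartition is present with high support
  up <- paste0("UP", 1:8)
  freq <- sum(vapply(bc$trees, hasBipartition, logical(1), grp = up))
  expect_gte(100 * freq / 50, 95)
  # and it is retained in the strict-majority consensus
  expect_true(hasBipartition(bc$consensus, up))
  # determinism and the single-replicate convention
  bc2 <- bootstrapConsensus(gm$genotypes, replicates = 50, seed = 5)
  expect_equal(ape::write.tree(bc$consensus), ape::write.tree(bc2$consensus))
  one <- bootstrapConsensus(gm$genotypes, replicates = 1, seed = 5)
  expect_equal(length(one$trees), 1L)
  expect_equal(one$consensus$tip.label, one$trees[[1]]$tip.label)
})
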