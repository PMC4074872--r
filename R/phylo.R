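## F84 pairwise distances from SNP dosages, neighbor-joining trees, and
## bootstrap consensus with bipartition supports.
##
## Each sample's genotype at a biallelic site is treated as an unordered
## pair of bases: homozygotes contribute their base with weight 1,
## heterozygotes contribute both alleles with weight 1/2 (the fractional
## reading of an IUPAC ambiguity code). Distances use pairwise deletion:
## only sites non-missing in both samples enter a pair's computation.

## Expected mismatch weight between two diploid genotypes at a biallelic
## site, and the per-pair transition/transversion split.
.isTransition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' F84 distance between two samples' SNP genotypes
#'
#' Computes the closed-form F84 distance from the expected proportions of
#' transition (`P`) and transversion (`Q`) differences over shared
#' (pairwise non-missing) sites, with base frequencies estimated
#' empirically from those same sites. Heterozygous genotypes contribute
#' fractionally (each allele with weight 1/2). With `piR = piA + piG`,
#' `piY = piC + piT`, `A = piA piG / piR + piC piT / piY`,
#' `B = piA piG + piC piT`, `C = piR piY`:
#' `d = -2A log(1 - P/(2A) - (A - B) Q / (2 A C)) +
#'      2 (A - B - C) log(1 - Q / (2 C))`.
#'
#' @param dosI,dosJ integer dosage vectors (0/1/2/NA) for the two samples.
#' @param ref,alt site alleles (single characters).
#' @param weights optional non-negative site weights (used by the
#'   bootstrap); default 1.
#' @param minShared minimum number of shared sites; below it the distance
#'   is `NA`.
#' @return list with `distance`, `nShared`, `P`, `Q`.
#' @export
f84Distance <- function(dosI, dosJ, ref, alt, weights = NULL,
                        minShared = 1) {
  if (is.null(weights)) weights <- rep(1, length(dosI))
  shared <- !is.na(dosI) & !is.na(dosJ) & weights > 0
  w <- weights[shared]
  nShared <- sum(w)
  if (sum(shared) < minShared || nShared <= 0)
    return(list(distance = NA_real_, nShared = sum(shared),
                P = NA_real_, Q = NA_real_))
  di <- dosI[shared] / 2      # reference-allele fraction for sample i
  dj <- dosJ[shared] / 2
  # allele-sharing mismatch: identical genotypes contribute 0, opposite
  # homozygotes 1, heterozygote-vs-homozygote 1/2
  mism <- abs(di - dj)
  ts <- .isTransition(ref[shared], alt[shared])
  P <- sum(w * mism * ts) / nShared
  Q <- sum(w * mism * !ts) / nShared
  # empirical base composition over shared sites (both samples)
  bases <- c("A", "C", "G", "T")
  comp <- (di + dj) / 2
  pi <- vapply(bases, function(b) {
    sum(w * (comp * (ref[shared] == b) + (1 - comp) * (alt[shared] == b)))
  }, numeric(1)) / nShared
  pi <- pmax(pi, 1e-6)
  pi <- pi / sum(pi)
  d <- .f84FromPQ(P, Q, pi)
  list(distance = d, nShared = sum(shared), P = P, Q = Q)
}

## Closed-form F84 distance from observed P (transitions), Q
## (transversions) and base frequencies pi (A, C, G, T).
.f84FromPQ <- function(P, Q, pi) {
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  A <- pi["A"] * pi["G"] / piR + pi["C"] * pi["T"] / piY
  B <- pi["A"] * pi["G"] + pi["C"] * pi["T"]
  C <- piR * piY
  x <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  y <- 1 - Q / (2 * C)
  if (is.na(x) || is.na(y) || x <= 0 || y <= 0) return(NA_real_)
  unname(-2 * A * log(x) + 2 * (A - B - C) * log(y))
}

#' All-pairs F84 distance matrix
#'
#' @param ge a [GenotypeExperiment-class].
#' @param weights optional site weights (bootstrap resampling).
#' @param minShared minimum shared sites per pair; pairs below it get
#'   `NA` and are reported in the `flagged` attribute.
#' @return symmetric numeric matrix with zero diagonal; attribute
#'   `nShared` holds the per-pair shared-site counts.
#' @export
f84DistanceMatrix <- function(ge, weights = NULL, minShared = 1) {
  d <- dosage(ge)
  rr <- sites(ge)
  ref <- rr$ref; alt <- rr$alt
  n <- ncol(d)
  out <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
  ns <- matrix(0L, n, n, dimnames = dimnames(out))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- f84Distance(d[, i], d[, j], ref, alt, weights, minShared)
      out[i, j] <- out[j, i] <- r$distance
      ns[i, j] <- ns[j, i] <- r$nShared
    }
  }
  attr(out, "nShared") <- ns
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with the deficit moved to the parent branch so path lengths are
#' approximately preserved.
#'
#' @param dm symmetric distance matrix (>= 3 taxa, no `NA`).
#' @return an unrooted `phylo` tree.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(is.na(dm))) stop("distance matrix contains NA")
  tr <- ape::nj(as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- which(tr$edge[, 2] == tr$edge[e, 1])
    if (length(parent) == 1)
      tr$edge.length[parent] <- max(0, tr$edge.length[parent] + deficit)
  }
  tr
}

#' Bootstrap neighbor-joining consensus tree
#'
#' Resamples sites with replacement `replicates` times, recomputes the F84
#' distance matrix and NJ tree per replicate, and returns the
#' strict-majority consensus: bipartitions present in more than half of
#' the replicate trees, treated as unrooted. Node labels carry the
#' bootstrap support as a percentage in \[0, 100\].
#'
#' @param ge a [GenotypeExperiment-class] with at least 10 sites.
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed integer seed for the resampling.
#' @return list with `consensus` (a `phylo` with `node.label` supports)
#'   and `trees` (the replicate trees, a `multiPhylo`).
#' @export
bootstrapConsensus <- function(ge, replicates = 100, seed = 1) {
  nSites <- nrow(ge)
  if (nSites < 10) stop("bootstrap needs at least 10 sites")
  set.seed(seed)
  trees <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    w <- as.numeric(rmultinom(1, nSites, rep(1 / nSites, nSites)))
    dm <- f84DistanceMatrix(ge, weights = w)
    if (any(is.na(dm))) {
      mx <- max(dm, na.rm = TRUE)
      dm[is.na(dm)] <- mx * 1.1
      warning("replicate ", b, ": undefined distances replaced by maximum")
    }
    tr <- njTree(dm)
    # root every replicate at the same tip so that rooted clade
    # representations agree across trees; the consensus is still reported
    # as (and interpreted as) unrooted
    trees[[b]] <- ape::root(tr, outgroup = tr$tip.label[1],
                            resolve.root = TRUE)
  }
  class(trees) <- "multiPhylo"
  if (replicates == 1) {
    cons <- trees[[1]]
    cons$node.label <- rep(100, cons$Nnode)
    return(list(consensus = cons, trees = trees))
  }
  # strict majority: a bipartition must appear in > 50% of replicates
  pStrict <- 0.5 + 1 / (2 * replicates)
  cons <- ape::consensus(trees, p = pStrict, check.labels = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- replicates
  cons$node.label <- round(100 * counts / replicates)
  list(consensus = cons, trees = trees)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm symmetric matrix with taxon names.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePhylipDist <- function(dm, path) {
  dm <- as.matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    nm <- formatC(substr(rownames(dm)[i], 1, 10), width = -10)
    writeLines(paste0(nm, paste(sprintf("%.6f", dm[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}
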