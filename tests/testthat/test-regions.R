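# Top-quantile region calling, EDR intersection, EDS identification and
# EDG assignment.

test_that("top-quantile threshold selects exactly the k largest plus ties", {
  set.seed(2)
  v <- runif(1000)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq(1, by = 2000,
                                                    length.out = 1000),
                                                width = 2000),
                               value = v)
  reg <- callTopRegions(gr, quantile = 0.005, mergeGap = 0)
  thr <- S4Vectors::metadata(reg)$threshold
  expect_equal(thr, sort(v, decreasing = TRUE)[5])     # brute-force sort
  expect_equal(sum(v >= thr), 5)
  # all-equal values: everything ties at the threshold and is called
  grTie <- gr
  grTie$value <- rep(1, 1000)
  regTie <- callTopRegions(grTie, quantile = 0.005, mergeGap = 0)
  expect_equal(sum(BiocGenerics::width(regTie)), 1000 * 2000)
})

test_that("consecutive significant windows merge into one region", {
  # three overlapping 20-kb windows, 2-kb step, clearly above the rest
  starts <- seq(1, by = 2000, length.out = 600)
  v <- rep(0.1, 600); v[c(100, 101, 102)] <- 0.9
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 20000),
                               value = v)
  reg <- callTopRegions(gr, quantile = 3 / 600, mergeGap = 2000)
  expect_equal(length(reg), 1)
  expect_equal(BiocGenerics::start(reg), starts[100])
  expect_equal(BiocGenerics::end(reg), starts[102] + 20000 - 1)
})

test_that("EDR intersection equals a per-base bitmap oracle", {
  expect_equal(length(intersectToEdrs(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300)))), 0)
  got <- intersectToEdrs(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 300)))
  expect_equal(BiocGenerics::start(got), 150)
  expect_equal(BiocGenerics::end(got), 200)
  set.seed(4)
  for (rep in 1:5) {
    mk <- function() {
      s <- sort(sample.int(1000, 8))
      GenomicRanges::reduce(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s, s + sample.int(80, 8))))
    }
    a <- mk(); b <- mk()
    got <- intersectToEdrs(a, b)
    bitmap <- function(gr) {
      x <- logical(2000)
      for (i in seq_along(gr))
        x[BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]] <- TRUE
      x
    }
    want <- bitmap(a) & bitmap(b)
    gotBase <- logical(2000)
    for (i in seq_along(got))
      gotBase[BiocGenerics::start(got)[i]:BiocGenerics::end(got)[i]] <- TRUE
    expect_identical(gotBase, want)
  }
})

test_that("EDS calling applies region gating and the strict 60% rule", {
  freqs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100L, 150L, 200L, 500L), width = 1),
    p1 = c(0.9, 0.6, 0.5, 0.95), p2 = c(0.2, 0.0, 0.4, 0.05))
  edrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 300))
  eds <- identifyEds(freqs, edrs, minDiff = 0.6)
  # site 1: diff 0.7 in region -> EDS; site 2: diff exactly 0.6 -> excluded;
  # site 3: small diff; site 4: diff 0.9 but outside the region
  expect_equal(BiocGenerics::start(eds), 100)
  expect_equal(eds$diff, 0.7)
  # brute-force recount over region-contained SNPs
  inR <- IRanges::overlapsAny(freqs, edrs)
  expect_equal(length(eds),
               sum(inR & abs(freqs$p1 - freqs$p2) > 0.6))
})

test_that("EDG assignment classifies genic and 1-kb flank EDSs", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(5000L, 20000L, 40000L), width = 2000),
    gene_id = c("gA", "gB", "gC"))
  edrs <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(4000L, 19000L, 39000L),
                                                  width = 5000))
  # gA: EDS inside gene; gB: EDS 999 bp upstream; gC: EDS 1001 bp upstream
  eds <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(6000L, 19001L, 38999L), width = 1),
    p1 = 1, p2 = 0)
  edgs <- assignEdgs(edrs, genes, eds, flank = 1000)
  expect_equal(edgs$gene_id, c("gA", "gB", "gC"))
  expect_equal(edgs$edsClass, c("genic", "flank", "none"))
  # chromosome naming mismatch is refused
  genes2 <- GenomicRanges::GRanges("1", IRanges::IRanges(5000, 7000),
                                   gene_id = "gX")
  expect_error(assignEdgs(edrs, genes2, eds), "chromosome")
})

test_that("EDS-to-gene classes match a brute-force distance oracle", {
  set.seed(11)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1000, by = 5000, length.out = 20),
                             width = 2000),
    gene_id = paste0("g", 1:20))
  edrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200000))
  eds <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sort(sample.int(105000, 30)), width = 1),
    p1 = 1, p2 = 0)
  edgs <- assignEdgs(edrs, genes, eds, flank = 1000)
  for (i in seq_along(edgs)) {
    dmin <- min(abs(pmax(BiocGenerics::start(edgs)[i] -
                           BiocGenerics::start(eds), 0) +
                    pmax(BiocGenerics::start(eds) -
                           BiocGenerics::end(edgs)[i], 0)))
    want <- if (dmin == 0) "genic" else if (dmin <= 1000) "flank" else "none"
    expect_equal(edgs$edsClass[i], want)
  }
})

test_that("coordinate conversions are exact inverse pairs", {
  expect_equal(toBedCoords(1001, 2000), data.frame(start = 1000L, end = 2000))
  expect_equal(fromBedCoords(1000, 2000), data.frame(start = 1001L, end = 2000))
  set.seed(5)
  s <- sample.int(1e6, 50); e <- s + sample.int(1e4, 50)
  bed <- toBedCoords(s, e)
  back <- fromBedCoords(bed$start, bed$end)
  expect_equal(back$start, s)
  expect_equal(back$end, e)
})
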