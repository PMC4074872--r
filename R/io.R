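## File interfaces: VCF genotypes, GFF3/BED annotation, newick trees, and
## the TSV tables passed between pipeline stages. Coordinates are 1-based
## inclusive everywhere except BED output (0-based half-open).

#' Write genotypes as a VCF v4.2 file
#'
#' Serializes a [GenotypeExperiment-class] as plain-text VCF with
#' biallelic records and a single `GT` FORMAT field; missing genotypes
#' are `./.`. Dosages map to genotypes on the reference-allele scale
#' (2 = `0/0`, 1 = `0/1`, 0 = `1/1`). Population labels are recorded in
#' `##SAMPLE` header lines so a round trip preserves them.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
writeVcfGenotypes <- function(ge, path) {
  rr <- sites(ge)
  d <- dosage(ge)
  pops <- populations(ge)
  gtMap <- c("1/1", "0/1", "0/0")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtMap[d[ok] + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=EcotypeScan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               sprintf("##SAMPLE=<ID=%s,Population=%s>",
                       names(pops), unname(pops)),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(d)),
                     collapse = "\t")), con)
  body <- cbind(as.character(GenomicRanges::seqnames(rr)),
                BiocGenerics::start(rr),
                names(rr), rr$ref, rr$alt, ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNP records, converts
#' `GT` to reference-allele dosages (`.` missing) and attaches population
#' labels from `##SAMPLE` header lines or an explicit assignment table.
#'
#' @param path VCF file (plain or gzipped).
#' @param populations optional named character vector (sample ->
#'   population), overriding header `##SAMPLE` lines.
#' @return a [GenotypeExperiment-class].
#' @export
readVcfGenotypes <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"])
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  alt <- gsub("[|]", "/", gt)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[alt == "0/0"] <- 2L
  dos[alt %in% c("0/1", "1/0")] <- 1L
  dos[alt == "1/1"] <- 0L
  if (is.null(populations)) {
    meta <- v@meta
    sampleLines <- grep("^##SAMPLE=", meta, value = TRUE)
    if (length(sampleLines)) {
      id <- sub('.*ID=([^,>]+).*', "\\1", sampleLines)
      pop <- sub('.*Population=([^,>]+).*', "\\1", sampleLines)
      populations <- setNames(pop, id)
    } else {
      populations <- setNames(rep("unknown", ncol(gt)), colnames(gt))
    }
  }
  GenotypeExperiment(dos,
                     chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     population = populations[colnames(gt)],
                     sampleNames = colnames(gt))
}

#' Read gene models from GFF3 (or BED)
#'
#' Imports via \pkg{rtracklayer}; for GFF3, rows of type `gene` are kept
#' and `gene_id` is taken from the `ID` attribute.
#'
#' @param path GFF3 or BED file (format chosen by extension).
#' @return `GRanges` with a `gene_id` column.
#' @export
readGenes <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc)) gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  gr$gene_id <- if ("ID" %in% names(mc)) as.character(gr$ID)
    else if ("name" %in% names(mc)) as.character(gr$name)
    else paste0("gene", seq_along(gr))
  gr
}

#' Write gene models as GFF3
#'
#' @param genes `GRanges` with `gene_id`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGenesGff3 <- function(genes, path) {
  out <- genes
  S4Vectors::mcols(out) <- NULL
  out$source <- "EcotypeScan"
  out$type <- "gene"
  out$ID <- genes$gene_id
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Write regions as a BED file (0-based half-open)
#'
#' @param regions `GRanges` (1-based inclusive, as used internally).
#' @param path output path.
#' @param names optional names column.
#' @return the path, invisibly.
#' @export
writeBedRegions <- function(regions, path, names = NULL) {
  bed <- toBedCoords(BiocGenerics::start(regions), BiocGenerics::end(regions))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = bed$start, end = bed$end)
  if (!is.null(names)) df$name <- names
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive GRanges
#'
#' @param path BED path.
#' @return `GRanges`.
#' @export
readBedRegions <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write / read a site-frequency table
#'
#' TSV with columns `chrom`, `pos`, `p1`, `n1`, `mask1`, `p2`, `n2`,
#' `mask2`, the interface between the genotyping and scan stages.
#'
#' @param freqs `GRanges` from [alleleFrequencies()].
#' @param path TSV path.
#' @return `writeFrequencyTsv`: the path invisibly; `readFrequencyTsv`:
#'   the `GRanges`.
#' @export
writeFrequencyTsv <- function(freqs, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(freqs)),
                   pos = BiocGenerics::start(freqs),
                   as.data.frame(S4Vectors::mcols(freqs)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrequencyTsv
#' @export
readFrequencyTsv <- function(path) {
  df <- read.delim(path)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L))
  for (cl in setdiff(names(df), c("chrom", "pos")))
    S4Vectors::mcols(gr)[[cl]] <- df[[cl]]
  names(gr) <- paste(df$chrom, df$pos, sep = ":")
  gr
}

#' Read and write newick trees
#'
#' Thin wrappers over \pkg{ape}'s newick support, preserving branch
#' lengths and integer node supports.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `writeNewick`: the path invisibly; `readNewick`: a `phylo`.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  ape::read.tree(path)
}

#' Read a phenotype TSV
#'
#' Expects columns `accession`, `ecotype`, `environment`, `trait`,
#' `value`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPhenotypeTsv <- function(path) {
  .checkPhenotypeTable(read.delim(path))
}
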