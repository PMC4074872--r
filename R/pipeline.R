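## Pipeline orchestration: one configuration object holding every stage
## parameter at its published default, and a driver that runs
## genotyping -> FST scan -> cross-population scan -> EDR/EDS/EDG calling
## -> per-population sweep scans -> EDG population assignment ->
## enrichment, writing a checksummed output manifest.

#' Pipeline configuration
#'
#' All stage parameters with their standard defaults: 20-kb FST windows
#' sliding by 2 kb, top-5-per-mille quantiles for both differentiation
#' scans, a 0.1-cM / 2-kb-grid / 150-SNP cross-population scan, a 1-kb
#' grid and top-5% quantile with a 10-kb gene flank for the
#' single-population sweep scan, allele-frequency masking at more than 10
#' called individuals per population, a more-than-100-sample subset for
#' structure, an EDS allele-frequency differential of 0.6, a 1-kb EDG
#' flank, 100 bootstrap replicates and at most 10000 EM iterations.
#'
#' @param ... overrides of the defaults listed above.
#' @return a named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    window = 20000, step = 2000,
    fstQuantile = 0.005,
    xpclrWindowCM = 0.1, xpclrGrid = 2000, xpclrMaxSnps = 150,
    xpclrQuantile = 0.005,
    recRate = 4,
    clrGrid = 1000, clrQuantile = 0.05, geneFlank = 10000,
    edsMinDiff = 0.6, edgFlank = 1000,
    minCalled = 10, structureMinCalled = 100,
    bootstrapReplicates = 100, emMaxIter = 10000,
    seed = 1)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless.
#'
#' @param config a [pipelineConfig()] list.
#' @param path YAML file path.
#' @return `writePipelineConfig`: the path invisibly;
#'   `readPipelineConfig`: the configuration.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the full ecotype-differentiation pipeline
#'
#' Executes, on a genotype table with two population labels: allele
#' frequency estimation with masking, the windowed Nei FST scan, the
#' cross-population composite-likelihood scan, top-quantile region
#' calling for both, their intersection into ecotype differentiated
#' regions (EDRs), EDS and EDG identification, per-population
#' single-population sweep scans with gene selection, EDG population
#' assignment, and (when categories are supplied) chi-square enrichment.
#' All stage outputs are written under `outDir` together with a
#' `manifest.json` listing the effective configuration and an MD5
#' checksum per output file; runs are deterministic given the
#' configuration.
#'
#' @param ge a [GenotypeExperiment-class] (populations `upland` /
#'   `irrigated`), or a VCF path readable by [readVcfGenotypes()].
#' @param genes `GRanges` with `gene_id`, or a GFF3/BED path.
#' @param categories optional data.frame (`gene_id`, `category`).
#' @param outDir output directory (created).
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with `freqs`, `fstWindows`, `xpclrScores`,
#'   `fstRegions`, `xpclrRegions`, `edrs`, `eds`, `edgs`, `sweeps` (per
#'   population), `assignment`, `enrichment`, `manifest`.
#' @export
runPipeline <- function(ge, genes, categories = NULL,
                        outDir = tempfile("ecotypescan"),
                        config = pipelineConfig()) {
  if (is.character(ge)) {
    if (!file.exists(ge)) stop("genotype input not found: ", ge)
    ge <- readVcfGenotypes(ge)
  }
  if (is.character(genes)) {
    if (!file.exists(genes)) stop("gene annotation not found: ", genes)
    genes <- readGenes(genes)
  }
  gChrom <- unique(as.character(GenomicRanges::seqnames(genes)))
  sChrom <- unique(as.character(GenomicRanges::seqnames(sites(ge))))
  if (!any(gChrom %in% sChrom))
    stop("chromosome names differ between genotypes (",
         paste(sChrom, collapse = ","), ") and genes (",
         paste(gChrom, collapse = ","), ")")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  freqs <- stage("allele_frequencies",
                 alleleFrequencies(ge, minCalled = config$minCalled))
  fstWin <- stage("fst_scan",
                  fstWindowScan(freqs, window = config$window,
                                step = config$step))
  xp <- stage("xpclr_scan",
              xpclrScan(freqs, gridStep = config$xpclrGrid,
                        windowCM = config$xpclrWindowCM,
                        maxSnps = config$xpclrMaxSnps,
                        recRate = config$recRate))
  fstReg <- stage("fst_regions",
                  callTopRegions(fstWin, quantile = config$fstQuantile,
                                 mergeGap = config$step))
  xpReg <- stage("xpclr_regions",
                 callTopRegions(xp, quantile = config$xpclrQuantile,
                                mergeGap = config$xpclrGrid,
                                expand = config$xpclrGrid %/% 2,
                                column = "score"))
  edrs <- stage("edr_intersection", intersectToEdrs(fstReg, xpReg, freqs))
  eds <- stage("eds", identifyEds(freqs, edrs, minDiff = config$edsMinDiff))
  edgs <- stage("edg", assignEdgs(edrs, genes, eds, flank = config$edgFlank))

  sweeps <- list()
  for (popIdx in 1:2) {
    popName <- c("upland", "irrigated")[popIdx]
    p <- S4Vectors::mcols(freqs)[[paste0("p", popIdx)]]
    fr <- freqs
    S4Vectors::mcols(fr)$p <- p
    sweeps[[popName]] <- stage(paste0("clr_", popName), {
      bg <- backgroundSfs(p)
      sc <- clrScan(fr, bg, gridStep = config$clrGrid)
      callSweepRegions(sc, quantile = config$clrQuantile,
                       geneFlank = config$geneFlank, genes = genes)
    })
  }
  assignment <- stage("edg_assignment",
                      assignEdgPopulation(edgs$gene_id,
                                          sweeps$upland$genes,
                                          sweeps$irrigated$genes))
  enr <- NULL
  if (!is.null(categories) && length(edgs))
    enr <- stage("enrichment",
                 enrichmentTest(edgs$gene_id, categories, genes$gene_id))

  # outputs + manifest
  paths <- c(
    frequencies = writeFrequencyTsv(freqs, file.path(outDir, "frequencies.tsv")),
    fst_windows = {
      f <- file.path(outDir, "fst_windows.tsv")
      write.table(as.data.frame(fstWin), f, sep = "\t", quote = FALSE,
                  row.names = FALSE); f
    },
    xpclr_scores = {
      f <- file.path(outDir, "xpclr_scores.tsv")
      write.table(as.data.frame(xp), f, sep = "\t", quote = FALSE,
                  row.names = FALSE); f
    },
    edrs = writeBedRegions(edrs, file.path(outDir, "edrs.bed")),
    eds = writeFrequencyTsv(eds, file.path(outDir, "eds.tsv")),
    edgs = {
      f <- file.path(outDir, "edgs.tsv")
      write.table(as.data.frame(edgs), f, sep = "\t", quote = FALSE,
                  row.names = FALSE); f
    },
    sweep_regions_upland = writeBedRegions(
      sweeps$upland$regions, file.path(outDir, "sweeps_upland.bed")),
    sweep_regions_irrigated = writeBedRegions(
      sweeps$irrigated$regions, file.path(outDir, "sweeps_irrigated.bed")),
    edg_assignment = {
      f <- file.path(outDir, "edg_assignment.tsv")
      write.table(assignment, f, sep = "\t", quote = FALSE,
                  row.names = FALSE); f
    })
  if (!is.null(enr)) {
    f <- file.path(outDir, "enrichment.tsv")
    write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["enrichment"] <- f
  }
  manifest <- list(config = unclass(config),
                   outputs = lapply(seq_along(paths), function(i)
                     list(name = names(paths)[i],
                          file = basename(paths[i]),
                          md5 = unname(tools::md5sum(paths[i])))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(freqs = freqs, fstWindows = fstWin, xpclrScores = xp,
                 fstRegions = fstReg, xpclrRegions = xpReg, edrs = edrs,
                 eds = eds, edgs = edgs, sweeps = sweeps,
                 assignment = assignment, enrichment = enr,
                 outDir = outDir, manifest = manifest))
}
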