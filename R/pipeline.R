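## End-to-end orchestration on a synthetic experiment: simulate ->
## call peaks -> consolidate -> compare conditions -> metagene ->
## dynamic methylation -> differential expression -> integration ->
## motif windows and k-mer enrichment -> validation against ground
## truth.  Deterministic under the config seed.

#' Run the full MeRIP-seq analysis pipeline on synthetic data
#'
#' Generates a synthetic experiment from `config`, then runs every
#' downstream stage with the package defaults (overlap fraction 0.5,
#' fold change 2, P 0.05, top 1000 motif peaks at P < 1e-5, 101-nt
#' windows).  When `outdir` is given, summary tables and a manifest
#' (parameters, file checksums, package version) are written there.
#'
#' @param config a [simulationConfig()].
#' @param outdir optional output directory for summary TSVs/manifest.
#' @param callerParams optional [peakCallerParams()]; by default the
#'   effective background size is the simulated genome size, so the
#'   global rate acts as a uniform floor and the transcriptome
#'   structure of the background comes from the input track.
#' @param minOverlapFraction overlap threshold for consolidation and
#'   common/unique classification (default 0.5).
#' @param topN number of top peaks for motif windows (default 1000).
#' @param verbose emit progress messages (default FALSE).
#' @return a list with all stage results; see Details in the vignette.
#' @export
runPipeline <- function(config = simulationConfig(), outdir = NULL,
                        callerParams = NULL, minOverlapFraction = 0.5,
                        topN = 1000, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  lines <- config$lines

  say("simulating transcriptome and MeRIP libraries")
  txome <- simulateTranscriptome(config)
  merip <- simulateMerip(config, txome)
  td <- txData(txome$models)
  if (is.null(callerParams))
    callerParams <- peakCallerParams(
      effectiveSize = sum(as.numeric(txome$seqlengths)))

  say("calling peaks per replicate")
  replicatePeaks <- list()
  for (ln in lines) {
    replicatePeaks[[ln]] <- lapply(seq_len(config$replicates), function(r)
      callPeaks(merip$coverage[[ln]][[r]]$ip,
                merip$coverage[[ln]][[r]]$input, callerParams,
                sample_id = sprintf("%s_r%d", ln, r), line = ln))
  }

  say("consolidating recurrent peaks and comparing conditions")
  recurrent <- lapply(replicatePeaks, consolidateRecurrent,
                      minFraction = minOverlapFraction)
  comparison <- classifyCommonUnique(recurrent[[lines[1L]]],
                                     recurrent[[lines[2L]]],
                                     minFraction = minOverlapFraction)

  say("metagene profiling and methylation summaries")
  st <- txome$segmented
  assignments <- lapply(recurrent, assignPeaksToTranscripts,
                        models = txome$models)
  profiles <- pies <- ppt <- methSummary <- list()
  for (ln in lines) {
    profiles[[ln]] <- suppressWarnings(
      metageneProfile(recurrent[[ln]], st, assignments[[ln]]))
    pies[[ln]] <- segmentPie(profiles[[ln]])
    ppt[[ln]] <- peaksPerTranscript(recurrent[[ln]], txome$models,
                                    assignments[[ln]])
    methSummary[[ln]] <- methylationSummary(recurrent[[ln]], txome$models,
                                            assignments[[ln]])
  }

  say("line-dynamic methylation on common peaks")
  commonPeaks <- comparison$common_a
  dyn <- dynGenes <- dynSummary <- NULL
  if (length(commonPeaks) >= 2L) {
    ## count in summit-centred core windows: equal-width intervals
    ## avoid diluting the condition effect with peak-flank baseline
    core <- GRanges(seqnames(commonPeaks),
                    IRanges(mcols(commonPeaks)$summit - 75L,
                            mcols(commonPeaks)$summit + 74L))
    countMat <- function(ln) vapply(seq_len(config$replicates),
      function(r) countCoverageInRegions(merip$coverage[[ln]][[r]]$ip,
                                         core),
      numeric(length(core)))
    cA <- countMat(lines[1L]); cB <- countMat(lines[2L])
    rownames(cA) <- rownames(cB) <- mcols(commonPeaks)$name %||%
      paste0("common_", seq_along(commonPeaks))
    dyn <- dynamicPeaks(cA, cB)
    hostA <- .peakHostTranscript(st, assignPeaksToTranscripts(
      commonPeaks, txome$models))
    geneOf <- rep(NA_character_, length(commonPeaks))
    geneOf[hostA$peak] <- hostA$gene_id
    keep <- !is.na(geneOf)
    dynGenes <- dynamicGeneDirections(dyn[keep, , drop = FALSE],
                                      geneOf[keep])
    dynSummary <- dynamicPeakSummary(dyn)
  }

  say("differential expression and integration")
  de <- diffExpression(merip$fpkm$input[[lines[1L]]],
                       merip$fpkm$input[[lines[2L]]])
  quad <- if (!is.null(dynGenes)) quadrantClassify(dynGenes, de) else NULL
  correlations <- lapply(merip$records, function(rec) list(
    binned = expressionMethylationCorrelation(rec, "binned"),
    gene = expressionMethylationCorrelation(rec, "gene")))

  say("motif windows and k-mer enrichment")
  motif <- list()
  for (ln in lines) {
    top <- suppressWarnings(selectTopPeaks(recurrent[[ln]], n = topN))
    if (length(top) == 0L) { motif[[ln]] <- NULL; next }
    host <- .peakHostTranscript(st, assignPeaksToTranscripts(
      top, txome$models))
    str <- rep("*", length(top))
    str[host$peak] <- td$strand[match(host$transcript_id,
                                      td$transcript_id)]
    strand(top) <- str
    windows <- extractWindows(top, txome$genome)
    controls <- shuffleControls(windows, seed = config$seed + 101L)
    motif[[ln]] <- list(
      n_windows = length(windows),
      enrichment = kmerEnrichment(windows, controls,
                                  motifs = c("GGACU", "RRACH")))
  }

  say("validating peak calls against ground truth")
  truthGr <- with(merip$truth$sites,
                  GRanges(chrom, IRanges(start, end), strand = "*"))
  validation <- lapply(recurrent, peakFdrRecall, truth = truthGr)

  out <- list(config = config, txome = txome, merip = merip,
              callerParams = callerParams,
              replicatePeaks = replicatePeaks, recurrent = recurrent,
              comparison = comparison, profiles = profiles, pies = pies,
              peaksPerTranscript = ppt, methylationSummary = methSummary,
              dynamic = dyn, dynamicSummary = dynSummary,
              dynamicGenes = dynGenes, diffExpression = de,
              quadrants = quad, correlations = correlations,
              motif = motif, validation = validation)
  if (!is.null(outdir)) .writePipelineOutputs(out, outdir)
  out
}

#' @noRd
.writePipelineOutputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  lines <- res$config$lines
  for (ln in lines) {
    writePeaksBED(res$recurrent[[ln]], fp(sprintf("recurrent_%s.bed", ln)))
    profileToTable(res$profiles[[ln]],
                   fp(sprintf("metagene_%s.tsv", ln)))
  }
  writePeaksBED(res$comparison$common_a, fp("common_peaks.bed"))
  writePeaksBED(res$comparison$unique_a,
                fp(sprintf("unique_%s.bed", lines[1L])))
  writePeaksBED(res$comparison$unique_b,
                fp(sprintf("unique_%s.bed", lines[2L])))
  summ <- do.call(rbind, res$methylationSummary)
  summ <- cbind(line = rownames(summ), summ)
  write.table(summ, fp("methylation_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$dynamic))
    write.table(res$dynamic, fp("dynamic_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(res$diffExpression, fp("diff_expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$quadrants))
    write.table(res$quadrants$calls, fp("quadrants.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  for (ln in lines)
    if (!is.null(res$motif[[ln]]))
      write.table(res$motif[[ln]]$enrichment,
                  fp(sprintf("motif_enrichment_%s.tsv", ln)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("meripr")),
    seed = res$config$seed,
    parameters = list(
      min_overlap_fraction = res$comparison$minFraction,
      p_threshold = res$callerParams$pThreshold,
      fc_threshold = res$callerParams$fcThreshold,
      effective_size = res$callerParams$effectiveSize),
    files = as.list(setNames(unname(tools::md5sum(files)),
                             basename(files))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
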