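## Expression/methylation integration: FPKM, the per-gene m6A
## enrichment level NNFPKM = FPKM_IP / FPKM_INPUT, the log2 Pearson
## correlation of expression with enrichment, quadrant classification
## of dynamic genes, summary ratios and gene-set over-representation.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = fragments * 1e9 / (transcript_length * total_fragments)`.
#'
#' @param fragments fragment counts.
#' @param transcriptLength transcript length(s) in nt (> 0).
#' @param totalFragments library size (> 0).
#' @return numeric FPKM values.
#' @examples
#' fpkm(100, 1000, 1e6)   # 100
#' @export
fpkm <- function(fragments, transcriptLength, totalFragments) {
  if (any(transcriptLength <= 0)) stop("transcript length must be > 0",
                                       call. = FALSE)
  if (any(totalFragments <= 0)) stop("library size must be > 0",
                                     call. = FALSE)
  fragments * 1e9 / (transcriptLength * totalFragments)
}

#' Per-gene expression/methylation records
#'
#' Combines input and IP FPKM into one table with the m6A enrichment
#' level `nnfpkm = fpkm_ip / fpkm_input` (NA, flagged, where
#' `fpkm_input` is 0).
#'
#' @param gene_id gene identifiers.
#' @param fpkm_input,fpkm_ip per-gene FPKM in the input and IP library
#'   (replicate means).
#' @param line optional condition label.
#' @return data.frame with columns `gene_id`, `fpkm_input`, `fpkm_ip`,
#'   `nnfpkm`, `nnfpkm_defined`, `line`.
#' @export
expressionRecords <- function(gene_id, fpkm_input, fpkm_ip,
                              line = NA_character_) {
  if (any(fpkm_input < 0) || any(fpkm_ip < 0))
    stop("FPKM must be >= 0", call. = FALSE)
  defined <- fpkm_input > 0
  data.frame(gene_id = gene_id, fpkm_input = fpkm_input,
             fpkm_ip = fpkm_ip,
             nnfpkm = ifelse(defined, fpkm_ip / fpkm_input, NA_real_),
             nnfpkm_defined = defined, line = line)
}

#' Correlation of mRNA expression with m6A enrichment
#'
#' Pearson correlation of `log2(fpkm_input)` with `log2(nnfpkm)` over
#' genes with both quantities positive.  The default mode averages both
#' axes within `bins` expression-ranked equal-count bins before
#' correlating (the standard way such global methylation/expression
#' trends are displayed); `method = "gene"` correlates the raw
#' gene-level values.
#'
#' @param records an [expressionRecords()] data.frame.
#' @param method `"binned"` (default) or `"gene"`.
#' @param bins number of equal-count bins for the binned mode.
#' @return list with `r`, `p_value`, `n` (genes used) and `method`;
#'   `r` is `NA` (flagged) when fewer than 3 usable genes or a constant
#'   axis remain.
#' @export
expressionMethylationCorrelation <- function(records,
                                             method = c("binned", "gene"),
                                             bins = 50) {
  method <- match.arg(method)
  ok <- records$fpkm_input > 0 & !is.na(records$nnfpkm) & records$nnfpkm > 0
  x <- log2(records$fpkm_input[ok]); y <- log2(records$nnfpkm[ok])
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n, method = method,
                flagged = TRUE))
  if (method == "binned") {
    nb <- min(bins, n)
    grp <- ceiling(rank(x, ties.method = "first") / (n / nb))
    x <- as.numeric(tapply(x, grp, mean))
    y <- as.numeric(tapply(y, grp, mean))
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
      return(list(r = NA_real_, p_value = NA_real_, n = n, method = method,
                  flagged = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = method, flagged = FALSE)
}

#' Quadrant classification of dynamic m6A genes
#'
#' Intersects gene-level dynamic methylation directions (high/low in
#' condition B, see [dynamicGeneDirections()]) with differential
#' expression directions (up/down in B).  A gene enters only when both
#' calls are made; the four labels are hyper-up, hyper-down, hypo-up
#' and hypo-down (hyper = high m6A in B).
#'
#' @param dynamicGenes data.frame with `gene_id` and `direction`
#'   (`high`/`low`), e.g. from [dynamicGeneDirections()].
#' @param de a [diffExpression()] result (uses rows with direction
#'   `up`/`down`).
#' @return list with `calls` (gene_id, m6a_direction, expr_direction,
#'   label) and `summary`: quadrant counts, `n_dynamic_genes`,
#'   `n_intersect`, `expressed_different_percent` (share of dynamic
#'   genes with an expression call, half-up to 1 decimal),
#'   `hyper_up_percent` and `hypo_down_percent` (integer percents of
#'   concordant calls within the hyper and hypo classes),
#'   `discordant_percent` (integer percent of hyper-down + hypo-up) and
#'   `concordant_fraction`.
#' @export
quadrantClassify <- function(dynamicGenes, de) {
  stopifnot(all(c("gene_id", "direction") %in% colnames(dynamicGenes)))
  dyn <- dynamicGenes[dynamicGenes$direction %in% c("high", "low"), ,
                      drop = FALSE]
  dex <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  common <- intersect(dyn$gene_id, dex$gene_id)
  m6a <- dyn$direction[match(common, dyn$gene_id)]
  expr <- dex$direction[match(common, dex$gene_id)]
  m6aLab <- ifelse(m6a == "high", "hyper", "hypo")
  label <- paste(m6aLab, expr, sep = "-")
  calls <- data.frame(gene_id = common, m6a_direction = m6aLab,
                      expr_direction = expr, label = label)
  quad <- setNames(
    vapply(c("hyper-up", "hyper-down", "hypo-up", "hypo-down"),
           function(l) sum(label == l), integer(1)),
    c("hyper-up", "hyper-down", "hypo-up", "hypo-down"))
  nInt <- length(common)
  nHyper <- quad[["hyper-up"]] + quad[["hyper-down"]]
  nHypo <- quad[["hypo-up"]] + quad[["hypo-down"]]
  nDisc <- quad[["hyper-down"]] + quad[["hypo-up"]]
  summary <- list(
    quadrants = quad,
    n_dynamic_genes = nrow(dyn),
    n_intersect = nInt,
    expressed_different_percent =
      if (nrow(dyn)) roundHalfUp(100 * nInt / nrow(dyn), 1) else NA_real_,
    hyper_up_percent =
      if (nHyper) roundHalfUp(100 * quad[["hyper-up"]] / nHyper) else NA_real_,
    hypo_down_percent =
      if (nHypo) roundHalfUp(100 * quad[["hypo-down"]] / nHypo) else NA_real_,
    discordant_percent =
      if (nInt) roundHalfUp(100 * nDisc / nInt) else NA_real_,
    concordant_fraction =
      if (nInt) (quad[["hyper-up"]] + quad[["hypo-down"]]) / nInt
      else NA_real_)
  list(calls = calls, summary = summary)
}

#' Methylation summary ratios from raw counts
#'
#' The worked-example arithmetic behind a per-condition summary row:
#' peaks per methylated transcript and per transcript (half-up, 2
#' decimals) and the percentage of methylated transcripts (half-up,
#' integer).
#'
#' @param nTranscripts,nMethylated,nPeaks the three counts.
#' @return list with `peaks_per_methylated_transcript`,
#'   `peaks_per_transcript` and `percent_methylated`.
#' @examples
#' methylationSummaryFromCounts(5965, 4615, 7097)
#' @export
methylationSummaryFromCounts <- function(nTranscripts, nMethylated, nPeaks) {
  stopifnot(nTranscripts > 0, nMethylated > 0)
  list(peaks_per_methylated_transcript = roundHalfUp(nPeaks / nMethylated, 2),
       peaks_per_transcript = roundHalfUp(nPeaks / nTranscripts, 2),
       percent_methylated = roundHalfUp(100 * nMethylated / nTranscripts))
}

#' Methylation summary for a peak set
#'
#' Counts representative transcripts, methylated transcripts and
#' assigned peaks (via [peaksPerTranscript()]) and reports the summary
#' ratios of [methylationSummaryFromCounts()].
#'
#' @param peaks a peak [GRanges].
#' @param models a [TranscriptModels-class].
#' @param assignment optional precomputed assignment table.
#' @return one-row data.frame with the counts and rounded ratios.
#' @export
methylationSummary <- function(peaks, models, assignment = NULL) {
  ppt <- peaksPerTranscript(peaks, models, assignment)
  ratios <- methylationSummaryFromCounts(ppt$n_transcripts,
                                         max(1L, ppt$n_methylated),
                                         ppt$n_peaks)
  data.frame(n_transcripts = ppt$n_transcripts,
             n_methylated = ppt$n_methylated,
             n_peaks = ppt$n_peaks,
             peaks_per_methylated_transcript =
               if (ppt$n_methylated) ratios$peaks_per_methylated_transcript
               else NA_real_,
             peaks_per_transcript = ratios$peaks_per_transcript,
             percent_methylated =
               roundHalfUp(100 * ppt$n_methylated / ppt$n_transcripts))
}

#' Read gene sets from a GMT-like TSV
#'
#' One set per line: set id, description, then member genes,
#' tab-separated.
#'
#' @param path path to the file.
#' @return named list of character vectors (names = set ids, with a
#'   `description` attribute each).
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields",
                             call. = FALSE)
    genes <- unique(f[-(1:2)])
    attr(genes, "description") <- f[2L]
    out[[f[1L]]] <- genes
  }
  out
}

#' Gene-set over-representation (hypergeometric test)
#'
#' Upper-tail hypergeometric p-value per set for the overlap between
#' `hits` and each set, both intersected with `universe`.  Sets with
#' fewer than 2 universe members are skipped.
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param universe character vector of all considered genes.
#' @param geneSets named list of character vectors (e.g. [readGMT()]).
#' @param alpha significance threshold for the flag column (0.05).
#' @return data.frame with set id, set size (in universe), overlap,
#'   `p_value` and `significant`.
#' @export
genesetOverrepresentation <- function(hits, universe, geneSets,
                                      alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  hits <- unique(hits)
  if (!all(hits %in% universe))
    stop("hits must be a subset of the universe", call. = FALSE)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], universe)
    if (length(set) < 2L) return(NULL)
    ov <- length(intersect(set, hits))
    p <- phyper(ov - 1L, length(set), length(universe) - length(set),
                length(hits), lower.tail = FALSE)
    data.frame(set_id = nm, set_size = length(set), n_hits = length(hits),
               overlap = ov, p_value = p, significant = p < alpha)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(set_id = character(), set_size = integer(),
                      n_hits = integer(), overlap = integer(),
                      p_value = numeric(), significant = logical()))
  do.call(rbind, rows)
}
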