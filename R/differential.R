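## Line-dynamic methylation on common peaks (G-test on normalized
## pooled fragment counts) and differential expression on input
## libraries (Welch t on log2 FPKM).  Thresholds follow the raw
## fold-change >= 2 and P < 0.05 convention; a BH-adjusted column is
## emitted for users but plays no part in the calls.

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: per column, the median ratio to the
#' row-wise geometric mean, over rows where that mean is finite.
#'
#' @param counts numeric matrix (features x samples).
#' @return numeric vector of size factors (geometric mean 1 scale).
#' @export
sizeFactorsMOR <- function(counts) {
  counts <- as.matrix(counts)
  logGeo <- rowMeans(log(counts))
  ok <- is.finite(logGeo)
  if (!any(ok)) {
    warning("no feature with all-positive counts; size factors set to 1",
            call. = FALSE)
    return(setNames(rep(1, ncol(counts)), colnames(counts)))
  }
  sf <- apply(counts[ok, , drop = FALSE], 2L, function(cnt)
    exp(median(log(cnt) - logGeo[ok])))
  setNames(sf, colnames(counts))
}

#' Line-dynamic methylation calls on common peaks
#'
#' Per common peak, replicate IP fragment counts from the two
#' conditions are scaled by size factors (median-of-ratios over the
#' common-peak matrix unless `sizeFactors` is supplied, e.g. library
#' sizes) and pooled per condition.  The test statistic is the G-test
#' with 1 df on the pooled normalized counts `(O_A, O_B)` against the
#' expected equal split (by replicate count; normalization equalises
#' the per-replicate mass): `G = 2 * sum(O * log(O / E))`.  The fold change is the ratio of
#' normalized replicate means with a 0.5 pseudocount.  A peak is called
#' `high` (higher in B) when `log2fc >= log2(fcThreshold)` and
#' `p < pThreshold`, `low` symmetrically, otherwise `ns`.
#'
#' @param countsA,countsB numeric matrices (peaks x replicates) of IP
#'   fragment counts in the common peak intervals.
#' @param sizeFactors optional length `ncol(countsA) + ncol(countsB)`
#'   normalization factors (A replicates first); counts are divided by
#'   them.
#' @param fcThreshold,pThreshold call thresholds (defaults 2 and 0.05).
#' @param peakIds peak identifiers (default rownames of `countsA`).
#' @return data.frame with per-peak normalized means, `log2fc` (B over
#'   A), `G`, `p_value`, BH-adjusted `padj`, `direction` in
#'   `{high, low, ns}` and a `zero` flag for all-zero peaks.
#' @export
dynamicPeaks <- function(countsA, countsB, sizeFactors = NULL,
                         fcThreshold = 2, pThreshold = 0.05,
                         peakIds = NULL) {
  countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
  stopifnot(nrow(countsA) == nrow(countsB),
            ncol(countsA) >= 2L, ncol(countsB) >= 2L)
  nA <- ncol(countsA); nB <- ncol(countsB)
  if (is.null(peakIds))
    peakIds <- rownames(countsA) %||% paste0("peak_", seq_len(nrow(countsA)))
  mat <- cbind(countsA, countsB)
  if (is.null(sizeFactors)) {
    ## two-pass normalization: an asymmetric share of truly dynamic
    ## peaks contaminates the median ratio, so refit the factors on
    ## peaks that look non-dynamic under the first pass
    sizeFactors <- sizeFactorsMOR(mat)
    norm0 <- sweep(mat, 2L, sizeFactors, "/")
    lfc0 <- log2((rowMeans(norm0[, nA + seq_len(nB), drop = FALSE]) + 0.5) /
                   (rowMeans(norm0[, seq_len(nA), drop = FALSE]) + 0.5))
    stable <- abs(lfc0) < log2(fcThreshold)
    if (sum(stable) >= 20L)
      sizeFactors <- suppressWarnings(
        sizeFactorsMOR(mat[stable, , drop = FALSE]))
  }
  stopifnot(length(sizeFactors) == nA + nB, all(sizeFactors > 0))
  norm <- sweep(mat, 2L, sizeFactors, "/")
  normA <- norm[, seq_len(nA), drop = FALSE]
  normB <- norm[, nA + seq_len(nB), drop = FALSE]

  oA <- rowSums(normA); oB <- rowSums(normB)
  ## after normalization every replicate carries the same expected
  ## mass, so the null splits the pooled total by replicate count
  shareA <- nA / (nA + nB)
  tot <- oA + oB
  eA <- tot * shareA; eB <- tot * (1 - shareA)
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  G <- 2 * (term(oA, eA) + term(oB, eB))
  p <- pchisq(G, df = 1L, lower.tail = FALSE)
  zero <- tot == 0
  p[zero] <- 1; G[zero] <- 0

  mA <- rowMeans(normA); mB <- rowMeans(normB)
  log2fc <- log2((mB + 0.5) / (mA + 0.5))
  lfcT <- log2(fcThreshold)
  direction <- rep("ns", length(p))
  direction[!zero & p < pThreshold & log2fc >= lfcT] <- "high"
  direction[!zero & p < pThreshold & log2fc <= -lfcT] <- "low"
  data.frame(peak_id = peakIds, mean_norm_a = mA, mean_norm_b = mB,
             log2fc = log2fc, G = G, p_value = p,
             padj = p.adjust(p, "BH"), direction = direction,
             zero = zero, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary of line-dynamic peak calls
#'
#' @param results a [dynamicPeaks()] result (or any data.frame with a
#'   `direction` column over `{high, low, ns}`).
#' @return list with `n_tested`, `n_dynamic`, `n_high`, `n_low` and
#'   `low_share_percent` (share of dynamic peaks lower in condition B,
#'   rounded half-up to 1 decimal).
#' @export
dynamicPeakSummary <- function(results) {
  nH <- sum(results$direction == "high")
  nL <- sum(results$direction == "low")
  nD <- nH + nL
  list(n_tested = nrow(results), n_dynamic = nD, n_high = nH, n_low = nL,
       low_share_percent = if (nD > 0) roundHalfUp(100 * nL / nD, 1)
                           else NA_real_)
}

#' Gene-level dynamic methylation directions
#'
#' Aggregates per-peak dynamic calls to genes.  Genes whose dynamic
#' peaks all agree get that direction; genes with conflicting high/low
#' peaks are excluded (reported via the `n_conflicts` attribute).
#'
#' @param results a [dynamicPeaks()] result.
#' @param geneIds gene id per row of `results`.
#' @return data.frame (`gene_id`, `direction`) over genes with at least
#'   one dynamic peak and no conflict; attribute `n_conflicts` counts
#'   excluded genes.
#' @export
dynamicGeneDirections <- function(results, geneIds) {
  stopifnot(length(geneIds) == nrow(results))
  dyn <- results$direction != "ns"
  if (!any(dyn)) {
    out <- data.frame(gene_id = character(), direction = character())
    attr(out, "n_conflicts") <- 0L
    return(out)
  }
  tb <- table(geneIds[dyn], results$direction[dyn])
  hasH <- tb[, intersect("high", colnames(tb)), drop = FALSE]
  hasL <- tb[, intersect("low", colnames(tb)), drop = FALSE]
  nH <- if (ncol(hasH)) hasH[, 1L] else rep(0L, nrow(tb))
  nL <- if (ncol(hasL)) hasL[, 1L] else rep(0L, nrow(tb))
  conflict <- nH > 0 & nL > 0
  out <- data.frame(gene_id = rownames(tb)[!conflict],
                    direction = ifelse(nH[!conflict] > 0, "high", "low"))
  attr(out, "n_conflicts") <- sum(conflict)
  out
}

#' Differential expression between conditions
#'
#' Welch t-test on `log2(FPKM + 1)` across replicates; the fold change
#' is the ratio of FPKM means with a pseudocount of 1.  A small
#' variance guard (`eps`) prevents zero-variance blowups; genes with
#' identical replicate vectors in both conditions get `p = 1`.  Genes
#' present in only one table are treated as FPKM 0 in the other.
#'
#' @param fpkmA,fpkmB numeric matrices (genes x replicates, >= 2
#'   replicates) of FPKM values, rows named by gene.
#' @param fcThreshold,pThreshold call thresholds (defaults 2 and 0.05).
#' @param eps variance guard added to each group variance.
#' @return data.frame with per-gene means, `log2fc` (B over A), `t`,
#'   `p_value`, BH-adjusted `padj` and `direction` in `{up, down, ns}`.
#' @export
diffExpression <- function(fpkmA, fpkmB, fcThreshold = 2,
                           pThreshold = 0.05, eps = 1e-8) {
  fpkmA <- as.matrix(fpkmA); fpkmB <- as.matrix(fpkmB)
  stopifnot(ncol(fpkmA) >= 2L, ncol(fpkmB) >= 2L)
  genes <- union(rownames(fpkmA), rownames(fpkmB))
  if (is.null(genes))
    stop("FPKM matrices must have gene rownames", call. = FALSE)
  align <- function(m) {
    out <- matrix(0, length(genes), ncol(m),
                  dimnames = list(genes, colnames(m)))
    i <- intersect(genes, rownames(m))
    out[i, ] <- m[i, ]
    out
  }
  A <- align(fpkmA); B <- align(fpkmB)
  if (any(A < 0) || any(B < 0)) stop("FPKM must be >= 0", call. = FALSE)
  xA <- log2(A + 1); xB <- log2(B + 1)
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  vA <- apply(xA, 1L, var); vB <- apply(xB, 1L, var)
  se2 <- vA / nA + vB / nB + eps
  tstat <- (mB - mA) / sqrt(se2)
  df <- se2^2 / ((vA / nA + eps / 2)^2 / (nA - 1) +
                   (vB / nB + eps / 2)^2 / (nB - 1))
  p <- 2 * pt(-abs(tstat), df)
  same <- vA == 0 & vB == 0 & mA == mB
  p[same] <- 1; tstat[same] <- 0

  fc <- (rowMeans(B) + 1) / (rowMeans(A) + 1)
  log2fc <- log2(fc)
  lfcT <- log2(fcThreshold)
  direction <- rep("ns", length(p))
  direction[p < pThreshold & log2fc >= lfcT] <- "up"
  direction[p < pThreshold & log2fc <= -lfcT] <- "down"
  data.frame(gene_id = genes, mean_fpkm_a = rowMeans(A),
             mean_fpkm_b = rowMeans(B), log2fc = log2fc, t = tstat,
             p_value = p, padj = p.adjust(p, "BH"),
             direction = direction, row.names = NULL)
}
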