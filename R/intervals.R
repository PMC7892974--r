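## Peak sets are GRanges with metadata columns summit, fold_change,
## p_value, sample_id, line.  This module owns peak I/O and the
## fraction-overlap set algebra: replicate-recurrent consolidation and
## common/unique classification between conditions.

#' Construct or sanitise a peak GRanges
#'
#' Ensures the metadata columns `summit` (genomic position, defaults to
#' the interval midpoint), `fold_change` (> 0, default 1), `p_value`
#' (in \[0,1\], default 1), `sample_id` and `line` are present and valid.
#'
#' @param gr a [GRanges] of peak intervals.
#' @param sample_id,line optional labels recycled over the peaks.
#' @return the validated [GRanges].
#' @export
m6aPeaks <- function(gr, sample_id = NULL, line = NULL) {
  stopifnot(is(gr, "GRanges"))
  if (length(gr) == 0L) {
    mcols(gr) <- DataFrame(summit = integer(0), fold_change = numeric(0),
                           p_value = numeric(0), sample_id = character(0),
                           line = character(0))
    return(gr)
  }
  mc <- mcols(gr)
  if (is.null(mc$summit))
    mc$summit <- as.integer(floor((start(gr) + end(gr)) / 2))
  if (is.null(mc$fold_change)) mc$fold_change <- 1
  if (is.null(mc$p_value)) mc$p_value <- 1
  if (!is.null(sample_id)) mc$sample_id <- rep(sample_id, length.out = length(gr))
  if (is.null(mc$sample_id)) mc$sample_id <- NA_character_
  if (!is.null(line)) mc$line <- rep(line, length.out = length(gr))
  if (is.null(mc$line)) mc$line <- NA_character_
  mcols(gr) <- mc
  if (length(gr)) {
    if (any(mc$summit < start(gr) | mc$summit > end(gr)))
      stop("peak summit outside its interval", call. = FALSE)
    if (any(mc$fold_change <= 0)) stop("fold_change must be > 0", call. = FALSE)
    if (any(mc$p_value < 0 | mc$p_value > 1))
      stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  gr
}

#' Read peaks from a BED6+ file
#'
#' Columns 1-6 are standard BED (0-based half-open, converted to the
#' 1-based closed GRanges convention); optional columns 7-8 carry the
#' enrichment fold change and p-value, optional column 9 the summit
#' (0-based genomic position).  Missing columns 7-8 default to 1 with a
#' warning; a missing summit defaults to the interval midpoint.
#'
#' @param path path to a BED file.
#' @param sample_id,line optional provenance labels.
#' @return a peak [GRanges] (see [m6aPeaks()]).
#' @export
readPeaksBED <- function(path, sample_id = NULL, line = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               colClasses = "character"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("BED parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (is.null(df) || nrow(df) == 0L)
    return(m6aPeaks(GRanges(), sample_id, line))
  if (ncol(df) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  s0 <- as.numeric(df[[2L]]); e0 <- as.numeric(df[[3L]])
  bad <- which(!(s0 < e0))
  if (length(bad))
    stop(sprintf("invalid interval (start >= end) at line %d of %s",
                 bad[1L], path), call. = FALSE)
  gr <- GRanges(df[[1L]], IRanges(s0 + 1L, e0),
                strand = if (ncol(df) >= 6L) df[[6L]] else "*")
  mcols(gr)$name <- if (ncol(df) >= 4L) df[[4L]] else
    paste0("peak_", seq_len(nrow(df)))
  mcols(gr)$score <- if (ncol(df) >= 5L) as.numeric(df[[5L]]) else 0
  if (ncol(df) >= 8L) {
    mcols(gr)$fold_change <- as.numeric(df[[7L]])
    mcols(gr)$p_value <- as.numeric(df[[8L]])
  } else {
    warning("BED lacks fold_change/p_value columns; defaulting to 1",
            call. = FALSE)
  }
  if (ncol(df) >= 9L) mcols(gr)$summit <- as.integer(df[[9L]]) + 1L
  m6aPeaks(gr, sample_id, line)
}

#' Write peaks as BED6+2(+1)
#'
#' Inverse of [readPeaksBED()]: writes chrom, 0-based start, end, name,
#' score, strand, fold_change, p_value and (if `summit = TRUE`) the
#' 0-based summit position.
#'
#' @param peaks a peak [GRanges].
#' @param path output path.
#' @param summit also write the summit as column 9 (default TRUE).
#' @return (invisibly) the output path.
#' @export
writePeaksBED <- function(peaks, path, summit = TRUE) {
  peaks <- m6aPeaks(peaks)
  if (length(peaks) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  nm <- mcols(peaks)$name
  if (is.null(nm)) nm <- paste0("peak_", seq_along(peaks))
  sc <- mcols(peaks)$score
  if (is.null(sc)) sc <- 0
  df <- data.frame(
    chrom = as.character(seqnames(peaks)), start = start(peaks) - 1L,
    end = end(peaks), name = nm, score = sc,
    strand = as.character(strand(peaks)),
    fold_change = mcols(peaks)$fold_change,
    p_value = mcols(peaks)$p_value)
  if (summit) df$summit <- mcols(peaks)$summit - 1L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Fraction of overlap between two intervals
#'
#' Pairwise overlap fraction between parallel (recycled) [GRanges].
#' With the default `basis = "shorter"` the overlap length is divided
#' by the length of the shorter interval, which makes the relation
#' symmetric; `"a"` divides by the length of the first interval
#' (bedtools `-f` semantics) and `"reciprocal"` takes the minimum of
#' both one-sided fractions.  Intervals on different sequences overlap
#' by 0; strand is ignored.
#'
#' @param a,b parallel [GRanges] vectors (length-1 arguments recycle).
#' @param basis denominator rule, see above.
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 250))
#' overlapFraction(a, b)   # 0.5
#' @export
overlapFraction <- function(a, b, basis = c("shorter", "a", "reciprocal")) {
  basis <- match.arg(basis)
  n <- max(length(a), length(b))
  if (n == 0L) return(numeric(0))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  ov <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  wa <- width(a); wb <- width(b)
  switch(basis,
         shorter = ov / pmin(wa, wb),
         a = ov / wa,
         reciprocal = pmin(ov / wa, ov / wb))
}

#' Consolidate replicate peak sets into recurrent peaks
#'
#' A recurrent peak is a chain of peaks, at most one per replicate and
#' covering at least `minReplicates` replicates, in which every pair of
#' members overlaps by at least `minFraction` (see [overlapFraction()]).
#' Only maximal chains qualify (no peak of an uncovered replicate is
#' compatible with all members).  Candidate chains are ordered by the
#' coordinates of their member intersection (then decreasing size) and
#' accepted greedily so that each input peak supports at most one
#' recurrent peak.  The emitted peak is the intersection of its
#' members, with summit the (rounded) median of member summits, fold
#' change the mean and p-value the minimum over members.
#'
#' @param replicatePeaks list (length >= 2) of peak [GRanges], one per
#'   replicate.
#' @param minFraction pairwise overlap fraction threshold (default 0.5).
#' @param minReplicates minimum number of replicates per chain;
#'   default all replicates.
#' @param basis overlap fraction basis, see [overlapFraction()].
#' @return a coordinate-sorted recurrent peak [GRanges] with an extra
#'   `n_replicates` column.
#' @export
consolidateRecurrent <- function(replicatePeaks, minFraction = 0.5,
                                 minReplicates = length(replicatePeaks),
                                 basis = "shorter") {
  stopifnot(is.list(replicatePeaks), length(replicatePeaks) >= 2L)
  nrep <- length(replicatePeaks)
  replicatePeaks <- lapply(replicatePeaks, m6aPeaks)
  sizes <- lengths(replicatePeaks)
  if (any(sizes == 0L) && minReplicates >= nrep) {
    warning("a replicate has no peaks; no recurrent peaks possible",
            call. = FALSE)
    return(m6aPeaks(GRanges(), sample_id = "recurrent"))
  }
  pool <- suppressWarnings(do.call(c, unname(replicatePeaks)))
  strand(pool) <- "*"
  repid <- rep(seq_len(nrep), sizes)
  if (length(pool) == 0L) return(m6aPeaks(GRanges(), sample_id = "recurrent"))

  red <- reduce(pool, ignore.strand = TRUE)
  comp <- subjectHits(findOverlaps(pool, red, ignore.strand = TRUE))

  cand <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) > 40L)
      warning("overlap component with ", length(idx),
              " peaks; consolidation may be slow", call. = FALSE)
    cand <- c(cand, .enumerateChains(pool, repid, idx, minFraction,
                                     minReplicates, basis))
  }
  if (length(cand) == 0L) return(m6aPeaks(GRanges(), sample_id = "recurrent"))

  istart <- vapply(cand, function(ch) max(start(pool)[ch]), numeric(1))
  iend <- vapply(cand, function(ch) min(end(pool)[ch]), numeric(1))
  seqid <- vapply(cand, function(ch) as.character(seqnames(pool)[ch[1L]]),
                  character(1))
  ord <- order(seqid, istart, iend, -lengths(cand))
  used <- logical(length(pool))
  keep <- integer(0)
  for (k in ord) {
    if (!any(used[cand[[k]]])) {
      keep <- c(keep, k)
      used[cand[[k]]] <- TRUE
    }
  }
  if (length(keep) == 0L) return(m6aPeaks(GRanges(), sample_id = "recurrent"))

  sm <- mcols(pool)$summit; fc <- mcols(pool)$fold_change
  pv <- mcols(pool)$p_value; ln <- mcols(pool)$line
  out <- GRanges(seqid[keep], IRanges(istart[keep], iend[keep]),
                 strand = "*")
  mcols(out) <- DataFrame(
    summit = vapply(cand[keep], function(ch)
      as.integer(round(median(sm[ch]))), integer(1)),
    fold_change = vapply(cand[keep], function(ch) mean(fc[ch]), numeric(1)),
    p_value = vapply(cand[keep], function(ch) min(pv[ch]), numeric(1)),
    sample_id = "recurrent",
    line = vapply(cand[keep], function(ch) {
      u <- unique(ln[ch]); if (length(u) == 1L) u else NA_character_
    }, character(1)),
    n_replicates = lengths(cand[keep]))
  ## clamp summit into the (smaller) intersection interval
  mcols(out)$summit <- pmin(pmax(mcols(out)$summit, start(out)), end(out))
  sort(out, ignore.strand = TRUE)
}

## All maximal pairwise-compatible chains within one overlap component.
#' @noRd
.enumerateChains <- function(pool, repid, idx, minFraction, minReplicates,
                             basis) {
  reps <- sort(unique(repid[idx]))
  byrep <- split(idx, repid[idx])
  chains <- list()
  compat <- function(p, chosen) {
    all(overlapFraction(pool[rep(p, length(chosen))], pool[chosen],
                        basis = basis) >= minFraction)
  }
  recur <- function(ri, chosen) {
    if (ri > length(reps)) {
      if (length(chosen) >= minReplicates)
        chains[[length(chains) + 1L]] <<- chosen
      return(invisible())
    }
    cands <- byrep[[as.character(reps[ri])]]
    ok <- cands[vapply(cands, compat, logical(1), chosen = chosen)]
    for (p in ok) recur(ri + 1L, c(chosen, p))
    recur(ri + 1L, chosen)            # skip this replicate
    invisible()
  }
  recur(1L, integer(0))
  if (length(chains) == 0L) return(list())
  ## keep maximal chains only
  maximal <- vapply(chains, function(ch) {
    absent <- setdiff(reps, repid[ch])
    for (r in absent) {
      cands <- byrep[[as.character(r)]]
      if (any(vapply(cands, compat, logical(1), chosen = ch))) return(FALSE)
    }
    TRUE
  }, logical(1))
  chains[maximal]
}

#' Classify peaks as common or condition-unique
#'
#' A peak of set A is *common* when at least one peak of set B overlaps
#' it by `minFraction` or more; otherwise it is *unique* to A
#' (symmetrically for B).  Matching is non-exclusive: one B peak may
#' certify several A peaks.  Each matched peak records its best-overlap
#' partner (ties broken towards the leftmost partner).
#'
#' @param peaksA,peaksB consolidated peak [GRanges] for the two
#'   conditions.
#' @param minFraction overlap fraction threshold (default 0.5).
#' @param basis overlap fraction basis, see [overlapFraction()].
#' @return a list with elements `pairs` (DataFrame of all qualifying
#'   `(a, b, fraction)` index pairs plus best-partner flags),
#'   `common_a`, `unique_a`, `common_b`, `unique_b` (peak GRanges) and
#'   `summary` (named counts; `n_pairs` is symmetric in A/B).
#' @export
classifyCommonUnique <- function(peaksA, peaksB, minFraction = 0.5,
                                 basis = "shorter") {
  peaksA <- m6aPeaks(peaksA); peaksB <- m6aPeaks(peaksB)
  hits <- findOverlaps(peaksA, peaksB, ignore.strand = TRUE)
  frac <- overlapFraction(peaksA[queryHits(hits)], peaksB[subjectHits(hits)],
                          basis = basis)
  ok <- frac >= minFraction
  qa <- queryHits(hits)[ok]; qb <- subjectHits(hits)[ok]; fr <- frac[ok]
  pairs <- DataFrame(a = qa, b = qb, fraction = fr)
  ## best partner per matched A peak: highest fraction, ties leftmost B
  if (nrow(pairs)) {
    orda <- order(pairs$a, -pairs$fraction, start(peaksB)[pairs$b])
    pairs$best_for_a <- FALSE
    pairs$best_for_a[orda[!duplicated(pairs$a[orda])]] <- TRUE
    ordb <- order(pairs$b, -pairs$fraction, start(peaksA)[pairs$a])
    pairs$best_for_b <- FALSE
    pairs$best_for_b[ordb[!duplicated(pairs$b[ordb])]] <- TRUE
  } else {
    pairs$best_for_a <- logical(0)
    pairs$best_for_b <- logical(0)
  }
  inA <- unique(qa); inB <- unique(qb)
  list(pairs = pairs,
       common_a = peaksA[sort(inA)],
       unique_a = peaksA[setdiff(seq_along(peaksA), inA)],
       common_b = peaksB[sort(inB)],
       unique_b = peaksB[setdiff(seq_along(peaksB), inB)],
       summary = c(n_a = length(peaksA), n_b = length(peaksB),
                   n_pairs = nrow(pairs),
                   n_common_a = length(inA), n_unique_a = length(peaksA) - length(inA),
                   n_common_b = length(inB), n_unique_b = length(peaksB) - length(inB)),
       minFraction = minFraction, basis = basis)
}

#' Assign peaks to transcripts by summit position
#'
#' A peak is assigned to every transcript whose exons contain its
#' summit; peaks whose summit is exonic in no transcript are labelled
#' intergenic (one `NA` row).
#'
#' @param peaks a peak [GRanges].
#' @param models a [TranscriptModels-class] object.
#' @return a [S4Vectors::DataFrame] with columns `peak` (index into
#'   `peaks`), `transcript_id`, `gene_id`, `representative`; intergenic
#'   peaks carry `NA` ids.
#' @export
assignPeaksToTranscripts <- function(peaks, models) {
  peaks <- m6aPeaks(peaks)
  td <- txData(models)
  if (length(peaks) == 0L)
    return(DataFrame(peak = integer(), transcript_id = character(),
                     gene_id = character(), representative = logical()))
  summits <- GRanges(seqnames(peaks),
                     IRanges(mcols(peaks)$summit, width = 1L), strand = "*")
  ex <- unlist(exonsByTranscript(models), use.names = FALSE)
  hits <- findOverlaps(summits, ex, ignore.strand = TRUE)
  txOfExon <- rep(names(exonsByTranscript(models)),
                  lengths(exonsByTranscript(models)))
  out <- DataFrame(peak = queryHits(hits),
                   transcript_id = txOfExon[subjectHits(hits)])
  out <- out[!duplicated(paste(out$peak, out$transcript_id)), , drop = FALSE]
  i <- match(out$transcript_id, td$transcript_id)
  out$gene_id <- td$gene_id[i]
  out$representative <- td$representative[i]
  inter <- setdiff(seq_along(peaks), out$peak)
  if (length(inter))
    out <- rbind(out, DataFrame(peak = inter,
                                transcript_id = NA_character_,
                                gene_id = NA_character_,
                                representative = NA))
  out[order(out$peak), , drop = FALSE]
}
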