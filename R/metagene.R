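## Positional statistics of peaks on transcripts: the 5-segment x
## 20-bin metagene profile, per-segment pie fractions and the
## peaks-per-transcript distribution.  A peak contributes through its
## summit to exactly one bin, so bin counts always sum to the number of
## peaks used.

#' Locate peak summits within a segmented transcript
#'
#' Maps genomic summit positions on one transcript to their metagene
#' segment and 20-bin index (bin 0 is 5'-most within the segment):
#' `bin = floor(20 * offset / segment_length)`, clamped to 19.
#'
#' @param st a [SegmentedTranscripts-class] object.
#' @param tx a transcript id.
#' @param summitPos vector of genomic summit positions.
#' @return a data.frame with columns `segment` (factor; `"exonic"` for
#'   non-coding transcripts, `NA` for non-exonic summits) and `bin`
#'   (0-19, `NA` when no 5x20 scheme applies).
#' @export
locatePeak <- function(st, tx, summitPos) {
  stopifnot(is(st, "SegmentedTranscripts"))
  spos <- splicedPosition(st@models, tx, summitPos)
  b <- segmentBreaks(st)[tx, ]
  labs <- .segmentLabels()
  segment <- rep(NA_character_, length(spos))
  bin <- rep(NA_integer_, length(spos))
  if (anyNA(b)) {                      # non-coding: single exonic region
    segment[!is.na(spos)] <- "exonic"
  } else {
    ok <- which(!is.na(spos))
    if (length(ok)) {
      j <- findInterval(spos[ok], b)
      j <- pmin(j, 5L)
      segment[ok] <- labs[j]
      len <- b[j + 1L] - b[j]
      bin[ok] <- pmin(19L, as.integer((20L * (spos[ok] - b[j])) %/% len))
    }
  }
  data.frame(segment = factor(segment, levels = c(labs, "exonic")),
             bin = bin)
}

## Pick, per peak, a single representative coding transcript from an
## assignment table (first by transcript id).
#' @noRd
.peakHostTranscript <- function(st, assignment) {
  td <- txData(st)
  a <- assignment[!is.na(assignment$transcript_id) &
                    assignment$representative, , drop = FALSE]
  coding <- td$coding[match(a$transcript_id, td$transcript_id)]
  a <- a[coding, , drop = FALSE]
  if (nrow(a) == 0L) return(a)
  ord <- order(a$peak, a$transcript_id)
  a <- a[ord, , drop = FALSE]
  a[!duplicated(a$peak), , drop = FALSE]
}

#' Metagene profile of a peak set
#'
#' Bins each peak, via its summit on its host transcript (the
#' representative coding isoform of the gene; one host per peak), into
#' the 5-segment x 20-bin metagene scheme.
#'
#' @param peaks a peak [GRanges].
#' @param st a [SegmentedTranscripts-class] object.
#' @param assignment optional precomputed [assignPeaksToTranscripts()]
#'   table for `peaks`.
#' @return a [MetageneProfile-class]; peaks with no exonic summit on a
#'   representative coding transcript are not counted.
#' @export
metageneProfile <- function(peaks, st, assignment = NULL) {
  stopifnot(is(st, "SegmentedTranscripts"))
  peaks <- m6aPeaks(peaks)
  if (is.null(assignment))
    assignment <- assignPeaksToTranscripts(peaks, st@models)
  hosts <- .peakHostTranscript(st, assignment)
  counts <- numeric(100L)
  used <- 0L
  if (nrow(hosts)) {
    summit <- mcols(peaks)$summit[hosts$peak]
    for (tx in unique(hosts$transcript_id)) {
      i <- hosts$transcript_id == tx
      loc <- locatePeak(st, tx, summit[i])
      okrow <- !is.na(loc$bin)
      if (!any(okrow)) next
      seg <- as.integer(loc$segment[okrow])     # 1..5
      idx <- (seg - 1L) * 20L + loc$bin[okrow] + 1L
      tab <- tabulate(idx, nbins = 100L)
      counts <- counts + tab
      used <- used + sum(okrow)
    }
  }
  if (used == 0L)
    warning("no usable peaks for the metagene profile", call. = FALSE)
  new("MetageneProfile", counts = counts, nPeaks = as.numeric(used))
}

#' Fraction of peaks per metagene segment
#'
#' @param x either a [MetageneProfile-class] or a peak [GRanges] (then
#'   `st` is required and [metageneProfile()] is run first).
#' @param st a [SegmentedTranscripts-class] (when `x` is peaks).
#' @param ... passed to [metageneProfile()].
#' @return named numeric vector of five fractions summing to 1 (all
#'   `NA` when no peak was usable).
#' @export
segmentPie <- function(x, st = NULL, ...) {
  prof <- if (is(x, "MetageneProfile")) x else metageneProfile(x, st, ...)
  if (prof@nPeaks == 0) {
    out <- setNames(rep(NA_real_, 5L), .segmentLabels())
    return(out)
  }
  tap <- tapply(binCounts(prof), binSegments(prof), sum) / prof@nPeaks
  setNames(as.numeric(tap), .segmentLabels())
}

#' Peaks per transcript statistics
#'
#' Counts assigned peaks per representative transcript.  A transcript
#' with at least one assigned peak is "methylated"; the reported ratios
#' are total peaks / methylated transcripts and total peaks / all
#' transcripts, both rounded half-up to 2 decimals, plus a histogram of
#' per-transcript peak counts over `{1, 2, 3, >=4}`.
#'
#' @param peaks a peak [GRanges].
#' @param models a [TranscriptModels-class].
#' @param assignment optional precomputed [assignPeaksToTranscripts()]
#'   table for `peaks`.
#' @return list with `histogram`, `per_transcript` (named counts),
#'   `n_transcripts`, `n_methylated`, `n_peaks`,
#'   `peaks_per_methylated_transcript` and `peaks_per_transcript`.
#' @export
peaksPerTranscript <- function(peaks, models, assignment = NULL) {
  td <- txData(models)
  reps <- td$transcript_id[td$representative]
  if (length(reps) == 0L) stop("no transcripts", call. = FALSE)
  peaks <- m6aPeaks(peaks)
  if (is.null(assignment))
    assignment <- assignPeaksToTranscripts(peaks, models)
  a <- assignment[!is.na(assignment$transcript_id) &
                    assignment$representative, , drop = FALSE]
  ## one host transcript per peak so each peak counts once
  a <- a[order(a$peak, a$transcript_id), , drop = FALSE]
  a <- a[!duplicated(a$peak), , drop = FALSE]
  perTx <- table(factor(a$transcript_id, levels = reps))
  meth <- perTx[perTx > 0]
  nPeaks <- nrow(a)
  hist <- c(`1` = sum(meth == 1), `2` = sum(meth == 2),
            `3` = sum(meth == 3), `>=4` = sum(meth >= 4))
  list(histogram = hist,
       per_transcript = perTx,
       n_transcripts = length(reps),
       n_methylated = length(meth),
       n_peaks = nPeaks,
       peaks_per_methylated_transcript =
         if (length(meth)) roundHalfUp(nPeaks / length(meth), 2) else NA_real_,
       peaks_per_transcript = roundHalfUp(nPeaks / length(reps), 2))
}

#' Export a metagene profile as a tidy table
#'
#' @param profile a [MetageneProfile-class].
#' @param path optional TSV output path.
#' @return (invisibly) a data.frame with bin index, segment, count and
#'   density columns.
#' @export
profileToTable <- function(profile, path = NULL) {
  df <- data.frame(bin = 0:99,
                   segment = binSegments(profile),
                   segment_bin = rep(0:19, times = 5L),
                   count = binCounts(profile),
                   density = binDensity(profile))
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
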