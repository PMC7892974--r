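## S4 containers.  Peaks are deliberately *not* wrapped in a class: a
## peak set is a GRanges with the metadata columns summit, fold_change,
## p_value, sample_id and line (see validatePeaks()), so the whole
## GenomicRanges toolbox applies to them directly.

#' Transcript models parsed from a GTF
#'
#' Holds one record per transcript: its exon chain (a [GRangesList]
#' named by transcript id, exons sorted by genomic coordinate) and a
#' per-transcript table with gene id, coding status, the genomic
#' coordinates of the leftmost/rightmost CDS base and the spliced
#' length.  One isoform per gene is flagged `representative` (longest
#' CDS, ties broken by spliced length then id); metagene work uses only
#' representative isoforms.
#'
#' @slot exons [GRangesList] of exons, one element per transcript.
#' @slot txdata [S4Vectors::DataFrame] with columns `transcript_id`,
#'   `gene_id`, `seqid`, `strand`, `coding`, `cds_left`, `cds_right`,
#'   `spliced_length`, `cds_spliced_length`, `representative`.
#' @seealso [readTranscriptsGTF()], [segmentTranscripts()]
#' @export
setClass("TranscriptModels",
  representation(exons = "CompressedGRangesList", txdata = "DFrame"))

setValidity("TranscriptModels", function(object) {
  td <- object@txdata
  need <- c("transcript_id", "gene_id", "seqid", "strand", "coding",
            "cds_left", "cds_right", "spliced_length",
            "cds_spliced_length", "representative")
  if (!all(need %in% colnames(td)))
    return(paste("txdata must have columns:", paste(need, collapse = ", ")))
  if (length(object@exons)) {
    if (!identical(names(object@exons), as.character(td$transcript_id)))
      return("exons must be named by txdata$transcript_id, same order")
    w <- sum(width(object@exons))
    if (!all(w == td$spliced_length))
      return("spliced_length must equal the sum of exon widths")
    u <- unlist(object@exons, use.names = FALSE)
    grp <- rep(seq_along(object@exons), lengths(object@exons))
    n <- length(u)
    if (n > 1L) {
      sameTx <- grp[-1L] == grp[-n]
      if (any(sameTx & start(u)[-1L] <= end(u)[-n]))
        return("exons must be sorted and non-overlapping within a transcript")
    }
    cod <- which(td$coding)
    if (length(cod)) {
      hit <- function(p, i) {
        rows <- which(grp == i)
        any(p >= start(u)[rows] & p <= end(u)[rows])
      }
      for (i in cod)
        if (!hit(td$cds_left[i], i) || !hit(td$cds_right[i], i))
          return(sprintf("CDS bounds of %s are not exonic",
                         td$transcript_id[i]))
    }
  }
  TRUE
})

#' Transcripts segmented into the five metagene regions
#'
#' For every coding transcript the spliced sequence is partitioned into
#' five non-overlapping segments: 5'UTR, start-codon segment (100 nt
#' centred on the first CDS base), CDS, stop-codon segment (100 nt
#' centred one base past the last CDS base) and 3'UTR.  Segments are
#' stored as 0-based spliced breakpoints `b0..b5`; segment `j` occupies
#' spliced positions `[b[j], b[j+1])` and the five segments always tile
#' the whole spliced transcript.  Non-coding transcripts carry an `NA`
#' row and are treated as a single "exonic" region.
#'
#' @slot models the parent [TranscriptModels-class].
#' @slot breaks integer matrix (transcripts x 6) of spliced breakpoints.
#' @seealso [segmentTranscripts()], [locatePeak()]
#' @export
setClass("SegmentedTranscripts",
  representation(models = "TranscriptModels", breaks = "matrix"))

setValidity("SegmentedTranscripts", function(object) {
  b <- object@breaks
  if (ncol(b) != 6L) return("breaks must have 6 columns")
  if (!identical(rownames(b), names(object@models@exons)))
    return("breaks rownames must match transcript ids")
  ok <- stats::complete.cases(b)
  if (any(ok)) {
    bb <- b[ok, , drop = FALSE]
    if (any(bb[, 1L] != 0L)) return("b0 must be 0")
    if (any(bb != t(apply(bb, 1L, cummax)))) return("breaks must be monotone")
    L <- object@models@txdata$spliced_length[ok]
    if (any(bb[, 6L] != L)) return("b5 must equal the spliced length")
  }
  TRUE
})

#' Per-base fragment-start coverage of one sequencing library
#'
#' Coverage is stored as one [S4Vectors::Rle] of non-negative counts per
#' reference sequence, counting *fragment 5' starts* at each base.  The
#' library size (`totalFragments`) and the nominal fragment length
#' (~100 nt after chemical fragmentation) travel with the track so the
#' peak caller can scale libraries against each other and compute its
#' global background rate.
#'
#' @slot cov a [S4Vectors::RleList] of per-base counts.
#' @slot totalFragments library size (number of fragments).
#' @slot fragmentLength nominal fragment length in nt.
#' @seealso [fragmentCoverage()], [callPeaks()]
#' @export
setClass("FragmentCoverage",
  representation(cov = "RleList", totalFragments = "numeric",
                 fragmentLength = "numeric"))

setValidity("FragmentCoverage", function(object) {
  if (length(object@cov) && any(min(object@cov) < 0))
    return("coverage counts must be non-negative")
  if (length(object@totalFragments) != 1L || object@totalFragments < 0)
    return("totalFragments must be a single non-negative number")
  if (length(object@fragmentLength) != 1L || object@fragmentLength <= 0)
    return("fragmentLength must be a single positive number")
  TRUE
})

#' Metagene profile over 5 segments x 20 bins
#'
#' One peak contributes exactly one count, via its summit, to one of the
#' 100 bins (segments ordered 5'UTR, start codon, CDS, stop codon,
#' 3'UTR; 20 bins each, bin 0 is 5'-most within its segment).
#'
#' @slot counts numeric vector of 100 bin counts.
#' @slot nPeaks number of peaks used (equals `sum(counts)`).
#' @seealso [metageneProfile()], [binCounts()], [binDensity()]
#' @export
setClass("MetageneProfile",
  representation(counts = "numeric", nPeaks = "numeric"))

setValidity("MetageneProfile", function(object) {
  if (length(object@counts) != 100L) return("counts must have length 100")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!isTRUE(all.equal(sum(object@counts), object@nPeaks)))
    return("sum(counts) must equal nPeaks")
  TRUE
})

## ---- accessors ----

#' @describeIn TranscriptModels per-transcript metadata table.
#' @param object a `TranscriptModels` object.
#' @export
txData <- function(object) {
  stopifnot(is(object, "TranscriptModels") ||
            is(object, "SegmentedTranscripts"))
  if (is(object, "SegmentedTranscripts")) object@models@txdata
  else object@txdata
}

#' @describeIn TranscriptModels exon [GRangesList] named by transcript.
#' @export
exonsByTranscript <- function(object) {
  stopifnot(is(object, "TranscriptModels") ||
            is(object, "SegmentedTranscripts"))
  if (is(object, "SegmentedTranscripts")) object@models@exons
  else object@exons
}

#' @describeIn SegmentedTranscripts spliced breakpoint matrix (tx x 6).
#' @param object a `SegmentedTranscripts` object.
#' @export
segmentBreaks <- function(object) {
  stopifnot(is(object, "SegmentedTranscripts"))
  object@breaks
}

#' @describeIn FragmentCoverage per-base count [S4Vectors::RleList].
#' @param object a `FragmentCoverage` object.
#' @export
coverageRle <- function(object) {
  stopifnot(is(object, "FragmentCoverage"))
  object@cov
}

#' @describeIn FragmentCoverage library size in fragments.
#' @export
totalFragments <- function(object) {
  stopifnot(is(object, "FragmentCoverage"))
  object@totalFragments
}

#' @describeIn MetageneProfile raw bin counts (length 100).
#' @param object a `MetageneProfile` object.
#' @export
binCounts <- function(object) {
  stopifnot(is(object, "MetageneProfile"))
  object@counts
}

#' @describeIn MetageneProfile bin counts normalised to sum 1 (all-`NA`
#'   when the profile holds no peaks).
#' @export
binDensity <- function(object) {
  stopifnot(is(object, "MetageneProfile"))
  if (object@nPeaks == 0) rep(NA_real_, 100L)
  else object@counts / object@nPeaks
}

#' @describeIn MetageneProfile segment label of each of the 100 bins.
#' @export
binSegments <- function(object) {
  factor(rep(.segmentLabels(), each = 20L), levels = .segmentLabels())
}

## ---- show methods ----

setMethod("show", "TranscriptModels", function(object) {
  td <- object@txdata
  cat(sprintf("TranscriptModels: %d transcripts, %d genes (%d coding, %d representative)\n",
              nrow(td), length(unique(td$gene_id)), sum(td$coding),
              sum(td$representative)))
})

setMethod("show", "SegmentedTranscripts", function(object) {
  ok <- sum(stats::complete.cases(object@breaks))
  cat(sprintf("SegmentedTranscripts: %d transcripts (%d segmented into 5 regions)\n",
              nrow(object@breaks), ok))
})

setMethod("show", "FragmentCoverage", function(object) {
  cat(sprintf("FragmentCoverage: %d seqs, %.0f fragments, fragment length %d nt\n",
              length(object@cov), object@totalFragments,
              as.integer(object@fragmentLength)))
})

setMethod("show", "MetageneProfile", function(object) {
  cat(sprintf("MetageneProfile: %d peaks over 5 segments x 20 bins\n",
              as.integer(object@nPeaks)))
  if (object@nPeaks > 0) {
    seg <- tapply(object@counts, binSegments(object), sum) / object@nPeaks
    cat("  segment mass:",
        paste(sprintf("%s=%.2f", names(seg), seg), collapse = " "), "\n")
  }
})

#' Build a FragmentCoverage track
#'
#' @param cov an [S4Vectors::RleList] (or coercible list of numeric
#'   vectors) of per-base fragment-start counts.
#' @param totalFragments library size; defaults to the total count in
#'   the track.
#' @param fragmentLength nominal fragment length (nt), default 100.
#' @return a [FragmentCoverage-class] object.
#' @export
fragmentCoverage <- function(cov, totalFragments = NULL,
                             fragmentLength = 100) {
  if (!is(cov, "RleList"))
    cov <- as(lapply(cov, Rle), "SimpleRleList")
  if (is.null(totalFragments))
    totalFragments <- sum(as.numeric(sum(cov)))
  new("FragmentCoverage", cov = cov,
      totalFragments = as.numeric(totalFragments),
      fragmentLength = as.numeric(fragmentLength))
}
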