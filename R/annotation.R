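## Transcript annotation: GTF ingestion, spliced-coordinate arithmetic
## and segmentation into the five metagene regions.
##
## Spliced coordinates are 0-based offsets along the mature transcript,
## position 0 being the 5' end (strand-aware).  Genomic coordinates are
## 1-based closed, the GRanges convention.

#' Read transcript models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (attributes `gene_id`/`transcript_id`)
#' into a [TranscriptModels-class] object.  Exons are sorted and merged
#' per transcript; transcripts without a CDS feature are flagged
#' non-coding.  Per gene, the isoform with the longest spliced CDS
#' (ties: longest spliced length, then lexicographically smallest id)
#' is flagged representative; metagene profiling uses only those.
#'
#' @param path path to a GTF file.
#' @return a [TranscriptModels-class] object.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "meripr")
#' readTranscriptsGTF(gtf)
#' @export
readTranscriptsGTF <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  nlines <- length(readLines(path, warn = FALSE))
  if (nlines == 0L || {
    ln <- readLines(path, warn = FALSE)
    all(grepl("^\\s*(#|$)", ln))
  }) {
    warning("empty GTF: ", path, call. = FALSE)
    return(.makeTranscriptModels(GRanges(), character(), character()))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!all(c("type", "gene_id", "transcript_id") %in% colnames(mcols(gr))))
    stop("GTF must carry type, gene_id and transcript_id attributes",
         call. = FALSE)
  exons <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  if (length(exons) == 0L) {
    warning("GTF contains no exon features: ", path, call. = FALSE)
    return(.makeTranscriptModels(GRanges(), character(), character()))
  }
  if (anyNA(exons$transcript_id) || anyNA(exons$gene_id))
    stop("exon feature with missing gene_id/transcript_id in ", path,
         call. = FALSE)
  .makeTranscriptModels(exons, cds = cds)
}

## Assemble a TranscriptModels from exon/CDS GRanges (also used by the
## simulator, which builds annotation in memory).
#' @noRd
.makeTranscriptModels <- function(exons, gene_id = exons$gene_id,
                                  transcript_id = exons$transcript_id,
                                  cds = GRanges()) {
  if (length(exons) == 0L) {
    td <- DataFrame(transcript_id = character(), gene_id = character(),
                    seqid = character(), strand = character(),
                    coding = logical(), cds_left = integer(),
                    cds_right = integer(), spliced_length = integer(),
                    cds_spliced_length = integer(),
                    representative = logical())
    return(new("TranscriptModels",
               exons = GRangesList(), txdata = td))
  }
  mcols(exons) <- DataFrame(gene_id = gene_id, transcript_id = transcript_id)
  exl <- reduce(split(exons, exons$transcript_id))   # sorts and merges
  txid <- names(exl)
  first <- exons[match(txid, exons$transcript_id)]
  gid <- first$gene_id
  seqid <- as.character(seqnames(first))
  str <- as.character(strand(first))
  splen <- as.integer(sum(width(exl)))

  cds_left <- cds_right <- rep(NA_integer_, length(txid))
  if (length(cds)) {
    cl <- tapply(start(cds), cds$transcript_id, min)
    cr <- tapply(end(cds), cds$transcript_id, max)
    i <- match(txid, names(cl))
    cds_left <- as.integer(cl[i])
    cds_right <- as.integer(cr[i])
  }
  coding <- !is.na(cds_left)

  td <- DataFrame(transcript_id = txid, gene_id = gid, seqid = seqid,
                  strand = str, coding = coding, cds_left = cds_left,
                  cds_right = cds_right, spliced_length = splen,
                  cds_spliced_length = NA_integer_,
                  representative = FALSE)
  obj <- new("TranscriptModels", exons = exl, txdata = td)

  ## spliced CDS length via the exon chain; errors if CDS not exonic
  chains <- .chainList(obj)
  cdslen <- rep(0L, length(txid))
  for (i in which(coding)) {
    s <- .splicedPos(chains[[i]],
                     if (str[i] == "+") cds_left[i] else cds_right[i])
    t1 <- .splicedPos(chains[[i]],
                      if (str[i] == "+") cds_right[i] else cds_left[i])
    if (is.na(s) || is.na(t1))
      stop("CDS of ", txid[i], " extends outside its exons", call. = FALSE)
    cdslen[i] <- as.integer(t1 - s + 1L)
  }
  td$cds_spliced_length <- cdslen

  ## representative isoform per gene: longest CDS, then spliced length, id
  ord <- order(td$gene_id, -td$cds_spliced_length, -td$spliced_length,
               td$transcript_id)
  rep_idx <- ord[!duplicated(td$gene_id[ord])]
  td$representative[rep_idx] <- TRUE
  obj@txdata <- td
  validObject(obj)
  obj
}

## Exon chains (transcript 5'->3' order) for all transcripts at once;
## avoids per-transcript S4 extraction in hot loops.
#' @noRd
.chainList <- function(models) {
  ex <- if (is(models, "TranscriptModels")) models@exons else models
  td <- txData(models)
  u <- unlist(ex, use.names = FALSE)
  grp <- factor(rep(seq_along(ex), lengths(ex)))
  sl <- split(start(u), grp); el <- split(end(u), grp)
  out <- vector("list", length(ex))
  names(out) <- names(ex)
  for (i in seq_along(ex)) {
    s <- sl[[i]]; e <- el[[i]]
    str <- td$strand[i]
    if (str == "-") { s <- rev(s); e <- rev(e) }
    w <- e - s + 1L
    out[[i]] <- list(starts = s, ends = e, widths = w,
                     cum = c(0L, cumsum(w)), strand = str)
  }
  out
}

## Exon chain of one transcript in transcript (5'->3') order.
#' @noRd
.exonChain <- function(models, tx) {
  i <- match(tx, names(models@exons))
  if (is.na(i)) stop("unknown transcript: ", tx, call. = FALSE)
  ex <- models@exons[[i]]
  s <- start(ex); e <- end(ex)
  str <- models@txdata$strand[i]
  if (str == "-") { s <- rev(s); e <- rev(e) }
  w <- e - s + 1L
  list(starts = s, ends = e, widths = w, cum = c(0L, cumsum(w)),
       strand = str)
}

## Core maps on one chain (0-based spliced <-> 1-based genomic).
#' @noRd
.splicedPos <- function(ch, genomicPos) {
  out <- rep(NA_integer_, length(genomicPos))
  for (j in seq_along(ch$starts)) {
    hit <- !is.na(genomicPos) & genomicPos >= ch$starts[j] &
      genomicPos <= ch$ends[j]
    if (any(hit)) {
      off <- if (ch$strand == "-") ch$ends[j] - genomicPos[hit]
             else genomicPos[hit] - ch$starts[j]
      out[hit] <- ch$cum[j] + as.integer(off)
    }
  }
  out
}

#' @noRd
.genomicPos <- function(ch, splicedPos) {
  out <- rep(NA_integer_, length(splicedPos))
  L <- ch$cum[length(ch$cum)]
  ok <- !is.na(splicedPos) & splicedPos >= 0L & splicedPos < L
  if (any(ok)) {
    j <- findInterval(splicedPos[ok], ch$cum)
    off <- splicedPos[ok] - ch$cum[j]
    out[ok] <- as.integer(
      if (ch$strand == "-") ch$ends[j] - off else ch$starts[j] + off)
  }
  out
}

#' Genomic position to spliced offset
#'
#' Maps genomic positions (1-based) on a transcript to 0-based offsets
#' along its spliced sequence; position 0 is the 5' end, so the mapping
#' is strand-aware.  Non-exonic positions map to `NA`.
#'
#' @param models a [TranscriptModels-class] object.
#' @param tx a transcript id.
#' @param genomicPos vector of genomic positions.
#' @return integer vector of spliced offsets (`NA` where not exonic).
#' @export
splicedPosition <- function(models, tx, genomicPos) {
  .splicedPos(.exonChain(models, tx), genomicPos)
}

#' Spliced offset to genomic position
#'
#' Inverse of [splicedPosition()]: maps 0-based spliced offsets to
#' 1-based genomic positions.
#'
#' @inheritParams splicedPosition
#' @param splicedPos vector of 0-based spliced offsets.
#' @return integer vector of genomic positions (`NA` out of range).
#' @export
genomicPosition <- function(models, tx, splicedPos) {
  .genomicPos(.exonChain(models, tx), splicedPos)
}

#' Spliced interval to genomic pieces
#'
#' Maps a 0-based half-open spliced interval `[sstart, send)` to its
#' genomic exon pieces, returned in transcript (5'->3') order.
#'
#' @inheritParams splicedPosition
#' @param sstart,send 0-based half-open spliced interval bounds.
#' @return a [GRanges] of genomic pieces with an `piece` rank column;
#'   empty when `sstart >= send`.
#' @export
splicedToGenomic <- function(models, tx, sstart, send) {
  ch <- .exonChain(models, tx)
  td <- txData(models)
  seqid <- td$seqid[match(tx, td$transcript_id)]
  m <- .piecesMat(ch, sstart, send)
  if (nrow(m) == 0L)
    return(GRanges(seqnames = character(0), ranges = IRanges(),
                   strand = character(0)))
  GRanges(seqnames = seqid, ranges = IRanges(m[, 1L], m[, 2L]),
          strand = ch$strand, piece = seq_len(nrow(m)))
}

## Genomic pieces (matrix of 1-based closed gstart/gend rows, in
## transcript order) of the 0-based half-open spliced interval.
#' @noRd
.piecesMat <- function(ch, sstart, send) {
  if (send <= sstart) return(matrix(integer(0), 0L, 2L))
  pieces <- list()
  for (j in seq_along(ch$starts)) {
    lo <- max(sstart, ch$cum[j]); hi <- min(send, ch$cum[j + 1L])
    if (lo < hi) {
      if (ch$strand == "-") {
        gs <- ch$ends[j] - (hi - 1L - ch$cum[j])
        ge <- ch$ends[j] - (lo - ch$cum[j])
      } else {
        gs <- ch$starts[j] + (lo - ch$cum[j])
        ge <- ch$starts[j] + (hi - 1L - ch$cum[j])
      }
      pieces[[length(pieces) + 1L]] <- c(gs, ge)
    }
  }
  do.call(rbind, pieces)
}

#' Segment transcripts into the five metagene regions
#'
#' For each coding transcript, with `s` the spliced offset of the first
#' CDS base and `t` one past the last CDS base, the spliced sequence is
#' tiled as 5'UTR `[0, s-50)`, start-codon segment `[s-50, s+50)`, CDS
#' `[s+50, t-50)`, stop-codon segment `[t-50, t+50)` and 3'UTR
#' `[t+50, L)`.  Segments are truncated at the transcript ends, never
#' overlapped; a CDS shorter than 100 nt yields an empty CDS segment
#' with the two codon segments abutting at the CDS spliced midpoint.
#' Non-coding transcripts get an `NA` breakpoint row (single "exonic"
#' region).
#'
#' @param models a [TranscriptModels-class] object.
#' @return a [SegmentedTranscripts-class] object.
#' @export
segmentTranscripts <- function(models) {
  td <- txData(models)
  n <- nrow(td)
  chains <- .chainList(models)
  br <- matrix(NA_integer_, n, 6L,
               dimnames = list(td$transcript_id,
                               c("b0", "b1", "b2", "b3", "b4", "b5")))
  for (i in seq_len(n)) {
    if (!td$coding[i]) next
    L <- td$spliced_length[i]
    firstBase <- if (td$strand[i] == "+") td$cds_left[i] else td$cds_right[i]
    lastBase <- if (td$strand[i] == "+") td$cds_right[i] else td$cds_left[i]
    s <- .splicedPos(chains[[i]], firstBase)
    t1 <- .splicedPos(chains[[i]], lastBase) + 1L
    br[i, ] <- .segmentBreaks(s, t1, L)
  }
  new("SegmentedTranscripts", models = models, breaks = br)
}

## Breakpoints b0..b5 for one transcript (0-based spliced coords).
#' @noRd
.segmentBreaks <- function(s, t, L) {
  if (t - s >= 100L) { b <- s + 50L; cc <- t - 50L }
  else b <- cc <- s + (t - s) %/% 2L
  raw <- c(0L, s - 50L, b, cc, t + 50L, L)
  as.integer(cummax(pmin(pmax(raw, 0L), L)))
}

#' Spliced segment lengths per transcript
#'
#' @param st a [SegmentedTranscripts-class] object.
#' @return matrix (transcripts x 5) of spliced segment lengths in nt;
#'   `NA` rows for non-coding transcripts.
#' @export
segmentLengths <- function(st) {
  b <- segmentBreaks(st)
  out <- b[, -1L, drop = FALSE] - b[, -6L, drop = FALSE]
  colnames(out) <- .segmentLabels()
  out
}

#' Export segment pieces as a BED-like table
#'
#' One row per genomic piece of each segment; column 4 is
#' `transcript_id|segment_label`.  Coordinates are written 0-based
#' half-open (BED convention).
#'
#' @param st a [SegmentedTranscripts-class] object.
#' @param path output path (TSV, no header).  Omit to just get the
#'   data frame back.
#' @return (invisibly) the exported data frame.
#' @export
segmentsToBed <- function(st, path = NULL) {
  td <- txData(st)
  labs <- .segmentLabels()
  rows <- list()
  for (i in which(td$coding)) {
    tx <- td$transcript_id[i]
    b <- segmentBreaks(st)[tx, ]
    for (j in seq_len(5L)) {
      g <- splicedToGenomic(st@models, tx, b[j], b[j + 1L])
      if (length(g) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(seqnames(g)), start = start(g) - 1L,
        end = end(g), name = paste0(tx, "|", labs[j]), score = 0L,
        strand = as.character(strand(g)))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(), start = integer(),
                         end = integer(), name = character(),
                         score = integer(), strand = character())
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(out)
}
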