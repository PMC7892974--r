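## Motif-discovery input preparation (top peaks, 101-nt summit windows,
## shuffled controls) and a built-in IUPAC k-mer enrichment test, so
## the canonical m6A motif claim (GGACU within RRACH) is checkable
## without external motif-discovery binaries.

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Select the top enriched peaks
#'
#' Filters peaks with `fold_change > fcMin` and `p_value < pMax`, sorts
#' by ascending p-value (ties: descending fold change, then
#' coordinate) and keeps the first `n`.  The result is a pure function
#' of the peak set, invariant to input order.
#'
#' @param peaks a peak [GRanges].
#' @param n number of peaks to keep (default 1000).
#' @param fcMin fold-change filter, exclusive (default 2).
#' @param pMax p-value filter, exclusive (default 1e-5).
#' @return the selected peak [GRanges]; warns when fewer than `n`
#'   qualify.
#' @export
selectTopPeaks <- function(peaks, n = 1000, fcMin = 2, pMax = 1e-5) {
  peaks <- m6aPeaks(peaks)
  keep <- mcols(peaks)$fold_change > fcMin & mcols(peaks)$p_value < pMax
  sel <- peaks[keep]
  ord <- order(mcols(sel)$p_value, -mcols(sel)$fold_change,
               as.character(seqnames(sel)), start(sel), end(sel))
  sel <- sel[ord]
  if (length(sel) < n)
    warning(sprintf("only %d of the requested %d peaks qualify",
                    length(sel), as.integer(n)), call. = FALSE)
  head(sel, n)
}

#' Extract summit-centred sequence windows
#'
#' Cuts a `2 * flank + 1` nt window (default 101 nt) centred on each
#' peak summit from the genome, reverse-complemented for minus-strand
#' peaks so the window reads in transcript sense.  Windows truncated at
#' contig ends are flagged.
#'
#' @param peaks a peak [GRanges]; the `strand` should be that of the
#'   host transcript.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param flank half-window in nt (default 50).
#' @return a [Biostrings::DNAStringSet] with metadata columns
#'   `peak_id`, `origin` (`"target"`) and `truncated`.
#' @export
extractWindows <- function(peaks, genome, flank = 50) {
  peaks <- m6aPeaks(peaks)
  missing <- setdiff(unique(as.character(seqnames(peaks))), names(genome))
  if (length(missing))
    stop("genome is missing sequence(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ids <- mcols(peaks)$name
  if (is.null(ids)) ids <- paste0("peak_", seq_along(peaks))
  seqs <- vector("list", length(peaks))
  trunc <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    sq <- as.character(seqnames(peaks))[i]
    len <- length(genome[[sq]])
    s <- mcols(peaks)$summit[i]
    lo <- max(1L, s - flank); hi <- min(len, s + flank)
    trunc[i] <- (hi - lo + 1L) < (2L * flank + 1L)
    w <- subseq(genome[[sq]], lo, hi)
    if (as.character(strand(peaks))[i] == "-") w <- reverseComplement(w)
    seqs[[i]] <- w
  }
  out <- DNAStringSet(seqs)
  names(out) <- ids
  mcols(out) <- DataFrame(peak_id = ids, origin = "target",
                          truncated = trunc)
  out
}

## Altschul-Erickson shuffle of one character vector: preserves the
## dinucleotide count multiset (and the first/last base).
#' @noRd
.dinucShuffle <- function(ch, maxTries = 200L) {
  n <- length(ch)
  if (n <= 3L || length(unique(ch)) == 1L) return(ch)
  from <- ch[-n]; to <- ch[-1L]
  verts <- unique(ch)
  last <- ch[n]
  outEdges <- split(seq_along(from), from)   # edge index -> to[i]
  for (try in seq_len(maxTries)) {
    ## pick a random terminal (last-used) edge per non-final vertex and
    ## check the terminal edges form an arborescence towards `last`
    term <- vapply(verts, function(v) {
      if (v == last || is.null(outEdges[[v]])) NA_integer_
      else { e <- outEdges[[v]]; e[sample.int(length(e), 1L)] }
    }, integer(1L))
    names(term) <- verts
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(term[[v]])) next
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(term[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- to[term[[cur]]]
      }
      if (!ok) break
    }
    if (!ok) next
    ## order each vertex's edges randomly, terminal edge last
    lists <- lapply(verts, function(v) {
      e <- outEdges[[v]]
      if (is.null(e)) return(integer(0))
      t <- term[[v]]
      if (!is.na(t)) e <- setdiff(e, t)
      e <- if (length(e) > 1L) sample(e) else e
      c(e, if (!is.na(t)) t)
    })
    names(lists) <- verts
    ptr <- setNames(rep(1L, length(verts)), verts)
    res <- character(n); res[1L] <- ch[1L]
    cur <- ch[1L]
    good <- TRUE
    for (i in 2:n) {
      e <- lists[[cur]]
      if (ptr[[cur]] > length(e)) { good <- FALSE; break }
      nxt <- to[e[ptr[[cur]]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    if (good) return(res)
  }
  warning("dinucleotide shuffle failed to converge; returning input",
          call. = FALSE)
  ch
}

#' Shuffled control sequences
#'
#' Per-sequence shuffles preserving the mononucleotide
#' (`mode = "mono"`) or dinucleotide (default; Altschul-Erickson
#' Eulerian-path shuffle) composition.  Deterministic under `seed`.
#'
#' @param windows a [Biostrings::DNAStringSet] (or character vector).
#' @param mode `"dinucleotide"` (default) or `"mono"`.
#' @param seed RNG seed (the caller's RNG state is restored).
#' @return a [Biostrings::DNAStringSet] of shuffled sequences with
#'   `origin = "shuffled-control"` metadata.
#' @export
shuffleControls <- function(windows, mode = c("dinucleotide", "mono"),
                            seed = 1L) {
  mode <- match.arg(mode)
  chs <- strsplit(as.character(windows), "")
  shuffled <- .withSeed(seed, lapply(chs, function(ch) {
    if (mode == "mono") {
      if (length(ch) > 1L) sample(ch) else ch
    } else .dinucShuffle(ch)
  }))
  out <- DNAStringSet(vapply(shuffled, paste, character(1), collapse = ""))
  names(out) <- if (!is.null(names(windows)))
    paste0(names(windows), "_shuf") else
      paste0("shuf_", seq_along(out))
  mcols(out) <- DataFrame(peak_id = names(out), origin = "shuffled-control",
                          truncated = FALSE)
  out
}

## Count IUPAC pattern occurrences (overlaps allowed, U == T).
#' @noRd
.countIUPAC <- function(pattern, seqs) {
  pat <- toupper(chartr("Uu", "Tt", pattern))
  bad <- setdiff(strsplit(pat, "")[[1L]], names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(bad, collapse = ""), call. = FALSE)
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(chartr("Uu", "Tt", seqs))
  vcountPattern(pat, seqs, fixed = FALSE)
}

#' K-mer / IUPAC motif enrichment of targets over controls
#'
#' Counts pattern occurrences (IUPAC-expanded, overlapping, U
#' equivalent to T) in target and control sequences and compares the
#' per-position match rates with a two-proportion z-test (upper tail:
#' enrichment in targets).  Optionally an empirical p-value from extra
#' dinucleotide shuffles of the targets.
#'
#' @param targets,controls [Biostrings::DNAStringSet]s (or character).
#' @param motifs IUPAC patterns, e.g. `c("GGACU", "RRACH")`.
#' @param nShuffle if > 0, number of extra target shuffles for an
#'   empirical p-value (at least 100 is sensible).
#' @param seed RNG seed for the empirical shuffles.
#' @return data.frame with per-motif target/control rates, `z`, normal
#'   upper-tail `p_value` and (if requested) `p_empirical`.
#' @export
kmerEnrichment <- function(targets, controls,
                           motifs = c("GGACU", "RRACH"),
                           nShuffle = 0, seed = 1L) {
  if (!is(targets, "DNAStringSet")) targets <- DNAStringSet(targets)
  if (!is(controls, "DNAStringSet")) controls <- DNAStringSet(controls)
  if (length(targets) == 0L || length(controls) == 0L)
    stop("need at least one target and one control sequence",
         call. = FALSE)
  rows <- lapply(motifs, function(m) {
    k <- nchar(m)
    ct <- .countIUPAC(m, targets)
    cc <- .countIUPAC(m, controls)
    posT <- sum(pmax(0L, width(targets) - k + 1L))
    posC <- sum(pmax(0L, width(controls) - k + 1L))
    p1 <- sum(ct) / posT; p2 <- sum(cc) / posC
    pool <- (sum(ct) + sum(cc)) / (posT + posC)
    z <- if (pool == 0 || pool == 1) 0 else
      (p1 - p2) / sqrt(pool * (1 - pool) * (1 / posT + 1 / posC))
    out <- data.frame(motif = m, target_count = sum(ct),
                      control_count = sum(cc),
                      target_rate = p1, control_rate = p2, z = z,
                      p_value = stats::pnorm(z, lower.tail = FALSE))
    if (nShuffle > 0) {
      rates <- .withSeed(seed, vapply(seq_len(nShuffle), function(i) {
        sh <- shuffleControls(targets, seed = NULL)
        sum(.countIUPAC(m, sh)) / posT
      }, numeric(1)))
      out$p_empirical <- (1 + sum(rates >= p1)) / (nShuffle + 1)
    }
    out
  })
  do.call(rbind, rows)
}

#' Write motif windows as FASTA
#'
#' @param windows a [Biostrings::DNAStringSet] (targets or controls).
#' @param path output FASTA path.
#' @return (invisibly) the path.
#' @export
writeWindowsFasta <- function(windows, path) {
  writeXStringSet(windows, path)
  invisible(path)
}
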