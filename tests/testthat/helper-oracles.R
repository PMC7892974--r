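## Independent brute-force oracles and randomized fixture builders.
## The oracles deliberately use the dumbest possible machinery
## (per-base vectors, exhaustive enumeration) so they share no code
## path with the implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## ---- random transcript models via a GTF written in code ----

## Returns list(models, info) where info holds, per transcript, the
## per-spliced-base genomic position vector (the brute-force map), the
## spliced CDS bounds [s, t) and the strand.
randomModels <- function(nTx, seed, maxExons = 4) {
  set.seed(seed)
  lines <- character(0)
  info <- list()
  cursor <- 1L
  for (i in seq_len(nTx)) {
    tid <- sprintf("tx%03d", i)
    ne <- sample.int(maxExons, 1L)
    ew <- sample(30:400, ne, replace = TRUE)
    gaps <- if (ne > 1L) sample(20:300, ne - 1L, replace = TRUE) else integer(0)
    strand <- sample(c("+", "-"), 1L)
    es <- integer(ne); ee <- integer(ne); pos <- cursor + 100L
    for (j in seq_len(ne)) {
      es[j] <- pos; ee[j] <- pos + ew[j] - 1L
      pos <- ee[j] + 1L + if (j < ne) gaps[j] else 0L
    }
    cursor <- ee[ne] + 500L
    L <- sum(ew)
    ## brute-force spliced -> genomic map: one genomic position per base
    gvec <- unlist(lapply(seq_len(ne), function(j) es[j]:ee[j]))
    if (strand == "-") gvec <- rev(gvec)
    ## random CDS in spliced coords (sometimes very short)
    s <- sample.int(max(1L, L - 20L), 1L) - 1L
    t <- min(L, s + sample(c(sample(10:60, 1L), sample(100:600, 1L)), 1L))
    cl <- min(gvec[s + 1L], gvec[t]); cr <- max(gvec[s + 1L], gvec[t])
    for (j in seq_len(ne))
      lines <- c(lines, sprintf(
        "chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"g%03d\"; transcript_id \"%s\";",
        es[j], ee[j], strand, i, tid))
    lines <- c(lines, sprintf(
      "chr1\ttest\tCDS\t%d\t%d\t.\t%s\t.\tgene_id \"g%03d\"; transcript_id \"%s\";",
      cl, cl, strand, i, tid), sprintf(
      "chr1\ttest\tCDS\t%d\t%d\t.\t%s\t.\tgene_id \"g%03d\"; transcript_id \"%s\";",
      cr, cr, strand, i, tid))
    info[[tid]] <- list(gvec = gvec, s = s, t = t, L = L, strand = strand)
  }
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  list(models = readTranscriptsGTF(path), info = info)
}

## ---- per-base segment labeller (rule text, if-chain) ----

oracleLabels <- function(s, t, L) {
  if (t - s >= 100L) { b <- s + 50L; cc <- t - 50L }
  else { m <- s + (t - s) %/% 2L; b <- m; cc <- m }
  a <- s - 50L; d <- t + 50L
  vapply(0:(L - 1L), function(i) {
    if (i < a) "five_prime_utr"
    else if (i < b) "start_codon"
    else if (i < cc) "cds"
    else if (i < d) "stop_codon"
    else "three_prime_utr"
  }, character(1))
}

## bin of spliced base i given the label vector
oracleBin <- function(labels, i) {
  lab <- labels[i + 1L]
  pos <- which(labels == lab)
  off <- i - (pos[1L] - 1L)
  min(19L, (20L * off) %/% length(pos))
}

## ---- interval oracles (base counting / exhaustive pairs) ----

oracleFraction <- function(s1, e1, s2, e2) {
  ov <- length(intersect(seq(s1, e1), seq(s2, e2)))
  ov / min(e1 - s1 + 1, e2 - s2 + 1)
}

## exhaustive chain enumeration + the documented greedy selection,
## for min_replicates = all replicates
oracleRecurrent <- function(sets, minFraction = 0.5) {
  idx <- lapply(sets, seq_along)
  tuples <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  keep <- list()
  for (r in seq_len(nrow(tuples))) {
    ivs <- lapply(seq_along(sets), function(j) {
      p <- sets[[j]][tuples[r, j][[1L]]]
      c(start(p), end(p))
    })
    okpair <- TRUE
    for (a in seq_along(ivs)) for (b in seq_along(ivs)) {
      if (a < b && oracleFraction(ivs[[a]][1], ivs[[a]][2],
                                  ivs[[b]][1], ivs[[b]][2]) < minFraction)
        okpair <- FALSE
    }
    if (okpair)
      keep[[length(keep) + 1L]] <- list(
        members = unlist(tuples[r, ]),
        istart = max(vapply(ivs, `[`, numeric(1), 1L)),
        iend = min(vapply(ivs, `[`, numeric(1), 2L)))
  }
  if (length(keep) == 0L) return(matrix(numeric(0), 0L, 2L))
  ord <- order(vapply(keep, `[[`, numeric(1), "istart"),
               vapply(keep, `[[`, numeric(1), "iend"))
  used <- lapply(sets, function(s) logical(length(s)))
  picked <- list()
  for (r in ord) {
    mem <- keep[[r]]$members
    if (any(mapply(function(u, m) u[m], used, mem))) next
    for (j in seq_along(mem)) used[[j]][mem[j]] <- TRUE
    picked[[length(picked) + 1L]] <- c(keep[[r]]$istart, keep[[r]]$iend)
  }
  m <- do.call(rbind, picked)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

## exhaustive hypergeometric upper tail
oracleHyperTail <- function(overlap, setSize, universe, nHits) {
  ks <- overlap:min(setSize, nHits)
  sum(choose(setSize, ks) * choose(universe - setSize, nHits - ks)) /
    choose(universe, nHits)
}

## random peak set on one sequence
randomPeakSet <- function(n, span = 2e4, wmin = 50, wmax = 300) {
  s <- sort(sample.int(span, n))
  w <- sample(wmin:wmax, n, replace = TRUE)
  m6aPeaks(GRanges("chr1", IRanges(s, s + w - 1L)))
}

## tiny deterministic coverage track from explicit per-base counts
trackFromCounts <- function(counts, totalFragments = sum(counts),
                            fragmentLength = 100) {
  fragmentCoverage(list(chr1 = counts), totalFragments = totalFragments,
                   fragmentLength = fragmentLength)
}
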