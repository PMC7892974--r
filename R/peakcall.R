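## IP-vs-input Poisson window peak caller.  A deliberate, fully
## specified simplification of the MACS approach: sliding windows of
## fragment-start counts, a background rate taken as the maximum of the
## library-scaled input rate at several local scales and a global rate
## based on an effective (transcriptome) size, and an upper-tail
## Poisson test per window.

#' Peak caller parameters
#'
#' @param windowSize sliding window width in nt (default 100).
#' @param step window step in nt (default 50; must be <= windowSize).
#' @param effectiveSize background size in nt over which library
#'   fragments are assumed uniform when no input signal is available;
#'   for MeRIP-seq this is the transcriptome size (default 1.77e8, a
#'   calculated chicken transcriptome size).
#' @param pThreshold Poisson p-value threshold (default 1e-5).
#' @param fcThreshold minimum IP/background fold change (default 2).
#' @param mergeGap significant windows closer than this are merged into
#'   one peak (default `windowSize`).
#' @param localScales window widths (nt) over which the input rate is
#'   estimated; the background takes the maximum across scales, so
#'   broad estimates guard against undersampled narrow ones.
#' @param localUpperZ one-sided sampling allowance on each local input
#'   estimate: the rate is taken as `(count + z * sqrt(count + 1))`
#'   scaled to the window, correcting the plug-in bias of a raw count
#'   (a single noisy draw used as if it were the true rate inflates
#'   the null tail).  Set to 0 for the raw scaled count.
#' @param localMinCount minimum input fragments a scale must hold for
#'   its estimate to be trusted (default 20, i.e. CV ~22%);
#'   undersampled scales defer to broader scales and the global rate.
#' @return a named list of validated parameters.
#' @export
peakCallerParams <- function(windowSize = 100, step = 50,
                             effectiveSize = 1.77e8, pThreshold = 1e-5,
                             fcThreshold = 2, mergeGap = windowSize,
                             localScales = c(windowSize, 1000, 5000),
                             localUpperZ = 1, localMinCount = 20) {
  for (nm in c("windowSize", "step", "effectiveSize", "pThreshold",
               "fcThreshold", "mergeGap"))
    .assertScalarNumeric(get(nm), nm, positive = nm != "mergeGap")
  if (step > windowSize) stop("step must be <= windowSize", call. = FALSE)
  stopifnot(localUpperZ >= 0, localMinCount >= 0)
  list(windowSize = as.integer(windowSize), step = as.integer(step),
       effectiveSize = effectiveSize, pThreshold = pThreshold,
       fcThreshold = fcThreshold, mergeGap = as.integer(mergeGap),
       localScales = sort(unique(as.integer(localScales))),
       localUpperZ = localUpperZ, localMinCount = localMinCount)
}

## Sum of v over [starts, starts + width - 1], clamped to the vector.
#' @noRd
.windowSums <- function(cs, lo, hi, n) {
  lo <- pmax(1L, lo); hi <- pmin(n, hi)
  cs[hi + 1L] - cs[lo]
}

#' Call m6A peaks from IP and input coverage
#'
#' For each sliding window the IP fragment-start count `k` is tested
#' against `lambda_bg`, the maximum of (i) the global rate
#' `totalFragments(ip) * windowSize / effectiveSize` and (ii) the
#' library-scaled input rate estimated over each of
#' `params$localScales` centred on the window, each taken with the
#' one-sided sampling allowance `localUpperZ` (see
#' [peakCallerParams()]).  Windows with upper-tail
#' Poisson `P(X >= k) < pThreshold` and `k / lambda_bg >= fcThreshold`
#' are merged when closer than `mergeGap`; each merged peak carries the
#' summit (argmax of the fragment-length-smoothed IP signal), a fold
#' change (summed window counts over summed lambdas) and the minimum
#' window p-value.
#'
#' @param ip,input [FragmentCoverage-class] tracks over the same
#'   reference sequences.
#' @param params a [peakCallerParams()] list.
#' @param sample_id,line provenance labels stored on the peaks.
#' @param returnWindows if TRUE, return the per-window statistics (a
#'   [GRanges] with `k`, `lambda`, `p_value`) instead of merged peaks;
#'   used for calibration diagnostics.
#' @return a sorted peak [GRanges] (see [m6aPeaks()]), or the window
#'   table when `returnWindows = TRUE`.
#' @export
callPeaks <- function(ip, input, params = peakCallerParams(),
                      sample_id = NA_character_, line = NA_character_,
                      returnWindows = FALSE) {
  stopifnot(is(ip, "FragmentCoverage"), is(input, "FragmentCoverage"))
  seqids <- names(coverageRle(ip))
  if (!all(seqids %in% names(coverageRle(input))))
    stop("input track is missing sequences present in the IP track",
         call. = FALSE)
  ratio <- if (totalFragments(input) > 0)
    totalFragments(ip) / totalFragments(input) else {
      warning("input library is empty; using the global rate only",
              call. = FALSE)
      0
    }
  w <- params$windowSize
  lamGlobal <- totalFragments(ip) * w / params$effectiveSize
  fl <- max(1L, as.integer(ip@fragmentLength))
  out <- list(); winout <- list()

  for (sq in seqids) {
    vip <- as.numeric(coverageRle(ip)[[sq]])
    vin <- as.numeric(coverageRle(input)[[sq]])
    n <- length(vip)
    if (length(vin) != n)
      stop("IP and input lengths differ on ", sq, call. = FALSE)
    if (n < 2L) next
    starts <- if (n <= w) 1L else seq.int(1L, n - w + 1L, by = params$step)
    csip <- c(0, cumsum(vip)); csin <- c(0, cumsum(vin))
    k <- .windowSums(csip, starts, starts + w - 1L, n)
    centre <- starts + w %/% 2L
    lam <- rep(lamGlobal, length(starts))
    if (ratio > 0) {
      z <- params$localUpperZ %||% 0
      minCnt <- params$localMinCount %||% 0
      for (s in params$localScales) {
        lo <- centre - s %/% 2L
        hi <- lo + s - 1L
        covw <- pmin(n, hi) - pmax(1L, lo) + 1L
        cnt <- .windowSums(csin, lo, hi, n)
        est <- (cnt + z * sqrt(cnt + 1)) / covw * w * ratio
        est[cnt < minCnt] <- 0   # too few fragments to trust this scale
        lam <- pmax(lam, est)
      }
    }
    p <- ppois(k - 1, lam, lower.tail = FALSE)
    if (returnWindows) {
      winout[[sq]] <- GRanges(sq, IRanges(starts, pmin(n, starts + w - 1L)),
                              k = k, lambda = lam, p_value = p)
      next
    }
    sig <- which(p < params$pThreshold & k >= params$fcThreshold * lam &
                   k > 0)
    if (length(sig) == 0L) next
    win <- IRanges(starts[sig], pmin(n, starts[sig] + w - 1L))
    merged <- reduce(win, min.gapwidth = params$mergeGap + 1L)
    mi <- subjectHits(findOverlaps(win, merged))
    fc <- as.numeric(tapply(k[sig], mi, sum) / tapply(lam[sig], mi, sum))
    pv <- as.numeric(tapply(p[sig], mi, min))
    ## summit: argmax of fragment-length rolling sum inside the peak
    summit <- integer(length(merged))
    for (i in seq_along(merged)) {
      a <- start(merged)[i]; b <- end(merged)[i]
      lo <- pmax(a, seq.int(a, b) - fl %/% 2L)
      hi <- pmin(b, seq.int(a, b) + (fl - fl %/% 2L) - 1L)
      sm <- .windowSums(csip, lo, hi, n)
      summit[i] <- a + which.max(sm) - 1L
    }
    gr <- GRanges(sq, merged, strand = "*", summit = summit,
                  fold_change = fc, p_value = pv)
    out[[sq]] <- gr
  }
  if (returnWindows)
    return(sort(suppressWarnings(do.call(c, unname(winout))),
                ignore.strand = TRUE))
  if (length(out) == 0L)
    return(m6aPeaks(GRanges(), sample_id = sample_id, line = line))
  res <- sort(suppressWarnings(do.call(c, unname(out))),
              ignore.strand = TRUE)
  mcols(res)$name <- paste0(ifelse(is.na(sample_id), "peak", sample_id),
                            "_", seq_along(res))
  m6aPeaks(res, sample_id = sample_id, line = line)
}

#' Recall and false-discovery proportion against ground truth
#'
#' A truth site counts as recovered when some called peak overlaps it
#' by at least `matchFraction` of the shorter interval; a called peak
#' counts as spurious when it matches no truth site.
#'
#' @param called called peak [GRanges].
#' @param truth ground-truth site [GRanges].
#' @param matchFraction overlap fraction threshold (default 0.5).
#' @return list with `recall`, `fdp`, `n_called`, `n_truth` and
#'   `flagged` (TRUE when a convention filled in an undefined value:
#'   empty truth gives `recall = NA`, no calls give `fdp = 0`).
#' @export
peakFdrRecall <- function(called, truth, matchFraction = 0.5) {
  flagged <- FALSE
  if (length(truth) == 0L) {
    return(list(recall = NA_real_, fdp = if (length(called)) 1 else 0,
                n_called = length(called), n_truth = 0L, flagged = TRUE))
  }
  if (length(called) == 0L)
    return(list(recall = 0, fdp = 0, n_called = 0L,
                n_truth = length(truth), flagged = TRUE))
  hits <- findOverlaps(called, truth, ignore.strand = TRUE)
  frac <- overlapFraction(called[queryHits(hits)], truth[subjectHits(hits)])
  ok <- frac >= matchFraction
  recTruth <- unique(subjectHits(hits)[ok])
  matchedCalled <- unique(queryHits(hits)[ok])
  list(recall = length(recTruth) / length(truth),
       fdp = 1 - length(matchedCalled) / length(called),
       n_called = length(called), n_truth = length(truth),
       flagged = flagged)
}

#' Count fragment starts in regions
#'
#' @param cov a [FragmentCoverage-class] track.
#' @param regions a [GRanges].
#' @return numeric vector of per-region summed counts.
#' @export
countCoverageInRegions <- function(cov, regions) {
  stopifnot(is(cov, "FragmentCoverage"), is(regions, "GRanges"))
  rle <- coverageRle(cov)
  out <- numeric(length(regions))
  for (sq in unique(as.character(seqnames(regions)))) {
    i <- which(as.character(seqnames(regions)) == sq)
    if (!sq %in% names(rle)) stop("no coverage for ", sq, call. = FALSE)
    v <- rle[[sq]]
    s <- pmax(1L, start(regions)[i]); e <- pmin(length(v), end(regions)[i])
    out[i] <- viewSums(Views(v, s, e))
  }
  out
}

#' Write a coverage track as bedGraph
#'
#' Zero-count runs are omitted; the reader restores them given the
#' sequence lengths.
#'
#' @param cov a [FragmentCoverage-class] track.
#' @param path output path (.bedGraph).
#' @return (invisibly) the output path.
#' @export
writeCoverageBedGraph <- function(cov, path) {
  gr <- as(coverageRle(cov), "GRanges")
  gr <- gr[gr$score > 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path path to a bedGraph file.
#' @param seqlengths named integer vector of reference sequence lengths.
#' @param totalFragments library size; defaults to the total count.
#' @param fragmentLength nominal fragment length (default 100).
#' @return a [FragmentCoverage-class] track.
#' @export
readCoverageBedGraph <- function(path, seqlengths, totalFragments = NULL,
                                 fragmentLength = 100) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  missing <- setdiff(as.character(seqnames(gr)), names(seqlengths))
  if (length(missing))
    stop("bedGraph has sequences without declared lengths: ",
         paste(missing, collapse = ", "), call. = FALSE)
  seqlevels(gr) <- names(seqlengths)
  seqlengths(gr) <- seqlengths
  cov <- coverage(gr, weight = "score")
  fragmentCoverage(cov, totalFragments = totalFragments,
                   fragmentLength = fragmentLength)
}
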