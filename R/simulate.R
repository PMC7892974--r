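## Synthetic two-condition, three-replicate MeRIP-seq generator.  It
## emulates the statistical structure of a desk-scale m6A study: a
## small random transcriptome, a configurable fraction of methylated
## transcripts carrying 1-4 enrichment sites biased towards CDS and
## the codon-flanking segments, GGACU embedded at most true sites,
## condition-dynamic sites with a configurable low share, and gene
## expression coupled log-linearly to m6A enrichment.  Ground truth is
## returned separately from the emitted files so downstream recovery
## tests never reverse-engineer outputs.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: ~70% of coding
#' transcripts methylated, 1-4 sites per methylated transcript (60/25/
#' 10/5%), placement biased to CDS and the codon segments, 16-fold IP
#' enrichment at sites (so that the composition-normalised, observable
#' fold stays well above the caller's fold-2 gate even for
#' condition-reduced sites), 35% of sites condition-dynamic with a
#' 71.1% low-in-B share, and a negative expression-methylation
#' coupling (slope -0.8, noise 0.3 in log2).  See the package vignette
#' for the reasoning behind each value.
#'
#' @param nGenes number of genes (one representative isoform each).
#' @param seed integer seed governing every random draw.
#' @param lengthMeanlog,lengthSdlog,minLength spliced transcript length
#'   distribution (log-normal, nt).
#' @param utr5Frac,cdsFrac,utr3Frac spliced length shares of the
#'   5'UTR / CDS / 3'UTR.
#' @param maxExons,minExonWidth,intronMeanlog,intronSdlog exon/intron
#'   structure.
#' @param isoformProbs probabilities of 1, 2 or 3 isoforms per gene.
#' @param gc genomic GC content.
#' @param intergenicGap,nChroms gene spacing and chromosome count.
#' @param methylatedFraction fraction of coding genes carrying sites.
#' @param peaksPerTxProbs site-count distribution over 1..4.
#' @param segmentWeights site placement weights over the five segments.
#' @param siteWidth site width in spliced nt.
#' @param minSiteGap minimum spliced distance between site centres.
#' @param motifEmbedProb probability a site carries an embedded GGACU.
#' @param enrichmentFold IP enrichment fold at sites (condition A).
#' @param dynamicFraction fraction of sites with a condition effect.
#' @param lowShare share of dynamic sites that are lower in B.
#' @param dynamicEffectFold fold applied to the site enrichment in B.
#' @param exprMeanlog2 mean log2 expression.
#' @param couplingSlope,couplingSigma expression-methylation coupling:
#'   `log2 e = exprMeanlog2 + slope * centred(log2 A) + N(0, sigma)`
#'   where `A` is the gene-level enrichment.
#' @param exprConcordProb,exprConcordShift probability and log2 size of
#'   a concordant condition-B expression shift for dynamic genes.
#' @param nbDispersion negative-binomial dispersion of per-gene counts.
#' @param libSizeInput,libSizeIP library sizes (fragments/replicate).
#' @param fragmentLength fragment length (nt).
#' @param replicates replicates per condition.
#' @param lines condition labels (B plays the "fat"-type condition).
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(nGenes = 400, seed = 1,
    lengthMeanlog = log(2400), lengthSdlog = 0.45, minLength = 600,
    utr5Frac = 0.15, cdsFrac = 0.60, utr3Frac = 0.25,
    maxExons = 5, minExonWidth = 200,
    intronMeanlog = log(400), intronSdlog = 0.6,
    isoformProbs = c(0.70, 0.20, 0.10), gc = 0.42,
    intergenicGap = 6000, nChroms = 2,
    methylatedFraction = 0.7,
    peaksPerTxProbs = c(`1` = 0.60, `2` = 0.25, `3` = 0.10, `4` = 0.05),
    segmentWeights = c(five_prime_utr = 0.05, start_codon = 0.15,
                       cds = 0.40, stop_codon = 0.25,
                       three_prime_utr = 0.15),
    siteWidth = 100, minSiteGap = 300, motifEmbedProb = 0.8,
    enrichmentFold = 48, dynamicFraction = 0.35, lowShare = 0.711,
    dynamicEffectFold = 4.5, exprMeanlog2 = log2(30),
    couplingSlope = -0.5, couplingSigma = 0.3,
    exprConcordProb = 0.15, exprConcordShift = 1.0,
    nbDispersion = 0.1, libSizeInput = 5.4e5, libSizeIP = 5.4e5,
    fragmentLength = 100, replicates = 3, lines = c("A", "B")) {
  cfg <- as.list(environment())
  stopifnot(abs(utr5Frac + cdsFrac + utr3Frac - 1) < 1e-8,
            abs(sum(peaksPerTxProbs) - 1) < 1e-8,
            abs(sum(isoformProbs) - 1) < 1e-8,
            all(segmentWeights >= 0), sum(segmentWeights) > 0,
            methylatedFraction >= 0, methylatedFraction <= 1,
            dynamicFraction >= 0, dynamicFraction <= 1,
            lowShare >= 0, lowShare <= 1,
            enrichmentFold >= 1, dynamicEffectFold >= 1,
            nbDispersion >= 0, libSizeInput > 0, libSizeIP > 0,
            nGenes >= 2, replicates >= 2, length(lines) == 2L)
  cfg$segmentWeights <- segmentWeights / sum(segmentWeights)
  class(cfg) <- "SimulationConfig"
  cfg
}

## Random partition of L into n parts of at least minw.
#' @noRd
.partition <- function(L, n, minw) {
  if (n == 1L) return(L)
  x <- stats::rgamma(n, shape = 2)
  w <- floor(L * x / sum(x)); w[n] <- L - sum(w[-n])
  for (i in seq_len(n)) if (w[i] < minw) {
    j <- which.max(w); d <- minw - w[i]
    w[j] <- w[j] - d; w[i] <- minw
  }
  if (any(w < minw)) { w <- rep(L %/% n, n); w[n] <- L - sum(w[-n]) }
  as.integer(w)
}

#' Simulate a random annotated transcriptome
#'
#' Generates a random genome, gene models with 1-3 isoforms (extra
#' isoforms are 3'-truncated), and the true m6A sites: per methylated
#' gene, 1-4 sites placed within single exons according to the segment
#' weights, with GGACU written into the genome (transcript sense) at
#' motif-flagged site centres.
#'
#' @param config a [simulationConfig()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   ([TranscriptModels-class]), `segmented`
#'   ([SegmentedTranscripts-class]), `gtf` (exportable [GRanges]),
#'   `seqlengths`, and `truth` (`$sites` data.frame).
#' @export
simulateTranscriptome <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nGenes
  chroms <- paste0("chr", seq_len(config$nChroms))
  cursor <- setNames(rep(1L, config$nChroms), chroms)

  exRows <- list(); cdsRows <- list()
  for (g in seq_len(n)) {
    gid <- sprintf("gene%03d", g)
    L <- max(config$minLength,
             round(stats::rlnorm(1, config$lengthMeanlog,
                                 config$lengthSdlog)))
    u5 <- max(10L, round(config$utr5Frac * L))
    u3 <- max(10L, round(config$utr3Frac * L))
    cdsL <- L - u5 - u3
    ne <- sample.int(min(config$maxExons,
                         max(1L, L %/% (config$minExonWidth + 50L))), 1L)
    ew <- .partition(L, ne, config$minExonWidth)
    iw <- if (ne > 1L)
      pmax(80L, round(stats::rlnorm(ne - 1L, config$intronMeanlog,
                                    config$intronSdlog)))
      else integer(0)
    chrom <- chroms[(g - 1L) %% config$nChroms + 1L]
    strand <- sample(c("+", "-"), 1L)
    gstart <- cursor[[chrom]] + config$intergenicGap
    es <- integer(ne); ee <- integer(ne)
    pos <- gstart
    for (j in seq_len(ne)) {
      es[j] <- pos; ee[j] <- pos + ew[j] - 1L
      pos <- ee[j] + 1L + if (j < ne) iw[j] else 0L
    }
    cursor[[chrom]] <- ee[ne]

    nIso <- sample.int(3L, 1L, prob = config$isoformProbs)
    for (k in seq_len(nIso)) {
      tid <- sprintf("%s.t%d", gid, k)
      if (k == 1L || ne < 3L) { ks <- es; ke <- ee }
      else {                      # drop the transcript-3'-most exon
        drop <- if (strand == "+") ne else 1L
        ks <- es[-drop]; ke <- ee[-drop]
      }
      exRows[[length(exRows) + 1L]] <- data.frame(
        chrom = chrom, start = ks, end = ke, strand = strand,
        gene_id = gid, transcript_id = tid)
      ## CDS on the spliced axis of this isoform
      isoL <- sum(ke - ks + 1L)
      s0 <- u5; t0 <- min(u5 + cdsL, isoL - 10L)
      if (t0 - s0 >= 60L)
        cdsRows[[length(cdsRows) + 1L]] <- data.frame(
          chrom = chrom, start = ks, end = ke, strand = strand,
          gene_id = gid, transcript_id = tid, s0 = s0, t0 = t0)[1L, ]
    }
  }
  exdf <- do.call(rbind, exRows)
  exons <- GRanges(exdf$chrom, IRanges(exdf$start, exdf$end),
                   strand = exdf$strand, gene_id = exdf$gene_id,
                   transcript_id = exdf$transcript_id)
  ## temporary models (exons only) provide the spliced->genomic maps
  tmp <- .makeTranscriptModels(exons)
  cdsG <- GRanges()
  if (length(cdsRows)) {
    chains <- .chainList(tmp)
    mats <- lapply(cdsRows, function(r)
      .piecesMat(chains[[r$transcript_id]], r$s0, r$t0))
    np <- vapply(mats, nrow, integer(1))
    m <- do.call(rbind, mats)
    ri <- rep(seq_along(cdsRows), np)
    cdsG <- GRanges(
      vapply(cdsRows, function(r) r$chrom, character(1))[ri],
      IRanges(m[, 1L], m[, 2L]),
      strand = vapply(cdsRows, function(r) r$strand, character(1))[ri],
      gene_id = vapply(cdsRows, function(r) r$gene_id, character(1))[ri],
      transcript_id = vapply(cdsRows, function(r) r$transcript_id,
                             character(1))[ri])
  }
  models <- .makeTranscriptModels(exons, cds = cdsG)
  st <- segmentTranscripts(models)

  seqlen <- setNames(as.integer(cursor + config$intergenicGap), chroms)
  genome <- DNAStringSet(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), seqlen[[ch]], replace = TRUE,
                 prob = c((1 - config$gc) / 2, config$gc / 2,
                          config$gc / 2, (1 - config$gc) / 2)),
          collapse = ""), character(1)))
  names(genome) <- chroms

  sites <- .placeSites(config, models, st)
  ## embed GGACU (DNA: GGACT) in transcript sense at motif-flagged sites
  if (nrow(sites)) {
    for (i in which(sites$motif)) {
      ch <- sites$chrom[i]
      lo <- sites$motif_start[i]; hi <- lo + 4L
      pat <- if (sites$strand[i] == "+") "GGACT" else "AGTCC"
      genome[[ch]] <- replaceAt(genome[[ch]], IRanges(lo, hi), pat)
    }
  }

  gtf <- c(granges(exons), granges(cdsG))
  mcols(gtf) <- DataFrame(
    type = c(rep("exon", length(exons)), rep("CDS", length(cdsG))),
    gene_id = c(exons$gene_id, if (length(cdsG)) cdsG$gene_id),
    transcript_id = c(exons$transcript_id,
                      if (length(cdsG)) cdsG$transcript_id),
    phase = c(rep(NA_integer_, length(exons)), .cdsPhases(cdsG)))
  list(genome = genome, models = models, segmented = st, gtf = gtf,
       seqlengths = seqlen, truth = list(sites = sites), config = config)
}

## GTF phase per CDS piece: bases to skip to reach the next codon
## boundary, accumulated along the transcript (pieces arrive in
## transcript order per isoform).
#' @noRd
.cdsPhases <- function(cdsG) {
  if (length(cdsG) == 0L) return(integer(0))
  phase <- integer(length(cdsG))
  for (t in unique(cdsG$transcript_id)) {
    i <- which(cdsG$transcript_id == t)
    w <- width(cdsG)[i]
    before <- cumsum(c(0L, w[-length(w)]))
    phase[i] <- (3L - before %% 3L) %% 3L
  }
  phase
}

## Choose methylated genes and place their sites.
#' @noRd
.placeSites <- function(config, models, st) {
  td <- txData(models)
  reps <- which(td$representative & td$coding)
  nMeth <- round(config$methylatedFraction * length(reps))
  methIdx <- sort(sample(reps, nMeth))
  half <- config$siteWidth %/% 2L
  labs <- .segmentLabels()
  chains <- .chainList(models)
  rows <- list()
  for (i in methIdx) {
    tx <- td$transcript_id[i]; L <- td$spliced_length[i]
    ch <- chains[[i]]
    b <- segmentBreaks(st)[tx, ]
    segLen <- b[-1L] - b[-6L]
    nSites <- sample.int(4L, 1L, prob = config$peaksPerTxProbs)
    centres <- integer(0); segs <- character(0)
    for (s in seq_len(nSites)) {
      for (try in seq_len(30L)) {
        wgt <- config$segmentWeights * (segLen > 0)
        if (sum(wgt) == 0) break
        j <- sample.int(5L, 1L, prob = wgt)
        c0 <- b[j] + sample.int(segLen[j], 1L) - 1L
        c0 <- min(max(c0, half), L - half - 1L)
        if (length(centres) && any(abs(centres - c0) < config$minSiteGap))
          next
        ## site must sit inside one exon (clipped if needed)
        ex <- findInterval(c0, ch$cum)
        elo <- ch$cum[ex]; ehi <- ch$cum[ex + 1L] - 1L
        if (c0 - elo < 5L || ehi - c0 < 5L) next
        slo <- max(c0 - half, elo); shi <- min(c0 + half - 1L, ehi)
        ## prefer full-width sites; accept edge-clipped ones only when
        ## placement keeps failing
        minw <- if (try <= 20L) config$siteWidth else config$siteWidth * 0.5
        if (shi - slo + 1L < minw) next
        centres <- c(centres, c0); segs <- c(segs, labs[j])
        glo <- .genomicPos(ch, slo)
        ghi <- .genomicPos(ch, shi)
        gmot <- range(.genomicPos(ch, c(c0 - 2L, c0 + 2L)))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = td$gene_id[i], transcript_id = tx,
          chrom = td$seqid[i], strand = td$strand[i],
          start = min(glo, ghi), end = max(glo, ghi),
          summit = .genomicPos(ch, c0),
          spliced_center = c0, segment = labs[j],
          motif = stats::runif(1) < config$motifEmbedProb,
          motif_start = gmot[1L])
        break
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      summit = integer(), spliced_center = integer(),
                      segment = character(), motif = logical(),
                      motif_start = integer()))
  out <- do.call(rbind, rows)
  out$site_id <- sprintf("site%04d", seq_len(nrow(out)))
  out
}

## log2 expression coupled to gene-level enrichment (latent model used
## by simulateMerip; exposed internally for calibration tests).
#' @noRd
.coupleExpression <- function(log2A, slope, sigma, meanlog2e) {
  meanlog2e + slope * (log2A - mean(log2A)) + stats::rnorm(length(log2A),
                                                           0, sigma)
}

#' Simulate IP/input fragment coverage, counts and FPKM
#'
#' Draws per-gene expression coupled to the gene-level m6A enrichment,
#' then for every condition x replicate samples input fragments
#' uniformly along spliced transcripts and IP fragments with site
#' regions upweighted by their enrichment fold.  The per-gene rate of
#' the IP and input library of one replicate share the same
#' negative-binomial gene factor (the two libraries come from the same
#' RNA sample), so under no enrichment the two tracks are
#' exchangeable.  Dynamic sites have their enrichment scaled in
#' condition B (`lowShare` of them down by `dynamicEffectFold`).
#'
#' @param config a [simulationConfig()].
#' @param txome a [simulateTranscriptome()] result for this config.
#' @return list with `coverage[[line]][[rep]]$ip/$input`
#'   ([FragmentCoverage-class]), `counts$input/$ip[[line]]` (gene x
#'   replicate matrices), `fpkm$input/$ip[[line]]`, `records[[line]]`
#'   ([expressionRecords()] data.frames) and `truth` (`$sites` with
#'   condition effects, `$genes` with latent expression/enrichment).
#' @export
simulateMerip <- function(config = simulationConfig(),
                          txome = simulateTranscriptome(config)) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 7919L)
  td <- txData(txome$models)
  repIdx <- which(td$representative)
  tx <- td$transcript_id[repIdx]
  gene <- td$gene_id[repIdx]
  L <- td$spliced_length[repIdx]
  nG <- length(tx)
  lines <- config$lines

  sites <- txome$truth$sites
  nS <- nrow(sites)
  ## site folds (condition A) and condition effects
  fA <- if (nS) 1 + (config$enrichmentFold - 1) *
          2^stats::rnorm(nS, 0, 0.1) else numeric(0)
  effect <- rep("none", nS)
  if (nS) {
    nDyn <- round(config$dynamicFraction * nS)
    dynIdx <- sample.int(nS, nDyn)
    nLow <- round(config$lowShare * nDyn)
    effect[dynIdx[seq_len(nLow)]] <- "low"
    if (nDyn > nLow) effect[dynIdx[(nLow + 1L):nDyn]] <- "high"
  }
  fB <- fA
  fB[effect == "low"] <- 1 + (fA[effect == "low"] - 1) /
    config$dynamicEffectFold
  fB[effect == "high"] <- 1 + (fA[effect == "high"] - 1) *
    config$dynamicEffectFold

  siteOfGene <- if (nS) split(seq_len(nS), sites$transcript_id) else list()
  enrich <- function(f) {
    A <- rep(1, nG)
    for (t in names(siteOfGene)) {
      i <- match(t, tx)
      if (is.na(i)) next
      s <- siteOfGene[[t]]
      w <- pmin(sites$end[s], sites$start[s] + config$siteWidth) -
        sites$start[s] + 1L
      A[i] <- 1 + sum((f[s] - 1) * w) / L[i]
    }
    A
  }
  A_a <- enrich(fA); A_b <- enrich(fB)

  log2e <- .coupleExpression(log2(A_a), config$couplingSlope,
                             config$couplingSigma, config$exprMeanlog2)
  e <- 2^log2e
  ## optional concordant expression shift in B for dynamic genes
  log2eB <- log2e
  dynGenes <- unique(sites$transcript_id[effect != "none"])
  for (t in dynGenes) {
    if (stats::runif(1) >= config$exprConcordProb) next
    i <- match(t, tx)
    s <- siteOfGene[[t]]
    dir <- if (sum(fB[s]) >= sum(fA[s])) 1 else -1
    log2eB[i] <- log2eB[i] + dir * config$exprConcordShift
  }
  eB <- 2^log2eB

  ## exon chains cached per representative transcript
  chains <- .chainList(txome$models)[repIdx]
  names(chains) <- tx
  chromOf <- td$seqid[repIdx]
  seqlen <- txome$seqlengths

  ## piecewise spliced weights per gene (baseline 1, sites upweighted)
  pieceTable <- function(i, f) {
    t <- tx[i]
    s <- siteOfGene[[t]]
    if (is.null(s) || all(f[s] == 1))
      return(cbind(lo = 0L, hi = L[i], w = L[i]))
    slo <- vapply(s, function(k) {
      .splicedPos(chains[[t]],
                  if (td$strand[repIdx[i]] == "+")
                    sites$start[k] else sites$end[k])
    }, integer(1))
    shi <- slo + (sites$end[s] - sites$start[s])
    ord <- order(slo); slo <- slo[ord]; shi <- shi[ord]; fs <- f[s][ord]
    bounds <- sort(unique(c(0L, slo, shi + 1L, L[i])))
    lo <- bounds[-length(bounds)]; hi <- bounds[-1L]
    w <- hi - lo
    mult <- rep(1, length(lo))
    for (k in seq_along(slo)) {
      inside <- lo >= slo[k] & hi <= shi[k] + 1L
      mult[inside] <- fs[k]
    }
    cbind(lo = lo, hi = hi, w = w * mult)
  }

  lineEffects <- list(fA, fB); names(lineEffects) <- lines
  lineExpr <- list(e, eB); names(lineExpr) <- lines

  coverage <- list(); counts <- list(input = list(), ip = list())
  fpkms <- list(input = list(), ip = list()); records <- list()
  for (ln in lines) {
    f <- lineEffects[[ln]]; eg <- lineExpr[[ln]]
    A <- enrich(f)
    inW <- eg * L; ipW <- eg * L * A
    pieces <- lapply(seq_len(nG), function(i) pieceTable(i, f))
    covLine <- list()
    cin <- matrix(0, nG, config$replicates,
                  dimnames = list(gene, paste0(ln, "_r",
                                               seq_len(config$replicates))))
    cip <- cin
    for (r in seq_len(config$replicates)) {
      gamma <- if (config$nbDispersion > 0)
        stats::rgamma(nG, shape = 1 / config$nbDispersion,
                      rate = 1 / config$nbDispersion) else rep(1, nG)
      muIn <- config$libSizeInput * inW * gamma / sum(inW * gamma)
      muIp <- config$libSizeIP * ipW * gamma / sum(ipW * gamma)
      kin <- stats::rpois(nG, muIn); kip <- stats::rpois(nG, muIp)
      cin[, r] <- kin; cip[, r] <- kip
      gpIn <- vector("list", nG); gpIp <- vector("list", nG)
      for (i in seq_len(nG)) {
        ch <- chains[[tx[i]]]
        if (kin[i] > 0) {
          sp <- sample.int(L[i], kin[i], replace = TRUE) - 1L
          gpIn[[i]] <- .mapSplicedVec(ch, sp)
        }
        if (kip[i] > 0) {
          pt <- pieces[[i]]
          pidx <- sample.int(nrow(pt), kip[i], replace = TRUE,
                             prob = pt[, "w"])
          sp <- pt[pidx, "lo"] +
            floor(stats::runif(kip[i]) * (pt[pidx, "hi"] - pt[pidx, "lo"]))
          gpIp[[i]] <- .mapSplicedVec(ch, as.integer(sp))
        }
      }
      vin <- vip <- list()
      for (chrom in names(seqlen)) {
        gi <- which(chromOf == chrom)
        vin[[chrom]] <- tabulate(unlist(gpIn[gi]), nbins = seqlen[[chrom]])
        vip[[chrom]] <- tabulate(unlist(gpIp[gi]), nbins = seqlen[[chrom]])
      }
      covLine[[r]] <- list(
        input = fragmentCoverage(vin, totalFragments = sum(kin),
                                 fragmentLength = config$fragmentLength),
        ip = fragmentCoverage(vip, totalFragments = sum(kip),
                              fragmentLength = config$fragmentLength))
    }
    coverage[[ln]] <- covLine
    counts$input[[ln]] <- cin; counts$ip[[ln]] <- cip
    fpkms$input[[ln]] <- sapply(seq_len(config$replicates), function(r)
      fpkm(cin[, r], L, max(1, sum(cin[, r]))))
    fpkms$ip[[ln]] <- sapply(seq_len(config$replicates), function(r)
      fpkm(cip[, r], L, max(1, sum(cip[, r]))))
    dimnames(fpkms$input[[ln]]) <- dimnames(cin)
    dimnames(fpkms$ip[[ln]]) <- dimnames(cip)
    records[[ln]] <- expressionRecords(
      gene, rowMeans(fpkms$input[[ln]]), rowMeans(fpkms$ip[[ln]]),
      line = ln)
  }

  sites$effect <- effect
  sites$fold_a <- fA; sites$fold_b <- fB
  genes <- data.frame(gene_id = gene, transcript_id = tx,
                      spliced_length = L, log2_expression = log2e,
                      log2_expression_b = log2eB,
                      enrichment_a = A_a, enrichment_b = A_b,
                      methylated = tx %in% sites$transcript_id)
  list(coverage = coverage, counts = counts, fpkm = fpkms,
       records = records, seqlengths = seqlen,
       truth = list(sites = sites, genes = genes), config = config)
}

## Vectorized spliced (0-based) -> genomic (1-based) map on one chain.
#' @noRd
.mapSplicedVec <- function(ch, sp) {
  j <- findInterval(sp, ch$cum)
  off <- sp - ch$cum[j]
  if (ch$strand == "-") ch$ends[j] - off else ch$starts[j] + off
}

#' Write a complete synthetic fixture to disk
#'
#' Emits genome FASTA, GTF, 2 x replicates x 2 bedGraph coverage
#' tracks, count and FPKM TSVs, the ground truth as JSON and a
#' manifest with md5 checksums.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if needed).
#' @param txome,merip optional precomputed simulation results.
#' @return (invisibly) the manifest list.
#' @export
emitFixture <- function(config = simulationConfig(), outdir,
                        txome = simulateTranscriptome(config),
                        merip = simulateMerip(config, txome)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  writeXStringSet(txome$genome, fp("genome.fa"))
  rtracklayer::export(txome$gtf, fp("annotation.gtf"), format = "gtf")
  for (ln in config$lines) for (r in seq_len(config$replicates)) {
    writeCoverageBedGraph(merip$coverage[[ln]][[r]]$input,
                          fp(sprintf("cov_%s_r%d_input.bedGraph", ln, r)))
    writeCoverageBedGraph(merip$coverage[[ln]][[r]]$ip,
                          fp(sprintf("cov_%s_r%d_ip.bedGraph", ln, r)))
  }
  for (what in c("input", "ip")) for (ln in config$lines) {
    write.table(merip$counts[[what]][[ln]],
                fp(sprintf("counts_%s_%s.tsv", what, ln)),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(merip$fpkm[[what]][[ln]],
                fp(sprintf("fpkm_%s_%s.tsv", what, ln)),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  jsonlite::write_json(
    list(sites = merip$truth$sites, genes = merip$truth$genes),
    fp("truth.json"), digits = NA, auto_unbox = TRUE)
  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("meripr")),
    seed = config$seed, n_genes = config$nGenes,
    files = as.list(setNames(unname(tools::md5sum(files)),
                             basename(files))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
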