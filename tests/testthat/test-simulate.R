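test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(nGenes = 25, seed = 77)
  t1 <- simulateTranscriptome(cfg)
  t2 <- simulateTranscriptome(cfg)
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  expect_identical(t1$truth$sites, t2$truth$sites)
  m1 <- simulateMerip(cfg, t1)
  m2 <- simulateMerip(cfg, t2)
  expect_identical(m1$counts, m2$counts)
  expect_identical(
    as.numeric(coverageRle(m1$coverage$A[[1]]$ip)$chr1),
    as.numeric(coverageRle(m2$coverage$A[[1]]$ip)$chr1))
})

test_that("simulated annotation satisfies the segmentation contracts", {
  cfg <- simulationConfig(nGenes = 40, seed = 78)
  tx <- simulateTranscriptome(cfg)
  td <- txData(tx$models)
  sl <- segmentLengths(tx$segmented)
  cod <- td$coding
  expect_true(all(rowSums(sl[cod, , drop = FALSE]) ==
                    td$spliced_length[cod]))
  # GTF written to disk re-imports to the same structure
  p <- tempfile(fileext = ".gtf")
  rtracklayer::export(tx$gtf, p, format = "gtf")
  back <- readTranscriptsGTF(p)
  tdb <- txData(back)
  i <- match(td$transcript_id, tdb$transcript_id)
  expect_false(anyNA(i))
  expect_equal(tdb$spliced_length[i], td$spliced_length)
  expect_equal(tdb$cds_left[i], td$cds_left)
  expect_equal(tdb$cds_right[i], td$cds_right)
})

test_that("transcript lengths follow the configured distribution", {
  cfg <- simulationConfig(nGenes = 500, seed = 79)
  tx <- simulateTranscriptome(cfg)
  td <- txData(tx$models)
  L <- td$spliced_length[td$representative]
  want <- exp(cfg$lengthMeanlog + cfg$lengthSdlog^2 / 2)
  expect_lt(abs(mean(L) - want) / want, 0.1)
})

test_that("ground truth realises the configured site structure", {
  cfg <- simulationConfig(nGenes = 150, seed = 80)
  tx <- simulateTranscriptome(cfg)
  m <- simulateMerip(cfg, tx)
  ts <- m$truth$sites
  # methylated fraction
  td <- txData(tx$models)
  nCoding <- sum(td$representative & td$coding)
  expect_equal(length(unique(ts$transcript_id)) / nCoding, 0.7,
               tolerance = 0.02)
  # low share among dynamic sites is the configured value up to rounding
  nd <- sum(ts$effect != "none")
  expect_lt(abs(sum(ts$effect == "low") / nd - 0.711),
            3 * sqrt(0.711 * 0.289 / nd))
  # sites do not overlap within a transcript and carry >= 1 folds
  expect_true(all(ts$fold_a >= 1) && all(ts$fold_b >= 1))
  bytx <- split(ts, ts$transcript_id)
  ok <- vapply(bytx, function(d) {
    if (nrow(d) < 2) return(TRUE)
    o <- order(d$start); all(d$start[o][-1] > d$end[o][-nrow(d)])
  }, logical(1))
  expect_true(all(ok))
  # motif embedding: GGACU (DNA sense) present at flagged site centres
  genome <- tx$genome
  hit <- vapply(which(ts$motif), function(i) {
    s <- Biostrings::subseq(genome[[ts$chrom[i]]], ts$motif_start[i],
                            ts$motif_start[i] + 4L)
    as.character(if (ts$strand[i] == "-") Biostrings::reverseComplement(s)
                 else s)
  }, character(1))
  expect_true(all(hit == "GGACT"))
})

test_that("no enrichment makes IP and input window counts exchangeable", {
  cfg <- simulationConfig(nGenes = 60, seed = 81, enrichmentFold = 1,
                          dynamicFraction = 0)
  tx <- simulateTranscriptome(cfg)
  m <- simulateMerip(cfg, tx)
  ipv <- as.numeric(coverageRle(m$coverage$A[[1]]$ip)$chr1)
  inv <- as.numeric(coverageRle(m$coverage$A[[1]]$input)$chr1)
  win <- function(v) {
    n <- (length(v) %/% 100) * 100
    colSums(matrix(v[seq_len(n)], 100))
  }
  ki <- win(ipv); kn <- win(inv)
  keep <- ki + kn > 0
  set.seed(1)
  ks <- suppressWarnings(stats::ks.test(ki[keep] + runif(sum(keep)),
                                        kn[keep] + runif(sum(keep))))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero coupling slope decouples expression from enrichment", {
  set.seed(82)
  log2A <- c(rep(0, 5000), rnorm(5000, 1.2, 0.4))
  e <- meripr:::.coupleExpression(log2A, slope = 0, sigma = 0.3,
                                  meanlog2e = log2(30))
  expect_lt(abs(cor(log2A, e)), 0.05)
  en <- meripr:::.coupleExpression(log2A, slope = -0.5, sigma = 0.3,
                                   meanlog2e = log2(30))
  expect_lt(cor(log2A, en), -0.5)
})

test_that("emitFixture writes a complete, checksum-stable file set", {
  cfg <- simulationConfig(nGenes = 8, seed = 83)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  m1 <- emitFixture(cfg, d1)
  m2 <- emitFixture(cfg, d2)
  need <- c("genome.fa", "annotation.gtf", "truth.json", "manifest.json",
            "cov_A_r1_ip.bedGraph", "cov_B_r3_input.bedGraph",
            "counts_input_A.tsv", "fpkm_ip_B.tsv")
  expect_true(all(need %in% list.files(d1)))
  expect_identical(m1$files, m2$files)     # checksums stable under the seed
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_true(length(truth$sites) > 0)
  # emitted coverage reads back to the in-memory track
  tx <- simulateTranscriptome(cfg)
  mer <- simulateMerip(cfg, tx)
  cov <- readCoverageBedGraph(file.path(d1, "cov_A_r1_ip.bedGraph"),
                              tx$seqlengths)
  expect_equal(as.numeric(coverageRle(cov)$chr1),
               as.numeric(coverageRle(mer$coverage$A[[1]]$ip)$chr1))
})
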