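test_that("BED peaks round-trip losslessly and parse the documented layout", {
  p <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tp1\t0\t+\t3.5\t1e-6", p)
  pk <- readPeaksBED(p)
  expect_equal(start(pk), 101L)          # 0-based half-open -> 1-based
  expect_equal(end(pk), 200L)
  expect_equal(mcols(pk)$fold_change, 3.5)
  expect_equal(mcols(pk)$p_value, 1e-6)
  expect_equal(mcols(pk)$summit, 150L)   # midpoint default

  set.seed(1)
  big <- randomPeakSet(100)
  mcols(big)$fold_change <- runif(100, 1, 20)
  mcols(big)$p_value <- runif(100)
  mcols(big)$summit <- start(big) + 5L
  out <- tempfile(fileext = ".bed")
  writePeaksBED(big, out)
  back <- readPeaksBED(out)
  expect_equal(start(back), start(big))
  expect_equal(end(back), end(big))
  expect_equal(mcols(back)$fold_change, mcols(big)$fold_change)
  expect_equal(mcols(back)$p_value, mcols(big)$p_value)
  expect_equal(mcols(back)$summit, mcols(big)$summit)
})

test_that("malformed and minimal BED inputs are handled as specified", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tok\t0\t+\t2\t0.1",
               "chr1\t300\t250\tbad\t0\t+\t2\t0.1"), p)
  expect_error(readPeaksBED(p), "line 2")
  writeLines("chr1\t100\t200\tp1\t0\t+", p)
  expect_warning(pk <- readPeaksBED(p), "defaulting")
  expect_equal(mcols(pk)$fold_change, 1)
  expect_equal(mcols(pk)$p_value, 1)
})

test_that("overlapFraction matches hand arithmetic and the base-counting oracle", {
  a <- GRanges("chr1", IRanges(1, 100))
  expect_equal(overlapFraction(a, a), 1)
  expect_equal(overlapFraction(a, GRanges("chr1", IRanges(201, 300))), 0)
  expect_equal(overlapFraction(a, GRanges("chr2", IRanges(1, 100))), 0)
  expect_equal(overlapFraction(a, GRanges("chr1", IRanges(51, 250))), 0.5)
  # basis variants on an asymmetric pair
  b <- GRanges("chr1", IRanges(51, 250))
  expect_equal(overlapFraction(a, b, basis = "a"), 0.5)
  expect_equal(overlapFraction(b, a, basis = "a"), 50 / 200)
  expect_equal(overlapFraction(a, b, basis = "reciprocal"), 0.25)
  set.seed(11)
  for (i in 1:100) {
    s1 <- sample.int(500, 1); e1 <- s1 + sample.int(200, 1)
    s2 <- sample.int(500, 1); e2 <- s2 + sample.int(200, 1)
    got <- overlapFraction(GRanges("chr1", IRanges(s1, e1)),
                           GRanges("chr1", IRanges(s2, e2)))
    expect_equal(got, oracleFraction(s1, e1, s2, e2))
    swap <- overlapFraction(GRanges("chr1", IRanges(s2, e2)),
                            GRanges("chr1", IRanges(s1, e1)))
    expect_equal(got, swap)    # shorter basis is symmetric
  }
})

test_that("recurrent consolidation reproduces the worked examples", {
  same <- m6aPeaks(GRanges("chr1", IRanges(101, 200)))
  out <- consolidateRecurrent(list(same, same, same))
  expect_length(out, 1)
  expect_equal(start(out), 101L); expect_equal(end(out), 200L)
  expect_equal(mcols(out)$n_replicates, 3L)

  # present in only 2 of 3 replicates with minReplicates = 3 -> dropped
  out2 <- suppressWarnings(consolidateRecurrent(
    list(same, same, m6aPeaks(GRanges("chr1", IRanges(5000, 5100))))))
  expect_length(out2, 0)
  # but kept at minReplicates = 2
  out3 <- consolidateRecurrent(
    list(same, same, m6aPeaks(GRanges("chr1", IRanges(5000, 5100)))),
    minReplicates = 2)
  expect_length(out3, 1)

  # [100,200), [150,260), [120,210) in 0-based -> intersection [150,200)
  r <- consolidateRecurrent(list(
    m6aPeaks(GRanges("chr1", IRanges(101, 200))),
    m6aPeaks(GRanges("chr1", IRanges(151, 260))),
    m6aPeaks(GRanges("chr1", IRanges(121, 210)))))
  expect_length(r, 1)
  expect_equal(c(start(r), end(r)), c(151L, 200L))

  expect_warning(consolidateRecurrent(list(same, m6aPeaks(GRanges()))),
                 "no peaks")
})

test_that("recurrent consolidation equals brute-force chain enumeration (randomized)", {
  set.seed(99)
  for (rep in 1:60) {
    sets <- lapply(1:3, function(j) randomPeakSet(sample(3:10, 1),
                                                  span = 5000))
    got <- consolidateRecurrent(sets)
    want <- oracleRecurrent(sets)
    expect_equal(length(got), nrow(want), label = paste("instance", rep))
    if (length(got)) {
      expect_equal(start(got), as.integer(want[, 1L]))
      expect_equal(end(got), as.integer(want[, 2L]))
    }
    # output never exceeds the smallest replicate set
    expect_lte(length(got), min(lengths(sets)))
  }
})

test_that("common/unique classification conserves peaks and matches pair enumeration", {
  a <- m6aPeaks(GRanges("chr1", IRanges(1, 100)))
  b <- m6aPeaks(GRanges("chr1", IRanges(c(41, 401), c(140, 500))))
  cmp <- classifyCommonUnique(a, b)
  expect_equal(unname(cmp$summary[["n_pairs"]]), 1)
  expect_length(cmp$common_a, 1)
  expect_length(cmp$unique_b, 1)
  expect_equal(start(cmp$unique_b), 401L)

  ident <- classifyCommonUnique(b, b)
  expect_length(ident$unique_a, 0)
  expect_length(ident$unique_b, 0)

  disj <- classifyCommonUnique(a, m6aPeaks(GRanges("chr1", IRanges(900, 999))))
  expect_length(disj$common_a, 0)
  expect_length(disj$unique_a, 1)

  set.seed(21)
  for (rep in 1:40) {
    pa <- randomPeakSet(sample(2:12, 1), span = 4000)
    pb <- randomPeakSet(sample(2:12, 1), span = 4000)
    cmp <- classifyCommonUnique(pa, pb)
    # conservation
    expect_equal(length(cmp$common_a) + length(cmp$unique_a), length(pa))
    expect_equal(length(cmp$common_b) + length(cmp$unique_b), length(pb))
    # oracle: exhaustive pair check
    want <- 0L
    for (i in seq_along(pa)) for (j in seq_along(pb))
      if (oracleFraction(start(pa)[i], end(pa)[i],
                         start(pb)[j], end(pb)[j]) >= 0.5)
        want <- want + 1L
    expect_equal(unname(cmp$summary[["n_pairs"]]), want)
    # swap symmetry of the pair count
    swp <- classifyCommonUnique(pb, pa)
    expect_equal(unname(swp$summary[["n_pairs"]]), want)
  }
})

test_that("peaks are assigned to transcripts by summit, intergenic flagged", {
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tt\texon\t101\t500\t.\t+\t.\tgene_id \"gA\"; transcript_id \"gA.t1\";",
    "chr1\tt\tCDS\t151\t450\t.\t+\t.\tgene_id \"gA\"; transcript_id \"gA.t1\";",
    "chr1\tt\texon\t101\t300\t.\t+\t.\tgene_id \"gA\"; transcript_id \"gA.t2\";",
    "chr1\tt\tCDS\t151\t290\t.\t+\t.\tgene_id \"gA\"; transcript_id \"gA.t2\";"),
    p)
  tm <- readTranscriptsGTF(p)
  pk <- m6aPeaks(GRanges("chr1", IRanges(c(180, 700), width = 20)))
  asn <- assignPeaksToTranscripts(pk, tm)
  # peak 1 summit in an exon shared by both isoforms -> both listed
  hit <- asn[!is.na(asn$transcript_id) & asn$peak == 1L, ]
  expect_setequal(hit$transcript_id, c("gA.t1", "gA.t2"))
  expect_equal(unique(hit$gene_id), "gA")      # one gene
  # peak 2 outside all exons -> intergenic NA row
  expect_true(is.na(asn$transcript_id[asn$peak == 2L]))
  # only gA.t1 (longest CDS) is representative
  expect_equal(txData(tm)$transcript_id[txData(tm)$representative], "gA.t1")
})
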