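test_that("GTF parsing builds transcript models with correct structure", {
  gtf <- system.file("extdata", "toy.gtf", package = "meripr")
  tm <- readTranscriptsGTF(gtf)
  td <- txData(tm)
  expect_setequal(td$transcript_id, c("g1.t1", "g2.t1"))
  g1 <- td[td$transcript_id == "g1.t1", ]
  expect_equal(g1$spliced_length, 300L)        # 100 + 200 exon nt
  expect_equal(g1$cds_left, 151L)
  expect_equal(g1$cds_right, 400L)
  expect_true(all(td$coding))
  expect_true(all(td$representative))
})

test_that("empty or exon-free GTF yields an empty collection with a warning", {
  p <- tempfile(fileext = ".gtf")
  writeLines(character(0), p)
  expect_warning(tm <- readTranscriptsGTF(p), "empty GTF")
  expect_equal(nrow(txData(tm)), 0L)
  expect_error(readTranscriptsGTF(tempfile()), "not found")
})

test_that("spliced/genomic position maps follow the exon chain", {
  gtf <- system.file("extdata", "toy.gtf", package = "meripr")
  tm <- readTranscriptsGTF(gtf)
  # plus strand: exons 101-200, 301-500
  expect_equal(splicedPosition(tm, "g1.t1", 101L), 0L)
  expect_equal(splicedPosition(tm, "g1.t1", 301L), 100L)
  expect_equal(splicedPosition(tm, "g1.t1", 250L), NA_integer_) # intronic
  # minus strand: exon 101-400, 5' end at genomic 400
  expect_equal(splicedPosition(tm, "g2.t1", 400L), 0L)
  expect_equal(splicedPosition(tm, "g2.t1", 101L), 299L)
  # inverses
  expect_equal(genomicPosition(tm, "g1.t1", c(0L, 100L, 299L)),
               c(101L, 301L, 500L))
  expect_equal(genomicPosition(tm, "g2.t1", 0L), 400L)
})

test_that("segment arithmetic matches the stated definition", {
  # spliced length 1000, s = 200, t = 800 -> 150/100/500/100/150
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tt\texon\t1\t1000\t.\t+\t.\tgene_id \"g\"; transcript_id \"t1\";",
    "chr1\tt\tCDS\t201\t800\t.\t+\t.\tgene_id \"g\"; transcript_id \"t1\";"),
    p)
  st <- segmentTranscripts(readTranscriptsGTF(p))
  expect_equal(unname(segmentLengths(st)["t1", ]),
               c(150, 100, 500, 100, 150))
})

test_that("short 5'UTR truncates the start-codon segment at the transcript start", {
  # s = 30: start_codon = [0, 80), five_prime_utr empty
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tt\texon\t1\t1000\t.\t+\t.\tgene_id \"g\"; transcript_id \"t1\";",
    "chr1\tt\tCDS\t31\t800\t.\t+\t.\tgene_id \"g\"; transcript_id \"t1\";"),
    p)
  st <- segmentTranscripts(readTranscriptsGTF(p))
  sl <- segmentLengths(st)["t1", ]
  expect_equal(unname(sl["five_prime_utr"]), 0)
  expect_equal(unname(sl["start_codon"]), 80)
  b <- segmentBreaks(st)["t1", ]
  expect_equal(unname(b[["b1"]]), 0L)
  expect_equal(unname(b[["b2"]]), 80L)
})

test_that("minus-strand segmentation is identical in spliced coordinates", {
  mk <- function(strand) {
    p <- tempfile(fileext = ".gtf")
    writeLines(c(
      sprintf("chr1\tt\texon\t1\t400\t.\t%s\t.\tgene_id \"g\"; transcript_id \"t1\";", strand),
      sprintf("chr1\tt\texon\t501\t1100\t.\t%s\t.\tgene_id \"g\"; transcript_id \"t1\";", strand),
      sprintf("chr1\tt\tCDS\t201\t900\t.\t%s\t.\tgene_id \"g\"; transcript_id \"t1\";",
              strand)), p)
    segmentTranscripts(readTranscriptsGTF(p))
  }
  stp <- mk("+"); stm <- mk("-")
  expect_equal(segmentLengths(stp), segmentLengths(stm))
  # genomic pieces of the minus-strand 5'UTR sit at the genomic right end
  g <- splicedToGenomic(stm@models, "t1", 0, 150)
  expect_true(all(GenomicRanges::start(g) > 900))
})

test_that("CDS shorter than 100 nt yields an empty CDS segment and abutting codon segments", {
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tt\texon\t1\t1000\t.\t+\t.\tgene_id \"g\"; transcript_id \"t1\";",
    "chr1\tt\tCDS\t401\t460\t.\t+\t.\tgene_id \"g\"; transcript_id \"t1\";"),
    p)
  st <- segmentTranscripts(readTranscriptsGTF(p))
  sl <- segmentLengths(st)["t1", ]
  expect_equal(unname(sl["cds"]), 0)
  expect_equal(sum(sl), 1000)
})

test_that("segmentation matches the per-base labeller and covers every base (randomized)", {
  rm <- randomModels(200, seed = 42)
  st <- segmentTranscripts(rm$models)
  sl <- segmentLengths(st)
  td <- txData(rm$models)
  for (tid in names(rm$info)) {
    inf <- rm$info[[tid]]
    lab <- oracleLabels(inf$s, inf$t, inf$L)
    expect_equal(unname(sl[tid, ]),
                 unname(vapply(colnames(sl), function(l) sum(lab == l),
                               numeric(1))),
                 label = tid)
    expect_equal(sum(sl[tid, ]), inf$L)    # full cover
  }
})

test_that("spliced/genomic round trip is the identity on every exonic base (randomized)", {
  rm <- randomModels(40, seed = 7)
  for (tid in names(rm$info)) {
    inf <- rm$info[[tid]]
    sp <- seq_len(inf$L) - 1L
    expect_equal(genomicPosition(rm$models, tid, sp), inf$gvec,
                 label = tid)
    expect_equal(splicedPosition(rm$models, tid, inf$gvec), sp,
                 label = tid)
  }
})

test_that("segment pieces export as BED-like rows covering coding transcripts", {
  gtf <- system.file("extdata", "toy.gtf", package = "meripr")
  st <- segmentTranscripts(readTranscriptsGTF(gtf))
  df <- segmentsToBed(st)
  expect_true(all(grepl("\\|", df$name)))
  expect_true(all(df$end > df$start))
  # total piece length equals total spliced length
  expect_equal(sum(df$end - df$start), sum(txData(st)$spliced_length))
})
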