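suppressPackageStartupMessages(library(Biostrings))

test_that("top-peak selection filters, orders and is input-order invariant", {
  gr <- GRanges("chr1", IRanges(seq(1, 900, by = 100), width = 50))
  pk <- m6aPeaks(gr)
  mcols(pk)$fold_change <- c(5, 1.5, 3, 8, 2.0, 6, 4, 9, 7)
  mcols(pk)$p_value <- c(1e-8, 1e-9, 1e-7, 1e-8, 1e-9, 2e-3, 1e-6, 1e-8, 1e-8)
  sel <- selectTopPeaks(pk, n = 3)
  # fc 1.5 and fc exactly 2 excluded (filter is fc > 2); p 2e-3 excluded
  expect_false(any(mcols(sel)$fold_change <= 2))
  expect_equal(mcols(sel)$p_value, sort(mcols(sel)$p_value))
  # ties in p broken by descending fc then coordinate
  expect_equal(mcols(sel)$p_value[1], 1e-8)
  expect_equal(mcols(sel)$fold_change[1], 9)
  set.seed(60)
  perm <- sample(length(pk))
  sel2 <- selectTopPeaks(pk[perm], n = 3)
  expect_equal(start(sel), start(sel2))
  expect_equal(mcols(sel)$fold_change, mcols(sel2)$fold_change)
  expect_warning(selectTopPeaks(pk, n = 100), "qualify")
})

test_that("window extraction is summit-centred, strand-aware and flags truncation", {
  set.seed(61)
  genome <- DNAStringSet(c(chr1 = paste(sample(c("A", "C", "G", "T"), 1000,
                                               replace = TRUE),
                                        collapse = "")))
  pk <- m6aPeaks(GRanges("chr1", IRanges(450, 550), strand = "+",
                         summit = 500L))
  w <- extractWindows(pk, genome)
  expect_equal(width(w), 101L)
  expect_equal(as.character(w[[1]]),
               as.character(subseq(genome[[1]], 450, 550)))
  expect_false(mcols(w)$truncated)
  # minus strand window equals the reverse complement
  pkm <- pk; strand(pkm) <- "-"
  wm <- extractWindows(pkm, genome)
  expect_equal(as.character(wm[[1]]),
               as.character(reverseComplement(subseq(genome[[1]], 450, 550))))
  # summit near the contig start -> truncated, flagged
  pk2 <- m6aPeaks(GRanges("chr1", IRanges(1, 60), summit = 21L))
  w2 <- extractWindows(pk2, genome)
  expect_equal(width(w2), 71L)
  expect_true(mcols(w2)$truncated)
  expect_error(extractWindows(m6aPeaks(GRanges("chrX", IRanges(1, 10))),
                              genome), "chrX")
})

test_that("shuffles preserve the promised composition and are seed-deterministic", {
  set.seed(62)
  seqs <- DNAStringSet(vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(30:101, 1), replace = TRUE,
                 prob = c(0.4, 0.1, 0.2, 0.3)), collapse = ""),
    character(1)))
  mono <- shuffleControls(seqs, mode = "mono", seed = 5)
  expect_equal(oligonucleotideFrequency(mono, 1),
               oligonucleotideFrequency(seqs, 1))
  din <- shuffleControls(seqs, mode = "dinucleotide", seed = 5)
  expect_equal(oligonucleotideFrequency(din, 2),
               oligonucleotideFrequency(seqs, 2))
  # first and last base are fixed points of the Eulerian shuffle
  expect_equal(as.character(subseq(din, 1, 1)),
               unname(as.character(subseq(seqs, 1, 1))),
               ignore_attr = TRUE)
  din2 <- shuffleControls(seqs, mode = "dinucleotide", seed = 5)
  expect_equal(as.character(din), as.character(din2))
  din3 <- shuffleControls(seqs, mode = "dinucleotide", seed = 6)
  expect_false(all(as.character(din) == as.character(din3)))
})

test_that("IUPAC k-mer counting handles overlaps, U/T and bad codes", {
  enr <- kmerEnrichment(DNAStringSet(c("GGACT")), DNAStringSet(c("AAAAA")),
                        motifs = "RRACH")
  expect_equal(enr$target_count, 1)
  enr2 <- kmerEnrichment(DNAStringSet(c("GGACTGGACT")),
                         DNAStringSet(c("AAAAAAAAAA")), motifs = "GGACU")
  expect_equal(enr2$target_count, 2)
  # overlapping matches are all counted
  enr3 <- kmerEnrichment(DNAStringSet(c("AAACAAACA")),
                         DNAStringSet(c("TTTTTTTTT")), motifs = "RRACH")
  expect_equal(enr3$target_count, 2)
  expect_error(kmerEnrichment(DNAStringSet("ACGT"), DNAStringSet("ACGT"),
                              motifs = "GGXCU"), "IUPAC")
})

test_that("targets compared against themselves show no enrichment", {
  set.seed(63)
  seqs <- DNAStringSet(vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 101, replace = TRUE), collapse = ""),
    character(1)))
  enr <- kmerEnrichment(seqs, seqs, motifs = c("GGACU", "RRACH", "AAAAA"))
  expect_true(all(abs(enr$z) < 1e-9))
})

test_that("embedded GGACU is detected against dinucleotide-shuffled controls", {
  set.seed(64)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 101, replace = TRUE),
                         collapse = "")
  seqs <- vapply(1:200, function(i) mk(), character(1))
  emb <- runif(200) < 0.8
  substr(seqs[emb], 49, 53) <- "GGACT"
  targets <- DNAStringSet(seqs)
  controls <- shuffleControls(targets, seed = 9)
  enr <- kmerEnrichment(targets, controls, motifs = "GGACU")
  expect_gt(enr$z, 5)
  # empirical p from extra shuffles agrees
  enr2 <- kmerEnrichment(targets, controls, motifs = "GGACU",
                         nShuffle = 30, seed = 10)
  expect_lte(enr2$p_empirical, 1 / 31)
})
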