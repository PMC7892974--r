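test_that("FPKM arithmetic and scaling laws hold", {
  expect_equal(fpkm(100, 1000, 1e6), 100)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(100, 1000, 2e6), 50)    # doubling the library halves FPKM
  expect_equal(fpkm(100, 2000, 1e6), 50)
  expect_error(fpkm(10, 0, 1e6), "length")
  expect_error(fpkm(10, 100, 0), "library")
})

test_that("expression records define NNFPKM only for expressed genes", {
  r <- expressionRecords(c("a", "b"), c(10, 0), c(30, 5))
  expect_equal(r$nnfpkm, c(3, NA))
  expect_equal(r$nnfpkm_defined, c(TRUE, FALSE))
  expect_error(expressionRecords("a", -1, 1), ">= 0")
})

test_that("perfect log-linear anticorrelation gives r = -1 in both modes", {
  set.seed(40)
  fi <- 2^runif(200, 0, 10)
  rec <- expressionRecords(paste0("g", 1:200), fi, 42)  # nnfpkm = 42/fi
  expect_equal(expressionMethylationCorrelation(rec, "gene")$r, -1,
               tolerance = 1e-12)
  expect_equal(expressionMethylationCorrelation(rec, "binned")$r, -1,
               tolerance = 1e-12)
})

test_that("independent log-normal axes give near-zero gene-level correlation", {
  set.seed(41)
  n <- 1e4
  fi <- rlnorm(n, 3, 1)
  nn <- rlnorm(n, 0, 0.5)
  rec <- expressionRecords(paste0("g", 1:n), fi, fi * nn)
  r <- expressionMethylationCorrelation(rec, "gene")$r
  expect_lt(abs(r), 0.05)
})

test_that("correlation recovers the closed-form attenuated value", {
  # log2 nnfpkm = slope * log2 fpkm_input + noise:
  # r = slope * sd(x) / sqrt(slope^2 var(x) + sigma^2)
  set.seed(42)
  n <- 2e4; slope <- -0.8; sigma <- 0.3
  x <- rnorm(n, 5, 1)
  y <- slope * x + rnorm(n, 0, sigma)
  rec <- expressionRecords(paste0("g", 1:n), 2^x, 2^(x + y))
  got <- expressionMethylationCorrelation(rec, "gene")$r
  want <- slope * 1 / sqrt(slope^2 * 1 + sigma^2)
  expect_equal(got, want, tolerance = 0.05)
})

test_that("correlation is invariant to rescaling the input FPKM", {
  set.seed(43)
  fi <- rlnorm(500, 3, 1); ip <- rlnorm(500, 3, 1)
  r1 <- expressionMethylationCorrelation(
    expressionRecords(paste0("g", 1:500), fi, ip), "gene")$r
  r2 <- expressionMethylationCorrelation(
    expressionRecords(paste0("g", 1:500), fi * 7, ip * 7), "gene")$r
  expect_equal(r1, r2, tolerance = 1e-10)
  # degenerate inputs are flagged
  flat <- expressionRecords(c("a", "b", "c"), c(2, 2, 2), c(4, 4, 4))
  expect_true(expressionMethylationCorrelation(flat, "gene")$flagged)
})

test_that("quadrant classification concatenates the two directions", {
  dyn <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    direction = c("high", "high", "low", "low"))
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g5"),
                   direction = c("up", "down", "down", "up"))
  q <- quadrantClassify(dyn, de)
  expect_equal(q$calls$label[q$calls$gene_id == "g1"], "hyper-up")
  expect_equal(q$calls$label[q$calls$gene_id == "g3"], "hypo-down")
  expect_equal(unname(q$summary$quadrants),
               c(1L, 1L, 0L, 1L))
  expect_equal(q$summary$n_intersect, 3L)
  # empty intersection -> zero calls, undefined concordance
  q0 <- quadrantClassify(dyn[0, ], de)
  expect_equal(nrow(q0$calls), 0L)
  expect_true(is.na(q0$summary$concordant_fraction))
})

test_that("methylation summary ratios reduce to the documented arithmetic", {
  s <- methylationSummaryFromCounts(100, 100, 100)
  expect_equal(s$percent_methylated, 100)
  expect_equal(s$peaks_per_transcript, 1)
  # half-up rounding on a .5 boundary
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(2.5), 3)
  expect_equal(roundHalfUp(-2.5), -3)
})

test_that("hypergeometric enrichment equals the exhaustive tail sum", {
  # fixed case: universe 100, set 10, hits 20, overlap 5
  hits <- paste0("g", 1:20)
  uni <- paste0("g", 1:100)
  sets <- list(s1 = paste0("g", c(1:5, 51:55)))
  got <- genesetOverrepresentation(hits, uni, sets)
  expect_equal(got$overlap, 5L)
  expect_equal(got$p_value, oracleHyperTail(5, 10, 100, 20),
               tolerance = 1e-12)
  expect_equal(got$p_value, 0.02546455, tolerance = 1e-6)
  expect_true(got$significant)
  # randomized equivalence with the oracle
  set.seed(50)
  for (i in 1:25) {
    uni <- paste0("g", 1:60)
    hits <- sample(uni, sample(5:30, 1))
    st <- sample(uni, sample(3:20, 1))
    p <- genesetOverrepresentation(hits, uni, list(s = st))$p_value
    expect_equal(p, oracleHyperTail(length(intersect(st, hits)),
                                    length(st), 60, length(hits)),
                 tolerance = 1e-10)
  }
  # edge behaviour
  all10 <- paste0("g", 1:10)
  pmin_ <- genesetOverrepresentation(all10, paste0("g", 1:100),
                                     list(s = all10))
  expect_lt(pmin_$p_value, 1e-10)
  none <- genesetOverrepresentation(paste0("g", 90:99), paste0("g", 1:100),
                                    list(s = paste0("g", 1:10)))
  expect_gt(none$p_value, 0.5)
  expect_error(genesetOverrepresentation("a", character(0), list()),
               "universe")
  # sets with < 2 universe members are skipped
  skip2 <- genesetOverrepresentation(all10, paste0("g", 1:100),
                                     list(s = c("g1", "zzz")))
  expect_equal(nrow(skip2), 0L)
})

test_that("GMT-like gene set files parse one set per line", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tlipid metabolism\tg1\tg2\tg3",
               "setB\ttranscription\tg2\tg4"), p)
  gs <- readGMT(p)
  expect_equal(names(gs), c("setA", "setB"))
  expect_equal(as.character(gs$setB), c("g2", "g4"))
  expect_equal(attr(gs$setA, "description"), "lipid metabolism")
  writeLines("bad\tonly-two-fields", p)
  expect_error(readGMT(p), "fewer than 3")
})
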