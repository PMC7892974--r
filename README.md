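# meripr

Downstream analysis of MeRIP-seq (m6A) experiments in R.

MeRIP-seq measures N6-methyladenosine, the most common internal mRNA
modification, by pairing an antibody-enriched (IP) sequencing library
with a whole-RNA (input) control from the same fragmented sample.
`meripr` is for analysts working with such data in a two-condition,
replicated design (the motivating setting is adipose tissue from lean-
and fat-type broiler chicken lines). It provides, as composable
Bioconductor-style functions:

* **Peak calling** (`callPeaks()`): sliding-window Poisson test of IP
  fragment counts against a background rate
  `lambda_bg = max(lambda_global, lambda_input,local)`, with the input
  rate estimated at several local scales (a simplified, fully
  specified stand-in for the MACS approach with the effective size set
  to the transcriptome scale).
* **Peak set algebra** (`consolidateRecurrent()`,
  `classifyCommonUnique()`): replicate-recurrent peaks and
  common/condition-unique classification under the >= 50%
  overlap-fraction rule (fraction of the shorter interval).
* **Metagene profiling** (`segmentTranscripts()`, `metageneProfile()`):
  transcripts split into 5'UTR / start codon (100 nt centred) / CDS /
  stop codon / 3'UTR, 20 bins each; each peak counted once via its
  summit.
* **Differential methylation and expression** (`dynamicPeaks()`,
  `diffExpression()`): G-test on normalized pooled IP counts of common
  peaks, and Welch t on log2 FPKM, both at the fold-change >= 2 and
  P < 0.05 convention.
* **Integration** (`expressionMethylationCorrelation()`,
  `quadrantClassify()`): NNFPKM = FPKM_IP / FPKM_INPUT as the per-gene
  m6A level, log2 Pearson correlation with expression, and
  hyper-up / hyper-down / hypo-up / hypo-down quadrants;
  `genesetOverrepresentation()` runs hypergeometric tests on
  user-supplied gene sets.
* **Motif preparation** (`selectTopPeaks()`, `extractWindows()`,
  `shuffleControls()`, `kmerEnrichment()`): top-1000 peaks, 101-nt
  summit windows, dinucleotide-preserving shuffled controls and a
  built-in IUPAC k-mer test for GGACU/RRACH-class motifs.
* **A synthetic data generator** (`simulationConfig()`,
  `simulateMerip()`, `emitFixture()`) producing a complete
  two-condition, three-replicate experiment with ground truth for
  every stage, and `runPipeline()` to execute the whole analysis on
  it.

See `vignettes/merip-analysis.Rmd` for the models, parameter meanings
and design choices.

## Worked example

Summary ratios from per-condition counts (transcripts, methylated
transcripts, peaks) — here the published counts for a lean-line
sample:

```r
library(meripr)
methylationSummaryFromCounts(5965, 4615, 7097)
#> $peaks_per_methylated_transcript
#> [1] 1.54
#> $peaks_per_transcript
#> [1] 1.19
#> $percent_methylated
#> [1] 77
```

So each methylated transcript carries on average 1.54 peaks, each
expressed transcript 1.19, and 77% of transcripts are methylated.

A complete synthetic experiment, from simulation through peak calling,
condition comparison and motif enrichment:

```r
res <- runPipeline(simulationConfig(seed = 1))
res$methylationSummary$A
#>   n_transcripts n_methylated n_peaks peaks_per_methylated_transcript
#> 1           400          280     421                             1.5
#>   peaks_per_transcript percent_methylated
#> 1                 1.05                 70
res$dynamicSummary$low_share_percent   # share of dynamic peaks lower in B
#> [1] 70.5
round(res$correlations$A$binned$r, 3)  # log2 expression vs log2 NNFPKM
#> [1] -0.965
round(res$motif$A$enrichment$z[1], 1)  # GGACU z vs shuffled controls
#> [1] 13.9
```

`res$validation` compares the called peaks with the generator's ground
truth (recall/false-discovery proportion), and `res$quadrants` holds
the hyper/hypo x up/down classification of dynamic genes.

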