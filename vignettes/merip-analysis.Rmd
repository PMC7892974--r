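---
title: "Downstream MeRIP-seq m6A analysis: models, parameters and design choices"
author: "meripr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downstream MeRIP-seq m6A analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experiment and the model

MeRIP-seq quantifies N6-methyladenosine (m6A) by sequencing two
libraries from the same fragmented RNA sample: an antibody-enriched
(IP) library and a whole-RNA (input) control.  Regions where IP
fragment coverage exceeds the input-derived expectation are m6A peaks.
`meripr` implements the downstream stages of a two-condition,
replicated MeRIP-seq design: peak calling, replicate-recurrent
consolidation, condition-level peak set algebra, metagene profiling,
differential methylation and expression, methylation--expression
integration, and motif-window analysis, together with a synthetic data
generator that provides ground truth for every stage.

## Peak calling

Coverage tracks (`FragmentCoverage`) store per-base counts of fragment
5' starts, the library size and the nominal fragment length (~100 nt
after chemical fragmentation).  `callPeaks()` slides windows of
`windowSize` (default 100 nt) at `step` 50 nt and tests the IP window
count `k` against a background rate

\[
\lambda_{bg} = \max\left(\lambda_{global},\;
  \max_{s \in \text{scales}} \hat\lambda_{input,s}\right),
\qquad
\lambda_{global} = \frac{N_{IP} \cdot w}{\text{effectiveSize}},
\]

where \(\hat\lambda_{input,s}\) is the library-scaled input rate
estimated over a window of scale \(s\) (defaults 100, 1000, 5000 nt)
centred on the tested window.  Two refinements keep this background
honest at desk-scale depth.  First, each scale estimate carries a
one-sided sampling allowance,
\(\hat\lambda = (c + z\sqrt{c+1})\,w/s\) with \(z = 1\)
(`localUpperZ`): a raw count used as if it were the true rate is a
plug-in estimator whose noise inflates the null tail severalfold at
small \(\alpha\).  Second, a scale whose input count is below
`localMinCount` (default 20, i.e. CV above ~22%) is not trusted and
defers to broader scales and the global rate; without this, upward
fluctuations of a 5-count window estimate veto genuinely enriched
windows at shallow depth.  Both parameters can be set to 0 to recover
the plain scaled-count background.  The per-window p-value is
the upper Poisson tail \(P(X \ge k \mid \lambda_{bg})\); windows with
\(p <\) `pThreshold` (default 1e-5) *and* \(k/\lambda_{bg} \ge\)
`fcThreshold` (default 2) are merged when closer than `mergeGap`.
Each peak reports its summit (argmax of the fragment-length-smoothed
IP signal), a fold change (summed counts over summed lambdas) and the
minimum window p-value.

The Poisson window test is a deliberate simplification of the MACS
approach, not a MACS clone: no fragment-shift model is built, no
duplicate filtering is done, and the test is Poisson rather than a
dynamic local model.  `effectiveSize` is the background size over
which fragments would be uniform if no input were available; 1.77e8
(a calculated chicken transcriptome size) is the default for real
data.  For the synthetic genome the pipeline passes the genome size
instead, so the global rate acts purely as a floor for regions without
input signal while the transcriptome structure of the background comes
from the input track itself.  Setting the floor at the *mean exonic*
rate instead would silently veto every below-average-expression gene
through the fold-change gate — an interaction worth knowing about when
choosing this parameter on real data.

## Recurrent peaks and condition comparison

`overlapFraction()` divides the overlap length by the length of the
*shorter* interval by default, which makes the \(\ge 50\%\) overlap
relation symmetric; bedtools-style one-sided (`"a"`) and reciprocal
bases are available.  `consolidateRecurrent()` emits one recurrent
peak per maximal chain of peaks (at most one per replicate, all
pairwise overlapping by \(\ge\) `minFraction`), greedily selected in
coordinate order so each input peak supports at most one chain; the
reported interval is the member intersection (the region supported by
every replicate), the summit the member median, the fold change the
member mean.  `classifyCommonUnique()` marks a peak common when any
peak of the other condition reaches the overlap fraction; matching is
non-exclusive, mirroring set-intersection semantics, so the symmetric
invariant is the number of qualifying pairs rather than the per-side
common counts.

## Metagene coordinates

Transcripts are segmented in *spliced* coordinates (the standard
choice for metagene plots; the alternative, unspliced genomic
proportions, would distort segments across introns).  With \(s\) the
spliced offset of the first CDS base and \(t\) one past the last, the
five segments are 5'UTR \([0, s-50)\), start codon \([s-50, s+50)\),
CDS \([s+50, t-50)\), stop codon \([t-50, t+50)\) and 3'UTR
\([t+50, L)\), truncated at transcript ends and never overlapping; a
CDS under 100 nt yields an empty CDS segment with the codon segments
abutting at the CDS midpoint, preserving the exact-cover invariant
(the five segments always tile the transcript).  Each segment is
divided into 20 bins; a peak contributes exactly once, through its
summit, to the bin containing it, so bin counts always sum to the
number of peaks used.  When a gene has several isoforms the one with
the longest CDS (ties: longest spliced length, then smallest id)
represents the gene; summit-based assignment gives each peak one
unambiguous segment and bin.

## Differential methylation and expression

Line-dynamic methylation is tested on common peaks with a G-test on
pooled normalized IP counts: counts are scaled by median-of-ratios
size factors (or user-supplied factors), summed per condition into
\((O_A, O_B)\), and compared against the equal split expected after
normalization, \(G = 2\sum O \log(O/E)\) with 1 df.  The fold change
is the ratio of normalized means with a 0.5 pseudocount; calls require
\(|\log_2 FC| \ge 1\) and \(p < 0.05\) (raw, matching the emulated
study's thresholds; a BH column is emitted but not used for calls).
The pipeline counts fragments in fixed-width summit-centred windows
(151 nt) rather than whole peak intervals, because variable peak
flanks dilute the condition effect without adding signal.

Differential expression uses Welch's t on \(\log_2(\text{FPKM}+1)\)
across replicates with a small variance guard (`eps = 1e-8`); the fold
change is the ratio of FPKM means with pseudocount 1.  Identical
replicate vectors give \(p = 1\) by convention.

## Integration

\(\text{FPKM} = 10^9 f / (L N)\); the m6A enrichment level is
NNFPKM \(=\) FPKM\(_{IP}\)/FPKM\(_{INPUT}\).
`expressionMethylationCorrelation()` computes the Pearson correlation
of \(\log_2\) FPKM\(_{INPUT}\) with \(\log_2\) NNFPKM.  The default
averages both axes within 50 expression-ranked equal-count bins before
correlating — global methylation/expression trends are conventionally
displayed this way, and near-perfect published correlation
coefficients are only attainable on binned averages; the gene-level
mode is one keyword away and is the right choice for effect-size
estimation.  Quadrant classification intersects gene-level dynamic
methylation directions (genes with conflicting peak directions are
excluded and counted, not majority-voted) with expression directions;
percentages print at the conventions used for such tables
(integer percents within classes, one decimal for the
dynamic-and-expressed share, round-half-up).  Gene-set
over-representation is an upper-tail hypergeometric test against
user-supplied GMT-like sets.

## Motif windows

`selectTopPeaks()` filters fold change \(> 2\) and \(p < 10^{-5}\),
sorts by p (ties: fold change, coordinate) and keeps the top 1000.
Windows of 101 nt centred on summits are cut in transcript sense
(reverse-complemented on minus-strand hosts) and paired with
per-sequence shuffled controls — mononucleotide, or the default
Altschul--Erickson Eulerian-path shuffle that preserves the exact
dinucleotide count multiset.  `kmerEnrichment()` counts IUPAC-expanded
motif occurrences (overlaps allowed, U equivalent to T) and compares
per-position rates with a two-proportion z-test; DREME-compatible
FASTA pairs can be written for external motif discovery.

# The synthetic data generator

`simulationConfig()` defines the emulated study: two conditions
("A" = lean-type reference, "B" = fat-type) with three replicates of
paired IP/input libraries over a ~4 Mb two-chromosome genome with 400
genes.  Sampling proceeds as: random gene models (1--3 isoforms, the
non-representative ones 3'-truncated); ~70% of coding genes methylated
with 1--4 sites each (probabilities 0.60/0.25/0.10/0.05); site
placement weighted over segments (5'UTR 0.05, start codon 0.15, CDS
0.40, stop codon 0.25, 3'UTR 0.15); GGACU written into the genome at
80% of site centres; per-replicate gene rates drawn once and shared
between the IP and input library of that replicate (they come from the
same RNA), with negative-binomial dispersion 0.1 across replicates;
input fragment starts uniform along the spliced transcript, IP starts
upweighted by the site folds.

Several defaults deserve their reasoning spelled out:

* **Site enrichment fold 48, width 100 nt.**  What a caller can see is
  the *composition-normalised* fold: scaling IP to input depth divides
  every site fold by the transcriptome-average enrichment, which
  itself grows with the site fold.  The observable fold of a
  condition-reduced site therefore *saturates* as the base fold grows;
  the binding quantity is the methylated mass share per transcript
  (site width x sites / length).  At 100-nt sites and 2.4-kb
  transcripts the average gene enrichment is ~2 (a realistic NNFPKM),
  base-fold-48 sites are observable at fold ~20, and sites reduced
  4.5-fold in condition B remain at observable fold ~4 — comfortably
  past the caller's fold-2 gate even after the three-replicate
  recurrence requirement, which cubes any per-replicate miss
  probability.  Published per-peak fold changes in comparable studies
  reach the hundreds, so these magnitudes are unremarkable.
* **Library size 5.4e5 fragments/replicate** (~0.4 starts per exonic
  nt, mean window rate ~40).  At half this depth the Poisson
  \(p < 10^{-5}\) cut implies an *observed* fold of 2.4--3 for
  below-average-expression genes, which silently filters
  condition-reduced sites; at the chosen depth the implicit fold
  approaches the nominal gate across the expression range.
* **Dynamic sites: 35% of sites, 71.1% of them lower in B, effect fold
  4.5.**  The low share is assigned by deterministic rounding so the
  realized truth matches the configured value up to rounding.
* **Expression--methylation coupling: slope -0.5, noise 0.3 (log2).**
  Expression is drawn as
  \(\log_2 e = \mu + \beta\,(\log_2 A - \overline{\log_2 A}) +
  \varepsilon\) with \(A\) the gene-level enrichment, giving the
  negative global correlation reported for such data.  A steeper slope
  over the 3+ log2-unit enrichment range of multi-site genes crushes
  their expression and, through within-gene IP competition, pushes
  their condition-low sites under the caller's detection threshold;
  -0.5 keeps the coupling clearly negative without that corner.
* **Concordant expression shifts**: 15% of dynamic genes shift their
  condition-B expression by 1.0 log2 in the direction of the
  methylation change, populating the hyper-up/hypo-down quadrants.

Ground truth (site positions, folds, condition effects, latent
expression) is returned separately from the emitted files, so recovery
tests never reverse-engineer outputs.

## What passing tests do and do not show

The generator emulates the *statistical structure* of a MeRIP-seq
study, not its molecular reality: fragments are placed directly (no
sequencing errors, no alignment, no duplicates, no GC or mappability
bias), isoform usage is one-representative-per-gene, site strengths
are independent across genes, and the background is exactly the
negative-binomial/Poisson hierarchy the caller assumes up to the
shared-sample gene factors.  Parameter recovery on this generator
therefore demonstrates internal consistency of the pipeline — that the
algebra, tests and thresholds do what they claim under known truth —
and calibrated behaviour under the stated noise model.  It does not
certify performance on real libraries, where background violations
(immunoprecipitation efficiency, fragment-length structure,
expression-dependent biases) are the dominant error source.  The
detected low share of dynamic peaks carries a small downward estimator
bias (~3--5 points at the default conditions): condition-reduced peaks
sit closer to every threshold than condition-raised ones, so misses
are asymmetric, and false-dynamic calls dilute the share toward 50%.

## Problem sizes

Default analyses run at 400 genes, three replicates per condition,
~5.4e5 fragments per library (~4 Mb genome, ~80 s for a full pipeline
run).  The test suite uses 25--200 genes for unit and property checks,
brute-force oracle comparisons on hundreds of randomized small
instances, and the full default size for end-to-end parameter
recovery; the caller power scenario is evaluated at enrichment fold 8
over a background of ~5 fragments per window, and its null calibration
on enrichment-free tracks with >= 1e4 exonic windows.

# Numerical choices and degenerate inputs

* Percentages and ratios print with round-half-up at the precision of
  the corresponding published tables (2 decimals for peaks-per-
  transcript ratios, integer or one-decimal percents).
* Pseudocounts: 0.5 on normalized peak counts, 1 on FPKM; both prevent
  infinite fold changes and are stated in the output docs.
* Zero-variance Welch tests use an epsilon guard; all-zero genes and
  all-zero peaks are flagged `ns` rather than dropped.
* Empty peak sets, empty GTFs, missing BED columns and empty gene sets
  degrade to empty results with warnings, never to errors, except
  where the input is structurally invalid (negative intervals, CDS
  outside exons), which error with the offending record named.
* Ties: top-peak selection breaks p-value ties by descending fold
  change then coordinate; common-peak best partners break fraction
  ties towards the leftmost partner; both make results independent of
  input order.
* RNG: every stochastic routine takes a seed and restores the caller's
  RNG state; the pipeline derives all stage seeds from the single
  config seed.

# Known limitations

* The caller tests windows independently; no multiple-testing
  correction is applied at the window level (the merged-peak p is a
  minimum).  This mirrors the emulated workflow but inflates
  peak-level significance.
* diffReps' negative-binomial windowing is not reproduced; the G-test
  on peak-level counts is the defined stand-in and is anti-conservative
  under strong overdispersion, which the fold-change gate largely
  offsets (type-I is verified <= 0.05 under the null generator).
* Gene expression differences between conditions propagate into IP
  counts and can masquerade as methylation changes; no input-based
  correction is attempted, as in the emulated workflow.
* The equal-count-binned correlation mode is a presentation tool;
  binned r values are not comparable across bin counts.
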