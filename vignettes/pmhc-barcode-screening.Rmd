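---
title: "Methods: DNA-barcoded pMHC multimer screening analysis"
author: "pmhcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-barcoded pMHC multimer screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhcscreen)
```

# The assay and its computational model

DNA-barcoded pMHC multimer screening detects antigen-specific CD8+ T cells
at scale. A library of peptide–MHC class I complexes is multimerized on
fluorescent dextran backbones, each reagent tagged with a unique
double-stranded AxBy DNA barcode. Reagents are pooled according to each
donor's HLA class I type, multimer-binding CD8+ T cells are sorted, and the
co-sorted barcodes are PCR-amplified and sequenced. A barcode that is
*enriched* in a sorted sample — relative to the composition of the
un-sorted reagent pool, sequenced in triplicate as a baseline — marks a
T-cell population recognizing that peptide–HLA combination.

This package implements that analysis chain for the NT1-style cohort
design: seven proteins restricted to hypocretin neurons, screened across an
eight-allele HLA panel (~1,183 reagents), in three cohorts (NT1 patients,
HLA-DQB1\*06:02-positive and -negative healthy controls). Because the raw
study data are not publicly deposited, the package pairs every analysis
stage with a seeded synthetic-data generator whose ground truth makes the
stage testable.

# Read model and barcode processing

A sequenced amplicon is modeled as a fixed-offset layout

```
read = seq_a (25 nt) | UMI (6 nt) | seq_b (25 nt)
```

The assay's oligos define the A/B 25-mers and the 6-nt unique molecular
identifier (UMI), but not the sequenced read layout; the fixed-offset
single-end layout is this package's choice, made to keep parsing exactly
invertible. Reads shorter than 56 nt are counted as unparseable rather than
discarded silently; per sample, `assigned + unassigned + unparseable =
total` is an enforced invariant.

**Assignment.** A read is assigned if and only if both regions fall within
`max_mismatch` substitutions (default 1) of the same barcode's A and B
sequences, with a unique minimizer; ties stay unassigned. Dictionaries are
generated by rejection sampling under a minimum pairwise Hamming distance
of 5 within the A set and within the B set, which makes single-mismatch
decoding provably unambiguous. Implementation detail: for tolerance ≤ 1 the
assignment uses an exact hash of the 1-mismatch neighborhood (fast and
identical to a nearest-neighbor scan, which the test suite verifies);
larger tolerances fall back to an exhaustive Hamming scan.

**Clonal reduction.** Per barcode and sample, the clonally reduced count is
the number of *distinct* UMI sequences among assigned reads. Collapse is
exact-match only: with 6-nt UMIs (4,096 states) and the modest per-barcode
depths this assay produces, UMI-error networks would mostly merge genuinely
distinct molecules; the simpler rule is also exactly testable against a
set-cardinality oracle. The package assigns reads first and collapses UMIs
second; whether the original online tool orders these steps the same way is
unpublished, but under exact-match collapse with error-free UMIs the two
orders coincide.

# Enrichment calling

## TMM normalization

Between-sample scaling factors use the trimmed mean of M-values. The
reference sample is the one whose upper quartile of library-size-scaled
counts is closest to the mean upper quartile. For sample *j* against
reference *r*, on barcodes positive in both,

$$M_b = \log_2\frac{y_{bj}/N_j}{y_{br}/N_r}, \qquad
  A_b = \tfrac12\left(\log_2 \frac{y_{bj}}{N_j} + \log_2\frac{y_{br}}{N_r}\right),$$

the M and A values are doubly trimmed (default 30% two-sided on M, 5% on
A, rank-based), and the factor is $2^{\bar M}$ with $\bar M$ the mean of
the surviving M-values weighted by inverse binomial asymptotic variances
$w_b^{-1} = \left(\frac{N_j-y_{bj}}{N_j y_{bj}} +
\frac{N_r-y_{br}}{N_r y_{br}}\right)^{-1}$. Factors are rescaled to
geometric mean 1. Because M-values are formed on library-size proportions,
a uniform depth change of any sample leaves all factors at 1 exactly; the
precision weights, however, depend on depth, so factors are only
*approximately* invariant when one sample of a heterogeneous table is
rescaled. A sample sharing no positive barcode with the reference receives
factor 1 with a warning. The test suite checks the implementation against
an independently coded from-definition oracle (tolerance 1e-8) and against
edgeR's TMM as an external cross-check.

## The exact split test

The published analysis defers significance to a count-based RNA-seq-style
test without specifying the variant; this package uses a self-contained
negative-binomial exact split test, documented as an approximation to that
family of tests. Counts are first rescaled to a common effective library
size (library size × TMM factor) and rounded. For one barcode, let $y$ be
the sorted-sample count and $b_1,\dots,b_m$ the baseline replicate counts
($m = 3$ by design). Under a shared NB mean with dispersion $\varphi$, the
sum of the baselines is NB with shape $m/\varphi$, and conditional on the
total $T = y + \sum b_i$ the sample count follows

$$P(K = k \mid T) \propto \binom{k + 1/\varphi - 1}{k}
  \binom{T - k + m/\varphi - 1}{T - k},$$

a beta-binomial-type law free of the unknown mean. The one-sided enrichment
tail $P(K \ge y \mid T)$ is doubled and capped at 1. As
$\varphi \to 0$ this converges to the binomial split
$K \mid T \sim \mathrm{Bin}(T, 1/(1+m))$ — the exact Poisson split test,
which the package returns in closed form at `dispersion = 0` and which
serves as the independent oracle for the NB path in the test suite.

**Dispersion.** By default (`"auto"`) a common dispersion is estimated from
the normalized baseline replicates by pooled method of moments,
$\hat\varphi = \sum_b (v_b - \mu_b) / \sum_b \mu_b^2$, floored at 1e-4.
Three replicates carry little information per barcode; pooling across the
~1,200 barcodes stabilizes the estimate. A fixed dispersion can be supplied
instead.

**Numerical choices.** Binomial-coefficient log-weights are accumulated as
cumulative sums of $\log\frac{r-1+i}{i}$ (stable for any shape, including
the near-Poisson regime); tails are combined by log-sum-exp; p-values are
floored at the smallest positive normal double so they remain in $(0, 1]$
even for astronomically enriched barcodes; barcodes with zero counts
everywhere get $p = 1$ and log2 fold change 0. The display fold change
$\log_2\frac{y + 0.5}{\bar b + 0.5}$ uses a pseudocount of 0.5 *only* for
display, never inside the test.

## Hit thresholds

A barcode–sample pair is a hit when the raw $p < 0.001$ **and** its clonal
read count is strictly above 100. Both gates follow the published rule; the
analysis that introduced them observed that $p < 0.001$ corresponded to an
FDR below 0.1 on their data, so the package reports Benjamini–Hochberg FDR
values alongside but gates on the raw p. The strict reading of "above 100"
makes exactly 100 clonal reads a non-hit; the 100-read filter operates on
clonal (not raw) counts, and the significance test runs on clonal counts as
well, since both are stated in terms of clonally reduced reads.

# Library design and recognition profiling

Binding predictions (percentile rank scores computed upstream; the
predictor itself is out of scope) are filtered at %Rank ≤ 2 — inclusive,
so a score of exactly 2 is a binder — deduplicating identical (peptide,
HLA) pairs across protein isoforms by best score. Each donor is screened
only with the library fraction matching their 1–4 panel alleles; the panel
size is the denominator of the donor's recognition percentage.

The estimated frequency of a detected population, as a percentage of CD8+
cells, is the population's share of the sample's assigned clonal reads
times the multimer-positive gate percentage. Two readings were open: raw
versus clonal reads in the numerator (clonal chosen, consistent with the
hit filter; raw available behind a flag) and whether the denominator
includes unassigned reads (excluded here — only assigned reads carry pMHC
identity). Per-protein sums aggregate populations across HLA contexts, and
additivity (protein sums equal the total over populations) is a tested
invariant.

**Hotspots.** The colocalization of recognized peptides of different HLA
restrictions is only shown graphically in the source study; this package
operationalizes it — and labels the definition as its own — as: any
protein residue covered by recognized peptides of ≥ 2 distinct HLA
restrictions seeds a hotspot, reported as the union (1-based, closed
interval) of all peptides covering such residues, with overlapping seeded
intervals merged. Coordinates are 1-based closed throughout, the usual
convention for epitope positions.

# Cohort statistics

* **Fisher exact tests** are two-sided by the sum-of-smaller-point-
  probabilities convention (the one used by common statistical software and
  the one that reproduces both of the study's printed p-values: the 9/9 vs
  4/11 patient split gives p ≈ 0.00472 → 0.005, the 13/15 vs 3/14
  DQ-negative-control split gives p ≈ 0.000679 → 0.0007). Point
  probabilities are computed in log space with a 1e-7 relative tie
  tolerance; the implementation is verified against exhaustive enumeration
  for every 2×2 table with total ≤ 40.
* **Mann–Whitney** uses the exact distribution when the combined sample
  size is ≤ 20 without ties, otherwise the normal approximation with tie
  and continuity correction; which path the original analysis used is
  unstated, so both are provided and the choice is reported.
* **ANOVA with Tukey contrasts** runs on log10-transformed frequencies
  (any base gives identical F and p; base 10 matches the −log10 display
  convention), with Tukey–Kramer standard errors for unequal group sizes.
  Degenerate input with no between-group variation returns F = 0, p = 1
  rather than 0/0. Normality pre-checks never gate the analysis; test
  choice is the caller's, as in the source study's figure legends.
* The single DQB1\*06:02-negative patient is excluded from patient versus
  DQ-positive-control comparisons in the source analysis. A single
  three-group ANOVA cannot drop a donor from one pairwise contrast only, so
  the cohort report excludes DQ-negative patients from the frequency
  comparison entirely; within-cohort contingency tables keep all donors,
  matching the published 9/9 vs 4/11 split which includes the full patient
  cohort.

# The synthetic-data generator

The generator emulates, with one master seed and per-sample streams derived
by stable hashing of `(seed, sample label)` (so adding a sample never
perturbs another):

* **Dictionaries**: rejection-sampled 25-mers at pairwise Hamming ≥ 5;
  infeasible requests raise an explicit capacity error.
* **Libraries**: ~1,183 binders allocated over 7 proteins × 8 HLA alleles
  proportionally to protein length (canonical lengths 131–735 aa) with
  log-normal
  jitter, so some protein–HLA cells can be empty, as in real predictions.
* **Cohorts**: donor records with 1–4 panel alleles, DQB1\*06:02 status by
  cohort (one seronegative patient by default, mirroring 19/20), multimer
  gates log-normal around 0.1% of CD8+ cells.
* **Reads**: multinomial draws from the reagent-pool composition
  (log-normal jitter around uniform) at a configurable depth, UMIs uniform
  over 4^6, constant Sanger qualities, independent per-base substitution
  errors only (no indels — the amplicons are short and fixed-layout).
  Spiked barcodes are multiplied by their fold enrichment and renormalized.
* **Counts**: a count-level companion draws negative-binomial noise
  (default dispersion 0.05) around the multinomial expectation for larger
  simulation studies where reads are unnecessary.

Default study conditions follow the emulated assay: triplicate baselines,
10^5 reads per sample for count-level studies (the study's per-sample
depths are unreported; 10^5 is Ion-Torrent-scale and desk-friendly), 10^4
reads in the FASTQ-level demo, 50× spike-ins. The cohort frequency model
places patients and DQ-negative controls at 10^-2.3 % of CD8+ (≈ 0.005%)
with sd 0.5 log10 and ~2 populations per donor, and DQ-positive controls
0.5 log10 (3.2-fold) lower. That separation is the package's own
calibration: the source study reports a significant but unquantified
difference, and the generator's effect size was set by a power calculation
so that the patient-vs-DQ-positive Tukey contrast is detectable with ~95%
power at the emulated cohort sizes (20/23/29 donors) — large enough to be
a reliable validation target, small enough to remain in the
low-frequency-autoreactivity regime the assay addresses.

**What the generator does not model** — and hence what passing tests do
and do not show about real data: PCR amplification bias and chimeras,
Ion-Torrent flow-space error structure (indels in particular), dextran
conjugation stoichiometry, flow-cytometry optics and gating variability,
shared structure between donors' T-cell repertoires, and any real
distribution of autoreactive frequencies. Tests demonstrate that the
pipeline recovers the truth of this generative model at realistic scales
and calibrations; they cannot certify performance on real sequencing data.

# Problem sizes and runtime envelope

The bundled validation uses: the full 1,183-barcode library for null
calibration (20 sorted samples, ~23,660 tests) and spike recovery (20
replicates × 5 spikes); 100 simulated cohorts for the power study; an
exhaustive Fisher sweep over all 2×2 tables with total ≤ 40 (~136,000
tables); and a FASTQ-level demo of 100 barcodes × 9 samples at 10^4 reads.
These sizes were chosen to exercise full-scale library dimensions while
keeping a complete run in the low minutes on one CPU.

# Known limitations

* The exact split test is an approximation to the unpublished reference
  analysis (an edgeR-based workflow); quantile-adjusted conditional ML
  dispersion estimation and GLM extensions are deliberately out of scope.
* UMI collapse ignores sequencing errors inside the UMI, which slightly
  inflates clonal counts at high per-barcode depth (saturation near 4^6 is
  handled, error-driven inflation is not).
* Sample identity is file-level; in-read sample indices are not supported.
* Hotspot calling is a definition of convenience for a graphically-reported
  phenomenon; interval boundaries depend on that operationalization.
* `estimated_frequency` propagates no uncertainty; it is the point
  estimate the assay's literature uses.
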