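# pmhcscreen

Analysis toolkit for **DNA-barcoded peptide–MHC (pMHC) multimer screening**
of antigen-specific CD8+ T cells, with a narcolepsy-type-1 (NT1) style
cohort design built in. Large libraries of pMHC multimers, each tagged with
a unique AxBy DNA barcode, are used to stain and sort multimer-binding CD8+
T cells; sequencing the amplified barcodes reveals which peptide–HLA
specificities each donor's T cells recognize. This package implements the
computational half of that assay for R users: read processing, enrichment
calling, frequency estimation, per-donor recognition profiling, and
HLA-stratified cohort statistics — together with a fully seeded
synthetic-data generator so that every stage can be exercised and validated
without access to raw study data.

## What it computes

**Barcode processing.** Each amplicon read is `seq_a (25 nt) + UMI (6 nt) +
seq_b (25 nt)` at fixed offsets. Reads are assigned to dictionary barcodes
by Hamming-tolerant matching of both regions (default tolerance 1
substitution per region; dictionaries are generated with pairwise Hamming
distance ≥ 5, so single-mismatch decoding is unambiguous). Per barcode *b*
and sample *s* the pipeline reports raw read counts and **clonally reduced
counts** — the number of distinct 6-nt unique molecular identifiers (UMIs),
which collapses PCR duplicates.

**Enrichment calling.** Counts are normalized by the trimmed mean of
M-values (TMM): with reference sample *r*,

    M_b = log2( (y_bs / N_s) / (y_br / N_r) ),   A_b = ½·[log2(y_bs/N_s) + log2(y_br/N_r)]

are doubly trimmed (30% on M, 5% on A) and combined by a precision-weighted
mean to give per-sample scaling factors (geometric mean 1). Each sorted
sample is then compared against the mean of triplicate reagent-pool
baselines: the log2 fold change uses a display pseudocount of 0.5, and
significance comes from a negative-binomial exact split test that conditions
on the cell's total normalized count (dispersion estimated from the baseline
replicates by method of moments, floored at 1e-4; the dispersion-zero limit
is the exact Poisson split test). A barcode represents true T-cell
recognition when `p < 0.001` and its clonal read count exceeds 100;
Benjamini–Hochberg FDR values are reported alongside.

**Recognition profiling.** The frequency of each detected population, as a
percentage of CD8+ cells, is

    estimated_frequency = (reads for the pMHC / total assigned reads) × multimer-gate %

summed per protein within each donor; the **recognition percentage**
(populations / screened panel size × 100) corrects for HLA-dependent panel
sizes, since each donor is screened only with the library fraction matching
their HLA type (1–4 alleles of an eight-allele panel).

**Cohort statistics.** Two-sided Fisher exact tests (hypergeometric
enumeration) on recognition stratified by carriage of the five
NT1-associated HLA class I alleles (A\*11:01, B\*18:01, B\*35:01, B\*51:01,
C\*04:01); Mann–Whitney rank tests on recognition percentages; and one-way
ANOVA with Tukey–Kramer contrasts on log-transformed population frequencies
across the three cohorts (NT1 patients, DQB1\*06:02-positive and -negative
controls).

## Worked example

Simulate a 100-reagent screen for one donor with five 50×-enriched
barcodes, process the reads, and call recognition:

```r
library(pmhcscreen)

dict  <- generate_barcode_dictionary(100, seed = 1)
lib   <- build_library(simulate_prediction_table(n_binders = 100, seed = 1), dict)
donor <- simulate_cohort(1, 0, 0, seed = 1)
panel <- build_donor_panel(donor, lib)      # donor carries A*02:01;A*03:01 -> 26 reagents

pool  <- setNames(rep(1/100, 100), dict$barcode_id)
tmp   <- tempfile()
base  <- simulate_baseline_reads(sim_truth(pool, depth = 1e4, seed = 1), dict, tmp)
spikes <- panel$panel$barcode_id[1:5]
truth  <- sim_truth(pool[panel$panel$barcode_id], depth = 1e4,
                    spiked_barcodes = spikes, fold_enrichment = 50, seed = 1)
sorted <- simulate_sorted_sample(truth, donor, dict, tmp,
                                 error_rate = 0.002, panel = panel)

counts <- process_samples(c(base$files, setNames(sorted$file, donor$donor_id)), dict)
counts
#> count_table: 100 barcodes x 4 samples
#>   total raw reads: 39,975; total clonal reads: 37,762
#>   unassigned: 25; unparseable: 0

enr <- call_enrichment(counts, names(base$files))
hits(enr)[, c("barcode_id", "log2_fc", "p_value", "clonal_reads")]
#>   barcode_id log2_fc   p_value clonal_reads
#> 1     BC0001    5.29 2.23e-308         1541
#> 2     BC0006    5.17 2.23e-308         1473
#> 3     BC0007    5.35 2.23e-308         1469
#> 4     BC0008    5.17 2.23e-308         1441
#> 5     BC0024    5.37 2.23e-308         1469

summarize_donor(enr, donor, panel, counts)
#> recognition_profile for NT1_01 (NT1)
#>   5 population(s) across a 26-reagent panel (recognition 19.231%)
#>   summed estimated frequency: 0.05013% of CD8+
```

All five spiked barcodes — and nothing else — pass the `p < 0.001` and
clonal-reads > 100 thresholds: each shows the expected ~log2(50) ≈ 5.3-fold
enrichment over the triplicate baseline (the tiny p-values are floored at
the smallest representable double). The donor's recognition percentage is
5/26 × 100 = 19.2%, and each population's frequency is its share of the
donor's clonal reads times the simulated multimer gate.

The full pipeline (simulate → process → call → profile → stats) runs as one
seeded, manifest-logged command:

```r
run_pipeline(demo_run_config("demo_out", seed = 1))
```

or from a shell via the thin wrapper
`Rscript inst/scripts/pmhcscreen-run.R --out demo_out --seed 1`
(a YAML scenario like `inst/extdata/demo_config.yaml` can be passed with
`--config`; exit codes: 0 ok, 2 configuration error, 3 integrity error).

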