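## Shared fixtures, built in code at test time.

fixture_dictionary <- function(n = 20, seed = 11) {
  generate_barcode_dictionary(n, seed = seed)
}

## A small reagent library over 2 proteins x 2 HLAs with known cell counts.
fixture_toy_library <- function() {
  data.frame(
    pmhc_id = sprintf("pMHC%04d", 1:6),
    peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD",
                "EEEEEEEEE", "FFFFFFFFF", "GGGGGGGGG"),
    protein = c("HCRT", "HCRT", "HCRT", "RFX4", "RFX4", "RFX4"),
    start_pos = c(1L, 10L, 20L, 5L, 50L, 100L),
    hla = c("A*02:01", "A*02:01", "B*07:02", "A*02:01", "B*07:02", "B*07:02"),
    barcode_id = sprintf("BC%04d", 1:6),
    stringsAsFactors = FALSE
  )
}

fixture_donor <- function(donor_id = "NT1_01", cohort = "NT1",
                          hla = "A*02:01", dq = TRUE, gate = 0.1) {
  data.frame(
    donor_id = donor_id, cohort = cohort, hla_class_I = hla,
    dqb1_0602 = dq, multimer_gate_pct = gate, cd8_total = 5e5,
    stringsAsFactors = FALSE
  )
}

## Count-level fixture: baseline + sorted samples with optional spikes.
fixture_counts <- function(n_barcodes = 200, depth = 1e5, n_baseline = 3,
                           sorted = list(), dispersion = 0.05, seed = 5) {
  ids <- sprintf("BC%04d", seq_len(n_barcodes))
  set.seed(seed)
  w <- 10^rnorm(n_barcodes, 0, 0.25)
  truth <- sim_truth(stats::setNames(w / sum(w), ids), depth = depth,
                     seed = seed)
  simulate_count_matrix(truth, sorted = sorted, n_baseline = n_baseline,
                        dispersion = dispersion)
}
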