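test_that("barcode dictionaries satisfy length, uniqueness and Hamming constraints", {
  d <- generate_barcode_dictionary(10, length = 25, umi_length = 6,
                                   min_hamming = 5, seed = 1)
  expect_equal(nrow(d), 10)
  expect_true(all(nchar(d$seq_a) == 25))
  expect_true(all(nchar(d$seq_b) == 25))
  expect_true(all(grepl("^[ACGT]+$", c(d$seq_a, d$seq_b))))
  expect_false(any(duplicated(paste(d$seq_a, d$seq_b))))
  ham <- function(x, y) sum(charToRaw(x) != charToRaw(y))
  for (set in list(d$seq_a, d$seq_b)) {
    for (i in 1:9) for (j in (i + 1):10) {
      expect_gte(ham(set[i], set[j]), 5)
    }
  }
  ## deterministic given the seed
  expect_identical(d, generate_barcode_dictionary(10, seed = 1))
  expect_false(identical(d$seq_a,
                         generate_barcode_dictionary(10, seed = 2)$seq_a))
})

test_that("infeasible dictionary requests raise a capacity error, not truncation", {
  expect_error(
    generate_barcode_dictionary(5, length = 2, min_hamming = 2, seed = 1,
                                max_attempts = 2000),
    class = "pmhc_capacity_error"
  )
})

test_that("simulated cohorts have requested sizes, 1-4 panel alleles and consistent DQ status", {
  don <- simulate_cohort(4, 5, 6, seed = 3)
  expect_equal(as.vector(table(don$cohort)[c("NT1", "DQ0602_pos_control",
                                             "DQ0602_neg_control")]),
               c(4, 5, 6))
  n_alleles <- lengths(split_alleles(don$hla_class_I))
  expect_true(all(n_alleles >= 1 & n_alleles <= 4))
  expect_true(all(unlist(split_alleles(don$hla_class_I)) %in% hla_panel()))
  expect_true(all(don$multimer_gate_pct >= 0 & don$multimer_gate_pct <= 100))
  ## DQ status: controls strictly by cohort; one seronegative patient by default
  expect_true(all(don$dqb1_0602[don$cohort == "DQ0602_pos_control"]))
  expect_false(any(don$dqb1_0602[don$cohort == "DQ0602_neg_control"]))
  expect_equal(sum(!don$dqb1_0602[don$cohort == "NT1"]), 1)
  expect_equal(nrow(simulate_cohort(0, 0, 0, seed = 1)), 0)
  expect_error(simulate_cohort(2, 2, 2, allele_pool = character(0)),
               class = "pmhc_config_error")
})

test_that("baseline read counts follow the multinomial expectation", {
  dict <- fixture_dictionary(50, seed = 7)
  comp <- stats::setNames(rep(1 / 50, 50), dict$barcode_id)
  tr <- sim_truth(comp, depth = 2e4, seed = 21)
  out <- simulate_baseline_reads(tr, dict, withr::local_tempdir(),
                                 n_replicates = 3)
  expect_equal(colSums(out$expected_counts), rep(2e4, 3),
               ignore_attr = TRUE)
  ## each barcode within 5 binomial sd of n*p
  p <- 1 / 50
  sd5 <- 5 * sqrt(2e4 * p * (1 - p))
  expect_true(all(abs(out$expected_counts - 2e4 * p) <= sd5))
  ## FASTQ files agree with the returned counts
  parsed <- parse_reads(out$files[1])
  expect_equal(parsed$n_total, 2e4)
  expect_equal(parsed$n_unparseable, 0)
})

test_that("a zero-proportion barcode never appears in simulated reads", {
  dict <- fixture_dictionary(10, seed = 2)
  comp <- stats::setNames(c(0, rep(1 / 9, 9)), dict$barcode_id)
  tr <- sim_truth(comp, depth = 3000, seed = 5)
  out <- simulate_baseline_reads(tr, dict, withr::local_tempdir(),
                                 n_replicates = 1)
  expect_equal(unname(out$expected_counts[1, 1]), 0)
  parsed <- parse_reads(out$files[1])
  bc <- assign_barcodes(parsed$reads$seq_a_region, parsed$reads$seq_b_region,
                        dict, max_mismatch = 0)
  expect_false(dict$barcode_id[1] %in% bc)
})

test_that("identical seeds give byte-identical FASTQ output", {
  dict <- fixture_dictionary(10, seed = 2)
  tr <- sim_truth(stats::setNames(rep(0.1, 10), dict$barcode_id),
                  depth = 2000, seed = 77)
  f1 <- simulate_baseline_reads(tr, dict, withr::local_tempdir())$files
  f2 <- simulate_baseline_reads(tr, dict, withr::local_tempdir())$files
  for (k in seq_along(f1)) {
    expect_identical(readBin(f1[k], "raw", file.size(f1[k])),
                     readBin(f2[k], "raw", file.size(f2[k])))
  }
})

test_that("error-free simulated reads round-trip to their generating barcode", {
  dict <- fixture_dictionary(15, seed = 4)
  donor <- fixture_donor()
  tr <- sim_truth(stats::setNames(rep(1 / 15, 15), dict$barcode_id),
                  depth = 3000, spiked_barcodes = dict$barcode_id[1:2],
                  fold_enrichment = 10, seed = 6)
  st <- simulate_sorted_sample(tr, donor, dict, withr::local_tempdir(),
                               error_rate = 0)
  parsed <- parse_reads(st$file)
  bc <- assign_barcodes(parsed$reads$seq_a_region, parsed$reads$seq_b_region,
                        dict, max_mismatch = 0)
  expect_false(anyNA(bc))
  expect_equal(as.vector(table(factor(bc, levels = dict$barcode_id))),
               unname(st$counts))
})

test_that("spiked compositions renormalize to 1 and respect the donor panel", {
  dict <- fixture_dictionary(12, seed = 9)
  comp <- stats::setNames(runif(12), dict$barcode_id)
  tr <- sim_truth(comp, depth = 1000, spiked_barcodes = dict$barcode_id[1:5],
                  fold_enrichment = 50, seed = 1)
  sc <- spiked_composition(tr)
  expect_equal(sum(sc), 1, tolerance = 1e-12)
  expect_equal(nrow(simulate_sorted_sample(
    tr, fixture_donor(), dict, withr::local_tempdir(), error_rate = 0
  )$truth_table), 5)
  ## no spikes: composition equals the baseline composition
  tr0 <- sim_truth(comp, depth = 1000, seed = 1)
  expect_equal(spiked_composition(tr0), tr0$baseline_composition)
  ## spikes outside the donor panel are rejected
  lib <- fixture_toy_library()
  panel <- build_donor_panel(fixture_donor(hla = "A*02:01"), lib)
  tr_bad <- sim_truth(stats::setNames(rep(1 / 6, 6), lib$barcode_id),
                      depth = 100, spiked_barcodes = lib$barcode_id[3],
                      fold_enrichment = 5, seed = 1)
  expect_error(
    simulate_sorted_sample(tr_bad, fixture_donor(hla = "A*02:01"),
                           fixture_dictionary(6), withr::local_tempdir(),
                           panel = panel),
    class = "pmhc_validation_error"
  )
  expect_error(sim_truth(comp, spiked_barcodes = dict$barcode_id[1],
                         fold_enrichment = 0.5),
               class = "pmhc_config_error")
})

test_that("count-level simulation is deterministic and centred on depth x composition", {
  ids <- sprintf("BC%04d", 1:100)
  tr <- sim_truth(stats::setNames(rep(0.01, 100), ids), depth = 1e5, seed = 3)
  ct <- simulate_count_matrix(tr, sorted = list(S1 = list(spiked = ids[1],
                                                          fold = 50)),
                              n_baseline = 3, dispersion = 0.05)
  ct2 <- simulate_count_matrix(tr, sorted = list(S1 = list(spiked = ids[1],
                                                           fold = 50)),
                               n_baseline = 3, dispersion = 0.05)
  expect_identical(ct$clonal, ct2$clonal)
  expect_equal(mean(ct$clonal[, 1:3]), 1000, tolerance = 0.05)
  expect_gt(ct$clonal[ids[1], "S1"], 5 * median(ct$clonal[, "S1"]))
})
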