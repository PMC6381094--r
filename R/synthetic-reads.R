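#' Define the ground truth of a simulated screening sample
#'
#' A `sim_truth` object fixes everything the read and count simulators need:
#' the baseline (reagent-pool) barcode composition, sequencing depth, the
#' spiked (truly enriched) barcodes with their fold enrichments, and the
#' master seed. Weights are normalized to proportions on construction.
#'
#' @param baseline_composition Named non-negative numeric weights, one per
#'   barcode id; normalized to sum to 1.
#' @param depth Reads per sample (> 0).
#' @param spiked_barcodes Character vector of barcode ids that are truly
#'   enriched in sorted samples.
#' @param fold_enrichment Fold enrichment (> 1) per spiked barcode; a scalar
#'   is recycled.
#' @param seed Integer master seed; per-sample streams are derived from it.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(baseline_composition, depth = 1e5,
                      spiked_barcodes = character(0),
                      fold_enrichment = numeric(0), seed = 1) {
  if (is.null(names(baseline_composition))) {
    abort_config("baseline_composition must be named by barcode id")
  }
  if (any(baseline_composition < 0)) abort_config("proportions must be non-negative")
  s <- sum(baseline_composition)
  if (s <= 0) abort_config("baseline_composition must have positive total")
  comp <- baseline_composition / s
  if (depth <= 0) abort_config("depth must be > 0")
  if (length(spiked_barcodes)) {
    if (!all(spiked_barcodes %in% names(comp))) {
      abort_validation("spiked barcodes missing from baseline composition")
    }
    fold_enrichment <- rep_len(fold_enrichment, length(spiked_barcodes))
    if (any(fold_enrichment <= 1)) abort_config("fold_enrichment must be > 1 for spikes")
    names(fold_enrichment) <- spiked_barcodes
  }
  structure(
    list(
      baseline_composition = comp,
      depth = depth,
      spiked_barcodes = spiked_barcodes,
      fold_enrichment = fold_enrichment,
      seed = as.integer(seed)
    ),
    class = "sim_truth"
  )
}

#' Composition of a sorted sample under a spike-in truth
#'
#' Multiplies the baseline composition by the fold enrichment of each spiked
#' barcode and renormalizes to proportions.
#'
#' @param truth A [sim_truth()] object.
#' @return Named numeric proportions summing to 1.
#' @export
spiked_composition <- function(truth) {
  comp <- truth$baseline_composition
  if (length(truth$spiked_barcodes)) {
    comp[truth$spiked_barcodes] <-
      comp[truth$spiked_barcodes] * truth$fold_enrichment
  }
  comp / sum(comp)
}

## Build read strings for a vector of per-barcode counts:
## read = seq_a (25 nt) + UMI (umi_length nt, uniform random) + seq_b (25 nt).
build_reads <- function(dictionary, counts) {
  idx <- match(names(counts), dictionary$barcode_id)
  if (anyNA(idx)) abort_validation("counts refer to barcodes missing from the dictionary")
  assignment <- rep(idx, counts)
  n <- length(assignment)
  if (n == 0L) return(character(0))
  umi_len <- dictionary$umi_length[1]
  paste0(
    dictionary$seq_a[assignment],
    random_umis(n, umi_len),
    dictionary$seq_b[assignment]
  )
}

## Independent per-base substitution errors at `rate`; no indels.
apply_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  width <- nchar(reads[1])
  hit <- which(runif(length(reads) * width) < rate)
  for (h in hit) {
    i <- ((h - 1L) %% length(reads)) + 1L
    pos <- ((h - 1L) %/% length(reads)) + 1L
    old <- substr(reads[i], pos, pos)
    substr(reads[i], pos, pos) <- sample(setdiff(DNA_BASES, old), 1)
  }
  reads
}

write_fastq <- function(reads, ids, path, qual_char = "I") {
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- ids
  qual <- Biostrings::BStringSet(strrep(qual_char, nchar(reads)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Simulate replicate baseline (reagent-pool) FASTQ samples
#'
#' Per replicate, reads are drawn multinomially from the baseline composition
#' at the stated depth; each read is `seq_a + UMI + seq_b` with a uniformly
#' random UMI and a constant Sanger quality string. Replicates use RNG
#' streams derived from `(seed, sample label)`, so outputs are byte-identical
#' given the same truth.
#'
#' @param truth A [sim_truth()] object.
#' @param dictionary Barcode dictionary from [generate_barcode_dictionary()].
#' @param out_dir Output directory for FASTQ files (created if missing).
#' @param n_replicates Number of baseline replicates (default 3, mirroring
#'   the triplicate reagent-pool baseline of the assay).
#' @param prefix Sample-id prefix for the replicates.
#' @return Invisibly, a list with `files` (named by sample id) and
#'   `expected_counts` (barcode x replicate matrix of multinomial draws).
#' @export
simulate_baseline_reads <- function(truth, dictionary, out_dir,
                                    n_replicates = 3, prefix = "baseline") {
  if (n_replicates < 1) abort_config("n_replicates must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comp <- truth$baseline_composition
  files <- character(0)
  expected <- matrix(0L, nrow = length(comp), ncol = n_replicates,
                     dimnames = list(names(comp), paste0(prefix, "_", seq_len(n_replicates))))
  for (i in seq_len(n_replicates)) {
    sample_id <- paste0(prefix, "_", i)
    path <- file.path(out_dir, paste0(sample_id, ".fastq"))
    counts <- with_seed(derive_seed(truth$seed, sample_id), {
      cn <- as.vector(rmultinom(1, truth$depth, comp))
      names(cn) <- names(comp)
      reads <- build_reads(dictionary, cn)
      write_fastq(reads, paste0(sample_id, ":", seq_along(reads)), path)
      cn
    })
    files[sample_id] <- path
    expected[, i] <- counts
  }
  invisible(list(files = files, expected_counts = expected))
}

#' Simulate a sorted (multimer-positive) FASTQ sample with spike-ins
#'
#' The sample composition is the baseline composition with the spiked
#' barcodes multiplied by their fold enrichment and renormalized; independent
#' per-base substitution errors are applied at `error_rate`.
#'
#' @param truth A [sim_truth()] object carrying the spike definition.
#' @param donor One-row donor record (a row of [simulate_cohort()] output);
#'   its `donor_id` names the sample and seeds its RNG stream.
#' @param dictionary Barcode dictionary.
#' @param out_dir Output directory for the FASTQ file.
#' @param error_rate Per-base substitution probability in `[0, 0.05]`.
#' @param panel Optional donor panel (from [build_donor_panel()]); when
#'   supplied, spiked barcodes outside the donor's screened panel raise a
#'   validation error.
#' @return Invisibly, a list with `file`, `counts` (per-barcode multinomial
#'   draw) and `truth_table` (spiked barcode ids, fold enrichments, expected
#'   proportions).
#' @export
simulate_sorted_sample <- function(truth, donor, dictionary, out_dir,
                                   error_rate = 0, panel = NULL) {
  if (error_rate < 0 || error_rate > 0.05) {
    abort_config("error_rate must be in [0, 0.05]")
  }
  if (!is.null(panel) && length(truth$spiked_barcodes) &&
      !all(truth$spiked_barcodes %in% panel$panel$barcode_id)) {
    abort_validation("spiked barcodes outside the donor's screened panel")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sample_id <- donor$donor_id
  comp <- spiked_composition(truth)
  out <- with_seed(derive_seed(truth$seed, paste0("sorted_", sample_id)), {
    cn <- as.vector(rmultinom(1, truth$depth, comp))
    names(cn) <- names(comp)
    reads <- apply_read_errors(build_reads(dictionary, cn), error_rate)
    path <- file.path(out_dir, paste0(sample_id, ".fastq"))
    write_fastq(reads, paste0(sample_id, ":", seq_along(reads)), path)
    list(file = path, counts = cn)
  })
  out$truth_table <- data.frame(
    barcode_id = truth$spiked_barcodes,
    fold_enrichment = unname(truth$fold_enrichment),
    expected_proportion = unname(comp[truth$spiked_barcodes]),
    stringsAsFactors = FALSE
  )
  invisible(out)
}

#' Simulate a barcode x sample count matrix without reads
#'
#' Count-level companion to the FASTQ simulators, used for larger simulation
#' studies (null calibration, spike recovery, power) where generating reads
#' is unnecessary. Baseline replicates follow the baseline composition;
#' sorted samples may carry spike-ins. Counts are drawn per barcode as
#' negative binomial around the multinomial expectation (`dispersion > 0`,
#' default 0.05 to emulate reagent-pool overdispersion) or Poisson
#' (`dispersion = 0`). Counts stand for clonally reduced reads; the raw and
#' clonal matrices of the returned table are identical.
#'
#' @param truth A [sim_truth()] object (its spikes are ignored here).
#' @param sorted A named list: sample id -> list(`spiked` = barcode ids,
#'   `fold` = fold enrichment scalar or vector).
#' @param n_baseline Number of baseline replicates.
#' @param dispersion Negative-binomial dispersion of the count noise.
#' @return A [count_table()].
#' @export
simulate_count_matrix <- function(truth, sorted = list(), n_baseline = 3,
                                  dispersion = 0.05) {
  comp <- truth$baseline_composition
  samples <- c(paste0("baseline_", seq_len(n_baseline)), names(sorted))
  m <- matrix(0, nrow = length(comp), ncol = length(samples),
              dimnames = list(names(comp), samples))
  draw <- function(sample_id, p) {
    with_seed(derive_seed(truth$seed, paste0("counts_", sample_id)), {
      mu <- truth$depth * p / sum(p)
      if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else rpois(length(mu), mu)
    })
  }
  for (i in seq_len(n_baseline)) {
    m[, i] <- draw(samples[i], comp)
  }
  for (s in names(sorted)) {
    p <- comp
    sp <- sorted[[s]]
    if (length(sp$spiked)) {
      if (!all(sp$spiked %in% names(p))) {
        abort_validation("spiked barcodes missing from composition")
      }
      p[sp$spiked] <- p[sp$spiked] * rep_len(sp$fold, length(sp$spiked))
    }
    m[, s] <- draw(s, p)
  }
  qc <- data.frame(
    sample_id = samples,
    total_reads = colSums(m),
    assigned = colSums(m),
    unassigned = 0L,
    unparseable = 0L,
    stringsAsFactors = FALSE
  )
  count_table(raw = m, clonal = m, qc = qc)
}
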