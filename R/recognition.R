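#' Estimated frequency of an antigen-specific T-cell population
#'
#' The frequency of a pMHC-specific population as a percentage of CD8+ T
#' cells: the fraction of sequencing reads specific for the pMHC out of all
#' assigned reads in the sorted sample, multiplied by the percentage of CD8+
#' cells falling inside the multimer-positive sorting gate.
#'
#' @param reads_pmhc Read count(s) for the pMHC barcode (vectorized).
#' @param total_reads Total assigned reads in the sample (> 0).
#' @param multimer_gate_pct Multimer-positive percentage of CD8+ cells, in
#'   `[0, 100]`.
#' @return Estimated frequency (percentage of CD8+ cells).
#' @examples
#' estimated_frequency(500, 10000, 0.1)  # 0.005
#' @export
estimated_frequency <- function(reads_pmhc, total_reads, multimer_gate_pct) {
  if (length(total_reads) != 1 || is.na(total_reads) || total_reads <= 0) {
    abort_validation("total_reads must be a single positive count")
  }
  if (multimer_gate_pct < 0 || multimer_gate_pct > 100) {
    abort_validation("multimer_gate_pct must lie in [0, 100]")
  }
  if (any(reads_pmhc < 0)) abort_validation("reads_pmhc must be >= 0")
  reads_pmhc / total_reads * multimer_gate_pct
}

#' Summarize one donor's recognition profile
#'
#' Converts a donor's enrichment hits into biological quantities: one
#' population per hit with its estimated frequency, per-protein summed
#' frequencies (aggregating across HLA contexts), the population count, and
#' the recognition percentage (populations / panel size x 100), which
#' corrects for HLA-dependent differences in screened panel size.
#'
#' @param results Enrichment results from [call_enrichment()] (any subset
#'   containing the donor's sample).
#' @param donor One-row donor record.
#' @param panel The donor's [build_donor_panel()].
#' @param counts The [count_table()] the results were called from; supplies
#'   the total assigned read denominator.
#' @param use_raw Use raw instead of clonally reduced reads in the frequency
#'   formula (default `FALSE`: clonal reads, consistent with the hit filter).
#' @return An object of class `recognition_profile`: a list with
#'   `donor_id`, `cohort`, `populations` (data.frame), `n_populations`,
#'   `per_protein_sum`, `sum_frequency`, `recognition_pct`, `panel_size`.
#' @export
summarize_donor <- function(results, donor, panel, counts, use_raw = FALSE) {
  sample_id <- donor$donor_id
  r <- results[results$sample_id == sample_id, , drop = FALSE]
  if (!nrow(r)) abort_config(sprintf("no enrichment results for sample %s", sample_id))
  h <- r[r$is_hit, , drop = FALSE]
  if (nrow(h) && !all(h$barcode_id %in% panel$panel$barcode_id)) {
    abort_integrity(sprintf(
      "hit barcode outside donor %s's screened panel (pipeline bug)", sample_id
    ))
  }
  mat <- if (use_raw) counts$raw else counts$clonal
  if (!sample_id %in% colnames(mat)) {
    abort_config(sprintf("sample %s missing from count table", sample_id))
  }
  total <- sum(mat[, sample_id])
  ann <- panel$panel[match(h$barcode_id, panel$panel$barcode_id), , drop = FALSE]
  reads <- mat[h$barcode_id, sample_id]
  populations <- data.frame(
    pmhc_id = ann$pmhc_id,
    barcode_id = h$barcode_id,
    protein = ann$protein,
    hla = ann$hla,
    peptide = ann$peptide,
    clonal_reads = h$clonal_reads,
    estimated_frequency = if (nrow(h)) {
      estimated_frequency(unname(reads), total, donor$multimer_gate_pct)
    } else numeric(0),
    p_value = h$p_value,
    fdr = h$fdr,
    neglog10_p = -log10(h$p_value),
    stringsAsFactors = FALSE
  )
  per_protein <- if (nrow(populations)) {
    tapply(populations$estimated_frequency, populations$protein, sum)
  } else {
    setNames(numeric(0), character(0))
  }
  structure(
    list(
      donor_id = donor$donor_id,
      cohort = donor$cohort,
      populations = populations,
      n_populations = nrow(populations),
      per_protein_sum = c(per_protein),
      sum_frequency = sum(populations$estimated_frequency),
      recognition_pct = if (panel$panel_size > 0) {
        nrow(populations) / panel$panel_size * 100
      } else NA_real_,
      panel_size = panel$panel_size
    ),
    class = "recognition_profile"
  )
}

#' @export
print.recognition_profile <- function(x, ...) {
  cat(sprintf("recognition_profile for %s (%s)\n", x$donor_id, x$cohort))
  cat(sprintf("  %d population(s) across a %d-reagent panel (recognition %.3f%%)\n",
              x$n_populations, x$panel_size,
              if (is.na(x$recognition_pct)) NA else x$recognition_pct))
  cat(sprintf("  summed estimated frequency: %.5f%% of CD8+\n", x$sum_frequency))
  invisible(x)
}

#' Donor-level summary table of recognition profiles
#'
#' @param profiles List of [summarize_donor()] outputs.
#' @return A `data.frame` with one row per donor: `donor_id`, `cohort`,
#'   `n_populations`, `sum_frequency`, `recognition_pct`, `panel_size`.
#' @export
profiles_summary <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      donor_id = p$donor_id, cohort = p$cohort,
      n_populations = p$n_populations,
      sum_frequency = p$sum_frequency,
      recognition_pct = p$recognition_pct,
      panel_size = p$panel_size,
      stringsAsFactors = FALSE
    )
  }))
}

#' Cohort-wide long table of detected populations
#'
#' One row per detected population across donors; the input to cohort-level
#' statistics and plotting exports.
#'
#' @param profiles List of [summarize_donor()] outputs.
#' @return A `data.frame` with `donor_id`, `cohort`, `protein`, `hla`,
#'   `pmhc_id`, `peptide`, `frequency_pct`, `p_value`, `fdr`.
#' @export
populations_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (!nrow(p$populations)) return(NULL)
    data.frame(
      donor_id = p$donor_id, cohort = p$cohort,
      protein = p$populations$protein,
      hla = p$populations$hla,
      pmhc_id = p$populations$pmhc_id,
      peptide = p$populations$peptide,
      frequency_pct = p$populations$estimated_frequency,
      p_value = p$populations$p_value,
      fdr = p$populations$fdr,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      donor_id = character(0), cohort = character(0), protein = character(0),
      hla = character(0), pmhc_id = character(0), peptide = character(0),
      frequency_pct = numeric(0), p_value = numeric(0), fdr = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
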