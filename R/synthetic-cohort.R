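#' The eight-allele HLA class I screening panel
#'
#' The five narcolepsy-associated risk alleles plus three common alleles
#' included for cohort coverage.
#'
#' @return Character vector of HLA allele names.
#' @export
hla_panel <- function() {
  c("A*02:01", "A*03:01", "B*07:02",
    "A*11:01", "B*18:01", "B*35:01", "B*51:01", "C*04:01")
}

#' NT1-associated HLA class I risk alleles
#'
#' @return Character vector of the five risk alleles used for cohort
#'   stratification.
#' @export
nt1_risk_alleles <- function() {
  c("A*11:01", "B*18:01", "B*35:01", "B*51:01", "C*04:01")
}

#' Lengths of the seven hypocretin-neuron-associated proteins
#'
#' Canonical-isoform lengths in amino acids for the proteins screened in the
#' narcolepsy setting; used as defaults by the prediction-table simulator and
#' by hotspot mapping.
#'
#' @return Named integer vector (protein -> length in aa).
#' @export
protein_lengths <- function() {
  c(HCRT = 131L, HCRTR2 = 444L, LHX9 = 397L, PDYN = 254L,
    QRFP = 136L, RFX4 = 735L, TRIB2 = 343L)
}

#' Simulate a three-cohort donor set
#'
#' Generates donor records for narcolepsy type 1 (NT1) patients and
#' HLA-DQB1*06:02-positive / -negative healthy controls. Each donor carries
#' between one and four class I alleles from the screening panel; DQB1*06:02
#' status follows the cohort label except for `dq_negative_patients` NT1
#' donors, mirroring the typical single seronegative patient in a cohort of
#' twenty.
#'
#' @param n_nt1,n_dq_pos,n_dq_neg Cohort sizes (>= 0).
#' @param allele_pool Alleles donors may carry; defaults to [hla_panel()].
#' @param seed Integer seed.
#' @param dq_negative_patients Number of NT1 donors simulated as
#'   DQB1*06:02-negative (default 1 when any patients are requested).
#' @return A `data.frame` with columns `donor_id`, `cohort` (one of `NT1`,
#'   `DQ0602_pos_control`, `DQ0602_neg_control`), `hla_class_I`
#'   (`;`-collapsed), `dqb1_0602`, `multimer_gate_pct` (percentage of CD8+
#'   cells inside the multimer-positive sorting gate) and `cd8_total`.
#' @export
simulate_cohort <- function(n_nt1, n_dq_pos, n_dq_neg,
                            allele_pool = hla_panel(), seed = 1,
                            dq_negative_patients = as.integer(n_nt1 > 0)) {
  if (length(allele_pool) == 0) abort_config("allele_pool must be non-empty")
  if (any(c(n_nt1, n_dq_pos, n_dq_neg) < 0)) abort_config("cohort sizes must be >= 0")
  if (dq_negative_patients > n_nt1) abort_config("dq_negative_patients exceeds n_nt1")
  with_seed(derive_seed(seed, "cohort"), {
    make <- function(nn, cohort, prefix, dq) {
      if (nn == 0L) return(NULL)
      alleles <- vapply(seq_len(nn), function(i) {
        k <- sample(1:4, 1, prob = c(0.2, 0.3, 0.3, 0.2))
        k <- min(k, length(allele_pool))
        paste(sort(sample(allele_pool, k)), collapse = ";")
      }, character(1))
      data.frame(
        donor_id = sprintf("%s_%02d", prefix, seq_len(nn)),
        cohort = cohort,
        hla_class_I = alleles,
        dqb1_0602 = dq,
        multimer_gate_pct = pmin(pmax(round(10^rnorm(nn, -1, 0.4), 4), 0.001), 10),
        cd8_total = round(runif(nn, 1e5, 1e6)),
        stringsAsFactors = FALSE
      )
    }
    nt1 <- make(n_nt1, "NT1", "NT1", TRUE)
    if (!is.null(nt1) && dq_negative_patients > 0) {
      nt1$dqb1_0602[sample(n_nt1, dq_negative_patients)] <- FALSE
    }
    out <- rbind(
      nt1,
      make(n_dq_pos, "DQ0602_pos_control", "HCP", TRUE),
      make(n_dq_neg, "DQ0602_neg_control", "HCN", FALSE)
    )
    if (is.null(out)) {
      out <- data.frame(
        donor_id = character(0), cohort = character(0),
        hla_class_I = character(0), dqb1_0602 = logical(0),
        multimer_gate_pct = numeric(0), cd8_total = numeric(0),
        stringsAsFactors = FALSE
      )
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-population frequencies across cohorts
#'
#' Draws estimated frequencies (% of CD8+ cells) for antigen-specific T-cell
#' populations, donor by donor, from a log-normal model in which NT1 patients
#' and DQB1*06:02-negative controls share a higher location than
#' DQB1*06:02-positive controls. This emulates the qualitative cohort
#' structure of the screening study (patients' per-population frequencies
#' stochastically dominate those of DQ-positive controls) and is the input
#' for power studies of the cohort-level ANOVA.
#'
#' @param donors Donor table from [simulate_cohort()].
#' @param mean_log10 Named numeric: mean log10 frequency (% of CD8+) per
#'   cohort. Defaults place patients and DQ-negative controls at 10^-2.3
#'   (~0.005%) and DQ-positive controls 0.5 log10 lower (~3.2-fold), an
#'   effect size set by a power calculation so the prescribed
#'   patient-vs-DQ-positive contrast is detectable with ~95% power at the
#'   emulated cohort sizes (see the methods vignette).
#' @param sd_log10 Log10-scale standard deviation of population frequencies.
#' @param lambda_populations Mean number of detected populations per donor
#'   (Poisson).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `donor_id`, `cohort`, `frequency_pct`.
#' @export
simulate_population_frequencies <- function(donors,
                                            mean_log10 = c(
                                              NT1 = -2.3,
                                              DQ0602_pos_control = -2.8,
                                              DQ0602_neg_control = -2.3
                                            ),
                                            sd_log10 = 0.5,
                                            lambda_populations = 2,
                                            seed = 1) {
  if (nrow(donors) == 0) abort_config("donors must be non-empty")
  with_seed(derive_seed(seed, "population_frequencies"), {
    rows <- lapply(seq_len(nrow(donors)), function(i) {
      k <- rpois(1, lambda_populations)
      if (k == 0L) return(NULL)
      mu <- mean_log10[[donors$cohort[i]]]
      data.frame(
        donor_id = donors$donor_id[i],
        cohort = donors$cohort[i],
        frequency_pct = 10^rnorm(k, mu, sd_log10),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(donor_id = character(0), cohort = character(0),
                        frequency_pct = numeric(0), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}
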