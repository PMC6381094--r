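#' Configure a screening-pipeline run
#'
#' Bundles every knob of an end-to-end simulated screen: library size,
#' sequencing depth, cohort composition, spike-in design, and enrichment
#' thresholds.
#'
#' @param out_dir Output directory (created on run).
#' @param seed Master seed; every random stream derives from it.
#' @param n_barcodes Dictionary size.
#' @param n_binders Reagent-library size (<= `n_barcodes`).
#' @param depth Reads per simulated sample.
#' @param n_baseline Baseline replicates (default 3).
#' @param error_rate Per-base substitution rate in sorted-sample reads.
#' @param n_nt1,n_dq_pos,n_dq_neg Cohort sizes.
#' @param spikes_per_donor Truly enriched barcodes per sorted sample.
#' @param fold_enrichment Fold enrichment of each spike.
#' @param max_mismatch Barcode-assignment mismatch tolerance per region.
#' @param baseline_jitter_sd Log10-normal jitter of reagent-pool proportions
#'   around uniform.
#' @param enrichment An [enrichment_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, n_barcodes = 100,
                       n_binders = n_barcodes, depth = 1e4, n_baseline = 3,
                       error_rate = 0.002, n_nt1 = 2, n_dq_pos = 2,
                       n_dq_neg = 2, spikes_per_donor = 5,
                       fold_enrichment = 50, max_mismatch = 1,
                       baseline_jitter_sd = 0.25,
                       enrichment = enrichment_config()) {
  if (n_baseline < 2) {
    abort_config("at least two baseline replicates are required (triplicate by design)")
  }
  if (n_binders > n_barcodes) abort_config("n_binders cannot exceed n_barcodes")
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), n_barcodes = n_barcodes,
         n_binders = n_binders, depth = depth, n_baseline = n_baseline,
         error_rate = error_rate, n_nt1 = n_nt1, n_dq_pos = n_dq_pos,
         n_dq_neg = n_dq_neg, spikes_per_donor = spikes_per_donor,
         fold_enrichment = fold_enrichment, max_mismatch = max_mismatch,
         baseline_jitter_sd = baseline_jitter_sd, enrichment = enrichment),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Flat YAML mapping of [run_config()] fields; nested `enrichment:` keys are
#' passed to [enrichment_config()].
#'
#' @param path YAML file path.
#' @param out_dir,seed Optional overrides of the file's values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) abort_config(sprintf("missing config file: %s", path))
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  if (is.null(y$out_dir)) abort_config("config must define out_dir")
  enr <- do.call(enrichment_config, if (is.null(y$enrichment)) list() else y$enrichment)
  y$enrichment <- NULL
  do.call(run_config, c(y, list(enrichment = enr)))
}

#' The bundled demonstration configuration
#'
#' A desk-scale scenario: 100 barcodes, six donors in three cohorts,
#' triplicate baselines, five 50x spike-ins per donor at 10^4 reads per
#' sample.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A [run_config()].
#' @export
demo_run_config <- function(out_dir, seed = 1) {
  run_config(out_dir = out_dir, seed = seed, n_barcodes = 100, depth = 1e4,
             n_baseline = 3, error_rate = 0.002, n_nt1 = 2, n_dq_pos = 2,
             n_dq_neg = 2, spikes_per_donor = 5, fold_enrichment = 50)
}

pipeline_paths <- function(out_dir) {
  list(
    dictionary = file.path(out_dir, "dictionary.tsv"),
    predictions = file.path(out_dir, "predictions.tsv"),
    library = file.path(out_dir, "library.tsv"),
    donors = file.path(out_dir, "donors.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    fastq_dir = file.path(out_dir, "fastq"),
    counts = file.path(out_dir, "counts.tsv"),
    qc = file.path(out_dir, "qc.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    hits = file.path(out_dir, "hits.tsv"),
    profiles = file.path(out_dir, "profiles.tsv"),
    populations = file.path(out_dir, "populations.tsv"),
    stats = file.path(out_dir, "stats.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
}

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) {
    abort_config(sprintf("missing %s (expected at %s); run the earlier stage first",
                         what, path))
  }
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
}

## jsonlite-friendly rendering of the stats report
stats_to_list <- function(report) {
  list(
    fisher = lapply(report$fisher, function(f) {
      list(table = unname(lapply(seq_len(nrow(f$table)),
                                 function(i) unname(f$table[i, ]))),
           p_value = f$p_value, degenerate = f$degenerate)
    }),
    mann_whitney = report$mann_whitney,
    anova = if (!is.null(report$anova$note)) {
      list(note = report$anova$note)
    } else {
      list(F = report$anova$F, p_value = report$anova$p_value,
           df = as.list(report$anova$df),
           tukey = report$anova$tukey,
           n = as.list(report$anova$n))
    }
  )
}

#' Run the screening pipeline end to end
#'
#' Orchestrates simulate -> process -> call -> profile -> stats as one
#' seeded, logged run. Every stage writes flat TSV artifacts under
#' `config$out_dir` plus a JSON manifest recording the seed, a configuration
#' hash and per-stage row counts; a rerun with the same configuration
#' produces identical files. Stages not selected are resumed from their
#' on-disk artifacts; a missing prerequisite fails fast naming the path.
#'
#' @param config A [run_config()] (or the path of a YAML file for
#'   [read_run_config()]).
#' @param stages Character subset of
#'   `c("simulate", "process", "call", "profile", "stats")`, in order.
#' @return Invisibly, a list with the artifact `paths` and in-memory
#'   `results` of the stages run.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "process", "call",
                                    "profile", "stats")) {
  if (is.character(config)) config <- read_run_config(config)
  all_stages <- c("simulate", "process", "call", "profile", "stats")
  stages <- all_stages[all_stages %in% stages]
  if (!length(stages)) abort_config("no valid stage selected")
  paths <- pipeline_paths(config$out_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  seed <- config$seed

  dictionary <- NULL
  library_df <- NULL
  donors <- NULL
  counts <- NULL
  enr <- NULL

  need_dictionary <- function() {
    if (is.null(dictionary)) {
      dictionary <<- read_tsv_checked(paths$dictionary, "barcode dictionary")
    }
    dictionary
  }
  need_library <- function() {
    if (is.null(library_df)) {
      library_df <<- read_tsv_checked(paths$library, "reagent library")
    }
    library_df
  }
  need_donors <- function() {
    if (is.null(donors)) donors <<- read_tsv_checked(paths$donors, "donor table")
    donors
  }
  need_counts <- function() {
    if (is.null(counts)) {
      if (!file.exists(paths$counts)) {
        abort_config(sprintf("missing count table (expected at %s)", paths$counts))
      }
      counts <<- read_count_table(paths$counts, paths$qc)
    }
    counts
  }
  baseline_ids <- paste0("baseline_", seq_len(config$n_baseline))

  if ("simulate" %in% stages) {
    dictionary <- generate_barcode_dictionary(config$n_barcodes, seed = seed)
    predictions <- simulate_prediction_table(n_binders = config$n_binders,
                                             seed = seed)
    library_df <- build_library(predictions, dictionary)
    donors <- simulate_cohort(config$n_nt1, config$n_dq_pos, config$n_dq_neg,
                              seed = seed)
    pool <- with_seed(derive_seed(seed, "reagent_pool"), {
      w <- 10^rnorm(nrow(library_df), 0, config$baseline_jitter_sd)
      stats::setNames(w / sum(w), library_df$barcode_id)
    })
    base_truth <- sim_truth(pool, depth = config$depth, seed = seed)
    simulate_baseline_reads(base_truth, dictionary, paths$fastq_dir,
                            n_replicates = config$n_baseline)
    truth_rows <- list()
    for (i in seq_len(nrow(donors))) {
      donor <- donors[i, ]
      panel <- suppressWarnings(build_donor_panel(donor, library_df))
      if (panel$panel_size == 0) next
      spiked <- with_seed(derive_seed(seed, paste0("spikes_", donor$donor_id)), {
        sample(panel$panel$barcode_id,
               min(config$spikes_per_donor, panel$panel_size))
      })
      donor_pool <- pool[panel$panel$barcode_id]
      donor_truth <- sim_truth(donor_pool, depth = config$depth,
                               spiked_barcodes = spiked,
                               fold_enrichment = config$fold_enrichment,
                               seed = seed)
      st <- simulate_sorted_sample(donor_truth, donor, dictionary,
                                   paths$fastq_dir,
                                   error_rate = config$error_rate,
                                   panel = panel)
      truth_rows[[donor$donor_id]] <- cbind(donor_id = donor$donor_id,
                                            st$truth_table)
    }
    truth <- do.call(rbind, truth_rows)
    write_tsv(dictionary, paths$dictionary)
    write_tsv(predictions, paths$predictions)
    write_tsv(library_df, paths$library)
    write_tsv(donors, paths$donors)
    write_tsv(truth, paths$truth)
    res$simulate <- list(dictionary = dictionary, library = library_df,
                         donors = donors, truth = truth)
  }

  if ("process" %in% stages) {
    dictionary <- need_dictionary()
    donors <- need_donors()
    if (!dir.exists(paths$fastq_dir)) {
      abort_config(sprintf("missing FASTQ directory: %s", paths$fastq_dir))
    }
    fq <- list.files(paths$fastq_dir, pattern = "\\.fastq$", full.names = TRUE)
    sample_ids <- sub("\\.fastq$", "", basename(fq))
    names(fq) <- sample_ids
    ## baselines first, then sorted samples in donor order
    ord <- c(intersect(baseline_ids, sample_ids),
             intersect(donors$donor_id, sample_ids))
    fq <- fq[ord]
    if (!all(baseline_ids %in% names(fq))) {
      abort_config("baseline FASTQ replicates missing; triplicate baseline required")
    }
    counts <- process_samples(fq, dictionary, config$max_mismatch)
    write_count_table(counts, paths$counts, paths$qc)
    res$process <- counts
  }

  if ("call" %in% stages) {
    counts <- need_counts()
    dictionary <- need_dictionary()
    if (!setequal(counts$barcode_ids, dictionary$barcode_id)) {
      abort_integrity("count table and dictionary disagree on the barcode set")
    }
    enr <- call_enrichment(counts, baseline_ids, config$enrichment)
    write_tsv(enr, paths$enrichment)
    write_tsv(hits(enr), paths$hits)
    res$call <- enr
  }

  if ("profile" %in% stages) {
    counts <- need_counts()
    donors <- need_donors()
    library_df <- need_library()
    if (is.null(enr)) {
      enr <- read_tsv_checked(paths$enrichment, "enrichment results")
    }
    profiles <- list()
    for (i in seq_len(nrow(donors))) {
      donor <- donors[i, ]
      if (!donor$donor_id %in% counts$samples) next
      panel <- suppressWarnings(build_donor_panel(donor, library_df))
      if (panel$panel_size == 0) next
      profiles[[donor$donor_id]] <-
        summarize_donor(enr, donor, panel, counts)
    }
    if (!length(profiles)) abort_integrity("no donor could be profiled")
    write_tsv(profiles_summary(profiles), paths$profiles)
    write_tsv(populations_table(profiles), paths$populations)
    res$profile <- profiles
  }

  if ("stats" %in% stages) {
    donors <- need_donors()
    summary_df <- if (!is.null(res$profile)) {
      profiles_summary(res$profile)
    } else {
      read_tsv_checked(paths$profiles, "donor profiles")
    }
    pops <- if (!is.null(res$profile)) {
      populations_table(res$profile)
    } else {
      read_tsv_checked(paths$populations, "population table")
    }
    report <- cohort_stats_report(summary_df, pops, donors)
    jsonlite::write_json(stats_to_list(report), paths$stats,
                         auto_unbox = TRUE, digits = NA, na = "null")
    res$stats <- report
  }

  cfg_plain <- unclass(config)
  cfg_plain$enrichment <- unclass(cfg_plain$enrichment)
  manifest <- list(
    package = "pmhcscreen",
    version = as.character(utils::packageVersion("pmhcscreen")),
    seed = seed,
    config = cfg_plain,
    config_hash = derive_seed(0, paste(deparse(cfg_plain), collapse = "")),
    stages_run = stages,
    artifact_rows = {
      existing <- Filter(file.exists, paths[!names(paths) %in%
                                              c("fastq_dir", "manifest", "stats")])
      lapply(existing, function(p) {
        nrow(data.table::fread(p, sep = "\t", data.table = FALSE))
      })
    }
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, results = res))
}
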