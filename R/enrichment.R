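#' Enrichment-calling configuration
#'
#' Parameters of the enrichment caller. Defaults follow the screening
#' analysis contract: doubly trimmed TMM normalization (30% trim on
#' log-ratios, 5% on average log-intensity), hits at `p < 0.001` with clonal
#' read counts strictly above 100, and a display pseudocount of 0.5 that
#' keeps log2 fold changes finite for zero baselines (never used in the
#' significance test).
#'
#' @param trim_m Two-sided trim fraction on M-values (log ratios).
#' @param trim_a Two-sided trim fraction on A-values (average log intensity).
#' @param dispersion Negative-binomial dispersion of the exact test:
#'   `"auto"` (method-of-moments over baseline replicates, floored at 1e-4)
#'   or a fixed value >= 0 (0 selects the exact Poisson-limit split test).
#' @param p_threshold Raw p-value threshold for hit calling.
#' @param min_clonal Clonal-read threshold; hits require strictly more.
#' @param pseudocount Pseudocount for fold-change display only.
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(trim_m = 0.30, trim_a = 0.05,
                              dispersion = "auto", p_threshold = 0.001,
                              min_clonal = 100, pseudocount = 0.5) {
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5) {
    abort_config("trim fractions must lie in [0, 0.5)")
  }
  if (!identical(dispersion, "auto") &&
      (!is.numeric(dispersion) || dispersion < 0)) {
    abort_config("dispersion must be \"auto\" or a number >= 0")
  }
  structure(
    list(trim_m = trim_m, trim_a = trim_a, dispersion = dispersion,
         p_threshold = p_threshold, min_clonal = min_clonal,
         pseudocount = pseudocount),
    class = "enrichment_config"
  )
}

## Pairwise TMM factor of `obs` against the reference column.
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) {
    warning("sample shares no positive barcode with the TMM reference; factor set to 1")
    return(1)
  }
  o <- obs[pos]; r <- ref[pos]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
          rank(a) >= lo_a & rank(a) <= hi_a
  keep <- keep & w > 0
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Per-sample scaling factors computed by the TMM procedure: the reference
#' is the sample whose upper quartile of library-size-scaled counts is
#' closest to the mean upper quartile; M (log ratio) and A (average log
#' intensity) values are formed on barcodes positive in both sample and
#' reference; after a double trim (`trim_m` on M, `trim_a` on A) the factor
#' is 2 to the precision-weighted mean M, with weights the inverse binomial
#' asymptotic variances. Factors are rescaled to geometric mean 1. M-values
#' are taken on library-size-normalized proportions, so a uniform depth
#' change of a sample leaves all factors at 1.
#'
#' @param counts Barcode x sample matrix, or a [count_table()] (its clonal
#'   matrix is used).
#' @param config An [enrichment_config()] supplying the trim fractions.
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, config = enrichment_config()) {
  m <- if (inherits(counts, "count_table")) counts$clonal else as.matrix(counts)
  if (ncol(m) < 2) abort_config("TMM needs at least two samples")
  lib <- colSums(m)
  if (any(lib <= 0)) abort_config("every sample must have a positive total")
  f75 <- apply(m, 2, function(x) quantile(x, 0.75, names = FALSE)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) 1 else
      tmm_pair(m[, j], m[, ref], lib[j], lib[ref], config$trim_m, config$trim_a)
  }, numeric(1))
  f <- f / geometric_mean(f)
  names(f) <- colnames(m)
  f
}

## Method-of-moments common dispersion over baseline replicates:
## pooled (var - mean) / mean^2, floored.
estimate_dispersion <- function(baseline, floor = 1e-4) {
  mu <- rowMeans(baseline)
  v <- apply(baseline, 1, var)
  ok <- mu > 0
  if (!any(ok)) return(floor)
  max(sum(v[ok] - mu[ok]) / sum(mu[ok]^2), floor)
}

#' Negative-binomial exact split test for one barcode
#'
#' Compares one sorted-sample count against pooled baseline replicate counts
#' (all on a common normalized scale), conditioning on their total. Under a
#' common negative-binomial mean with dispersion `phi`, the sample count
#' given the total follows a beta-binomial-type law with weights
#' `C(k + 1/phi - 1, k) * C(T - k + n_b/phi - 1, T - k)`; the one-sided
#' enrichment tail `P(K >= y | T)` is doubled and capped at 1. At
#' `dispersion = 0` the conditional law is exactly binomial
#' `(T, 1/(1 + n_b))` (the Poisson split test).
#'
#' @param y Observed (normalized, integer) count in the sorted sample.
#' @param baseline Integer vector of normalized baseline replicate counts.
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(y, baseline, dispersion) {
  total <- y + sum(baseline)
  if (total == 0) return(1)
  n_b <- length(baseline)
  if (dispersion <= 0) {
    p_one <- pbinom(y - 1, total, 1 / (1 + n_b), lower.tail = FALSE)
    return(max(min(1, 2 * p_one), .Machine$double.xmin))
  }
  r1 <- 1 / dispersion
  r2 <- n_b / dispersion
  i <- seq_len(total)
  lw1 <- c(0, cumsum(log((r1 - 1 + i) / i)))  # log C(k + r1 - 1, k), k = 0..total
  lw2 <- c(0, cumsum(log((r2 - 1 + i) / i)))
  lw <- lw1 + rev(lw2)
  lse <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  ## one-sided tail via log-sum-exp so extreme enrichment stays finite
  p_one <- exp(lse(lw[(y + 1):(total + 1)]) - lse(lw))
  max(min(1, 2 * p_one), .Machine$double.xmin)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return FDR values, elementwise >= `p`.
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort_validation("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Flag hits under the screening thresholds
#'
#' A barcode-sample pair represents true T-cell recognition when its raw
#' p-value is strictly below `p_threshold` and its clonal read count is
#' strictly above `min_clonal`. The FDR is reported alongside but the gate
#' operates on the raw p, reproducing the published rule (p < 0.001,
#' equivalent to FDR < 0.1 on the original data, plus clonal reads above
#' 100).
#'
#' @param results Enrichment results with columns `p_value`, `clonal_reads`.
#' @param config An [enrichment_config()].
#' @return `results` with a logical `is_hit` column.
#' @export
call_hits <- function(results, config = enrichment_config()) {
  results$is_hit <- results$p_value < config$p_threshold &
    results$clonal_reads > config$min_clonal
  results
}

#' Extract the sorted hit list
#'
#' @param results Output of [call_enrichment()] or [call_hits()].
#' @return The hit rows, sorted by p-value then barcode id.
#' @export
hits <- function(results) {
  h <- results[results$is_hit, , drop = FALSE]
  h <- h[order(h$p_value, h$barcode_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Call per-sample barcode enrichment against triplicate baselines
#'
#' The core caller: TMM normalization factors over all samples, counts
#' rescaled to a common effective library size, then per barcode and sorted
#' sample a log2 fold change versus the mean normalized baseline (with the
#' display pseudocount) and a [nb_exact_test()] p-value against the pooled
#' baseline replicates, BH-adjusted within sample. The significance test and
#' the hit filter both operate on clonally reduced counts.
#'
#' @param counts A [count_table()] (or barcode x sample matrix of clonal
#'   counts) containing baseline and sorted samples.
#' @param baseline Character vector (length >= 2) of baseline sample ids.
#' @param config An [enrichment_config()].
#' @return A long `data.frame` (`sample_id`, `barcode_id`, `log2_fc`,
#'   `p_value`, `fdr`, `clonal_reads`, `is_hit`) with attributes
#'   `tmm_factors` and `dispersion`.
#' @export
call_enrichment <- function(counts, baseline, config = enrichment_config()) {
  m <- if (inherits(counts, "count_table")) counts$clonal else as.matrix(counts)
  if (length(baseline) < 2) {
    abort_config("at least two baseline replicates are required (triplicate by design)")
  }
  if (!all(baseline %in% colnames(m))) {
    abort_config("baseline sample ids missing from the count table")
  }
  test_samples <- setdiff(colnames(m), baseline)
  if (!length(test_samples)) abort_config("no sorted samples to test")
  fac <- tmm_factors(m, config)
  eff <- colSums(m) * fac
  common <- geometric_mean(eff)
  norm <- sweep(m, 2, common / eff, "*")
  b_norm <- norm[, baseline, drop = FALSE]
  b_int <- round(b_norm)
  disp <- if (identical(config$dispersion, "auto")) {
    estimate_dispersion(b_norm)
  } else {
    config$dispersion
  }
  b_mean <- rowMeans(b_norm)
  out <- vector("list", length(test_samples))
  for (k in seq_along(test_samples)) {
    s <- test_samples[k]
    y <- norm[, s]
    y_int <- round(y)
    p <- vapply(seq_along(y_int), function(i) {
      nb_exact_test(y_int[i], b_int[i, ], disp)
    }, numeric(1))
    lfc <- log2((y + config$pseudocount) / (b_mean + config$pseudocount))
    zero <- y_int == 0 & rowSums(b_int) == 0
    p[zero] <- 1
    lfc[zero] <- 0
    out[[k]] <- data.frame(
      sample_id = s,
      barcode_id = rownames(m),
      log2_fc = lfc,
      p_value = p,
      fdr = adjust_fdr(p),
      clonal_reads = m[, s],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- call_hits(res, config)
  attr(res, "tmm_factors") <- fac
  attr(res, "dispersion") <- disp
  res
}
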