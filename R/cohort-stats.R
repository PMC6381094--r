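#' Construct a 2x2 contingency table
#'
#' Rows are the stratum (risk-allele carrier / non-carrier), columns the
#' recognition status (>= 1 detected population / none).
#'
#' @param a,b Carrier counts: detected / not detected.
#' @param c,d Non-carrier counts: detected / not detected.
#' @return A 2x2 integer matrix with informative dimnames.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(v < 0)) abort_validation("contingency counts must be >= 0")
  if (sum(v) == 0) abort_validation("contingency table must have a positive total")
  matrix(as.integer(v), nrow = 2, byrow = TRUE,
         dimnames = list(c("risk_carrier", "non_carrier"),
                         c("detected", "not_detected")))
}

#' Stratify recognition by NT1-associated HLA class I carriage
#'
#' Per cohort, cross-tabulates donors by whether they carry one of the
#' risk alleles and whether at least one antigen-specific population was
#' detected.
#'
#' @param summary Donor-level table from [profiles_summary()] (needs
#'   `donor_id`, `n_populations`).
#' @param donors Donor table (needs `donor_id`, `cohort`, `hla_class_I`).
#' @param risk_alleles Risk-allele set; defaults to [nt1_risk_alleles()].
#' @return A named list (one per cohort) of 2x2 matrices from
#'   [contingency_2x2()]; degenerate tables (an empty stratum) carry
#'   attribute `degenerate = TRUE`. Donors without HLA data are excluded
#'   with a warning.
#' @export
stratify_by_hla <- function(summary, donors, risk_alleles = nt1_risk_alleles()) {
  m <- merge(summary[, c("donor_id", "n_populations")], donors, by = "donor_id")
  no_hla <- is.na(m$hla_class_I) | m$hla_class_I == ""
  if (any(no_hla)) {
    warning(sprintf("%d donor(s) without HLA data excluded", sum(no_hla)))
    m <- m[!no_hla, , drop = FALSE]
  }
  carrier <- vapply(split_alleles(m$hla_class_I),
                    function(a) any(a %in% risk_alleles), logical(1))
  detected <- m$n_populations >= 1
  out <- lapply(split(seq_len(nrow(m)), m$cohort), function(i) {
    tab <- contingency_2x2(
      sum(carrier[i] & detected[i]), sum(carrier[i] & !detected[i]),
      sum(!carrier[i] & detected[i]), sum(!carrier[i] & !detected[i])
    )
    if (any(rowSums(tab) == 0)) attr(tab, "degenerate") <- TRUE
    tab
  })
  out
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' The standard two-sided definition: with margins fixed, the p-value is the
#' sum of hypergeometric point probabilities of all tables no more probable
#' than the observed one (log-space point probabilities; a relative
#' tolerance of 1e-7 guards against ties lost to rounding, as in common
#' statistical software).
#'
#' @param tab A 2x2 matrix (e.g. from [contingency_2x2()]).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(contingency_2x2(9, 0, 4, 7))  # ~0.00472
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) abort_validation("tab must be 2x2")
  if (any(tab < 0)) abort_validation("counts must be >= 0")
  if (sum(tab) == 0) abort_validation("empty table")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  k <- max(0, c1 - r2):min(r1, c1)
  lp <- dhyper(k, r1, r2, c1, log = TRUE)
  lobs <- dhyper(a, r1, r2, c1, log = TRUE)
  d <- exp(lp)
  min(1, sum(d[lp <= lobs + log(1 + 1e-7)]))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups: exact-distribution p-value when the
#' combined sample size is at most 20 and there are no ties, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) path;
#'   `NULL` selects automatically.
#' @return A list with `U` (for group `a`), `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) abort_config("both groups must be non-empty")
  ties <- any(duplicated(c(a, b)))
  if (is.null(exact)) exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(
    U = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal_approximation"
  )
}

#' One-way ANOVA with Tukey contrasts on log-transformed frequencies
#'
#' Frequencies are log10-transformed (any base yields identical F and p;
#' base 10 matches the display convention), then a one-way ANOVA is fitted
#' and all pairwise contrasts are adjusted by Tukey's honest significant
#' difference with Tukey-Kramer standard errors for unequal group sizes.
#'
#' @param groups Named list of at least three numeric vectors, each of
#'   length >= 2 and strictly positive.
#' @return A list with `F`, `p_value`, `df`, `tukey` (data.frame of pairwise
#'   comparisons: `comparison`, `diff`, `lwr`, `upr`, `p_adj`) and `n`.
#' @export
anova_tukey_log <- function(groups) {
  if (length(groups) < 3) abort_config("at least three groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 2)) abort_config("every group needs at least two values")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  for (g in names(groups)) {
    bad <- which(groups[[g]] <= 0)
    if (length(bad)) {
      abort_validation(sprintf(
        "non-positive frequency in group '%s' (record %d); log transform undefined",
        g, bad[1]
      ))
    }
  }
  d <- data.frame(
    value = log10(unlist(groups, use.names = FALSE)),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  grand <- mean(d$value)
  gm <- tapply(d$value, d$group, mean)
  ssb <- sum(sizes * (gm - grand)^2)
  sst <- sum((d$value - grand)^2)
  if (ssb <= 1e-12 * max(1, sst)) {
    comps <- utils::combn(names(groups), 2)
    return(list(
      F = 0, p_value = 1,
      df = c(between = length(groups) - 1L, within = nrow(d) - length(groups)),
      tukey = data.frame(
        comparison = paste(comps[2, ], comps[1, ], sep = "-"),
        diff = 0, lwr = NA_real_, upr = NA_real_, p_adj = 1,
        stringsAsFactors = FALSE
      ),
      n = sizes
    ))
  }
  fit <- aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(
    F = s[["F value"]][1],
    p_value = s[["Pr(>F)"]][1],
    df = c(between = s[["Df"]][1], within = s[["Df"]][2]),
    tukey = data.frame(
      comparison = rownames(tk),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    n = sizes
  )
}

#' Cohort-level statistical report
#'
#' Reproduces the screening study's cohort inference on a profiled cohort:
#' per-cohort Fisher exact tests of recognition stratified by risk-allele
#' carriage, Mann-Whitney tests of the recognition percentage between
#' carriers and non-carriers within each cohort, and a three-group ANOVA
#' with Tukey contrasts on log-transformed per-population frequencies.
#' DQB1*06:02-negative patients are excluded from the cross-cohort
#' frequency comparison (mirroring their exclusion from patient versus
#' DQ-positive-control contrasts).
#'
#' @param summary Donor-level table from [profiles_summary()].
#' @param populations Long table from [populations_table()].
#' @param donors Donor table.
#' @param risk_alleles Risk-allele set.
#' @param exclude_dq_negative_patients Drop DQB1*06:02-negative NT1 donors
#'   from the frequency ANOVA (default `TRUE`).
#' @return A list with components `fisher` (per cohort: table and p),
#'   `mann_whitney` (per cohort: recognition percentage carrier vs
#'   non-carrier) and `anova` (frequency comparison across cohorts, or a
#'   note when fewer than three cohorts have data).
#' @export
cohort_stats_report <- function(summary, populations, donors,
                                risk_alleles = nt1_risk_alleles(),
                                exclude_dq_negative_patients = TRUE) {
  tabs <- stratify_by_hla(summary, donors, risk_alleles)
  fisher <- lapply(tabs, function(tb) {
    list(table = tb, p_value = fisher_exact_two_sided(tb),
         degenerate = isTRUE(attr(tb, "degenerate")))
  })
  s2 <- summary[, setdiff(names(summary),
                          c("cohort", "hla_class_I", "dqb1_0602")),
                drop = FALSE]
  m <- merge(s2, donors[, c("donor_id", "cohort", "hla_class_I",
                            "dqb1_0602")], by = "donor_id")
  carrier <- vapply(split_alleles(m$hla_class_I),
                    function(a) any(a %in% risk_alleles), logical(1))
  mw <- lapply(split(seq_len(nrow(m)), m$cohort), function(i) {
    x <- m$recognition_pct[i][carrier[i]]
    y <- m$recognition_pct[i][!carrier[i]]
    if (!length(x) || !length(y)) {
      return(list(U = NA_real_, p_value = NA_real_, method = "undefined stratum"))
    }
    mann_whitney(x, y)
  })
  pops <- populations
  if (exclude_dq_negative_patients) {
    dq_neg_patients <- donors$donor_id[donors$cohort == "NT1" & !donors$dqb1_0602]
    pops <- pops[!(pops$donor_id %in% dq_neg_patients), , drop = FALSE]
  }
  groups <- split(pops$frequency_pct, pops$cohort)
  groups <- groups[lengths(groups) >= 2]
  anova_res <- if (length(groups) >= 3) {
    anova_tukey_log(groups)
  } else {
    list(note = "fewer than three cohorts with >= 2 detected populations")
  }
  list(fisher = fisher, mann_whitney = mw, anova = anova_res)
}
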