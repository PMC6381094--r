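test_that("the two published contingency tables give the published Fisher p-values", {
  ## patients: recognition in 9/9 risk-allele carriers vs 4/11 non-carriers
  p_pat <- fisher_exact_two_sided(contingency_2x2(9, 0, 4, 7))
  expect_equal(round(p_pat, 3), 0.005)
  ## DQ-negative controls: 13/15 vs 3/14
  p_neg <- fisher_exact_two_sided(contingency_2x2(13, 2, 3, 11))
  expect_equal(round(p_neg, 4), 0.0007)
  ## full precision against stats::fisher.test as an independent oracle
  expect_equal(p_pat, fisher.test(matrix(c(9, 4, 0, 7), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(p_neg, fisher.test(matrix(c(13, 3, 2, 11), 2))$p.value,
               tolerance = 1e-12)
})

test_that("Fisher p is 1 for symmetric tables and invariant to transposition", {
  expect_equal(fisher_exact_two_sided(contingency_2x2(1, 1, 1, 1)), 1)
  set.seed(4)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 6), 2)
    if (sum(tb) == 0) next
    p <- fisher_exact_two_sided(tb)
    expect_equal(p, fisher_exact_two_sided(t(tb)), tolerance = 1e-12)
    ## simultaneous row and column swap preserves the table's probability
    expect_equal(p, fisher_exact_two_sided(tb[2:1, 2:1]), tolerance = 1e-12)
  }
  expect_error(fisher_exact_two_sided(matrix(0, 2, 2)),
               class = "pmhc_validation_error")
})

test_that("Fisher enumeration matches fisher.test across an exhaustive small sweep", {
  for (total in c(4, 8, 12, 16)) {
    for (a in 0:total) for (b in 0:(total - a)) for (cc in 0:(total - a - b)) {
      d <- total - a - b - cc
      tb <- matrix(c(a, cc, b, d), 2)
      p <- fisher_exact_two_sided(tb)
      expect_equal(p, fisher.test(tb)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("HLA stratification rebuilds the published splits and recounts correctly", {
  ## cohort constructed with a 9/9 vs 4/11 recognition split among patients
  risk <- nt1_risk_alleles()
  donors <- data.frame(
    donor_id = sprintf("NT1_%02d", 1:20),
    cohort = "NT1",
    hla_class_I = c(rep(risk[1], 9), rep("A*02:01", 11)),
    dqb1_0602 = TRUE,
    stringsAsFactors = FALSE
  )
  summary <- data.frame(
    donor_id = donors$donor_id,
    n_populations = c(rep(1, 9), rep(1, 4), rep(0, 7))
  )
  tabs <- stratify_by_hla(summary, donors)
  expect_equal(unname(as.vector(t(tabs$NT1))), c(9, 0, 4, 7))
  expect_equal(round(fisher_exact_two_sided(tabs$NT1), 3), 0.005)
  ## random cohort: cells equal a brute-force recount
  set.seed(6)
  don2 <- simulate_cohort(10, 10, 10, seed = 2)
  summ2 <- data.frame(donor_id = don2$donor_id,
                      n_populations = rpois(30, 1))
  tabs2 <- stratify_by_hla(summ2, don2)
  for (coh in names(tabs2)) {
    sel <- don2$cohort == coh
    carrier <- vapply(split_alleles(don2$hla_class_I),
                      function(a) any(a %in% risk), logical(1))
    det <- summ2$n_populations[match(don2$donor_id, summ2$donor_id)] >= 1
    expect_equal(unname(as.vector(t(tabs2[[coh]]))),
                 c(sum(sel & carrier & det), sum(sel & carrier & !det),
                   sum(sel & !carrier & det), sum(sel & !carrier & !det)))
  }
  ## degenerate stratum flagged
  don3 <- donors[10:20, ]
  summ3 <- summary[10:20, ]
  expect_true(isTRUE(attr(stratify_by_hla(summ3, don3)$NT1, "degenerate")))
})

test_that("Mann-Whitney handles identical groups, separation and matches enumeration", {
  ## identical value sets: U = n^2/2, p = 1 on the approximate path
  mw <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(mw$U, 8)
  expect_equal(mw$p_value, 1)
  expect_equal(mw$method, "normal_approximation")
  ## fully separated 3 vs 3: exact two-sided p = 2/20
  mw2 <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(mw2$method, "exact")
  expect_equal(mw2$p_value, 0.1)
  ## exact path equals a brute-force enumeration over C(10,5) splits
  set.seed(12)
  for (rep in 1:5) {
    pool <- sample(100, 10)  # distinct values, no ties
    a <- pool[1:5]; b <- pool[6:10]
    got <- mann_whitney(a, b)
    expect_equal(got$method, "exact")
    r <- rank(c(a, b))
    u_obs <- sum(r[1:5]) - 5 * 6 / 2
    splits <- combn(10, 5)
    u_all <- apply(splits, 2, function(ix) sum(r[ix]) - 15)
    p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    expect_equal(got$p_value, p_oracle, tolerance = 1e-9)
    ## invariance under a monotone transform of the pooled values
    expect_equal(mann_whitney(exp(a / 20), exp(b / 20))$p_value, got$p_value)
  }
  expect_error(mann_whitney(numeric(0), 1:3), class = "pmhc_config_error")
})

test_that("log-scale ANOVA handles degenerate input and matches a sums-of-squares oracle", {
  ## identical values per group with equal means: no between-group signal
  res0 <- anova_tukey_log(list(a = c(5, 5), b = c(5, 5), c = c(5, 5)))
  expect_equal(res0$F, 0)
  expect_equal(res0$p_value, 1)
  ## two groups are rejected; nonpositive values are rejected by name
  expect_error(anova_tukey_log(list(a = 1:3, b = 2:4)),
               class = "pmhc_config_error")
  expect_error(anova_tukey_log(list(a = c(1, 2), b = c(2, 3), c = c(0, 1))),
               class = "pmhc_validation_error")
  ## random 3-group data: F from explicit sums of squares, Tukey p from
  ## the studentized range distribution with Tukey-Kramer standard errors
  set.seed(20)
  for (rep in 1:3) {
    g <- list(x = 10^rnorm(8, -2.3, 0.5), y = 10^rnorm(11, -2.8, 0.5),
              z = 10^rnorm(9, -2.4, 0.5))
    res <- anova_tukey_log(g)
    v <- lapply(g, log10)
    all_v <- unlist(v)
    grand <- mean(all_v)
    ssb <- sum(vapply(v, function(x) length(x) * (mean(x) - grand)^2, 1))
    ssw <- sum(vapply(v, function(x) sum((x - mean(x))^2), 1))
    df1 <- 2; df2 <- length(all_v) - 3
    f_oracle <- (ssb / df1) / (ssw / df2)
    expect_equal(res$F, f_oracle, tolerance = 1e-10)
    expect_equal(res$p_value, pf(f_oracle, df1, df2, lower.tail = FALSE),
                 tolerance = 1e-10)
    mse <- ssw / df2
    for (pair in list(c("y", "x"), c("z", "x"), c("z", "y"))) {
      se <- sqrt(mse / 2 * (1 / length(v[[pair[1]]]) + 1 / length(v[[pair[2]]])))
      q <- abs(mean(v[[pair[1]]]) - mean(v[[pair[2]]])) / se
      p_tk <- ptukey(q, nmeans = 3, df = df2, lower.tail = FALSE)
      got <- res$tukey$p_adj[res$tukey$comparison ==
                               paste(pair[1], pair[2], sep = "-")]
      expect_equal(got, p_tk, tolerance = 1e-6)
    }
  }
})

test_that("synthetic cohorts with dominating patient frequencies flag the prescribed contrast", {
  don <- simulate_cohort(20, 23, 29, seed = 31)
  fr <- simulate_population_frequencies(don, seed = 31)
  ## patients' frequencies stochastically dominate DQ-positive controls'
  expect_gt(median(fr$frequency_pct[fr$cohort == "NT1"]),
            median(fr$frequency_pct[fr$cohort == "DQ0602_pos_control"]))
  res <- anova_tukey_log(split(fr$frequency_pct, fr$cohort))
  p_contrast <- res$tukey$p_adj[res$tukey$comparison ==
                                  "NT1-DQ0602_pos_control"]
  expect_lt(p_contrast, 0.05)
})

test_that("the cohort report wires stratification, rank tests and the ANOVA together", {
  don <- simulate_cohort(8, 8, 8, seed = 17)
  set.seed(17)
  summ <- data.frame(donor_id = don$donor_id,
                     n_populations = rpois(24, 2),
                     recognition_pct = runif(24, 0, 3),
                     sum_frequency = runif(24, 0, 0.1),
                     panel_size = 300)
  fr <- simulate_population_frequencies(don, seed = 18)
  rep <- cohort_stats_report(summ, fr, don)
  expect_setequal(names(rep$fisher),
                  c("NT1", "DQ0602_pos_control", "DQ0602_neg_control"))
  for (f in rep$fisher) {
    expect_true(f$p_value > 0 && f$p_value <= 1)
  }
  ## DQ-negative patients are excluded from the frequency comparison
  dqn <- don$donor_id[don$cohort == "NT1" & !don$dqb1_0602]
  if (length(dqn) && any(fr$donor_id %in% dqn) && !is.null(rep$anova$n)) {
    expect_equal(unname(rep$anova$n["NT1"]),
                 sum(fr$cohort == "NT1" & !fr$donor_id %in% dqn))
  }
})
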