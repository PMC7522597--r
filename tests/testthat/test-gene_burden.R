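test_that("binomial burden p-values match brute-force tail summation", {
  tab <- tiny_prob_table()
  mat <- make_matrix(c("GENE1", "GENE1"), c("S1", "S2"),
                     subject_ids = paste0("S", 1:10))
  # force P_success to a round number: SF = 2 / (10 * 0.004) = 50 ->
  # GENE1 P_success = 0.05; use a direct model instead for the canonical
  # n = 10, p = 0.1, k = 2 example
  model <- compute_scaling_factor(mat, tab)
  res <- gene_binomial_test(model, mat, "GENE1")
  expect_equal(res$p_value,
               oracle_binom_tail(2, 10, res$p_success), tolerance = 1e-12)

  # canonical example: k = 2, n = 10, p = 0.1
  expect_equal(oracle_binom_tail(2, 10, 0.1),
               1 - 0.9^10 - 10 * 0.1 * 0.9^9, tolerance = 1e-12)
  expect_equal(stats::pbinom(1, 10, 0.1, lower.tail = FALSE),
               0.2639011, tolerance = 1e-6)

  # grid agreement with the oracle at 1e-12 relative
  set.seed(91)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    p <- stats::runif(1, 1e-4, 0.3)
    k <- sample(0:n, 1)
    expect_equal(ifelse(k <= 0, 1,
                        stats::pbinom(k - 1, n, p, lower.tail = FALSE)),
                 oracle_binom_tail(k, n, p),
                 tolerance = 1e-12)
  }
})

test_that("zero-carrier genes get p = 1 and unknown genes error", {
  tab <- tiny_prob_table()
  mat <- make_matrix("GENE1", "S1", subject_ids = paste0("S", 1:10))
  model <- compute_scaling_factor(mat, tab)
  expect_equal(gene_binomial_test(model, mat, "GENE3")$p_value, 1)
  expect_error(gene_binomial_test(model, mat, "NOPE"), "universe")
  res <- gene_burden_test(model, mat)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("multiple-test correction follows per-class BH and joint Bonferroni", {
  # single real test among m = 1000 universe genes
  res_t <- data.frame(gene = sprintf("G%04d", 1:1000), class = "truncating",
                      n_success = c(3, rep(0, 999)), n_trials = 100,
                      p_success = 1e-4,
                      p_value = c(1e-6, rep(1, 999)),
                      stringsAsFactors = FALSE)
  corr <- correct_multiple_tests(truncating = res_t)
  expect_equal(corr$truncating$bonferroni[1], 1e-3)
  expect_equal(corr$truncating$bh_fdr[1], 1e-6 * 1000 / 1)

  # BH by hand: (.01, .02, .03) with m = 3 -> all .03
  res3 <- data.frame(gene = c("A", "B", "C"), class = "truncating",
                     n_success = 1, n_trials = 10, p_success = 0.01,
                     p_value = c(.01, .02, .03), stringsAsFactors = FALSE)
  corr3 <- correct_multiple_tests(truncating = res3)
  expect_equal(corr3$truncating$bh_fdr, c(.03, .03, .03))

  # Bonferroni is joint across classes
  res_m <- res3
  res_m$class <- "missense"
  both <- correct_multiple_tests(truncating = res3, missense = res_m)
  expect_equal(both$truncating$bonferroni, pmin(1, res3$p_value * 6))
  # BH separate per class: unchanged by the other class
  expect_equal(both$truncating$bh_fdr, corr3$truncating$bh_fdr)

  # corrected values never fall below the raw p-value
  expect_true(all(both$truncating$bh_fdr >= both$truncating$p_value))
  expect_true(all(both$truncating$bonferroni >= both$truncating$p_value))

  # omission mode drops zero-carrier genes and shrinks m
  corr_o <- correct_multiple_tests(truncating = res_t, unobserved = "omit")
  expect_equal(nrow(corr_o$truncating), 1)
  expect_equal(corr_o$truncating$bonferroni, 1e-6)
})

test_that("BH output is monotone in the input p ordering", {
  set.seed(7)
  p <- sort(stats::runif(50))
  res <- data.frame(gene = sprintf("G%02d", 1:50), class = "truncating",
                    n_success = 1, n_trials = 10, p_success = 0.01,
                    p_value = p, stringsAsFactors = FALSE)
  corr <- correct_multiple_tests(truncating = res)
  expect_true(all(diff(corr$truncating$bh_fdr) >= 0))
})

test_that("fisher exact matches full-table enumeration and the CMLE OR", {
  set.seed(17)
  for (i in 1:20) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:8, 1); d <- sample(0:8, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    oracle <- oracle_fisher(a, b, c_, d)
    expect_equal(fisher_exact(a, b, c_, d, "greater")$p_value,
                 oracle$greater, tolerance = 1e-10)
    expect_equal(fisher_exact(a, b, c_, d, "two_sided")$p_value,
                 oracle$two_sided, tolerance = 1e-8)
  }
  # the reported OR maximizes the conditional likelihood (grid check)
  ft <- fisher_exact(4, 4, 23, 935, "greater")
  psi_hat <- ft$odds_ratio
  ll_hat <- nch_loglik(psi_hat, 4, 4, 23, 935)
  for (psi in psi_hat * c(0.8, 0.9, 1.1, 1.25)) {
    expect_lt(nch_loglik(psi, 4, 4, 23, 935), ll_hat)
  }
  # the conditional MLE differs from the sample OR
  expect_equal(ft$sample_odds_ratio, 4 * 935 / (4 * 23))
  expect_false(isTRUE(all.equal(ft$odds_ratio, ft$sample_odds_ratio)))
  # symmetric table
  sym <- fisher_exact(1, 1, 1, 1, "two_sided")
  expect_equal(sym$p_value, 1)
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)
  expect_error(fisher_exact(0, 0, 0, 0), "all-zero")
})

test_that("singleton comparison restricts its universe and tests two-sided", {
  singles <- structure(data.frame(
    gene = c("A", "B", "C", "D"),
    n_singleton_lof = c(10, 500, 480, 0),
    n_singleton_mis = c(5, 5, 5, 5), stringsAsFactors = FALSE),
    class = c("singleton_table", "data.frame"))
  mat <- make_matrix(rep("A", 5), paste0("S", 1:5),
                     subject_ids = paste0("S", 1:100))
  mat <- gene_subject_matrix(rbind(mat$counts,
                                   data.frame(gene = rep("B", 95),
                                              subject_id = paste0("S", 6:100),
                                              count = 1L)),
                             class = "truncating",
                             subject_ids = paste0("S", 1:100))
  res <- singleton_comparison(mat, singles, "truncating")
  # D lacks a truncating reference singleton: outside the universe
  expect_false("D" %in% res$gene)
  # concentration in A against a diffuse reference: enrichment
  rowA <- res[res$gene == "A", ]
  expect_equal(rowA$a, 5)
  expect_equal(rowA$c, 10)
  expect_gt(rowA$odds_ratio, 1)
  oracle <- oracle_fisher(rowA$a, rowA$b, rowA$c, rowA$d)
  expect_equal(rowA$p_value, oracle$two_sided, tolerance = 1e-8)
  expect_error(singleton_comparison_test(mat, singles, "D", "truncating"),
               "universe")
  ft <- singleton_comparison_test(mat, singles, "A", "truncating")
  expect_equal(ft$p_value, rowA$p_value)
})

test_that("region and residue-class enrichment build the right exact tests", {
  ann <- protein_annotation("NOTCH1", length = 2555,
                            regions = list(extracellular = c(19, 1735),
                                           transmembrane = c(1736, 1756)),
                            residue_classes = list(
                              disulfide_cysteine = c(100, 200, 300, 400)))
  cohort_pos <- c(100, 200, 300, 400, 500, 600, 700, 800)  # all in ECD
  ref_pos <- c(rep(777, 958), rep(2000, 455))
  ft <- region_enrichment(cohort_pos, ref_pos, ann, "extracellular")
  expect_equal(ft$table[1, ], c(8, 0))
  expect_equal(ft$table[2, ], c(958, 455))
  expect_error(region_enrichment(cohort_pos, ref_pos, ann, "kinase"),
               "unknown region")
  expect_error(region_enrichment(numeric(0), ref_pos, ann, "extracellular"),
               "no cohort")
  # matching proportions give OR near 1
  ft_null <- region_enrichment(c(rep(100, 2), 2000),
                               c(rep(100, 20), rep(2000, 10)),
                               ann, "extracellular")
  expect_equal(ft_null$odds_ratio, 1, tolerance = 1e-6)

  # residue class: 4 of 8 cohort vs 23 of 958 reference
  ref_cys <- c(rep(100, 23), rep(777, 935))
  ft2 <- residue_class_enrichment(cohort_pos, ref_cys, ann,
                                  "disulfide_cysteine")
  expect_equal(ft2$table[1, ], c(4, 4))
  expect_equal(ft2$table[2, ], c(23, 935))
  # no in-class variants anywhere: degenerate margin
  expect_error(residue_class_enrichment(c(500, 600), c(777), ann,
                                        "disulfide_cysteine"),
               "degenerate")
  # cohort depleted: one-sided p near 1
  ft3 <- residue_class_enrichment(c(500, 600), ref_cys, ann,
                                  "disulfide_cysteine")
  expect_gt(ft3$p_value, 0.9)
  expect_lt(ft3$odds_ratio, 1)
})

test_that("carrier fractions count distinct subjects once", {
  mt <- make_matrix(c("FLT4", "KDR", "FLT4"), c("S1", "S1", "S2"),
                    subject_ids = paste0("S", 1:10))
  mm <- make_matrix("NOTCH1", "S3", class = "missense",
                    subject_ids = paste0("S", 1:10))
  # S1 carries two listed genes but counts once
  expect_equal(carrier_fraction(mt, c("FLT4", "KDR")), 2 / 10)
  expect_equal(carrier_fraction(list(mt, mm), c("FLT4", "KDR", "NOTCH1")),
               3 / 10)
  expect_equal(carrier_fraction(mt, character(0)), 0)
  expect_equal(carrier_fraction(mt, "FLT4", subjects = c("S1", "S3")), 0.5)
  expect_error(carrier_fraction(mt, "FLT4", subjects = character(0)),
               "empty")
})

test_that("subject-subset matrices support subgroup re-analysis", {
  mt <- make_matrix(c("FLT4", "FLT4", "KDR"), c("S1", "S2", "S3"),
                    subject_ids = paste0("S", 1:10))
  sub <- subset_matrix(mt, c("S1", "S3", "S4"))
  expect_equal(sub$n_subjects, 3)
  expect_equal(unname(gene_counts(sub)["FLT4"]), 1L)
  expect_error(subset_matrix(mt, "S99"), "unknown subject")
})
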