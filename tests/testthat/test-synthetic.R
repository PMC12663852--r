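test_that("activity-score mixture has exact composition and is reproducible", {
  cfg <- cohort_config(n_samples = 100, mix_high = 0.3, n_genes = 10,
                       signature_size = 2, coupling_rho = NA, n_cells = 0,
                       seed = 7)
  a <- simulate_activity_scores(cfg)
  expect_equal(sum(a$true_labels == "high"), 30L)
  expect_equal(sum(a$true_labels == "low"), 70L)
  b <- simulate_activity_scores(cfg)
  expect_identical(a, b)

  big <- cohort_config(n_samples = 2000, mu_low = 0, mu_high = 3, sigma = 1,
                       n_genes = 10, signature_size = 2, coupling_rho = NA,
                       n_cells = 0, seed = 1)
  ab <- simulate_activity_scores(big)
  expect_lt(abs(mean(ab$scores[ab$true_labels == "high"]) - 3), 0.1)

  expect_error(cohort_config(n_samples = 3), "at least 4")
  expect_error(cohort_config(mu_low = 2, mu_high = 1), "exceed")
})

test_that("null expression has calibrated per-gene type-I error", {
  cfg <- cohort_config(n_samples = 200, n_genes = 220, signature_size = 200,
                       senescence_d = 0, coupling_rho = NA, n_cells = 0,
                       seed = 9)
  a <- simulate_activity_scores(cfg)
  expr <- simulate_expression(cfg, a$true_labels)
  lo <- a$true_labels == "low"
  pv <- apply(expr[1:200, ], 1, function(g) welch_t(g[lo], g[!lo])$p)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.05)
})

test_that("planted senescence shift raises signature genes in the low group", {
  cfg <- cohort_config(n_samples = 400, senescence_d = 1.2, n_genes = 150,
                       signature_size = 40, coupling_rho = NA, n_cells = 0,
                       seed = 3)
  a <- simulate_activity_scores(cfg)
  expr <- simulate_expression(cfg, a$true_labels)
  lo <- a$true_labels == "low"
  sig <- attr(expr, "signature_genes")$genes
  higher <- vapply(sig, function(g)
    mean(expr[g, lo]) > mean(expr[g, !lo]), TRUE)
  expect_gte(mean(higher), 0.95)
  # background genes carry no shift
  bg <- setdiff(rownames(expr), sig)[1:40]
  d_bg <- vapply(bg, function(g)
    welch_t(expr[g, lo], expr[g, !lo])$cohens_d, 0)
  expect_lt(abs(mean(d_bg)), 0.15)
  expect_identical(expr, simulate_expression(cfg, a$true_labels))
  expect_error(cohort_config(n_genes = 10, signature_size = 11), "exceed")
})

test_that("activity-senescence coupling is calibrated to the target", {
  cfg <- cohort_config(n_samples = 600, n_cells = 0, seed = 21)
  co <- simulate_cohort(cfg)
  sen <- ssgsea_score(co$expression, co$signature_genes)
  rho <- spearman_corr(co$scores,
                       setNames(sen$score, sen$id)[names(co$scores)])$rho
  expect_lt(abs(rho - (-0.57)), 0.08)
})

test_that("clinical covariates realize the configured odds ratios", {
  # OR = 1: mean sample OR across seeds near 1
  ors <- vapply(1:25, function(s) {
    cfg <- cohort_config(n_samples = 500, n_genes = 10, signature_size = 2,
                         coupling_rho = NA, n_cells = 0,
                         clinical_or = c(sex_female = 1), seed = s)
    a <- simulate_activity_scores(cfg)
    cl <- simulate_clinical(cfg, a$true_labels)
    lo <- a$true_labels == "low"
    f <- cl$sex == "female"
    (sum(lo & f) * sum(!lo & !f)) / (sum(lo & !f) * sum(!lo & f))
  }, 0)
  expect_lt(abs(mean(ors) - 1), 0.15)

  # OR = 2 at large n: sample OR inside a binomial tolerance band
  cfg2 <- cohort_config(n_samples = 5000, n_genes = 10, signature_size = 2,
                        coupling_rho = NA, n_cells = 0,
                        clinical_or = c(sex_female = 2), seed = 11)
  a2 <- simulate_activity_scores(cfg2)
  cl2 <- simulate_clinical(cfg2, a2$true_labels)
  lo <- a2$true_labels == "low"; f <- cl2$sex == "female"
  or2 <- (sum(lo & f) * sum(!lo & !f)) / (sum(lo & !f) * sum(!lo & f))
  expect_gte(or2, 1.6); expect_lte(or2, 2.5)
  expect_identical(cl2, simulate_clinical(cfg2, a2$true_labels))
  expect_error(cohort_config(clinical_or = c(bad = -2)), "positive")
  expect_true(all(cl2$age >= 18 & cl2$age <= 85))
})

test_that("genomic features carry the planted group differences", {
  cfg <- cohort_config(n_samples = 500, tmb_mean_low = 5, tmb_mean_high = 15,
                       n_genes = 10, signature_size = 2, coupling_rho = NA,
                       n_cells = 0, seed = 2)
  a <- simulate_activity_scores(cfg)
  g <- simulate_genomic_features(cfg, a$true_labels)
  lo <- a$true_labels == "low"
  hl <- median(outer(g$tmb[!lo], g$tmb[lo], "-"))
  expect_gt(hl, 0)
  expect_identical(g, simulate_genomic_features(cfg, a$true_labels))
  expect_true(all(g$cna_fraction > 0 & g$cna_fraction < 1))
  expect_true(all(g$tl_ratio > 0))

  # equal means: the rank-sum test is calibrated, not anti-conservative
  pv <- vapply(1:20, function(s) {
    cfg0 <- null_config(s, n_samples = 200)
    a0 <- simulate_activity_scores(cfg0)
    g0 <- simulate_genomic_features(cfg0, a0$true_labels)
    l0 <- a0$true_labels == "low"
    wilcoxon_rank_sum(g0$tmb[!l0], g0$tmb[l0])$p
  }, 0)
  expect_gte(mean(pv > 0.001), 0.95)
})

test_that("single-cell block has exact cycling composition and program shifts", {
  cfg <- cohort_config(n_cells = 1000, frac_cycling = 0.4, n_genes = 300,
                       signature_size = 50, seed = 5)
  sc <- simulate_single_cells(cfg)
  expect_equal(sum(sc$cycling), 400L)
  counts <- as.matrix(sc$counts)
  sig <- startsWith(rownames(counts), "SEN")
  act <- startsWith(rownames(counts), "TEL")
  expect_gt(mean(counts[sig, !sc$cycling]), mean(counts[sig, sc$cycling]))
  expect_gt(mean(counts[act, sc$cycling]), mean(counts[act, !sc$cycling]))
  sc2 <- simulate_single_cells(cfg)
  expect_identical(as.matrix(sc2$counts), counts)

  expect_error(simulate_single_cells(cohort_config(n_cells = 5, seed = 1)),
               "at least 10")
  expect_error(cohort_config(n_cells = 100, frac_cycling = 1.2), "0, 1")
})

test_that("full cohort bundle is internally consistent", {
  co <- simulate_cohort(cohort_config(n_samples = 60, n_genes = 50,
                                      signature_size = 10, n_cells = 20,
                                      seed = 13))
  expect_identical(names(co$scores), co$clinical$sample_id)
  expect_identical(names(co$scores), co$genomic$sample_id)
  expect_identical(colnames(co$expression), names(co$scores))
  expect_equal(sum(co$true_labels == "high"), round(0.43 * 60))
  expect_s3_class(co$signature_genes, "gene_set")
})
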