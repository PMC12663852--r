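test_that("exact 2x2 test handles independence, extremes, and zero margins", {
  r <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)

  r2 <- fisher_exact_2x2(c(10, 0, 0, 10))
  expect_equal(r2$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(r2$haldane)
  expect_equal(r2$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))

  r3 <- fisher_exact_2x2(c(0, 0, 3, 4))  # zero row margin
  expect_equal(r3$p, 1)
  expect_true(is.na(r3$odds_ratio))

  expect_error(fisher_exact_2x2(c(1, -1, 2, 2)), "non-negative")
})

test_that("exact 2x2 p matches full enumeration and fisher.test on small tables", {
  r <- fisher_exact_2x2(c(3, 1, 1, 3))
  expect_equal(r$p, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(r$odds_ratio, 9)

  set.seed(31)
  for (i in 1:40) {
    v <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    if ((v[1] + v[2]) == 0 || (v[3] + v[4]) == 0 ||
        (v[1] + v[3]) == 0 || (v[2] + v[4]) == 0) next
    r <- fisher_exact_2x2(v)
    expect_equal(r$p, oracle_fisher_p(v[1], v[2], v[3], v[4]),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(v, 2, byrow = TRUE))
    expect_equal(r$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("Welch t returns the textbook statistic and conventional d", {
  x <- c(2, 3, 4); y <- c(1, 2, 3)
  w <- welch_t(x, y)
  expect_equal(w$cohens_d, 1)

  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p, 1)
  expect_equal(same$cohens_d, 0)

  const <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p, 1)
  expect_equal(const$t, 0)

  set.seed(32)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30, 0.5)
    w <- welch_t(a, b)
    o <- oracle_welch(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p, o$p, tolerance = 1e-10)
  }
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("rank-sum test: exact p and Hodges-Lehmann by brute force", {
  x <- c(4, 5, 6); y <- c(1, 2, 3)
  w <- wilcoxon_rank_sum(x, y)
  expect_equal(sort(as.vector(outer(x, y, "-"))),
               c(1, 2, 2, 3, 3, 3, 4, 4, 5))
  expect_equal(w$hodges_lehmann, 3)
  expect_true(w$exact)
  expect_equal(w$p, 0.1, tolerance = 1e-12)
  expect_equal(w$p, oracle_wilcoxon_exact_p(x, y), tolerance = 1e-12)

  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$hodges_lehmann, 0)

  set.seed(33)
  for (i in 1:5) {         # tied / large samples use the corrected normal path
    a <- sample(1:8, 20, replace = TRUE)
    b <- sample(2:9, 25, replace = TRUE)
    w <- wilcoxon_rank_sum(a, b)
    expect_false(w$exact)
    expect_equal(w$p,
                 suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))$p.value)
    expect_equal(w$hodges_lehmann, median(outer(a, b, "-")))
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("Spearman rho equals Pearson on constructed average ranks", {
  u <- c(1, 4, 2, 8, 5, 7)
  expect_equal(spearman_corr(u, u^3)$rho, 1)
  expect_equal(spearman_corr(u, -u)$rho, -1)
  expect_equal(spearman_corr(u, u^3)$p, 0)

  set.seed(34)
  for (i in 1:8) {
    a <- sample(1:5, 20, replace = TRUE)   # heavy ties
    b <- sample(1:5, 20, replace = TRUE)
    s <- spearman_corr(a, b)
    expect_equal(s$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  }
  expect_warning(s <- spearman_corr(rep(1, 5), 1:5), "constant")
  expect_true(is.na(s$rho))
  expect_error(spearman_corr(1:3, 1:3), "at least 4")
})

test_that("step-up FDR adjustment matches the hand-computed rule and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_fdr(0.7), 0.7)
  set.seed(35)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))          # monotone in p
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("group-label symmetry: effects flip, p-values stay", {
  set.seed(36)
  x <- rnorm(15); y <- rnorm(20, 1)
  a <- welch_t(x, y); b <- welch_t(y, x)
  expect_equal(a$cohens_d, -b$cohens_d)
  expect_equal(a$p, b$p)
  wa <- wilcoxon_rank_sum(x, y); wb <- wilcoxon_rank_sum(y, x)
  expect_equal(wa$hodges_lehmann, -wb$hodges_lehmann)
  expect_equal(wa$p, wb$p)
  fa <- fisher_exact_2x2(c(8, 3, 2, 9)); fb <- fisher_exact_2x2(c(2, 9, 8, 3))
  expect_equal(fa$odds_ratio, 1 / fb$odds_ratio)
  expect_equal(fa$p, fb$p, tolerance = 1e-12)
})

test_that("feature battery detects planted effects and stays quiet under null", {
  cfg <- cohort_config(n_samples = 300, n_genes = 20, signature_size = 4,
                       coupling_rho = NA, n_cells = 0, seed = 41)
  co <- simulate_cohort(cfg)
  st <- consensus_stratify(co$scores, n_iter = 50, n_init = 5, seed = 42)
  res <- compare_features(co$genomic, st,
                          c(tmb = "wilcoxon", cna_fraction = "welch_t"))
  tmb <- res[res$feature_id == "tmb", ]
  expect_lt(tmb$q, 0.05)
  expect_identical(tmb$direction, "high_enriched")

  # constant feature: no evidence, no direction
  const <- data.frame(sample_id = st$sample_ids, flat = 1.5)
  rc <- compare_features(const, st, c(flat = "welch_t"))
  expect_equal(rc$p, 1)
  expect_equal(rc$q, 1)
  expect_identical(rc$direction, "none")

  # null features rarely yield BH discoveries
  set.seed(43)
  nulls <- as.data.frame(matrix(rnorm(300 * 50), 300, 50))
  names(nulls) <- paste0("f", 1:50)
  nulls$sample_id <- st$sample_ids
  plan <- setNames(rep("welch_t", 50), paste0("f", 1:50))
  rn <- compare_features(nulls, st, plan)
  expect_lte(sum(rn$q < 0.05), 2L)
  expect_true(all(rn$q >= rn$p - 1e-15))

  expect_error(compare_features(const, st, c(flat = "anova")), "unknown test")
  miss <- data.frame(sample_id = st$sample_ids, gone = NA_real_)
  expect_warning(rm <- compare_features(miss, st, c(gone = "welch_t")),
                 "all-missing")
  expect_equal(nrow(rm), 0L)
})
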