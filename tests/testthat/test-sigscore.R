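test_that("running-sum enrichment depends only on the sample's own column", {
  set.seed(1)
  expr <- rand_expr(30, 1)
  expr <- cbind(expr, expr[, 1, drop = FALSE], expr[, 1, drop = FALSE])
  colnames(expr) <- c("a", "b", "c")
  gs <- gene_set("sig", rownames(expr)[c(2, 5, 9)])
  sc <- ssgsea_score(expr, gs)
  expect_equal(sc$score[1], sc$score[2])
  expect_equal(sc$score[1], sc$score[3])
})

test_that("running-sum enrichment is invariant to monotone transforms and row order", {
  set.seed(2)
  expr <- rand_expr(40, 4)
  gs <- gene_set("sig", rownames(expr)[c(1, 7, 13, 20)])
  base <- ssgsea_score(expr, gs)
  expect_equal(ssgsea_score(exp(expr / 3), gs)$score, base$score)
  perm <- sample(nrow(expr))
  expect_equal(ssgsea_score(expr[perm, ], gs)$score, base$score)
})

test_that("running-sum enrichment matches the double-loop oracle", {
  set.seed(3)
  for (i in 1:12) {
    G <- sample(30:60, 1)
    expr <- rand_expr(G, sample(3:10, 1))
    k <- sample(4:10, 1)
    gs <- gene_set("sig", sample(rownames(expr), k))
    sc <- ssgsea_score(expr, gs, alpha = 0.25)
    exp_scores <- vapply(seq_len(ncol(expr)), function(j)
      oracle_ssgsea_col(expr[, j], rownames(expr), gs$genes, 0.25), 0)
    expect_lt(max(abs(sc$score - exp_scores)), 1e-9)
  }
})

test_that("gene-set overlap rules: drop with warning, error on none or all", {
  set.seed(4)
  expr <- rand_expr(20, 3)
  expect_warning(sc <- ssgsea_score(expr, gene_set("s", c("g1", "g5", "nope"))),
                 "dropped")
  expect_equal(nrow(sc), 3L)
  expect_error(ssgsea_score(expr, gene_set("s", c("x", "y"))), "no gene")
  expect_error(ssgsea_score(expr, gene_set("s", rownames(expr))),
               "complement")
})

test_that("single-cell composite hits min-max endpoints on a two-cell toy", {
  counts <- matrix(0, 6, 2, dimnames = list(paste0("g", 1:6), c("A", "B")))
  counts[1:2, "A"] <- c(9, 8)       # set genes highest in A
  counts[3:4, "A"] <- c(1, 1)
  counts[3:6, "B"] <- c(5, 4, 3, 2) # B expresses no set gene
  sc <- jasmine_score(counts, gene_set("s", c("g1", "g2")))
  expect_equal(setNames(sc$score, sc$id), c(A = 1, B = 0))
})

test_that("single-cell composite maps identical cells to zero", {
  counts <- matrix(rep(c(3, 0, 1, 2, 0), 4), 5, 4,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  sc <- jasmine_score(counts, gene_set("s", c("g1", "g3")))
  expect_equal(sc$score, rep(0, 4))
})

test_that("single-cell composite matches the brute-force oracle", {
  set.seed(5)
  for (i in 1:10) {
    counts <- matrix(rpois(20 * 5, 0.8), 20, 5,
                     dimnames = list(paste0("g", 1:20), paste0("c", 1:5)))
    if (all(counts == 0)) next
    genes <- sample(rownames(counts), 4)
    sc <- jasmine_score(counts, gene_set("s", genes))
    expect_equal(sc$score, oracle_jasmine(counts, genes), tolerance = 1e-12)
    expect_true(all(sc$score >= 0 & sc$score <= 1))
  }
})

test_that("single-cell composite input validation", {
  counts <- matrix(1, 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  expect_error(jasmine_score(counts, gene_set("s", "g1")), "2 cells")
  zeros <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  expect_error(jasmine_score(zeros, gene_set("s", "g1")), "all-zero")
})

test_that("recovery-curve AUC hits its extremes", {
  set.seed(6)
  G <- 100
  col <- sort(runif(G), decreasing = TRUE)
  expr <- matrix(col, G, 1, dimnames = list(sprintf("g%03d", 1:G), "s1"))
  # the three set genes occupy ranks 1-3 -> perfect recovery
  sc <- aucell_score(expr, gene_set("s", c("g001", "g002", "g003")),
                     top_fraction = 0.05)
  expect_equal(sc$score, 1)
  # no set gene inside the top 5 ranks -> zero
  sc0 <- aucell_score(expr, gene_set("s", c("g050", "g099")),
                      top_fraction = 0.05)
  expect_equal(sc0$score, 0)
})

test_that("recovery-curve AUC matches rank-by-rank enumeration", {
  set.seed(7)
  for (i in 1:10) {
    expr <- rand_expr(40, 3)
    genes <- sample(rownames(expr), 5)
    tf <- sample(c(0.1, 0.2, 0.3), 1)
    sc <- aucell_score(expr, gene_set("s", genes), top_fraction = tf)
    exp_scores <- vapply(seq_len(ncol(expr)), function(j)
      oracle_aucell_col(expr[, j], rownames(expr), genes, tf), 0)
    expect_equal(sc$score, unname(exp_scores), tolerance = 1e-12)
    expect_true(all(sc$score >= 0 & sc$score <= 1))
  }
  expect_error(aucell_score(rand_expr(10, 2), gene_set("s", "g1"),
                            top_fraction = 1.2), "top_fraction")
})

test_that("all engines are invariant to gene-row reordering", {
  set.seed(8)
  expr <- rand_expr(30, 4)
  counts <- matrix(rpois(30 * 4, 1), 30, 4, dimnames = dimnames(expr))
  gs <- gene_set("s", rownames(expr)[c(3, 11, 22)])
  perm <- sample(30)
  expect_equal(ssgsea_score(expr[perm, ], gs)$score,
               ssgsea_score(expr, gs)$score)
  expect_equal(jasmine_score(counts[perm, ], gs)$score,
               jasmine_score(counts, gs)$score)
  expect_equal(aucell_score(expr[perm, ], gs, 0.2)$score,
               aucell_score(expr, gs, 0.2)$score)
})
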