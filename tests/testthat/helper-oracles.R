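# Independent brute-force oracles. Each recomputes the quantity from first
# principles (enumeration, double loops, closed forms) without touching the
# package's code paths.

# Exhaustive 1-D 2-means: evaluate every sorted threshold split.
oracle_best_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  ss <- vapply(seq_len(n - 1L), function(m) {
    lo <- xs[1:m]; hi <- xs[(m + 1):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, 0)
  list(m = which.min(ss), ss = ss,
       unique = sum(abs(ss - min(ss)) < 1e-12) == 1L)
}

# Direct double-loop running-sum enrichment for one expression column.
oracle_ssgsea_col <- function(col, gene_ids, set_genes, alpha) {
  r <- rank(col)
  ord <- order(-r, gene_ids)
  in_set <- gene_ids %in% set_genes
  G <- length(col)
  n_out <- G - sum(in_set)
  denom <- sum(r[in_set]^alpha)
  es <- 0; p_in <- 0; p_out <- 0
  for (i in seq_len(G)) {
    g <- ord[i]
    if (in_set[g]) p_in <- p_in + r[g]^alpha / denom
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# Explicit per-cell rank table and 2x2 tables for the single-cell composite.
oracle_jasmine <- function(counts, set_genes) {
  in_set <- rownames(counts) %in% set_genes
  n_set <- sum(in_set)
  n_non <- nrow(counts) - n_set
  rank_comp <- or_comp <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    expressed <- counts[, j] > 0
    expr_set <- which(expressed & in_set)
    rank_comp[j] <- if (length(expr_set)) {
      r <- rank(counts[expressed, j])
      names(r) <- rownames(counts)[expressed]
      mean(r[rownames(counts)[expr_set]]) / sum(expressed)
    } else 0
    a <- sum(expressed & in_set); b <- n_set - a
    cc <- sum(expressed & !in_set); d <- n_non - cc
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    or_comp[j] <- a * d / (b * cc)
  }
  mm <- function(v) if (diff(range(v)) == 0) rep(0, length(v))
                    else (v - min(v)) / diff(range(v))
  (mm(rank_comp) + mm(or_comp)) / 2
}

# Rank-by-rank recovery-curve enumeration for one column.
oracle_aucell_col <- function(col, gene_ids, set_genes, top_fraction) {
  ord <- order(-rank(col), gene_ids)
  in_set <- gene_ids %in% set_genes
  m <- ceiling(top_fraction * length(col))
  hits <- 0; auc <- 0
  for (i in seq_len(m)) {
    if (in_set[ord[i]]) hits <- hits + 1
    auc <- auc + hits
  }
  k <- min(sum(in_set), m)
  ideal <- sum(pmin(seq_len(m), k))
  auc / ideal
}

# Full hypergeometric enumeration via log-binomials (independent of dhyper).
oracle_fisher_p <- function(a, b, cc, d) {
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc
  support <- max(0, n1 - m2):min(n1, m1)
  logp <- lchoose(m1, support) + lchoose(m2, n1 - support) -
    lchoose(m1 + m2, n1)
  p <- exp(logp)
  p_obs <- exp(lchoose(m1, a) + lchoose(m2, n1 - a) - lchoose(m1 + m2, n1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Textbook Welch formulas.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exact rank-sum p by enumeration of all group assignments (no ties).
oracle_wilcoxon_exact_p <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # Mann-Whitney U
  combs <- utils::combn(length(all_v), nx)
  u_all <- apply(combs, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(u_all - mu) >= abs(w_obs - mu) - 1e-9)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

rand_named <- function(n, gen = rnorm) setNames(gen(n), paste0("s", seq_len(n)))

rand_expr <- function(G, S, gene_prefix = "g") {
  m <- matrix(rnorm(G * S, 5, 2), G, S,
              dimnames = list(paste0(gene_prefix, seq_len(G)),
                              paste0("smp", seq_len(S))))
  m
}

null_config <- function(seed, n_samples = 150L) {
  cohort_config(n_samples = n_samples, mu_low = 0, mu_high = 0.5, sigma = 1,
                n_genes = 300L, signature_size = 50L, senescence_d = 0,
                coupling_rho = NA,
                tmb_mean_low = 8, tmb_mean_high = 8,
                cna_mean_low = 0.2, cna_mean_high = 0.2,
                loh_mean_low = 0.2, loh_mean_high = 0.2,
                tl_median_low = 1, tl_median_high = 1,
                clinical_or = c(sex_female = 1, low_stage = 1),
                n_cells = 0L, seed = seed)
}

# One pass of the null association battery; returns c(discoveries, features).
null_battery <- function(seed) {
  co <- simulate_cohort(null_config(seed))
  st <- consensus_stratify(co$scores, n_iter = 50, n_init = 5, seed = seed + 1L)
  sen <- ssgsea_score(co$expression, co$signature_genes)
  sen_v <- setNames(sen$score, sen$id)
  clin <- data.frame(sample_id = co$clinical$sample_id,
                     sex_female = co$clinical$sex == "female",
                     low_stage = harmonize_stage(co$clinical$stage) == "low-stage",
                     stringsAsFactors = FALSE)
  fam <- list(
    compare_features(clin, st, c(sex_female = "fisher", low_stage = "fisher")),
    compare_features(co$genomic, st,
                     c(tmb = "wilcoxon", cna_fraction = "welch_t",
                       loh_fraction = "welch_t", tl_ratio = "wilcoxon")),
    compare_features(data.frame(sample_id = names(sen_v),
                                senescence = unname(sen_v),
                                sen_vs_act = unname(sen_v)),
                     st, c(senescence = "welch_t", sen_vs_act = "spearman")))
  q <- unlist(lapply(fam, `[[`, "q"))
  c(disc = sum(q < 0.05), total = length(q))
}
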