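#' Configuration for a synthetic tumor cohort
#'
#' Defines the planted statistical structure the downstream analyses assume:
#' a two-component mixture of activity scores, a senescence gene program
#' anti-correlated with the activity group, group-elevated genomic
#' instability (TMB, CNA, LOH, telomere-length ratio), clinical covariates
#' with configurable odds ratios, and cycling/non-cycling single cells with
#' group-dependent program expression. Defaults emulate the study
#' conditions: a 43% high-activity mixture, a 125-gene senescence signature
#' shifted by d = 0.6 toward the low group, an activity–senescence Spearman
#' coupling of -0.57, and clinical odds ratios of 2 (female sex) and 3
#' (low stage) toward the low group.
#'
#' @param n_samples number of samples (at least 4).
#' @param mix_high planted fraction of high-activity samples, in (0, 1).
#' @param mu_low,mu_high activity-score means of the two components
#'   (`mu_high > mu_low`).
#' @param sigma common score standard deviation (> 0).
#' @param n_genes number of genes in the expression matrix.
#' @param signature_size number of planted senescence-signature genes
#'   (`<= n_genes`).
#' @param senescence_d planted standardized group difference on the
#'   signature genes (low minus high).
#' @param coupling_rho target Spearman correlation between activity score
#'   and the senescence program, in \[-1, 1\]; `NA` disables the continuous
#'   coupling term.
#' @param tmb_mean_low,tmb_mean_high group means of the negative-binomial
#'   tumor mutation burden (> 0).
#' @param tmb_dispersion negative-binomial size parameter (> 0).
#' @param cna_mean_low,cna_mean_high group means of the Beta-distributed
#'   copy-number-altered fraction, in (0, 1).
#' @param loh_mean_low,loh_mean_high group means of the Beta-distributed
#'   loss-of-heterozygosity fraction, in (0, 1).
#' @param beta_concentration concentration of the Beta draws (> 0).
#' @param tl_median_low,tl_median_high group medians of the log-normal
#'   tumor-to-normal telomere-length ratio (> 0).
#' @param tl_sdlog log-scale SD of the telomere-length ratio (> 0).
#' @param clinical_or named numeric vector of covariate odds ratios
#'   (association of the covariate level with the low group; `sex_female`
#'   and `low_stage` receive dedicated columns, any other name becomes a
#'   logical covariate).
#' @param covariate_base_rate covariate prevalence in the high group.
#' @param age_range integer range ages are drawn from uniformly.
#' @param n_cells number of single cells (0 disables the single-cell block).
#' @param frac_cycling planted fraction of cycling cells, in (0, 1).
#' @param activity_program_size number of planted activity-program genes in
#'   the single-cell block.
#' @param seed integer root seed; every generator derives a child seed from
#'   it (one stream per generator), so partial runs reproduce.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 400L, mix_high = 0.43,
                          mu_low = 0, mu_high = 1, sigma = 1,
                          n_genes = 1000L, signature_size = 125L,
                          senescence_d = 0.6, coupling_rho = -0.57,
                          tmb_mean_low = 5, tmb_mean_high = 15,
                          tmb_dispersion = 2,
                          cna_mean_low = 0.15, cna_mean_high = 0.30,
                          loh_mean_low = 0.12, loh_mean_high = 0.25,
                          beta_concentration = 30,
                          tl_median_low = 1.1, tl_median_high = 0.9,
                          tl_sdlog = 0.3,
                          clinical_or = c(sex_female = 2, low_stage = 3),
                          covariate_base_rate = 0.5,
                          age_range = c(18L, 85L),
                          n_cells = 600L, frac_cycling = 0.4,
                          activity_program_size = 50L,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_samples < 4L) stop("n_samples must be at least 4")
  if (!(cfg$mix_high > 0 && cfg$mix_high < 1)) stop("mix_high must be in (0, 1)")
  if (cfg$mu_high <= cfg$mu_low) stop("mu_high must exceed mu_low")
  if (cfg$sigma <= 0) stop("sigma must be positive")
  if (cfg$signature_size > cfg$n_genes)
    stop("signature_size cannot exceed n_genes")
  if (cfg$signature_size < 1L) stop("signature_size must be positive")
  if (cfg$tmb_mean_low <= 0 || cfg$tmb_mean_high <= 0 || cfg$tmb_dispersion <= 0)
    stop("TMB means and dispersion must be positive")
  for (f in c("cna_mean_low", "cna_mean_high", "loh_mean_low", "loh_mean_high"))
    if (!(cfg[[f]] > 0 && cfg[[f]] < 1)) stop(f, " must be in (0, 1)")
  if (cfg$beta_concentration <= 0) stop("beta_concentration must be positive")
  if (cfg$tl_median_low <= 0 || cfg$tl_median_high <= 0 || cfg$tl_sdlog <= 0)
    stop("telomere-length parameters must be positive")
  if (length(cfg$clinical_or) && (is.null(names(cfg$clinical_or)) ||
      any(!nzchar(names(cfg$clinical_or)))))
    stop("clinical_or must be a named vector")
  if (any(cfg$clinical_or <= 0)) stop("odds ratios must be positive")
  if (!is.na(cfg$coupling_rho) && abs(cfg$coupling_rho) > 1)
    stop("coupling_rho must be in [-1, 1]")
  if (cfg$n_cells > 0 && !(cfg$frac_cycling > 0 && cfg$frac_cycling < 1))
    stop("frac_cycling must be in (0, 1)")
  cfg$n_samples <- as.integer(cfg$n_samples)
  cfg$n_genes <- as.integer(cfg$n_genes)
  cfg$signature_size <- as.integer(cfg$signature_size)
  cfg$n_cells <- as.integer(cfg$n_cells)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cohort_config")
}

# Child-seed streams, one per generator (documented splitting rule).
.cfg_seeds <- function(config)
  setNames(derive_seeds(config$seed, 5L),
           c("scores", "expression", "clinical", "genomic", "cells"))

.sample_ids <- function(n) sprintf("S%04d", seq_len(n))

.cohort_gene_ids <- function(config) {
  n_sig <- config$signature_size
  n_act <- min(config$activity_program_size,
               max(0L, config$n_genes - n_sig))
  n_bg <- config$n_genes - n_sig - n_act
  c(sprintf("SEN%03d", seq_len(n_sig)),
    if (n_act > 0L) sprintf("TEL%03d", seq_len(n_act)),
    if (n_bg > 0L) sprintf("BG%04d", seq_len(n_bg)))
}

#' Simulate activity scores with planted low/high labels
#'
#' Exactly `round(mix_high * n)` samples are labelled high and drawn
#' `Normal(mu_high, sigma)`; the rest are low, `Normal(mu_low, sigma)`.
#' Which samples are high is itself a seeded draw.
#'
#' @param config a [cohort_config()].
#' @return list with `scores` (named numeric) and `true_labels` (named
#'   factor low/high).
#' @export
simulate_activity_scores <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  ids <- .sample_ids(n)
  n_high <- as.integer(round(config$mix_high * n))
  if (n_high < 1L || n_high > n - 1L)
    stop("mix_high leaves one group empty at this n_samples")
  withr::with_seed(.cfg_seeds(config)[["scores"]], {
    hi_idx <- sample.int(n, n_high)
    labels <- factor(ifelse(seq_len(n) %in% hi_idx, "high", "low"),
                     levels = c("low", "high"))
    scores <- numeric(n)
    scores[labels == "high"] <- rnorm(n_high, config$mu_high, config$sigma)
    scores[labels == "low"] <- rnorm(n - n_high, config$mu_low, config$sigma)
    list(scores = setNames(scores, ids), true_labels = setNames(labels, ids))
  })
}

#' Simulate a gene-by-sample expression matrix with a planted senescence
#' program
#'
#' Background genes are i.i.d. normal across groups (truncated at zero;
#' per-gene baselines and SDs are themselves drawn). Each of the
#' `signature_size` signature genes receives a mean shift of
#' `+senescence_d * (per-gene SD)` in low-labelled samples, plus a shared
#' continuous latent term anti-correlated with the activity score within
#' groups. The latent weight is calibrated by a one-dimensional root search:
#' first against a cheap proxy (the Spearman correlation between `scores`
#' and the realized mean of the standardized signature block), then refined
#' by a few secant steps against the Spearman correlation with the actual
#' single-sample enrichment score, so the planted `coupling_rho` is hit on
#' the scale downstream analyses measure. With `scores = NULL` or
#' `coupling_rho = NA` the latent term is dropped.
#'
#' @param config a [cohort_config()].
#' @param true_labels factor of low/high labels (length `n_samples`).
#' @param scores optional activity scores used to calibrate the continuous
#'   senescence–activity coupling.
#' @return matrix `n_genes x n_samples` with attributes
#'   `signature_genes` (a [gene_set()]) and `latent_weight`.
#' @export
simulate_expression <- function(config, true_labels, scores = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  if (length(true_labels) != n) stop("true_labels must have length n_samples")
  if (config$signature_size > config$n_genes)
    stop("signature_size cannot exceed n_genes")
  ids <- names(true_labels) %||% .sample_ids(n)
  gene_ids <- .cohort_gene_ids(config)
  n_sig <- config$signature_size
  is_low <- true_labels == "low"

  withr::with_seed(.cfg_seeds(config)[["expression"]], {
    mu_g <- runif(config$n_genes, 4, 8)
    sd_g <- runif(config$n_genes, 0.5, 1.5)
    noise <- matrix(rnorm(config$n_genes * n), config$n_genes, n)

    # Continuous latent coupling: c_i is the (negated) standardized
    # within-group residual of the activity score, so it adds
    # activity-senescence anti-correlation without moving group means.
    w <- 0
    if (!is.null(scores) && !is.na(config$coupling_rho) && n_sig > 0L) {
      resid <- scores - ave(scores, true_labels)
      s_within <- sd(resid)
      if (s_within > 0) {
        c_lat <- -resid / s_within
        ebar <- colMeans(noise[seq_len(n_sig), , drop = FALSE])
        shift0 <- config$senescence_d * as.numeric(is_low)
        f <- function(wc)
          spearman_corr(scores, shift0 + wc * c_lat + ebar)$rho -
            config$coupling_rho
        solve_in <- function(fn, lower, upper)
          tryCatch(uniroot(fn, c(lower, upper), tol = 1e-4)$root,
                   error = function(e) {
                     warning("coupling target unreachable; using boundary weight")
                     if (fn(upper) > 0) upper else lower
                   })
        w <- if (f(0) > 0) solve_in(f, 0, 10)
             else if (f(0) < 0) solve_in(f, -10, 0) else 0

        # Refine against the enrichment score actually measured downstream:
        # the proxy slightly attenuates the rank correlation, so take a few
        # secant steps on the ssGSEA-scale residual (deterministic).
        if (config$senescence_d != 0 || config$coupling_rho != 0) {
          build <- function(wc) {
            e <- mu_g + sd_g * noise
            sh <- shift0 + wc * c_lat
            e[seq_len(n_sig), ] <- e[seq_len(n_sig), , drop = FALSE] +
              outer(sd_g[seq_len(n_sig)], sh)
            e <- pmax(e, 0)
            dimnames(e) <- list(gene_ids, ids)
            e
          }
          g <- function(wc) {
            ss <- ssgsea_score(build(wc), gene_ids[seq_len(n_sig)])
            spearman_corr(scores, ss$score)$rho - config$coupling_rho
          }
          w0 <- w; w1 <- w + 0.05
          g0 <- g(w0)
          for (it in seq_len(4L)) {
            if (abs(g0) < 0.005) break
            g1 <- g(w1)
            if (g1 == g0) break
            w2 <- w1 - g1 * (w1 - w0) / (g1 - g0)
            w2 <- max(min(w2, 10), -10)
            w0 <- w1; g0 <- g1; w1 <- w2
          }
          w <- if (abs(g0) < 0.005) w0 else w1
        }
      }
    } else {
      c_lat <- numeric(n)
    }
    if (!exists("c_lat", inherits = FALSE)) c_lat <- numeric(n)

    expr <- mu_g + sd_g * noise
    if (n_sig > 0L) {
      shift <- config$senescence_d * as.numeric(is_low) +
        if (w != 0) w * c_lat else 0
      expr[seq_len(n_sig), ] <- expr[seq_len(n_sig), , drop = FALSE] +
        outer(sd_g[seq_len(n_sig)], shift)
    }
    expr <- pmax(expr, 0)
    dimnames(expr) <- list(gene_ids, ids)
    attr(expr, "signature_genes") <-
      gene_set("senescence_signature", gene_ids[seq_len(n_sig)],
               "planted senescence program")
    attr(expr, "latent_weight") <- w
    expr
  })
}

#' Simulate a clinical covariate table
#'
#' Binary covariates are drawn so that the expected 2x2 odds ratio of the
#' covariate level versus the low group equals `clinical_or[covariate]`:
#' the prevalence in the high group is `covariate_base_rate` and the
#' low-group prevalence is obtained by scaling the odds. `sex_female` maps
#' to a `sex` column (female/male), `low_stage` to a `stage` column (the
#' binary low/high-stage draw is expanded to Stage I–IV strings), and any
#' other name to a logical column. Ages are uniform on `age_range`.
#'
#' @inheritParams simulate_expression
#' @return data frame with `sample_id`, `age`, `sex`, `stage`, plus one
#'   logical column per additional covariate.
#' @export
simulate_clinical <- function(config, true_labels) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  if (length(true_labels) != n) stop("true_labels must have length n_samples")
  if (any(config$clinical_or <= 0)) stop("odds ratios must be positive")
  ids <- names(true_labels) %||% .sample_ids(n)
  is_low <- true_labels == "low"
  p_high <- config$covariate_base_rate
  draw_cov <- function(or) {
    odds_low <- or * p_high / (1 - p_high)
    p_low <- odds_low / (1 + odds_low)
    rbinom(n, 1L, ifelse(is_low, p_low, p_high)) == 1L
  }
  withr::with_seed(.cfg_seeds(config)[["clinical"]], {
    out <- data.frame(
      sample_id = ids,
      age = sample(seq(config$age_range[1], config$age_range[2]), n,
                   replace = TRUE),
      stringsAsFactors = FALSE)
    ors <- config$clinical_or
    out$sex <- if ("sex_female" %in% names(ors)) {
      ifelse(draw_cov(ors[["sex_female"]]), "female", "male")
    } else sample(c("female", "male"), n, replace = TRUE)
    low_stage <- if ("low_stage" %in% names(ors)) {
      draw_cov(ors[["low_stage"]])
    } else rbinom(n, 1L, 0.5) == 1L
    out$stage <- ifelse(low_stage,
                        sample(c("Stage I", "Stage II"), n, replace = TRUE),
                        sample(c("Stage III", "Stage IV"), n, replace = TRUE))
    for (cov in setdiff(names(ors), c("sex_female", "low_stage")))
      out[[cov]] <- draw_cov(ors[[cov]])
    out
  })
}

#' Simulate genomic-instability features
#'
#' TMB is negative binomial with group-dependent mean; CNA and LOH fractions
#' are Beta with group-dependent means; the tumor-to-normal telomere-length
#' ratio is log-normal with group-dependent median (longer telomeres in the
#' low-activity group by default).
#'
#' @inheritParams simulate_expression
#' @return data frame with `sample_id`, `tmb`, `cna_fraction`,
#'   `loh_fraction`, `tl_ratio`.
#' @export
simulate_genomic_features <- function(config, true_labels) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  if (length(true_labels) != n) stop("true_labels must have length n_samples")
  ids <- names(true_labels) %||% .sample_ids(n)
  is_low <- true_labels == "low"
  conc <- config$beta_concentration
  withr::with_seed(.cfg_seeds(config)[["genomic"]], {
    tmb_mu <- ifelse(is_low, config$tmb_mean_low, config$tmb_mean_high)
    cna_mu <- ifelse(is_low, config$cna_mean_low, config$cna_mean_high)
    loh_mu <- ifelse(is_low, config$loh_mean_low, config$loh_mean_high)
    tl_med <- ifelse(is_low, config$tl_median_low, config$tl_median_high)
    data.frame(
      sample_id = ids,
      tmb = rnbinom(n, size = config$tmb_dispersion, mu = tmb_mu),
      cna_fraction = rbeta(n, cna_mu * conc, (1 - cna_mu) * conc),
      loh_fraction = rbeta(n, loh_mu * conc, (1 - loh_mu) * conc),
      tl_ratio = rlnorm(n, log(tl_med), config$tl_sdlog),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a single-cell count matrix with cycling labels
#'
#' Exactly `round(frac_cycling * n_cells)` cells are flagged cycling.
#' Counts are Poisson around per-gene baselines; cycling cells express the
#' activity-program genes at a `2^senescence_d` fold elevation and the
#' senescence-signature genes at the reciprocal fold, and non-cycling cells
#' the reverse.
#'
#' @param config a [cohort_config()] with `n_cells >= 10`.
#' @return object of class `single_cell_matrix`: list with `counts` (sparse
#'   genes-x-cells `dgCMatrix`), `gene_ids`, `cell_ids`, `cycling` (logical
#'   per cell).
#' @export
simulate_single_cells <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_cells < 10L) stop("n_cells must be at least 10")
  if (!(config$frac_cycling > 0 && config$frac_cycling < 1))
    stop("frac_cycling must be in (0, 1)")
  gene_ids <- .cohort_gene_ids(config)
  n_sig <- config$signature_size
  is_sig <- startsWith(gene_ids, "SEN")
  is_act <- startsWith(gene_ids, "TEL")
  n_cells <- config$n_cells
  cell_ids <- sprintf("C%05d", seq_len(n_cells))
  n_cyc <- as.integer(round(config$frac_cycling * n_cells))
  withr::with_seed(.cfg_seeds(config)[["cells"]], {
    cycling <- seq_len(n_cells) %in% sample.int(n_cells, n_cyc)
    base <- exp(runif(length(gene_ids), log(0.2), log(2)))
    fold <- 2^config$senescence_d
    lam <- matrix(base, length(gene_ids), n_cells)
    lam[is_act, cycling] <- lam[is_act, cycling] * fold
    lam[is_act, !cycling] <- lam[is_act, !cycling] / fold
    lam[is_sig, cycling] <- lam[is_sig, cycling] / fold
    lam[is_sig, !cycling] <- lam[is_sig, !cycling] * fold
    counts <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam),
                     dimnames = list(gene_ids, cell_ids))
    structure(list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      gene_ids = gene_ids, cell_ids = cell_ids,
      cycling = setNames(cycling, cell_ids)),
      class = "single_cell_matrix")
  })
}

#' Simulate a complete synthetic cohort
#'
#' Chains the per-block generators (each on its own child seed): activity
#' scores with planted labels, expression with the planted senescence
#' program, clinical covariates, genomic-instability features, and (when
#' `n_cells > 0`) single cells.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `scores`,
#'   `true_labels`, `expression`, `signature_genes`, `clinical`, `genomic`,
#'   `cells` (or NULL), `latent_weight`, and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  act <- simulate_activity_scores(config)
  expr <- simulate_expression(config, act$true_labels, scores = act$scores)
  cohort <- list(
    scores = act$scores,
    true_labels = act$true_labels,
    expression = expr,
    signature_genes = attr(expr, "signature_genes"),
    clinical = simulate_clinical(config, act$true_labels),
    genomic = simulate_genomic_features(config, act$true_labels),
    cells = if (config$n_cells >= 10L) simulate_single_cells(config) else NULL,
    latent_weight = attr(expr, "latent_weight"),
    config = config)
  stopifnot(identical(cohort$clinical$sample_id, names(act$scores)),
            identical(cohort$genomic$sample_id, names(act$scores)))
  structure(cohort, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples (%d low / %d high), %d genes\n",
              length(x$scores), sum(x$true_labels == "low"),
              sum(x$true_labels == "high"), nrow(x$expression)))
  if (!is.null(x$cells))
    cat(sprintf("  single cells: %d (%d cycling)\n",
                length(x$cells$cell_ids), sum(x$cells$cycling)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Expression as TSV (gene rows, sample columns), single cells as an MTX
#' triplet with `genes.tsv`/`barcodes.tsv` sidecars plus a `cycling.tsv`
#' label file, clinical and genomic tables as TSV keyed by `sample_id`,
#' activity scores and true labels as TSV, and the signature as a GMT line.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scores_tsv(cohort$scores, file.path(dir, "activity_scores.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$true_labels),
               true_label = as.character(cohort$true_labels)),
    file.path(dir, "true_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$genomic, file.path(dir, "genomic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(list(cohort$signature_genes), file.path(dir, "signature.gmt"))
  if (!is.null(cohort$cells)) {
    write_mtx_dir(cohort$cells, file.path(dir, "cells"))
    utils::write.table(
      data.frame(cell_id = cohort$cells$cell_ids,
                 cycling = unname(cohort$cells$cycling)),
      file.path(dir, "cells", "cycling.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
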