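#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the small-p-values method: the sum of hypergeometric
#' probabilities (margins fixed) of all tables no more probable than the
#' observed one. The odds ratio is the sample cross-product ratio
#' `a*d / (b*c)`, with Haldane's +0.5 added to every cell if (and only if)
#' any cell is zero. A zero row or column margin yields p = 1 and an
#' undefined (NA) odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = covariate levels), or a length-4 vector `c(a, b, c, d)` read
#'   row-wise.
#' @return list with `p` (two-sided), `odds_ratio`, and `haldane` (logical,
#'   whether the correction was applied).
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.matrix(tab)) {
    if (!all(dim(tab) == 2L)) stop("table must be 2x2")
    v <- as.vector(t(tab))
  } else {
    if (length(tab) != 4L) stop("need 4 counts (a, b, c, d)")
    v <- as.numeric(tab)
  }
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  if (a + b + cc + d < 1) stop("table total must be at least 1")

  if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
    return(list(p = 1, odds_ratio = NA_real_, haldane = FALSE))

  haldane <- any(v == 0)
  odds_ratio <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else (a * d) / (b * cc)

  m1 <- a + b; m2 <- cc + d; n1 <- a + cc
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- dhyper(support, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(p = p, odds_ratio = odds_ratio, haldane = haldane)
}

#' Welch's two-sample t-test with Cohen's d
#'
#' Welch statistic with Satterthwaite degrees of freedom and two-sided
#' p-value; the effect size is Cohen's d = (mean(x) - mean(y)) / pooled SD,
#' with the pooled SD from the standard (n-1)-weighted formula.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @return list with `t`, `df`, `p`, `cohens_d`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = nx + ny - 2, p = 1, cohens_d = 0))
    stop("zero variance in both groups with unequal means")
  }
  tt <- t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = (mean(x) - mean(y)) / sqrt(sp2))
}

#' Wilcoxon rank-sum test with Hodges–Lehmann shift
#'
#' Rank-sum statistic with average ranks for ties. The p-value is exact (by
#' enumeration over the rank-sum distribution) when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used. The
#' Hodges–Lehmann estimate is the median of all `n_x * n_y` pairwise
#' differences `x_i - y_j`.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `W` (Mann–Whitney statistic), `p` (two-sided),
#'   `hodges_lehmann`, and `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  hl <- median(outer(x, y, "-"))
  list(W = unname(wt$statistic), p = wt$p.value,
       hodges_lehmann = hl, exact = exact)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average-ranked values; the p-value uses
#' the t-distribution approximation on rho with n - 2 degrees of freedom.
#' Constant input yields an undefined (NA) rho with a warning.
#'
#' @param u,v numeric vectors of equal length, at least 4.
#' @return list with `rho` and `p`.
#' @export
spearman_corr <- function(u, v) {
  keep <- complete.cases(u, v)
  u <- u[keep]; v <- v[keep]
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (length(u) < 4L) stop("need at least 4 paired observations")
  if (length(unique(u)) < 2L || length(unique(v)) < 2L) {
    warning("constant input: rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rank(u), rank(v))
  n <- length(u)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p)
}

#' Benjamini–Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped to 1, returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Compare features between low and high groups
#'
#' Runs one mapped test per feature comparing the stratified groups, attaches
#' the test's conventional effect measure, and applies Benjamini–Hochberg FDR
#' within the submitted feature family. Effects are oriented high-minus-low:
#' for `welch_t` the effect is Cohen's d of high vs low, for `wilcoxon` the
#' Hodges–Lehmann shift high vs low, for `fisher` the odds ratio of the
#' positive covariate level in the low vs the high group (so OR > 1 means
#' low-enriched), and for `spearman` rho between the feature and the
#' underlying activity scores. `direction` reports which group the feature
#' is enriched in by the sign of the effect.
#'
#' @param features data frame with a `sample_id` column plus one column per
#'   feature (numeric for welch_t/wilcoxon/spearman; logical, 0/1, or
#'   two-level factor/character for fisher).
#' @param cohort a `stratified_cohort` from [consensus_stratify()].
#' @param test_plan named character vector mapping feature name to one of
#'   `"fisher"`, `"welch_t"`, `"wilcoxon"`, `"spearman"`.
#' @return data frame of class `comparison_result` with columns feature_id,
#'   test, statistic, effect, p, q, n_low, n_high, direction.
#' @export
compare_features <- function(features, cohort, test_plan) {
  stopifnot(inherits(cohort, "stratified_cohort"))
  if (!("sample_id" %in% names(features)))
    stop("features must contain a sample_id column")
  idx <- match(cohort$sample_ids, features$sample_id)
  if (any(is.na(idx)))
    stop("features table is missing samples present in the cohort")
  features <- features[idx, , drop = FALSE]
  bad <- setdiff(names(test_plan), names(features))
  if (length(bad))
    stop("test plan names unknown features: ", paste(bad, collapse = ", "))
  ok_tests <- c("fisher", "welch_t", "wilcoxon", "spearman")
  if (!all(test_plan %in% ok_tests))
    stop("unknown test name(s): ",
         paste(setdiff(test_plan, ok_tests), collapse = ", "))

  is_low <- cohort$group == "low"
  rows <- list()
  for (feat in names(test_plan)) {
    test <- test_plan[[feat]]
    vals <- features[[feat]]
    keep <- !is.na(vals)
    if (!any(keep)) {
      warning("feature '", feat, "' is all-missing; skipped")
      next
    }
    v <- vals[keep]; lo <- is_low[keep]
    n_low <- sum(lo); n_high <- sum(!lo)
    res <- switch(test,
      welch_t = {
        w <- welch_t(v[!lo], v[lo])
        list(statistic = w$t, effect = w$cohens_d, p = w$p)
      },
      wilcoxon = {
        w <- wilcoxon_rank_sum(v[!lo], v[lo])
        list(statistic = w$W, effect = w$hodges_lehmann, p = w$p)
      },
      fisher = {
        pos <- .positive_level(v, feat)
        ft <- fisher_exact_2x2(c(sum(lo & pos), sum(lo & !pos),
                                 sum(!lo & pos), sum(!lo & !pos)))
        # OR > 1: positive level enriched in the low group
        list(statistic = ft$odds_ratio, effect = ft$odds_ratio, p = ft$p)
      },
      spearman = {
        s <- spearman_corr(v, cohort$scores[keep])
        list(statistic = s$rho, effect = s$rho, p = s$p)
      })
    direction <- if (is.na(res$effect)) "none" else if (test == "fisher") {
      if (res$effect > 1) "low_enriched"
      else if (res$effect < 1) "high_enriched" else "none"
    } else {
      if (res$effect > 0) "high_enriched"
      else if (res$effect < 0) "low_enriched" else "none"
    }
    rows[[feat]] <- data.frame(
      feature_id = feat, test = test, statistic = res$statistic,
      effect = res$effect, p = res$p, q = NA_real_,
      n_low = n_low, n_high = n_high, direction = direction,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(), class = c("comparison_result", "data.frame")))
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  class(out) <- c("comparison_result", "data.frame")
  out
}

# Positive level of a binary feature: TRUE for logicals, 1 for 0/1 numerics,
# the last sorted level for two-level factors/characters.
.positive_level <- function(v, feat) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1)))
      stop("feature '", feat, "' is numeric but not 0/1; fisher needs binary")
    return(v == 1)
  }
  lev <- sort(unique(as.character(v)))
  if (length(lev) != 2L)
    stop("feature '", feat, "' must have exactly 2 levels for fisher")
  as.character(v) == lev[2L]
}
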