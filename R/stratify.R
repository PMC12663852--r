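#' Validate an activity-score vector
#'
#' An activity-score vector is a named numeric vector: one finite, unitless
#' enrichment score per sample, with unique sample ids as names. Unnamed
#' vectors are given ids `S1, S2, ...`.
#'
#' @param scores numeric vector of per-sample scores.
#' @param min_n minimum number of samples required (default 4).
#' @return the validated named numeric vector.
#' @export
as_activity_scores <- function(scores, min_n = 4L) {
  if (!is.numeric(scores)) stop("scores must be numeric")
  if (length(scores) < min_n)
    stop("too few samples for stratification: need at least ", min_n)
  if (!all(is.finite(scores))) stop("scores must all be finite")
  if (is.null(names(scores)))
    names(scores) <- paste0("S", seq_along(scores))
  if (anyDuplicated(names(scores))) stop("sample ids must be unique")
  if (length(unique(scores)) < 2L)
    stop("degenerate scores: at least 2 distinct values required")
  scores
}

# Core 1-D k-means dynamics for k = 2 on pre-sorted scores, parameterised by
# the split index m (= number of samples in the lower cluster); works on
# prefix sums so each step is O(log n). Ties at the midpoint go to the lower
# cluster. Alternates Lloyd assignment/update steps with the single-point
# transfer polish until jointly stable; within-SS never increases, so the
# loop terminates (a cap guards exact-tie plateaus).
.lloyd2_from_split <- function(xs, cs, css, m) {
  n <- length(xs)
  repeat {
    steps <- 0L
    repeat {                               # Lloyd until the split is stable
      c_lo <- cs[m] / m
      c_hi <- (cs[n] - cs[m]) / (n - m)
      m2 <- min(max(findInterval((c_lo + c_hi) / 2, xs), 1L), n - 1L)
      if (m2 == m || (steps <- steps + 1L) > 1000L) break
      m <- m2
    }
    mp <- .polish2(cs, css, m)
    if (mp == m) return(m)
    m <- mp
  }
}

# Entry point from a random centroid pair: the first assignment reduces the
# initial centroids to a split index; the rest of the trajectory depends
# only on it.
.lloyd2_sorted <- function(xs, cs, css, c_lo, c_hi) {
  n <- length(xs)
  mid <- (min(c_lo, c_hi) + max(c_lo, c_hi)) / 2
  m <- findInterval(mid, xs)               # scores <= mid -> lower cluster
  if (m == 0L || m == n) {
    # empty cluster: reseed at the point farthest from the other centroid
    other <- cs[n] / n
    m <- if (abs(xs[1L] - other) >= abs(xs[n] - other)) 1L else n - 1L
  }
  .lloyd2_from_split(xs, cs, css, m)
}

.withinss_split <- function(cs, css, m) {
  n <- length(cs)
  ss_lo <- css[m] - cs[m]^2 / m
  ss_hi <- (css[n] - css[m]) - (cs[n] - cs[m])^2 / (n - m)
  ss_lo + ss_hi
}

# Single-point transfer polish (Hartigan-Wong style): after Lloyd converges,
# move boundary points across the split while the within-SS strictly
# improves. Plain Lloyd can stall one sample away from the optimum when two
# splits are near-tied; the transfer stage ends in a local minimum of the
# split-SS curve instead.
.polish2 <- function(cs, css, m) {
  n <- length(cs)
  ss <- .withinss_split(cs, css, m)
  repeat {
    ss_dn <- if (m > 1L) .withinss_split(cs, css, m - 1L) else Inf
    ss_up <- if (m < n - 1L) .withinss_split(cs, css, m + 1L) else Inf
    if (ss_dn < ss && ss_dn <= ss_up) { m <- m - 1L; ss <- ss_dn }
    else if (ss_up < ss) { m <- m + 1L; ss <- ss_up }
    else break
  }
  m
}

#' One-dimensional k-means (Lloyd's algorithm)
#'
#' Lloyd iterations from k distinct initial centroids sampled uniformly
#' without replacement from the observed score values, run until the
#' assignment is unchanged. For k = 2 a Hartigan–Wong style single-point
#' transfer stage then moves boundary points across the split while the
#' within-cluster sum of squares strictly improves, so runs do not stall one
#' sample away from a near-tied optimum. Clusters are returned in ascending
#' centroid order. Points equidistant from two centroids join the lower
#' cluster.
#'
#' @param scores numeric vector (at least `k` distinct values).
#' @param k number of clusters, at least 2. The stratification protocol
#'   uses `k = 2`.
#' @param seed integer seed; the run is deterministic given it.
#' @return list with `cluster` (integer assignment, 1 = lowest centroid),
#'   `centroids` (ascending), and `within_ss` (total within-cluster sum of
#'   squares).
#' @export
kmeans_1d <- function(scores, k = 2L, seed = NULL) {
  x <- as.numeric(scores)
  if (!all(is.finite(x))) stop("scores must be finite")
  if (k < 2L) stop("k must be at least 2")
  ux <- unique(x)
  if (length(ux) < k)
    stop("degenerate input: fewer than k distinct score values")
  run <- function() {
    init <- sort(ux[sample.int(length(ux), k)])
    if (k == 2L) {
      ord <- order(x)
      xs <- x[ord]
      cs <- cumsum(xs)
      css <- cumsum(xs^2)
      m <- .lloyd2_sorted(xs, cs, css, init[1L], init[2L])
      cl <- integer(length(x))
      cl[ord] <- rep(c(1L, 2L), c(m, length(x) - m))
      list(cluster = cl,
           centroids = c(cs[m] / m, (cs[length(x)] - cs[m]) / (length(x) - m)),
           within_ss = .withinss_split(cs, css, m))
    } else {
      .lloyd_general(x, init)
    }
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Plain Lloyd for general k (rarely used; the protocol fixes k = 2).
.lloyd_general <- function(x, centers) {
  k <- length(centers)
  assign_prev <- NULL
  repeat {
    d <- abs(outer(x, centers, "-"))
    cl <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(cl == j)) {         # reseed empty cluster at farthest point
        far <- which.max(apply(d[, -j, drop = FALSE], 1L, min))
        cl[far] <- j
      }
    }
    if (identical(cl, assign_prev)) break
    assign_prev <- cl
    centers <- vapply(seq_len(k), function(j) mean(x[cl == j]), 0)
  }
  ord <- order(centers)
  list(cluster = match(cl, ord), centroids = centers[ord],
       within_ss = sum((x - centers[cl])^2))
}

#' Consensus k-means stratification into low/high groups
#'
#' Runs `n_iter` clustering iterations; each iteration performs `n_init`
#' 1-D k-means (k = 2) runs from random centroid initialisations (pairs of
#' distinct observed values, all drawn from a single child stream of `seed`)
#' and keeps the partition with the smallest within-cluster sum of squares.
#' Within each partition the cluster with the larger centroid is labelled
#' "high"; the final per-sample label is the majority vote over the
#' `n_iter` iteration-level partitions, and the consensus fraction is the
#' share agreeing with it. Exact 50/50 vote ties are labelled "low" and
#' flagged. The defaults (1000 iterations of 50 initialisations, 50,000
#' Lloyd runs in total) mirror the published robustness protocol; because
#' every k = 2 Lloyd trajectory in one dimension is determined by its
#' initial threshold, the runs are evaluated through a memoised convergence
#' map and the full protocol costs milliseconds.
#'
#' @param scores named numeric vector of per-sample activity scores.
#' @param n_iter,n_init iteration and initialisation counts; the total
#'   number of aggregated partitions is their product.
#' @param seed integer root seed.
#' @param method consensus rule: `"majority"` (per-sample majority vote,
#'   default) or `"coassign"` (average-linkage cut of the co-assignment
#'   matrix; identical labelling in practice for 1-D scores).
#' @return an object of class `stratified_cohort`: list with `sample_ids`,
#'   `group` (factor low/high), `consensus_fraction` (in \[0.5, 1\]), `tie`
#'   (logical flag for exact vote ties), `boundary` (midpoint between the
#'   maximal low and minimal high score), `centroids` (low mean, high mean),
#'   `n_runs`, `scores`, and `seed`.
#' @export
consensus_stratify <- function(scores, n_iter = 1000L, n_init = 50L,
                               seed = 1L, method = c("majority", "coassign")) {
  method <- match.arg(method)
  x <- as_activity_scores(scores)
  n_runs <- as.numeric(n_iter) * as.numeric(n_init)
  if (n_runs < 1) stop("n_iter * n_init must be at least 1")
  n_runs <- as.integer(n_runs)

  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  css <- cumsum(xs^2)
  ux <- unique(xs)

  # Every Lloyd run converges to a threshold split of the sorted scores, and
  # the whole trajectory is determined by the initial threshold's split
  # index, so the convergence map F (initial split -> converged split) is
  # memoised once and all runs are table lookups. Each iteration keeps the
  # best-of-n_init split by within-SS and casts one vote; votes[m] =
  # iterations whose best split puts m samples low.
  n_iter <- as.integer(n_iter)
  n_init <- as.integer(n_init)
  ssvec <- vapply(seq_len(n - 1L), function(m) .withinss_split(cs, css, m), 0)
  Fmap <- .lloyd2_convergence_map(xs, cs, css)

  u <- length(ux)
  init_mid <- withr::with_seed(derive_seeds(seed, 1L), {
    i1 <- sample.int(u, n_runs, replace = TRUE)     # unordered distinct pair
    i2 <- sample.int(u - 1L, n_runs, replace = TRUE)
    i2 <- i2 + (i2 >= i1)
    (ux[i1] + ux[i2]) / 2
  })
  res <- Fmap[findInterval(init_mid, xs)]
  dim(res) <- c(n_init, n_iter)
  ssr <- matrix(ssvec[res], n_init, n_iter)
  best <- max.col(-t(ssr), ties.method = "first")   # first minimum per iter
  m_best <- res[cbind(best, seq_len(n_iter))]
  votes <- tabulate(m_best, nbins = n)

  # Sample at sorted rank r is low in iterations with split m >= r.
  votes_low_by_rank <- rev(cumsum(rev(votes)))  # rank r -> #votes for low
  if (method == "majority") {
    low_rank <- votes_low_by_rank * 2L >= n_iter  # ties -> low
  } else {
    low_rank <- .coassign_consensus(votes, n_iter)
  }
  tie_rank <- votes_low_by_rank * 2L == n_iter
  frac_rank <- pmax(votes_low_by_rank, n_iter - votes_low_by_rank) / n_iter

  group <- factor(rep("high", n), levels = c("low", "high"))
  group[ord[low_rank]] <- "low"
  consensus_fraction <- numeric(n)
  consensus_fraction[ord] <- frac_rank
  tie <- logical(n)
  tie[ord] <- tie_rank

  lo <- x[group == "low"]
  hi <- x[group == "high"]
  structure(list(
    sample_ids = names(x),
    group = setNames(group, names(x)),
    consensus_fraction = setNames(consensus_fraction, names(x)),
    tie = setNames(tie, names(x)),
    boundary = (max(lo) + min(hi)) / 2,
    centroids = c(low = mean(lo), high = mean(hi)),
    n_runs = n_runs,
    scores = x,
    seed = as.integer(seed)
  ), class = "stratified_cohort")
}

# Convergence map for k = 2 on sorted scores: F[m0] is the converged split
# index when the first assignment puts m0 samples low.
.lloyd2_convergence_map <- function(xs, cs, css) {
  n <- length(xs)
  vapply(seq_len(n - 1L), function(m0) .lloyd2_from_split(xs, cs, css, m0),
         0L)
}

# Co-assignment consensus: the votes over split indices induce the full
# consensus matrix for sorted samples (two sorted samples r < s co-cluster
# unless the split falls in [r, s-1]); cut its average-linkage tree at k = 2.
.coassign_consensus <- function(votes, n_runs) {
  n <- length(votes)
  cum <- cumsum(votes)                      # runs with split <= m
  co <- matrix(1, n, n)
  for (r in seq_len(n - 1L)) {
    s <- (r + 1L):n
    co[r, s] <- co[s, r] <- 1 - (cum[s - 1L] - c(0, cum)[r]) / n_runs
  }
  cl <- cutree(hclust(as.dist(1 - co), method = "average"), k = 2L)
  cl == cl[1L]                              # lowest-ranked sample defines low
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat("Consensus k-means stratification (k = 2)\n")
  cat(sprintf("  samples: %d  (low %d / high %d)\n", length(x$sample_ids),
              sum(x$group == "low"), sum(x$group == "high")))
  cat(sprintf("  boundary: %.4g   centroids: low %.4g, high %.4g\n",
              x$boundary, x$centroids[["low"]], x$centroids[["high"]]))
  cat(sprintf("  runs: %d   min consensus fraction: %.3f\n",
              x$n_runs, min(x$consensus_fraction)))
  invisible(x)
}

#' Stratify several named score vectors independently
#'
#' Applies [consensus_stratify()] to each vector of a named list (telomerase,
#' senescence, MAPK, ROS, ...), each with its own child seed derived from
#' `seed`. Errors name the offending vector.
#'
#' @param score_table named list of numeric score vectors (or a data frame of
#'   score columns sharing row names).
#' @inheritParams consensus_stratify
#' @return named list of `stratified_cohort` objects.
#' @export
stratify_scores_generic <- function(score_table, n_iter = 1000L,
                                    n_init = 50L, seed = 1L,
                                    method = c("majority", "coassign")) {
  method <- match.arg(method)
  if (is.data.frame(score_table)) {
    ids <- rownames(score_table)
    score_table <- lapply(score_table, function(col) setNames(col, ids))
  }
  if (is.null(names(score_table)) || any(names(score_table) == ""))
    stop("score_table must be a fully named list of score vectors")
  seeds <- derive_seeds(seed, length(score_table))
  out <- vector("list", length(score_table))
  names(out) <- names(score_table)
  for (i in seq_along(score_table)) {
    out[[i]] <- tryCatch(
      consensus_stratify(score_table[[i]], n_iter = n_iter, n_init = n_init,
                         seed = seeds[i], method = method),
      error = function(e) stop("score vector '", names(score_table)[i],
                               "': ", conditionMessage(e), call. = FALSE))
  }
  out
}
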