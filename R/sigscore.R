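#' Construct a gene set
#'
#' @param name set name (e.g. a 125-gene senescence signature).
#' @param genes character vector of unique gene identifiers.
#' @param description optional free-text description (kept for GMT output).
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(genes) || length(genes) == 0L)
    stop("genes must be a non-empty character vector")
  if (anyDuplicated(genes)) stop("gene set contains duplicate gene ids")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a single non-empty string")
  structure(list(name = name, genes = genes, description = description),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

.check_expr <- function(expr) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  if (!all(is.finite(expr))) stop("expression values must be finite")
  expr
}

# Intersect a gene set with matrix rows; absent genes are dropped with a
# warning (never imputed).
.overlap_genes <- function(gs, gene_ids) {
  if (!inherits(gs, "gene_set")) gs <- gene_set("gene_set", as.character(gs))
  hit <- gs$genes %in% gene_ids
  if (!any(hit))
    stop("no gene of set '", gs$name, "' is present in the matrix")
  if (!all(hit))
    warning(sum(!hit), " gene(s) of set '", gs$name,
            "' absent from the matrix; dropped")
  gs$genes[hit]
}

.sig_scores <- function(ids, scores, method, gs_name, params) {
  out <- data.frame(id = ids, score = unname(scores), method = method,
                    gene_set = gs_name, stringsAsFactors = FALSE)
  attr(out, "params") <- params
  class(out) <- c("sig_scores", "data.frame")
  out
}

#' Single-sample gene-set enrichment score (weighted running sum)
#'
#' For each sample, genes are ranked by expression (average ranks on ties;
#' the top-expressed gene carries the largest rank value G). Walking down the
#' list in descending rank order (ties broken by gene id so the score is
#' invariant to row order), the enrichment score is
#' `ES = sum_i [P_in(i) - P_out(i)]`, where `P_in` accumulates in-set genes
#' weighted by `rank^alpha` (normalised by the in-set total) and `P_out` is
#' the uniform ECDF over out-of-set genes. The raw ES is returned with no
#' cross-sample normalisation: each score depends on its own sample only, and
#' downstream use is rank- or group-based.
#'
#' @param expr numeric matrix, genes in rows (row names), samples in columns.
#' @param gs a [gene_set()] (or character vector of gene ids).
#' @param alpha rank-weighting exponent (default 0.25).
#' @return a `sig_scores` data frame (id, score, method, gene_set).
#' @export
ssgsea_score <- function(expr, gs, alpha = 0.25) {
  expr <- .check_expr(expr)
  if (!inherits(gs, "gene_set")) gs <- gene_set("gene_set", as.character(gs))
  genes <- .overlap_genes(gs, rownames(expr))
  G <- nrow(expr)
  if (length(genes) == G)
    stop("gene set covers every gene in the matrix (empty complement)")
  in_set <- rownames(expr) %in% genes
  n_out <- G - sum(in_set)
  gid <- rownames(expr)
  es <- apply(expr, 2L, function(col) {
    r <- rank(col)                            # ascending: top gene has G
    ord <- order(-r, gid)                     # walk down; stable by gene id
    w <- (r^alpha) * in_set
    p_in <- cumsum(w[ord]) / sum(w)
    p_out <- cumsum(!in_set[ord]) / n_out
    sum(p_in - p_out)
  })
  .sig_scores(colnames(expr), es, "ssgsea", gs$name, list(alpha = alpha))
}

#' Single-cell signature score (rank / odds-ratio composite)
#'
#' Per cell: (i) a rank component — the mean rank (ascending, average ties)
#' of the *expressed* (count > 0) set genes among all expressed genes of the
#' cell, divided by the number of expressed genes (cells expressing no set
#' gene get 0); (ii) an enrichment component — the odds ratio of the 2x2
#' table set/non-set by expressed/not-expressed, with Haldane +0.5 applied
#' to all cells of a table containing a zero. Each component is min–max
#' scaled to \[0, 1\] across cells (a degenerate range maps to 0 for all
#' cells), and the score is the arithmetic mean of the two scaled
#' components.
#'
#' @param sc a `single_cell_matrix` (from [simulate_single_cells()] or
#'   [read_mtx_dir()]) or a counts matrix (genes x cells,
#'   dimnames required; sparse `dgCMatrix` accepted).
#' @param gs a [gene_set()] or character vector.
#' @return a `sig_scores` data frame with one score per cell, all in \[0, 1\].
#' @export
jasmine_score <- function(sc, gs) {
  counts <- if (inherits(sc, "single_cell_matrix")) sc$counts else sc
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts need gene row names and cell column names")
  if (ncol(counts) < 2L) stop("at least 2 cells required")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero count matrix")
  genes <- .overlap_genes(gs, rownames(counts))
  gs_name <- if (inherits(gs, "gene_set")) gs$name else "gene_set"
  in_set <- rownames(counts) %in% genes
  n_set <- sum(in_set)
  n_non <- nrow(counts) - n_set

  n_cells <- ncol(counts)
  rank_comp <- numeric(n_cells)
  or_comp <- numeric(n_cells)
  for (j in seq_len(n_cells)) {
    expressed <- counts[, j] > 0
    ne <- sum(expressed)
    es <- expressed & in_set
    rank_comp[j] <- if (any(es) && ne > 0L) {
      r <- rank(counts[expressed, j])
      mean(r[in_set[expressed]]) / ne
    } else 0
    a <- sum(es); b <- n_set - a
    cc <- ne - a; d <- n_non - cc
    if (a == 0L || b == 0L || cc == 0L || d == 0L) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    or_comp[j] <- (a * d) / (b * cc)
  }
  minmax0 <- function(v) {
    rng <- range(v)
    if (rng[2] == rng[1]) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  score <- (minmax0(rank_comp) + minmax0(or_comp)) / 2
  stopifnot(all(score >= 0 & score <= 1))
  .sig_scores(colnames(counts), score, "jasmine", gs_name, list())
}

#' Recovery-curve AUC signature score
#'
#' Per sample (or spot/cell): genes are ordered by descending expression
#' (average ranks on ties, with a stable secondary order by gene id for the
#' top-m cut). Over the top `m = ceiling(top_fraction * G)` ranks, the area
#' under the step curve of cumulative set-gene recovery is computed and
#' normalised by the maximal possible area (all `min(|set|, m)` set genes at
#' the very top), so scores lie in \[0, 1\].
#'
#' @param expr genes-x-samples matrix (bulk, spot, or single-cell counts).
#' @param gs a [gene_set()] or character vector.
#' @param top_fraction fraction of top-ranked genes over which recovery is
#'   scored (default 0.05).
#' @return a `sig_scores` data frame, scores in \[0, 1\].
#' @export
aucell_score <- function(expr, gs, top_fraction = 0.05) {
  if (inherits(expr, "single_cell_matrix")) expr <- as.matrix(expr$counts)
  expr <- .check_expr(expr)
  if (!(top_fraction > 0 && top_fraction < 1))
    stop("top_fraction must be in (0, 1)")
  genes <- .overlap_genes(gs, rownames(expr))
  gs_name <- if (inherits(gs, "gene_set")) gs$name else "gene_set"
  G <- nrow(expr)
  m <- as.integer(ceiling(top_fraction * G))
  if (m < 1L) stop("top_fraction too small: no genes in the top set")
  in_set <- rownames(expr) %in% genes
  k_max <- min(sum(in_set), m)
  max_auc <- sum(pmin(seq_len(m), k_max))
  gid <- rownames(expr)
  score <- apply(expr, 2L, function(col) {
    ord <- order(-rank(col), gid)
    sum(cumsum(in_set[ord[seq_len(m)]])) / max_auc
  })
  stopifnot(all(score >= 0 & score <= 1))
  .sig_scores(colnames(expr), score, "aucell", gs_name,
              list(top_fraction = top_fraction))
}
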