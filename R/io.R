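#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40))
    gene_set(f[1L], unique(f[-(1:2)][nzchar(f[-(1:2)])]), f[2L])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(gs) {
    stopifnot(inherits(gs, "gene_set"))
    paste(c(gs$name, if (nzchar(gs$description)) gs$description else "na",
            gs$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Genes in rows (first column), samples in columns (header row).
#'
#' @param path TSV path.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  .check_expr(m)
}

#' Write a gene-by-sample expression matrix to TSV
#'
#' @param expr numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample scores from a two-column or multi-column TSV
#'
#' @param path TSV with a `sample_id` column; either a single `score`
#'   column or one column per score type.
#' @param column optional score column name (defaults to the second column).
#' @return named numeric vector.
#' @export
read_scores_tsv <- function(path, column = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("scores TSV needs a sample_id column")
  column <- column %||% setdiff(names(df), "sample_id")[1L]
  if (!column %in% names(df)) stop("no column '", column, "' in scores TSV")
  setNames(as.numeric(df[[column]]), df$sample_id)
}

#' Write per-sample scores to TSV
#'
#' @param scores named numeric vector.
#' @param path output path.
#' @param column score column name.
#' @export
write_scores_tsv <- function(scores, path, column = "score") {
  df <- data.frame(sample_id = names(scores), score = unname(scores),
                   stringsAsFactors = FALSE)
  names(df)[2L] <- column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-cell matrix from an MTX triplet directory
#'
#' Expects `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, and optionally
#' `cycling.tsv` (cell_id, cycling).
#'
#' @param dir directory path.
#' @return object of class `single_cell_matrix`.
#' @export
read_mtx_dir <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts))
    stop("sidecar files do not match matrix dimensions")
  dimnames(counts) <- list(genes, barcodes)
  cyc_path <- file.path(dir, "cycling.tsv")
  cycling <- if (file.exists(cyc_path)) {
    cdf <- utils::read.delim(cyc_path, stringsAsFactors = FALSE)
    setNames(as.logical(cdf$cycling), cdf$cell_id)[barcodes]
  } else NULL
  structure(list(counts = counts, gene_ids = genes, cell_ids = barcodes,
                 cycling = cycling),
            class = "single_cell_matrix")
}

#' Write a single-cell matrix as an MTX triplet directory
#'
#' @param sc a `single_cell_matrix`.
#' @param dir output directory (created if needed).
#' @export
write_mtx_dir <- function(sc, dir) {
  stopifnot(inherits(sc, "single_cell_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sc$counts, file.path(dir, "matrix.mtx"))
  writeLines(sc$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(sc$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a comparison-result table to TSV
#'
#' @param results a `comparison_result` data frame.
#' @param path output path.
#' @export
write_comparison_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
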