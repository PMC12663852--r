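#' Cohort grouping rules
#'
#' Age schemes, minimum group sizes, and the tumor-stage binarisation used
#' when building comparison cohorts. The `clinical` scheme splits young
#' adults (YA, 18–50 years inclusive) from older adults (OA, > 50); the
#' `aya` scheme splits adolescents and young adults (AYA, 15–39 inclusive)
#' from older adults (> 39). Stages I–II map to low-stage and III–IV to
#' high-stage.
#'
#' @param age_scheme `"clinical"` or `"aya"`.
#' @param min_group_n minimum samples per group for a comparison (default 15).
#' @param min_cohort_n minimum cohort size (default 50).
#' @return list of class `grouping_rules`.
#' @export
grouping_rules <- function(age_scheme = c("clinical", "aya"),
                           min_group_n = 15L, min_cohort_n = 50L) {
  age_scheme <- match.arg(age_scheme)
  if (min_group_n <= 0L || min_cohort_n <= 0L)
    stop("size thresholds must be positive")
  structure(list(age_scheme = age_scheme,
                 min_group_n = as.integer(min_group_n),
                 min_cohort_n = as.integer(min_cohort_n)),
            class = "grouping_rules")
}

#' Recurrence rules for mutations and fusions
#'
#' A mutated gene is recurrent when mutated in at least `min_cancer_types`
#' cancer types (default 2, "two or more"); a fusion is kept for a cancer
#' type when present in strictly more than `min_sample_fraction` of its
#' samples (default 0.01, a strict "> 1 %" cut).
#'
#' @param min_cancer_types integer threshold for recurrent mutations.
#' @param min_sample_fraction strict fraction threshold for fusions, in (0, 1).
#' @param top_n_genes number of top frequently mutated genes examined per
#'   cancer type (default 20; informational).
#' @return list of class `recurrence_rules`.
#' @export
recurrence_rules <- function(min_cancer_types = 2L,
                             min_sample_fraction = 0.01,
                             top_n_genes = 20L) {
  if (!(min_sample_fraction > 0 && min_sample_fraction < 1))
    stop("min_sample_fraction must be in (0, 1)")
  if (min_cancer_types < 1L) stop("min_cancer_types must be positive")
  structure(list(min_cancer_types = as.integer(min_cancer_types),
                 min_sample_fraction = min_sample_fraction,
                 top_n_genes = as.integer(top_n_genes)),
            class = "recurrence_rules")
}

#' Assign age-group labels
#'
#' Clinical scheme: 18 <= age <= 50 is YA, age > 50 is OA; AYA scheme:
#' 15 <= age <= 39 is AYA, age > 39 is OA. Ages below the lower bound are
#' labelled `excluded` rather than dropped, so the partition is exhaustive.
#'
#' @param ages numeric ages in years, non-negative.
#' @param scheme `"clinical"` or `"aya"`.
#' @return factor with levels YA/OA/excluded (clinical) or
#'   AYA/OA/excluded (aya); names preserved.
#' @export
assign_age_groups <- function(ages, scheme = c("clinical", "aya")) {
  scheme <- match.arg(scheme)
  if (any(ages < 0, na.rm = TRUE)) stop("ages must be non-negative")
  if (scheme == "clinical") {
    lab <- ifelse(is.na(ages), NA,
                  ifelse(ages < 18, "excluded", ifelse(ages <= 50, "YA", "OA")))
    lev <- c("YA", "OA", "excluded")
  } else {
    lab <- ifelse(is.na(ages), NA,
                  ifelse(ages < 15, "excluded", ifelse(ages <= 39, "AYA", "OA")))
    lev <- c("AYA", "OA", "excluded")
  }
  out <- factor(lab, levels = lev)
  names(out) <- names(ages)
  out
}

#' Harmonise tumor-stage strings
#'
#' Normalises common dialects ("Stage IIa", "stage iv", "III B") by
#' upper-casing, stripping a leading "STAGE" token and any sub-stage suffix,
#' then maps I/II to low-stage and III/IV to high-stage. Unparsable values
#' (including NA) become `unknown`; nothing is dropped.
#'
#' @param stage_strings character vector of stage annotations.
#' @return factor with levels low-stage / high-stage / unknown.
#' @export
harmonize_stage <- function(stage_strings) {
  s <- toupper(trimws(as.character(stage_strings)))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("^(IV|III|II|I)\\s*[A-C0-9]*$", "\\1", s)
  out <- ifelse(s %in% c("I", "II"), "low-stage",
                ifelse(s %in% c("III", "IV"), "high-stage", "unknown"))
  out[is.na(stage_strings)] <- "unknown"
  factor(out, levels = c("low-stage", "high-stage", "unknown"))
}

#' Partition mutated genes into recurrent and cancer-specific
#'
#' A gene present (mutated) in at least `rules$min_cancer_types` cancer
#' types is recurrent; a gene present in exactly one is cancer-specific.
#' Genes absent everywhere fall in neither list; together with those two
#' lists they exhaust the input rows.
#'
#' @param presence logical (or 0/1) matrix, genes in rows, cancer types in
#'   columns.
#' @param rules a [recurrence_rules()].
#' @return list with character vectors `recurrent` and `cancer_specific`.
#' @export
filter_recurrent_mutations <- function(presence, rules = recurrence_rules()) {
  if (length(presence) == 0L || nrow(presence) == 0L)
    return(list(recurrent = character(0), cancer_specific = character(0)))
  pm <- matrix(as.logical(presence), nrow(presence), ncol(presence),
               dimnames = dimnames(presence))
  n_types <- rowSums(pm)
  list(recurrent = rownames(pm)[n_types >= rules$min_cancer_types],
       cancer_specific = rownames(pm)[n_types == 1L &
                                        rules$min_cancer_types > 1L])
}

#' Keep fusions above the per-cancer recurrence fraction
#'
#' A fusion is kept for a cancer type iff `count / cohort_n` is strictly
#' greater than `rules$min_sample_fraction`.
#'
#' @param fusion_counts integer matrix, fusions in rows, cancer types in
#'   columns.
#' @param cohort_sizes named integer vector of per-cancer cohort sizes
#'   (names matching the columns).
#' @param rules a [recurrence_rules()].
#' @return named list (one element per cancer type) of kept fusion names.
#' @export
filter_frequent_fusions <- function(fusion_counts, cohort_sizes,
                                    rules = recurrence_rules()) {
  if (is.null(colnames(fusion_counts)))
    stop("fusion_counts needs cancer-type column names")
  if (!all(colnames(fusion_counts) %in% names(cohort_sizes)))
    stop("cohort_sizes missing for some cancer types")
  sizes <- cohort_sizes[colnames(fusion_counts)]
  if (any(sizes == 0)) stop("cohort size of zero")
  if (any(sweep(fusion_counts, 2L, sizes) > 0))
    stop("fusion counts exceed cohort sizes")
  out <- lapply(seq_len(ncol(fusion_counts)), function(j) {
    frac <- fusion_counts[, j] / sizes[j]
    rownames(fusion_counts)[frac > rules$min_sample_fraction]
  })
  names(out) <- colnames(fusion_counts)
  out
}

#' Cross-tabulate multi-axis low/high states
#'
#' Counts every observed combination of per-sample states over the given
#' stratifications (telomerase, senescence, MAPK, ROS, ...) plus optional
#' named boolean flags (e.g. an inflammatory immune-subtype indicator).
#' This is the tabulation behind a Sankey-style state-flow summary.
#'
#' @param stratifications named list of `stratified_cohort` objects sharing
#'   the same sample ids.
#' @param flags optional named list of logical vectors (named by sample id
#'   or aligned to the same ids).
#' @return list of class `state_crosstab` with `axes` and `counts` (a data
#'   frame of state combinations and an `n` column summing to the cohort
#'   size).
#' @export
cross_tabulate_states <- function(stratifications, flags = NULL) {
  if (is.null(names(stratifications)) || any(!nzchar(names(stratifications))))
    stop("stratifications must be a named list")
  ids <- stratifications[[1L]]$sample_ids
  states <- lapply(stratifications, function(s) {
    stopifnot(inherits(s, "stratified_cohort"))
    if (!identical(sort(s$sample_ids), sort(ids)))
      stop("mismatched sample ids across stratifications")
    as.character(s$group[ids])
  })
  if (!is.null(flags)) {
    if (is.null(names(flags)) || any(!nzchar(names(flags))))
      stop("flags must be named")
    for (f in names(flags)) {
      v <- flags[[f]]
      v <- if (!is.null(names(v))) {
        if (!all(ids %in% names(v))) stop("mismatched sample ids in flag '", f, "'")
        v[ids]
      } else {
        if (length(v) != length(ids)) stop("flag '", f, "' has wrong length")
        v
      }
      states[[f]] <- as.character(v)
    }
  }
  df <- as.data.frame(states, stringsAsFactors = FALSE)
  counts <- as.data.frame(table(df), stringsAsFactors = FALSE)
  names(counts)[ncol(counts)] <- "n"
  counts <- counts[counts$n > 0, , drop = FALSE]
  rownames(counts) <- NULL
  stopifnot(sum(counts$n) == length(ids))
  structure(list(axes = names(states), counts = counts),
            class = "state_crosstab")
}

#' @export
print.state_crosstab <- function(x, ...) {
  cat("State cross-tabulation over axes:",
      paste(x$axes, collapse = " x "), "\n")
  print(x$counts)
  invisible(x)
}
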