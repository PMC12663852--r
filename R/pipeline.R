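#' Default end-to-end pipeline configuration
#'
#' A single list (serialisable to JSON) naming either a simulation block or
#' input file paths, the stratification run counts, the scoring engine, the
#' grouping rules, and the root seed. The bundled default simulates a
#' 400-sample cohort (seed 42) and uses 1000 aggregated k-means partitions
#' per score vector, a desk-scale reduction of the full 50,000-partition
#' protocol.
#'
#' @param n_samples cohort size of the simulated block.
#' @param seed root seed for the whole run.
#' @param ... overrides for [cohort_config()] fields.
#' @return nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(n_samples = 400L, seed = 42L, ...) {
  structure(list(
    simulate = c(list(n_samples = n_samples), list(...)),
    stratify = list(n_iter = 200L, n_init = 5L),
    score = list(engine = "ssgsea", alpha = 0.25, top_fraction = 0.05),
    rules = list(age_scheme = "clinical", min_group_n = 15L,
                 min_cohort_n = 50L),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full stratification pipeline
#'
#' Chains simulate (or load) -> consensus-stratify activity scores -> score
#' the senescence signature -> stratify the senescence scores -> compare the
#' clinical, genomic, and score feature families between low and high
#' groups (each family BH-corrected on its own) -> cross-tabulate the
#' multi-axis states. When the cohort carries single cells, the senescence
#' signature is additionally scored per cell with the rank/odds-ratio
#' engine and compared between cycling and non-cycling cells. Fully
#' deterministic given the config seed; when `out_dir` is given, all stage
#' tables, a JSON summary and a plain-text log are written there with no
#' timestamps, so repeated runs are byte-identical.
#'
#' @param config a `pipeline_config` (list or JSON path).
#' @param out_dir optional output directory.
#' @return report list of class `pipeline_report` with the cohort,
#'   stratifications, scores, comparison tables, and cross-tabulation.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- as.integer(config$seed %||% 1L)
  seeds <- derive_seeds(seed, 4L)   # cohort, activity strat, pathway strat, spare
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  # --- inputs: simulate or load ------------------------------------------
  cohort <- .stage("simulate", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      scores <- read_scores_tsv(inp$scores_tsv, inp$column %||% NULL)
      expr <- read_expression_tsv(inp$expression_tsv)
      sig <- read_gmt(inp$gmt)[[1L]]
      list(scores = scores, true_labels = NULL, expression = expr,
           signature_genes = sig,
           clinical = utils::read.delim(inp$clinical_tsv,
                                        stringsAsFactors = FALSE),
           genomic = utils::read.delim(inp$genomic_tsv,
                                       stringsAsFactors = FALSE),
           cells = if (!is.null(inp$cells_dir)) read_mtx_dir(inp$cells_dir)
                   else NULL)
    } else {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- seeds[1L]
      simulate_cohort(do.call(cohort_config, sim_args))
    }
  })
  note("cohort: ", length(cohort$scores), " samples, ",
       nrow(cohort$expression), " genes")

  n_iter <- config$stratify$n_iter %||% 1000L
  n_init <- config$stratify$n_init %||% 50L

  # --- stratify activity scores ------------------------------------------
  activity <- .stage("stratify_activity",
    consensus_stratify(cohort$scores, n_iter = n_iter, n_init = n_init,
                       seed = seeds[2L]))
  note("activity stratification: ", sum(activity$group == "low"), " low / ",
       sum(activity$group == "high"), " high; boundary ",
       format(activity$boundary, digits = 4))

  # --- signature scoring --------------------------------------------------
  engine <- config$score$engine %||% "ssgsea"
  sen <- .stage("score_senescence", switch(engine,
    ssgsea = ssgsea_score(cohort$expression, cohort$signature_genes,
                          alpha = config$score$alpha %||% 0.25),
    aucell = aucell_score(cohort$expression, cohort$signature_genes,
                          top_fraction = config$score$top_fraction %||% 0.05),
    stop("unknown bulk scoring engine: ", engine)))
  sen_scores <- setNames(sen$score, sen$id)

  cell_report <- NULL
  if (!is.null(cohort$cells)) {
    cell_scores <- .stage("score_cells",
      jasmine_score(cohort$cells, cohort$signature_genes))
    cell_report <- list(scores = cell_scores)
    if (!is.null(cohort$cells$cycling)) {
      cyc <- cohort$cells$cycling[cell_scores$id]
      wt <- wilcoxon_rank_sum(cell_scores$score[!cyc], cell_scores$score[cyc])
      cell_report$noncycling_vs_cycling <- wt
      note("cells: senescence score non-cycling minus cycling HL = ",
           format(wt$hodges_lehmann, digits = 4), ", p = ",
           format(wt$p, digits = 4))
    }
  }

  # --- stratify pathway scores -------------------------------------------
  pathway <- .stage("stratify_pathways",
    stratify_scores_generic(list(senescence = sen_scores),
                            n_iter = n_iter, n_init = n_init,
                            seed = seeds[3L]))

  # --- association battery ------------------------------------------------
  rules <- do.call(grouping_rules, config$rules %||% list())
  comparisons <- .stage("compare", {
    clin <- cohort$clinical
    clin$age_group <- assign_age_groups(clin$age, rules$age_scheme)
    clin$stage_bin <- harmonize_stage(clin$stage)
    clin_feat <- data.frame(sample_id = clin$sample_id,
                            sex_female = clin$sex == "female",
                            stringsAsFactors = FALSE)
    clin_feat$low_stage <- ifelse(clin$stage_bin == "unknown", NA,
                                  clin$stage_bin == "low-stage")
    ag <- as.character(clin$age_group)
    clin_feat$young <- ifelse(ag == "excluded", NA,
                              ag %in% c("YA", "AYA"))
    extra <- setdiff(names(clin),
                     c("sample_id", "age", "sex", "stage", "age_group",
                       "stage_bin"))
    for (e in extra) clin_feat[[e]] <- clin[[e]]
    clin_plan <- setNames(rep("fisher", ncol(clin_feat) - 1L),
                          setdiff(names(clin_feat), "sample_id"))

    gen_feat <- cohort$genomic
    gen_plan <- c(tmb = "wilcoxon", cna_fraction = "welch_t",
                  loh_fraction = "welch_t", tl_ratio = "wilcoxon")
    gen_plan <- gen_plan[names(gen_plan) %in% names(gen_feat)]

    score_feat <- data.frame(sample_id = names(sen_scores),
                             senescence = unname(sen_scores),
                             senescence_vs_activity = unname(sen_scores),
                             stringsAsFactors = FALSE)
    score_plan <- c(senescence = "welch_t",
                    senescence_vs_activity = "spearman")

    list(clinical = compare_features(clin_feat, activity, clin_plan),
         genomic = compare_features(gen_feat, activity, gen_plan),
         scores = compare_features(score_feat, activity, score_plan))
  })
  for (fam in names(comparisons)) {
    sig <- comparisons[[fam]]
    note("family '", fam, "': ", sum(sig$q < 0.05), " of ", nrow(sig),
         " features at q < 0.05")
  }

  # --- multi-axis cross-tabulation ---------------------------------------
  crosstab <- .stage("cross_tabulate",
    cross_tabulate_states(c(list(telomerase = activity), pathway)))

  report <- structure(list(
    cohort = cohort, activity = activity, senescence_scores = sen,
    pathway = pathway, cells = cell_report, comparisons = comparisons,
    crosstab = crosstab, config = config, seed = seed, log = log
  ), class = "pipeline_report")

  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  act <- report$activity
  utils::write.table(
    data.frame(sample_id = act$sample_ids,
               group = as.character(act$group),
               consensus_fraction = unname(act$consensus_fraction)),
    file.path(out_dir, "groups.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$senescence_scores),
                     file.path(out_dir, "senescence_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (fam in names(report$comparisons))
    write_comparison_tsv(report$comparisons[[fam]],
                         file.path(out_dir, paste0("comparisons_", fam, ".tsv")))
  utils::write.table(report$crosstab$counts,
                     file.path(out_dir, "state_crosstab.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = report$seed,
    n_samples = length(report$cohort$scores),
    n_low = sum(act$group == "low"),
    n_high = sum(act$group == "high"),
    boundary = act$boundary,
    centroids = as.list(act$centroids),
    n_runs = act$n_runs,
    config = unclass(report$config))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("telostrat pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
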