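#' Run configuration for the end-to-end pipeline
#'
#' @param scoring a [scoring_config()].
#' @param panel analysis microRNA panel; must not contain the housekeeper.
#'   Default [ebc_mir_panel()].
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param n_permutations permutations for the topography test. Default 1000.
#' @param n_splits resampling splits for the model comparison. Default 100.
#' @param num_trees random-forest size. Default 500.
#' @param verbose emit progress messages to stderr. Default `TRUE`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scoring = scoring_config(), panel = ebc_mir_panel(),
                       seed = 1L, n_permutations = 1000L, n_splits = 100L,
                       num_trees = 500L, verbose = TRUE) {
  stopifnot(inherits(scoring, "scoring_config"), length(panel) >= 1L)
  panel <- normalize_mir_id(panel)
  if (anyDuplicated(panel)) stop("panel contains duplicate microRNA ids")
  if (any(is_housekeeper_id(panel, scoring$housekeeper_id)))
    stop("the housekeeper must not be part of the analysis panel")
  structure(list(scoring = scoring, panel = panel, seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 n_splits = as.integer(n_splits),
                 num_trees = as.integer(num_trees), verbose = verbose),
            class = "run_config")
}

#' @keywords internal
stage_try <- function(stage, verbose, expr) {
  if (verbose) message(sprintf("[%s] running", stage))
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the pipeline end to end
#'
#' Executes the stages the inputs allow: well scoring into a call matrix
#' (wells + reference-Tm CSVs), the airway-topography permutation tests
#' against EBC (profiles CSV), the panel logistic screen and the
#' clinical-vs-combined random-forest comparison (cohort CSV). Per-stage
#' outputs are written under `out_dir` together with a `MANIFEST` noting
#' completion state and a `report.json` embedding the configuration and
#' seeds. Any stage error is re-raised with a stage label; outputs of
#' completed stages are retained.
#'
#' @param config a [run_config()].
#' @param wells_csv,ref_tm_csv,profiles_csv,cohort_csv input paths (each
#'   optional; `NULL` skips the stage).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the per-stage results and the report.
#' @export
run_pipeline <- function(config = run_config(), wells_csv = NULL,
                         ref_tm_csv = NULL, profiles_csv = NULL,
                         cohort_csv = NULL, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  note <- function(x) manifest <<- c(manifest, x)
  results <- list()
  report <- list(package_version = as.character(utils::packageVersion("ebcmir")),
                 config = list(panel = config$panel, seed = config$seed,
                               n_permutations = config$n_permutations,
                               n_splits = config$n_splits,
                               num_trees = config$num_trees,
                               scoring = unclass(config$scoring)))

  if (!is.null(wells_csv)) {
    results$calls <- stage_try("score", config$verbose, {
      wells <- read_wells(wells_csv)
      if (is.null(ref_tm_csv)) stop("scoring needs a reference-Tm CSV")
      ref <- read_reference_tm(ref_tm_csv)
      calls <- score_wells(wells, ref, config$scoring)
      m <- build_call_matrix(calls, config$panel)
      write_call_matrix(m, file.path(out_dir, "calls.csv"))
      m
    })
    note("score: complete -> calls.csv")
    report$score <- list(n_samples = nrow(results$calls),
                         n_mirs = ncol(results$calls))
  }

  if (!is.null(profiles_csv)) {
    results$topography <- stage_try("topo", config$verbose, {
      set <- read_profiles(profiles_csv)
      others <- setdiff(set$tissues, "EBC")
      tests <- lapply(others, function(t)
        permutation_test(set, "EBC", t,
                         n_permutations = config$n_permutations,
                         seed = config$seed))
      names(tests) <- others
      tab <- data.frame(tissue_pair = paste("EBC", others, sep = "-"),
                        observed_sh = vapply(tests, `[[`, 0L, "observed_sh"),
                        p_value = vapply(tests, `[[`, 0, "p_value"),
                        n_permutations = vapply(tests, `[[`, 0L, "n_permutations"),
                        exhaustive = vapply(tests, `[[`, TRUE, "exhaustive"))
      utils::write.csv(tab, file.path(out_dir, "topography.csv"),
                       row.names = FALSE, na = "NA")
      tests
    })
    note("topo: complete -> topography.csv")
    report$topography <- lapply(results$topography, function(t)
      list(observed_sh = t$observed_sh, p_value = t$p_value))
  }

  if (!is.null(cohort_csv)) {
    cohort <- stage_try("read-cohort", config$verbose,
                        read_cohort(cohort_csv, config$panel))
    results$lr <- stage_try("lr-panel", config$verbose, {
      tab <- run_panel_lr(cohort, config$panel)
      utils::write.csv(tab, file.path(out_dir, "lr_panel.csv"),
                       row.names = FALSE, na = "NA")
      tab
    })
    note("lr-panel: complete -> lr_panel.csv")
    results$comparison <- stage_try("rf-comparison", config$verbose, {
      cmp <- resampled_roc_comparison(cohort, "clinical", "combined",
                                      n_splits = config$n_splits,
                                      seed = config$seed,
                                      num_trees = config$num_trees,
                                      panel = config$panel)
      utils::write.csv(data.frame(split = seq_along(cmp$auc_a),
                                  auc_clinical = cmp$auc_a,
                                  auc_combined = cmp$auc_b),
                       file.path(out_dir, "auc_splits.csv"), row.names = FALSE)
      utils::write.csv(cmp$roc_a, file.path(out_dir, "roc_clinical.csv"),
                       row.names = FALSE)
      utils::write.csv(cmp$roc_b, file.path(out_dir, "roc_combined.csv"),
                       row.names = FALSE)
      cmp
    })
    note("rf-comparison: complete -> auc_splits.csv, roc_*.csv")
    report$lr_panel <- list(n_mirs = nrow(results$lr),
                            n_significant_adjusted =
                              sum(results$lr$p_adj < 0.05, na.rm = TRUE))
    report$comparison <- list(mean_auc_clinical = results$comparison$mean_auc_a,
                              mean_auc_combined = results$comparison$mean_auc_b,
                              auc_difference_pct = results$comparison$auc_difference_pct,
                              welch_p = results$comparison$welch_p)
  }

  writeLines(manifest, file.path(out_dir, "MANIFEST"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$report <- report
  invisible(results)
}
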