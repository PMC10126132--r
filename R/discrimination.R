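#' @keywords internal
clinical_covariates <- function() {
  c("age", "gender", "smoking_status", "pack_years", "quit_years", "uld_group")
}

#' @keywords internal
#' Coerce cohort columns to the fixed factor codings used by every model:
#' reference levels are female, never-smoker, and the none/other underlying
#' lung disease group.
prepare_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("status", clinical_covariates())
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (!all(cohort$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  cohort$status <- factor(cohort$status, levels = c("control", "case"))
  cohort$gender <- factor(cohort$gender, levels = c("female", "male"))
  cohort$smoking_status <- factor(cohort$smoking_status,
                                  levels = c("never", "former", "current"))
  cohort$uld_group <- factor(cohort$uld_group,
                             levels = c("none_other", "risk", "granulomatous_airway"))
  cohort
}

#' @keywords internal
mir_columns <- function(cohort, panel = ebc_mir_panel()) {
  nm <- names(cohort)
  nm[normalize_mir_id(nm) %in% normalize_mir_id(panel)]
}

#' Covariate-adjusted univariate logistic regression for one microRNA
#'
#' Fits case-control status against one binary microRNA call, optionally
#' adjusted for the clinical covariates age, gender, smoking status
#' (never/former/current), pack-years, quit-years and the trichotomous
#' underlying-lung-disease group. Subjects with a missing call for this
#' microRNA are dropped (`n_used` records the remainder). Reports the Wald
#' p-value and log-odds coefficient of the microRNA term. Complete or
#' quasi-complete separation is flagged (`unreliable = TRUE`) rather than
#' silently reported.
#'
#' @param cohort cohort data frame (see [read_cohort()] / [generate_cohort()]).
#' @param mir_id microRNA column to test.
#' @param adjusted include the clinical covariates. Default `TRUE`.
#' @return One-row data frame: `mir_id`, `p`, `coefficient`, `n_used`,
#'   `adjusted`, `unreliable`.
#' @export
fit_univariate_lr <- function(cohort, mir_id, adjusted = TRUE) {
  cohort <- prepare_cohort(cohort)
  col <- mir_columns(cohort, panel = mir_id)
  if (length(col) != 1L) stop(sprintf("microRNA '%s' not found in cohort", mir_id))
  x <- cohort[[col]]
  keep <- !is.na(x)
  d <- cohort[keep, , drop = FALSE]
  d$.mir <- as.numeric(x[keep])
  if (length(unique(d$.mir)) < 2L)
    stop(sprintf("microRNA '%s' has zero variance among usable subjects", mir_id))
  fm <- if (adjusted)
    stats::as.formula(paste("status ~ .mir +", paste(clinical_covariates(), collapse = " + ")))
  else status ~ .mir
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fm, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  beta <- cf[".mir", "Estimate"]
  se <- cf[".mir", "Std. Error"]
  unreliable <- sep || abs(beta) > 15 || se > 15
  data.frame(mir_id = normalize_mir_id(mir_id),
             p = cf[".mir", "Pr(>|z|)"],
             coefficient = beta,
             n_used = nrow(d),
             adjusted = adjusted,
             unreliable = unreliable,
             stringsAsFactors = FALSE)
}

#' Unadjusted and adjusted logistic screen over a microRNA panel
#'
#' Applies [fit_univariate_lr()] to every microRNA in the panel, with and
#' without clinical adjustment, producing the two p-value columns of the
#' standard screen table. The housekeeper (either miR-423 arm) is excluded
#' with a message; a degenerate microRNA (zero variance, absent column)
#' yields an `NA` row with the failure noted in `note`, never an abort of
#' the whole panel.
#'
#' @param cohort cohort data frame.
#' @param panel microRNA ids to screen. Default [ebc_mir_panel()].
#' @return Data frame with one row per microRNA: `mir_id`, `p`, `p_adj`,
#'   `coefficient` (adjusted model log-odds), `n_used`, `unreliable`, `note`.
#' @export
run_panel_lr <- function(cohort, panel = ebc_mir_panel()) {
  hk <- is_housekeeper_id(panel)
  if (any(hk)) {
    message("excluding housekeeper from the analysis panel: ",
            paste(panel[hk], collapse = ", "))
    panel <- panel[!hk]
  }
  empty <- data.frame(mir_id = character(), p = numeric(), p_adj = numeric(),
                      coefficient = numeric(), n_used = integer(),
                      unreliable = logical(), note = character(),
                      stringsAsFactors = FALSE)
  if (length(panel) == 0L) return(empty)
  rows <- lapply(panel, function(m) {
    out <- data.frame(mir_id = normalize_mir_id(m), p = NA_real_,
                      p_adj = NA_real_, coefficient = NA_real_,
                      n_used = NA_integer_, unreliable = NA, note = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      un <- fit_univariate_lr(cohort, m, adjusted = FALSE)
      ad <- fit_univariate_lr(cohort, m, adjusted = TRUE)
      out$p <- un$p; out$p_adj <- ad$p
      out$coefficient <- ad$coefficient
      out$n_used <- ad$n_used
      out$unreliable <- un$unreliable || ad$unreliable
      out
    }, error = function(e) {
      out$note <- conditionMessage(e)
      out
    })
    res
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' @keywords internal
#' Assemble the model matrix columns for a feature set; microRNA calls stay
#' numeric 0/1 (possibly NA, imputed later), clinical factors keep their
#' fixed reference codings.
assemble_features <- function(cohort, feature_set = c("clinical", "mirs", "combined"),
                              panel = ebc_mir_panel()) {
  feature_set <- match.arg(feature_set)
  cohort <- prepare_cohort(cohort)
  mcols <- mir_columns(cohort, panel)
  feats <- switch(feature_set,
                  clinical = cohort[, clinical_covariates(), drop = FALSE],
                  mirs = cohort[, mcols, drop = FALSE],
                  combined = cohort[, c(clinical_covariates(), mcols), drop = FALSE])
  if (feature_set != "clinical" && length(mcols) == 0L)
    stop("cohort carries no panel microRNA columns")
  list(x = feats, y = cohort$status)
}

#' @keywords internal
#' Mode imputation for binary microRNA columns, fitted on the training rows
#' only and applied to both halves (no test-set leakage). Ties and all-NA
#' columns impute to 0 (absent).
impute_mir_na <- function(x_train, x_test, mir_names) {
  for (cn in intersect(mir_names, names(x_train))) {
    tr <- x_train[[cn]]
    if (anyNA(tr) || anyNA(x_test[[cn]])) {
      mode_val <- if (mean(tr, na.rm = TRUE) > 0.5 && !all(is.na(tr))) 1 else 0
      if (is.nan(mode_val)) mode_val <- 0
      x_train[[cn]][is.na(x_train[[cn]])] <- mode_val
      x_test[[cn]][is.na(x_test[[cn]])] <- mode_val
    }
  }
  list(train = x_train, test = x_test)
}

#' @keywords internal
#' Stratified split of row indices: fraction `prop` of each class into the
#' first part.
stratified_split <- function(y, prop = 0.5) {
  parts <- lapply(split(seq_along(y), y), function(idx) {
    k <- floor(length(idx) * prop)
    take <- sample(idx, k)
    list(a = take, b = setdiff(idx, take))
  })
  list(a = sort(unlist(lapply(parts, `[[`, "a"), use.names = FALSE)),
       b = sort(unlist(lapply(parts, `[[`, "b"), use.names = FALSE)))
}

#' @keywords internal
fit_rf <- function(x, y, num_trees, seed) {
  ranger::ranger(x = x, y = y, num.trees = num_trees, probability = TRUE,
                 num.threads = 1L, seed = seed,
                 respect.unordered.factors = "order")
}

#' @keywords internal
rf_case_prob <- function(fit, x) {
  stats::predict(fit, data = x, num.threads = 1L)$predictions[, "case"]
}

#' @keywords internal
roc_auc <- function(y, score) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c("control", "case"),
                                 direction = "<", quiet = TRUE)))
}

#' @keywords internal
confusion_metrics <- function(y, predicted_case) {
  tp <- sum(y == "case" & predicted_case)
  tn <- sum(y == "control" & !predicted_case)
  fp <- sum(y == "control" & predicted_case)
  fn <- sum(y == "case" & !predicted_case)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Repeated two-fold cross-validated random-forest metrics
#'
#' Builds a random-forest case-control classifier on one of three feature
#' sets (clinical covariates, the 24 binary microRNA calls, or their union)
#' and gauges it by stratified two-fold cross-validation repeated
#' `n_repeats` times. Out-of-fold class votes are thresholded at majority
#' (case probability > 0.5); accuracy, sensitivity, specificity, PPV and
#' NPV are averaged over all folds. Missing microRNA calls are mode-imputed
#' on each training fold only.
#'
#' @param cohort cohort data frame.
#' @param feature_set `"clinical"`, `"mirs"` or `"combined"`.
#' @param n_repeats repeats of the 2-fold split. Default 20.
#' @param seed integer seed governing fold assignment and forest randomness.
#' @param num_trees trees per forest. Default 500.
#' @param panel microRNA panel. Default [ebc_mir_panel()].
#' @return Object of class `rf_cv_metrics`: `metrics` (averaged named
#'   vector), `per_fold` (data frame), `feature_set`, `n_repeats`, `seed`.
#' @export
rf_cv_metrics <- function(cohort, feature_set = c("clinical", "mirs", "combined"),
                          n_repeats = 20L, seed = 1L, num_trees = 500L,
                          panel = ebc_mir_panel()) {
  feature_set <- match.arg(feature_set)
  fx <- assemble_features(cohort, feature_set, panel)
  y <- fx$y
  if (any(table(y) < 2L))
    stop("each class needs at least 2 subjects for stratified 2-fold CV")
  mirn <- mir_columns(cohort, panel)
  set.seed(seed)
  fold_rows <- list()
  for (r in seq_len(n_repeats)) {
    sp <- stratified_split(y, 0.5)
    halves <- list(sp$a, sp$b)
    for (h in 1:2) {
      test_idx <- halves[[h]]
      train_idx <- halves[[3 - h]]
      im <- impute_mir_na(fx$x[train_idx, , drop = FALSE],
                          fx$x[test_idx, , drop = FALSE], mirn)
      fit <- fit_rf(im$train, y[train_idx], num_trees,
                    seed = sample.int(.Machine$integer.max, 1L))
      prob <- rf_case_prob(fit, im$test)
      met <- confusion_metrics(y[test_idx], prob > 0.5)
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(repeat_index = r, fold = h, t(met))
    }
  }
  per_fold <- do.call(rbind, fold_rows)
  metrics <- colMeans(per_fold[, c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv")], na.rm = TRUE)
  structure(list(metrics = metrics, per_fold = per_fold,
                 feature_set = feature_set, n_repeats = n_repeats,
                 seed = seed, num_trees = num_trees),
            class = "rf_cv_metrics")
}

#' @export
print.rf_cv_metrics <- function(x, ...) {
  cat(sprintf("Random-forest %s model, stratified 2-fold CV x %d repeats (seed %s)\n",
              x$feature_set, x$n_repeats, x$seed))
  print(round(x$metrics, 3))
  invisible(x)
}

#' Compare two random-forest models by resampled ROC AUC
#'
#' The incremental-discrimination comparison: on each of `n_splits`
#' stratified 50/50 train/test splits, both feature sets' random forests are
#' trained on the identical training half and score the identical testing
#' half; the two per-split ROC AUCs are recorded and the resulting AUC
#' samples compared by a Welch two-independent-sample t-test. The AUC
#' difference is reported in percentage points
#' (`100 * (mean AUC_b - mean AUC_a)`). Repeated-CV confusion metrics for
#' both models (via [rf_cv_metrics()]) are attached.
#'
#' The t-test treats the per-split AUCs as independent samples even though
#' the splits overlap; an optional paired t-test on the per-split AUC
#' differences is also reported (`paired_p`) as a sensitivity check.
#'
#' @param cohort cohort data frame.
#' @param feature_set_a,feature_set_b feature sets to compare; defaults
#'   `"clinical"` vs `"combined"`.
#' @param n_splits number of 50/50 resampling splits. Default 100.
#' @param seed integer seed.
#' @param num_trees trees per forest. Default 500.
#' @param n_cv_repeats repeats for the attached 2-fold CV metrics. Default 20.
#' @param stratified stratify splits by status. Default `TRUE`; with
#'   `FALSE`, a split whose test half lacks a class is redrawn and counted
#'   in `n_redraws`.
#' @param panel microRNA panel. Default [ebc_mir_panel()].
#' @return Object of class `model_comparison` with the AUC vectors, their
#'   means, `auc_difference_pct`, `welch_p`, `paired_p`, both models' CV
#'   metrics, and the final split's ROC coordinates (`roc_a`, `roc_b`).
#' @export
resampled_roc_comparison <- function(cohort,
                                     feature_set_a = "clinical",
                                     feature_set_b = "combined",
                                     n_splits = 100L, seed = 1L,
                                     num_trees = 500L, n_cv_repeats = 20L,
                                     stratified = TRUE,
                                     panel = ebc_mir_panel()) {
  fa <- assemble_features(cohort, feature_set_a, panel)
  fb <- assemble_features(cohort, feature_set_b, panel)
  y <- fa$y
  mirn <- mir_columns(cohort, panel)
  set.seed(seed)
  auc_a <- auc_b <- numeric(n_splits)
  n_redraws <- 0L
  roc_a <- roc_b <- NULL
  for (s in seq_len(n_splits)) {
    repeat {
      sp <- if (stratified) stratified_split(y, 0.5) else {
        a <- sample(seq_along(y), floor(length(y) / 2))
        list(a = sort(a), b = sort(setdiff(seq_along(y), a)))
      }
      if (length(unique(y[sp$b])) == 2L && length(unique(y[sp$a])) == 2L) break
      n_redraws <- n_redraws + 1L
    }
    train <- sp$a; test <- sp$b
    seeds <- sample.int(.Machine$integer.max, 2L)
    ia <- impute_mir_na(fa$x[train, , drop = FALSE], fa$x[test, , drop = FALSE], mirn)
    ib <- impute_mir_na(fb$x[train, , drop = FALSE], fb$x[test, , drop = FALSE], mirn)
    fit_a <- fit_rf(ia$train, y[train], num_trees, seeds[1L])
    fit_b <- fit_rf(ib$train, y[train], num_trees, seeds[2L])
    pa <- rf_case_prob(fit_a, ia$test)
    pb <- rf_case_prob(fit_b, ib$test)
    auc_a[s] <- roc_auc(y[test], pa)
    auc_b[s] <- roc_auc(y[test], pb)
    if (s == n_splits) {
      ra <- pROC::roc(y[test], pa, levels = c("control", "case"),
                      direction = "<", quiet = TRUE)
      rb <- pROC::roc(y[test], pb, levels = c("control", "case"),
                      direction = "<", quiet = TRUE)
      roc_a <- data.frame(fpr = 1 - ra$specificities, tpr = ra$sensitivities)
      roc_b <- data.frame(fpr = 1 - rb$specificities, tpr = rb$sensitivities)
    }
  }
  wt <- stats::t.test(auc_b, auc_a, var.equal = FALSE)
  pt <- stats::t.test(auc_b - auc_a)
  cv_a <- rf_cv_metrics(cohort, feature_set_a, n_repeats = n_cv_repeats,
                        seed = seed, num_trees = num_trees, panel = panel)
  cv_b <- rf_cv_metrics(cohort, feature_set_b, n_repeats = n_cv_repeats,
                        seed = seed + 1L, num_trees = num_trees, panel = panel)
  structure(list(model_a_label = feature_set_a, model_b_label = feature_set_b,
                 auc_a = auc_a, auc_b = auc_b,
                 mean_auc_a = mean(auc_a), mean_auc_b = mean(auc_b),
                 auc_difference_pct = 100 * (mean(auc_b) - mean(auc_a)),
                 welch_p = wt$p.value, welch_statistic = unname(wt$statistic),
                 paired_p = pt$p.value,
                 cv_metrics_a = cv_a$metrics, cv_metrics_b = cv_b$metrics,
                 roc_a = roc_a, roc_b = roc_b,
                 n_splits = n_splits, n_redraws = n_redraws,
                 num_trees = num_trees, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Resampled ROC AUC model comparison\n")
  cat(sprintf("  %s: mean AUC %.3f   %s: mean AUC %.3f  (%d splits, %d trees, seed %s)\n",
              x$model_a_label, x$mean_auc_a, x$model_b_label, x$mean_auc_b,
              x$n_splits, x$num_trees, x$seed))
  cat(sprintf("  AUC difference: %+.2f%%  (Welch p = %.3g; paired p = %.3g)\n",
              x$auc_difference_pct, x$welch_p, x$paired_p))
  cat(sprintf("  CV metrics %s:  %s\n", x$model_a_label,
              paste(sprintf("%s %.2f", names(x$cv_metrics_a), x$cv_metrics_a),
                    collapse = ", ")))
  cat(sprintf("  CV metrics %s:  %s\n", x$model_b_label,
              paste(sprintf("%s %.2f", names(x$cv_metrics_b), x$cv_metrics_b),
                    collapse = ", ")))
  invisible(x)
}

#' @export
#' @importFrom graphics boxplot lines abline legend
plot.model_comparison <- function(x, which = c("auc", "roc"), ...) {
  which <- match.arg(which)
  if (which == "auc") {
    boxplot(list(x$auc_a, x$auc_b), names = c(x$model_a_label, x$model_b_label),
            ylab = "resampled ROC AUC",
            main = sprintf("AUC difference %+.2f%% (Welch p = %.3g)",
                           x$auc_difference_pct, x$welch_p), ...)
  } else {
    plot(x$roc_a$fpr, x$roc_a$tpr, type = "s", xlab = "false positive rate",
         ylab = "true positive rate", main = "ROC (final split)", ...)
    lines(x$roc_b$fpr, x$roc_b$tpr, type = "s", col = 2)
    abline(0, 1, lty = 3)
    legend("bottomright", legend = c(x$model_a_label, x$model_b_label),
           col = c(1, 2), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Clinically defined cohort subgroups
#'
#' Restricts a cohort to the standard analysis subgroups. A smoking filter
#' applies to cases and controls alike; a stage filter applies to cases only
#' (controls carry no stage and are all retained), so an early-stage view of
#' the full cohort keeps stage I/II cases plus every control.
#'
#' @param cohort cohort data frame.
#' @param smoking keep only subjects with these smoking statuses
#'   (subset of `"never"`, `"former"`, `"current"`), or `NULL` for all.
#' @param stages keep only cases with these stages (subset of
#'   `"I","II","III","IV"`), or `NULL` for all; controls always retained.
#' @return The filtered cohort data frame; an empty result is an error.
#' @export
#' @examples
#' sim <- generate_cohort(seed = 1)
#' nrow(subgroup_view(sim$cohort, smoking = "former"))
#' nrow(subgroup_view(sim$cohort, stages = c("I", "II")))
subgroup_view <- function(cohort, smoking = NULL, stages = NULL) {
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(smoking)) {
    smoking <- match.arg(smoking, c("never", "former", "current"),
                         several.ok = TRUE)
    keep <- keep & cohort$smoking_status %in% smoking
  }
  if (!is.null(stages)) {
    stages <- match.arg(stages, c("I", "II", "III", "IV"), several.ok = TRUE)
    keep <- keep & (cohort$status == "control" |
                      (!is.na(cohort$stage) & cohort$stage %in% stages))
  }
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop(sprintf("no subjects match subgroup (smoking = %s, stages = %s)",
                 paste(smoking %||% "any", collapse = "/"),
                 paste(stages %||% "any", collapse = "/")))
  rownames(out) <- NULL
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
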