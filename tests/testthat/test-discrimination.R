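test_that("the Welch comparison matches the closed-form oracle to 1e-10", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(100, 0.8, 0.03)
    y <- rnorm(100, 0.81, 0.05)
    expect_equal(stats::t.test(x, y, var.equal = FALSE)$p.value,
                 oracle_welch_p(x, y), tolerance = 1e-10)
  }
})

test_that("pipeline ROC AUC equals the Mann-Whitney oracle to 1e-12", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    y <- factor(ifelse(rbinom(n, 1, 0.5) == 1, "case", "control"),
                levels = c("control", "case"))
    if (length(unique(y)) < 2) next
    s <- rnorm(n)
    expect_equal(ebcmir:::roc_auc(y, s), oracle_auc(y == "case", s),
                 tolerance = 1e-12)
  }
})

test_that("univariate logistic regression recovers a planted odds ratio and flags degeneracies", {
  cohort <- generate_cohort(seed = 42)$cohort
  for (m in c("miR-21", "miR-33b", "miR-212")) {
    fit <- fit_univariate_lr(cohort, m, adjusted = TRUE)
    expect_lt(fit$p, 0.05)
    expect_gt(fit$coefficient, 0)
    expect_lte(fit$n_used, nrow(cohort))
  }
  # zero-variance microRNA is an error
  cohort[["miR-9"]] <- 1L
  expect_error(fit_univariate_lr(cohort, "miR-9"), "zero variance")
  # perfect separation is flagged, not silently reported
  cohort[["miR-31"]] <- as.integer(cohort$status == "case")
  sep <- fit_univariate_lr(cohort, "miR-31", adjusted = FALSE)
  expect_true(sep$unreliable)
})

test_that("null microRNA p-values are approximately uniform", {
  params <- cohort_sim_params(n_cases = 200, n_controls = 200,
                              mir_odds_ratios = rep(1, 24))
  base <- generate_cohort(params, seed = 7)$cohort
  set.seed(77)
  n_rep <- 600
  pvals <- vapply(seq_len(n_rep), function(i) {
    base[["miR-9"]] <- rbinom(nrow(base), 1, 0.3)
    fit_univariate_lr(base, "miR-9", adjusted = TRUE)$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  half_width <- 2.576 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(frac, 0.05 - half_width)
  expect_lt(frac, 0.05 + half_width)
})

test_that("the panel screen excludes the housekeeper and survives degenerate microRNAs", {
  cohort <- small_cohort(seed = 2)
  expect_identical(nrow(run_panel_lr(cohort, character(0))), 0L)
  expect_message(tab <- run_panel_lr(cohort, c("miR-21", "miR-423-3p", "miR423.5p")),
                 "housekeeper")
  expect_identical(tab$mir_id, "miR-21")
  # a constant microRNA yields a noted NA row, the rest of the panel survives
  cohort[["miR-31"]] <- 1L
  tab2 <- suppressMessages(run_panel_lr(cohort, c("miR-21", "miR-31")))
  expect_identical(nrow(tab2), 2L)
  expect_true(is.na(tab2$p_adj[tab2$mir_id == "miR-31"]))
  expect_match(tab2$note[tab2$mir_id == "miR-31"], "zero variance")
  expect_false(is.na(tab2$p_adj[tab2$mir_id == "miR-21"]))
})

test_that("a single feature equal to the class label classifies perfectly", {
  cohort <- small_cohort(seed = 3)
  cohort[["miR-21"]] <- as.integer(cohort$status == "case")
  cv <- rf_cv_metrics(cohort, "mirs", n_repeats = 3, seed = 1,
                      num_trees = 100, panel = "miR-21")
  expect_gt(cv$metrics[["accuracy"]], 0.98)
  expect_gt(cv$metrics[["sensitivity"]], 0.98)
  expect_gt(cv$metrics[["specificity"]], 0.98)
})

test_that("label-independent features give chance-level accuracy", {
  params <- cohort_sim_params(n_cases = 150, n_controls = 150,
                              age_mean_case = 60, age_mean_control = 60,
                              smoking_probs_case = c(current = .3, former = .4, never = .3),
                              smoking_probs_control = c(current = .3, former = .4, never = .3),
                              pack_years_mean_case = 30, pack_years_mean_control = 30,
                              quit_years_mean_case = 8, quit_years_mean_control = 8,
                              uld_probs_case = c(risk = .5, granulomatous_airway = .1, none_other = .4),
                              uld_probs_control = c(risk = .5, granulomatous_airway = .1, none_other = .4),
                              male_prob_case = .5, male_prob_control = .5,
                              mir_odds_ratios = rep(1, 24))
  accs <- vapply(1:5, function(s) {
    cohort <- generate_cohort(params, seed = 100 + s)$cohort
    rf_cv_metrics(cohort, "combined", n_repeats = 3, seed = s,
                  num_trees = 150)$metrics[["accuracy"]]
  }, numeric(1))
  expect_true(all(accs > 0.38 & accs < 0.62))
})

test_that("confusion metrics satisfy their defining identities", {
  set.seed(15)
  for (i in 1:25) {
    y <- factor(ifelse(rbinom(40, 1, 0.5) == 1, "case", "control"),
                levels = c("control", "case"))
    pred <- rbinom(40, 1, 0.5) == 1
    m <- ebcmir:::confusion_metrics(y, pred)
    tp <- sum(y == "case" & pred);  fn <- sum(y == "case" & !pred)
    tn <- sum(y == "control" & !pred); fp <- sum(y == "control" & pred)
    expect_equal(m[["accuracy"]], (tp + tn) / 40)
    expect_equal(m[["sensitivity"]], tp / (tp + fn))
    expect_equal(m[["specificity"]], tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m[["ppv"]], tp / (tp + fp))
    if (tn + fn > 0) expect_equal(m[["npv"]], tn / (tn + fn))
  }
})

test_that("the resampled comparison is reproducible and honest about identical models", {
  cohort <- small_cohort(seed = 5)
  c1 <- resampled_roc_comparison(cohort, n_splits = 8, seed = 31,
                                 num_trees = 100, n_cv_repeats = 2)
  c2 <- resampled_roc_comparison(cohort, n_splits = 8, seed = 31,
                                 num_trees = 100, n_cv_repeats = 2)
  expect_identical(c1$auc_a, c2$auc_a)
  expect_identical(c1$auc_b, c2$auc_b)
  expect_equal(c1$auc_difference_pct, 100 * (c1$mean_auc_b - c1$mean_auc_a))

  # same feature set on both sides: differences are forest noise only
  diffs <- vapply(1:3, function(s) {
    cc <- resampled_roc_comparison(cohort, "clinical", "clinical",
                                   n_splits = 20, seed = s, num_trees = 200,
                                   n_cv_repeats = 2)
    cc$auc_difference_pct
  }, numeric(1))
  expect_true(all(abs(diffs) < 0.5))
})

test_that("subgroup views filter smokers globally but stages for cases only", {
  cohort <- generate_cohort(seed = 8)$cohort
  fs <- subgroup_view(cohort, smoking = "former")
  expect_true(all(fs$smoking_status == "former"))
  expect_true(all(c("case", "control") %in% fs$status))

  es <- subgroup_view(cohort, stages = c("I", "II"))
  expect_true(all(es$stage[es$status == "case"] %in% c("I", "II")))
  expect_identical(sum(es$status == "control"), sum(cohort$status == "control"))

  cohort2 <- cohort
  cohort2$smoking_status <- "current"
  expect_error(subgroup_view(cohort2, smoking = "never"), "no subjects")
})
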