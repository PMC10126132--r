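# Independent oracles used to cross-check the implementation.
# These are deliberately naive (double loops, closed forms) and share no
# code with the package internals.

# SH by explicit double loop over individuals and microRNA positions.
oracle_sh <- function(arr, tissue_a, tissue_b) {
  total <- 0L
  for (ind in dimnames(arr)[[1L]]) {
    a <- arr[ind, tissue_a, ]
    b <- arr[ind, tissue_b, ]
    for (k in seq_along(a)) {
      if (!is.na(a[k]) && !is.na(b[k]) && a[k] != b[k]) total <- total + 1L
    }
  }
  total
}

# Welch two-sample t-test p-value from the closed-form statistic and
# Satterthwaite degrees of freedom.
oracle_welch_p <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tt), df)
}

# ROC AUC as the Mann-Whitney U statistic scaled by n_pos * n_neg.
oracle_auc <- function(is_case, score) {
  r <- rank(score)
  np <- sum(is_case)
  nn <- sum(!is_case)
  (sum(r[is_case]) - np * (np + 1) / 2) / (np * nn)
}

# Random binary profile array (individuals x tissues x mirs), optionally
# with missingness.
random_profile_array <- function(n_ind, tissues, n_mirs, prev = 0.5,
                                 missing_rate = 0) {
  arr <- array(stats::rbinom(n_ind * length(tissues) * n_mirs, 1L, prev),
               dim = c(n_ind, length(tissues), n_mirs),
               dimnames = list(sprintf("I%02d", seq_len(n_ind)), tissues,
                               sprintf("m%02d", seq_len(n_mirs))))
  if (missing_rate > 0)
    arr[stats::runif(length(arr)) < missing_rate] <- NA_integer_
  arr
}

# Small synthetic cohort for fast model tests.
small_cohort <- function(n_cases = 60, n_controls = 60, seed = 1, ...) {
  generate_cohort(cohort_sim_params(n_cases = n_cases, n_controls = n_controls,
                                    ...), seed = seed)$cohort
}
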