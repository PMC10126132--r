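test_that("hamming counts discordant positions and excludes missing pairwise", {
  expect_identical(as.integer(hamming(c(1, 0, 1), c(1, 1, 0))), 2L)
  v <- rbinom(13, 1, 0.5)
  expect_identical(as.integer(hamming(v, v)), 0L)
  expect_identical(as.integer(hamming(v, 1 - v)), 13L)
  h <- hamming(c(1, NA, 0, 1), c(0, 1, NA, 1))
  expect_identical(as.integer(h), 1L)
  expect_identical(attr(h, "n_compared"), 2L)
  expect_error(hamming(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("SH is additive over individuals and symmetric in the tissue pair", {
  arr <- array(NA_integer_, dim = c(2, 2, 3),
               dimnames = list(c("a", "b"), c("T1", "T2"), c("m1", "m2", "m3")))
  arr["a", "T1", ] <- c(1, 0, 1); arr["a", "T2", ] <- c(0, 1, 1)  # H = 2
  arr["b", "T1", ] <- c(0, 0, 0); arr["b", "T2", ] <- c(1, 1, 1)  # H = 3
  s <- similarity_statistic(tissue_profile_set(arr), "T1", "T2")
  expect_identical(as.integer(s), 5L)
  expect_identical(attr(s, "per_individual"), c(a = 2L, b = 3L))

  set.seed(11)
  for (i in 1:20) {
    a2 <- random_profile_array(6, c("T1", "T2"), 10, missing_rate = 0.1)
    set <- tissue_profile_set(a2)
    expect_identical(as.integer(similarity_statistic(set, "T1", "T2")),
                     as.integer(similarity_statistic(set, "T2", "T1")))
  }
})

test_that("SH matches the brute-force double-loop oracle, with and without missing", {
  set.seed(5)
  for (i in 1:30) {
    arr <- random_profile_array(12, c("EBC", "BAL"), 13,
                                missing_rate = sample(c(0, 0.15), 1))
    set <- tissue_profile_set(arr)
    expect_identical(as.integer(similarity_statistic(set, "EBC", "BAL")),
                     oracle_sh(arr, "EBC", "BAL"))
  }
})

test_that("individuals lacking a tissue profile are skipped and reported", {
  arr <- random_profile_array(5, c("EBC", "BAL"), 8)
  arr[2, "BAL", ] <- NA_integer_
  s <- similarity_statistic(tissue_profile_set(arr), "EBC", "BAL")
  expect_identical(attr(s, "n_individuals"), 4L)
  expect_identical(attr(s, "skipped"), "I02")
  arr[, "BAL", ] <- NA_integer_
  expect_error(similarity_statistic(tissue_profile_set(arr), "EBC", "BAL"),
               "no individual")
})

test_that("strict mode drops individuals with any missing call", {
  arr <- random_profile_array(6, c("EBC", "BAL"), 8)
  arr[3, "EBC", 1] <- NA_integer_
  set <- tissue_profile_set(arr)
  expect_identical(attr(similarity_statistic(set, "EBC", "BAL"), "n_individuals"), 6L)
  expect_identical(attr(similarity_statistic(set, "EBC", "BAL", strict = TRUE),
                        "n_individuals"), 5L)
})

test_that("a degenerate set where all profiles are identical gives p = 1", {
  prof <- rbinom(13, 1, 0.5)
  arr <- array(rep(prof, each = 4 * 2), dim = c(4, 2, 13),
               dimnames = list(paste0("I", 1:4), c("EBC", "BAL"), paste0("m", 1:13)))
  res <- permutation_test(tissue_profile_set(arr), "EBC", "BAL")
  expect_true(res$exhaustive)
  expect_equal(res$p_value, 1.0)

  arr12 <- array(rep(prof, each = 12 * 2), dim = c(12, 2, 13),
                 dimnames = list(sprintf("I%02d", 1:12), c("EBC", "BAL"),
                                 paste0("m", 1:13)))
  res12 <- permutation_test(tissue_profile_set(arr12), "EBC", "BAL",
                            n_permutations = 200, seed = 1)
  expect_false(res12$exhaustive)
  expect_equal(res12$p_value, 1.0)
})

test_that("four perfectly matched unique pairs give exact p = 1/24", {
  arr <- array(0L, dim = c(4, 2, 13),
               dimnames = list(paste0("I", 1:4), c("EBC", "BAL"), paste0("m", 1:13)))
  for (i in 1:4) { arr[i, "EBC", i] <- 1L; arr[i, "BAL", i] <- 1L }
  res <- permutation_test(tissue_profile_set(arr), "EBC", "BAL")
  expect_true(res$exhaustive)
  expect_identical(res$observed_sh, 0L)
  expect_identical(res$n_permutations, 24L)
  expect_equal(res$p_value, 1 / 24)
})

test_that("Monte-Carlo p agrees with the exhaustive p within 0.02 at B = 10000", {
  set.seed(21)
  for (i in 1:10) {
    arr <- random_profile_array(5, c("EBC", "BAL"), 10)
    set <- tissue_profile_set(arr)
    ex <- permutation_test(set, "EBC", "BAL", exhaustive_threshold = 7)
    mc <- permutation_test(set, "EBC", "BAL", n_permutations = 10000,
                           seed = 100 + i, exhaustive_threshold = 0)
    expect_true(ex$exhaustive); expect_false(mc$exhaustive)
    expect_lt(abs(mc$p_value - ex$p_value), 0.02)
  }
})

test_that("permutation results are reproducible for a fixed seed", {
  sim <- generate_tissue_profiles(seed = 4)
  r1 <- permutation_test(sim$set, "EBC", "BAL", n_permutations = 500, seed = 99)
  r2 <- permutation_test(sim$set, "EBC", "BAL", n_permutations = 500, seed = 99)
  expect_identical(r1, r2)
  expect_error(permutation_test(sim$set, "EBC", "BAL", n_permutations = 0),
               "n_permutations")
})

test_that("rejection rate is non-decreasing in the planted concordance", {
  levels <- c(0.5, 0.7, 0.9, 0.99)
  n_sims <- 60
  rates <- vapply(seq_along(levels), function(li) {
    conc <- c(EBC = levels[li], BAL = levels[li], BB = 0, SP = 0, MW = 0)
    params <- topo_sim_params(n_individuals = 12, n_mirs = 10,
                              concordance = conc)
    rej <- vapply(seq_len(n_sims), function(s) {
      sim <- generate_tissue_profiles(params, seed = 10000 * li + s)
      permutation_test(sim$set, "EBC", "BAL", n_permutations = 199,
                       seed = s)$p_value <= 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  # allow one-step sampling wiggle of 5 points; trend must be upward
  expect_true(all(diff(rates) >= -0.05))
  expect_gt(rates[4], rates[1])
})
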