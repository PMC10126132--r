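test_that("call_well applies the melt-curve and Ct rules with the stated boundaries", {
  cfg <- scoring_config()
  cases <- list(
    # ct, tm, reference_tm, expected
    list(36.0, 78.0, 78.5, "positive"),   # in tolerance, Ct below cutoff
    list(36.0, NA,   78.5, "negative"),   # no visible melt curve
    list(44.0, 78.5, 78.5, "negative"),   # Ct boundary is strict (< 44)
    list(43.99, 78.5, 78.5, "positive"),
    list(30.0, 80.2, 78.5, "negative"),   # |dTm| = 1.7 > 1.5
    list(30.0, 80.0, 78.5, "positive"),   # |dTm| = 1.5 exactly: inclusive
    list(NA,   78.5, 78.5, "negative")    # no amplification
  )
  for (cs in cases)
    expect_identical(call_well(cs[[1]], cs[[2]], cs[[3]], cfg), cs[[4]])
})

test_that("a missing reference Tm is an explicit error naming the microRNA", {
  expect_error(call_well(30, 78, NA, mir_id = "miR-21"), "miR-21")
  plate <- generate_qpcr_plate(2, mir_panel = c("miR-21", "miR-33b"), seed = 1)
  ref <- plate$reference_tm[plate$reference_tm$mir_id != "miR-33b", ]
  expect_error(score_wells(plate$wells, ref), "miR-33b")
})

test_that("call_sample scores a pair positive when at least one replicate is positive", {
  ref <- 78.5
  wells <- function(ct, tm) data.frame(sample_id = "s1", mir_id = "miR-21",
                                       replicate = seq_along(ct), ct = ct, tm = tm)
  one_pos <- call_sample(wells(c(NA, 36), c(NA, 78.5)), ref)
  expect_identical(one_pos$call, "positive")
  expect_identical(one_pos$n_positive_replicates, 1L)
  expect_identical(one_pos$n_replicates, 2L)
  expect_identical(call_sample(wells(c(NA, NA), c(NA, NA)), ref)$call, "negative")
  expect_identical(call_sample(wells(36, 78.5), ref)$call, "positive")
  # invariant to replicate order
  expect_identical(call_sample(wells(c(36, NA), c(78.5, NA)), ref)$call, "positive")
  expect_error(call_sample(data.frame(), ref), "at least one well")
})

test_that("relaxing Ct or Tm thresholds never turns a positive call negative", {
  set.seed(42)
  for (rep in 1:200) {
    ct <- ifelse(runif(1) < 0.15, NA, runif(1, 20, 45))
    tm <- ifelse(runif(1) < 0.15, NA, runif(1, 74, 83))
    tight <- scoring_config(tm_tolerance = 1.5, ct_positive_max = 44)
    loose <- scoring_config(tm_tolerance = 2.5, ct_positive_max = 44.9)
    if (call_well(ct, tm, 78.5, tight) == "positive")
      expect_identical(call_well(ct, tm, 78.5, loose), "positive")
  }
})

test_that("build_call_matrix fills missing cells, keeps order, rejects duplicates", {
  calls <- data.frame(sample_id = c("s1", "s1", "s2"),
                      mir_id = c("miR-21", "miR-33b", "miR-21"),
                      call = c("positive", "negative", "positive"))
  m <- build_call_matrix(calls, mir_panel = c("miR-21", "miR-33b"))
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(sum(is.na(m)), 1L)
  expect_true(is.na(m["s2", "miR-33b"]))
  expect_identical(m["s1", "miR-21"], 1L)
  expect_identical(rownames(m), c("s1", "s2"))

  empty <- build_call_matrix(calls[0, ], mir_panel = ebc_mir_panel())
  expect_identical(dim(empty), c(0L, 24L))

  dup <- rbind(calls, data.frame(sample_id = "s1", mir_id = "miR.21",
                                 call = "negative"))
  expect_error(build_call_matrix(dup, c("miR-21", "miR-33b")), "duplicate")
})

test_that("call matrix round-trips through CSV bit-identically, missing cells included", {
  set.seed(7)
  plate <- generate_qpcr_plate(6, mir_panel = ebc_mir_panel()[1:5],
                               tm_jitter_sd = 0.5, seed = 7)
  m <- build_call_matrix(score_wells(plate$wells, plate$reference_tm),
                         ebc_mir_panel()[1:6])  # 6th column all-missing
  path <- withr::local_tempfile(fileext = ".csv")
  write_call_matrix(m, path)
  expect_identical(read_call_matrix(path), m)
})

test_that("delta-Ct normalises to the housekeeper under its Ct cutoff", {
  cfg <- scoring_config(total_cycles = 40, ct_positive_max = 39,
                        housekeeper_ct_max = 35)
  w <- function(s, mir, ct) data.frame(sample_id = s, mir_id = mir,
                                       replicate = 1, ct = ct, tm = 78)
  wells <- rbind(w("a", "miR-423-3p", 25), w("a", "miR-141", 30),
                 w("b", "miR-423-3p", 36), w("b", "miR-141", 30),  # hk over cutoff
                 w("c", "miR-423-3p", 25), w("c", "miR-141", NA))  # target absent
  dm <- delta_ct_matrix(wells, "miR-141", cfg)
  expect_equal(dm["a", "miR-141"], 5.0)
  expect_true(is.na(dm["b", "miR-141"]))
  expect_true(is.na(dm["c", "miR-141"]))
  # housekeeper absent from a sample: warning plus missing row, not a crash
  expect_warning(dm2 <- delta_ct_matrix(rbind(w("d", "miR-141", 30)), "miR-141", cfg),
                 "housekeeper")
  expect_true(is.na(dm2["d", "miR-141"]))
})

test_that("fold-sensitivity follows perfect doubling and is reciprocal", {
  expect_equal(fold_sensitivity(27, 31), 16.0)
  expect_equal(fold_sensitivity(30, 30), 1.0)
  expect_equal(fold_sensitivity(20, 30), 1024.0)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 15, 40); b <- runif(1, 15, 40)
    expect_equal(fold_sensitivity(a, b) * fold_sensitivity(b, a), 1.0)
  }
})

test_that("amplicon length is template plus tag and rejects non-positive input", {
  expect_identical(amplicon_length(22, 40), 62L)
  expect_identical(amplicon_length(20, 40), 60L)
  expect_identical(amplicon_length(1, 1), 2L)
  expect_error(amplicon_length(0, 40), "positive")
  expect_error(amplicon_length(22, -1), "positive")
})

test_that("specificity delta-Ct censors non-amplified conditions at total cycles", {
  d <- specificity_delta_ct(25, 33)
  expect_equal(as.numeric(d), 8.0)
  expect_false(attr(d, "censored"))

  # oracle: treat non-amplification as Ct = total cycles
  censored_oracle <- 45 - 25
  d2 <- specificity_delta_ct(25, NA, total_cycles = 45)
  expect_equal(as.numeric(d2), censored_oracle)
  expect_true(attr(d2, "censored"))

  expect_equal(as.numeric(specificity_delta_ct(30, 30)), 0.0)
  expect_error(specificity_delta_ct(NA, NA), "at least one")
})
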