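test_that("Step-1 quantity gate: 28 tests in 2 weeks passes, 27 fails", {
  w <- default_window(n_days = 14)
  log28 <- flat_log(14, per_day = 2)                    # 28 evenly spread
  r <- assess_sufficiency(log28, w)
  expect_true(r$quantity_ok)
  expect_identical(r$total_tests, 28L)
  expect_equal(r$mean_tests_per_day, 2)

  log27 <- log28[-1, ]; class(log27) <- class(log28)
  r27 <- assess_sufficiency(log27, w)
  expect_false(r27$quantity_ok)
  expect_match(paste(r27$deficiencies, collapse = " "), "too_few_tests")
})

test_that("activation gate: 72 tests in 4 weeks with tag coverage", {
  w <- default_window(n_days = 28)
  log <- background_log(n_days = 28)   # 7-point regimen, ~196 tests
  r <- assess_sufficiency(log, w)
  expect_true(r$pattern_analysis_active)
  expect_true(r$quality_ok)
  # exactly at the activation threshold with full coverage
  expect_identical(r$thresholds_used$activation, 72L)

  sparse <- flat_log(28, per_day = 2)  # 56 < 72
  r2 <- assess_sufficiency(sparse, w)
  expect_false(r2$pattern_analysis_active)
  expect_true(r2$quantity_ok)          # 56 >= 56 pro-rated step1
  expect_match(paste(r2$deficiencies, collapse = " "), "below_activation")
})

test_that("quality gate fails when a required tag is uncovered", {
  w <- default_window(n_days = 14)
  log <- flat_log(14, per_day = 6, tag = "fasting")  # plenty, wrong tags
  r <- assess_sufficiency(log, w)
  expect_true(r$quantity_ok)
  expect_false(r$quality_ok)
  expect_true(any(grepl("tag_coverage:pre_breakfast", r$deficiencies)))
})

test_that("thresholds pro-rate by window length, rounding up", {
  w7 <- default_window(n_days = 7)
  r <- assess_sufficiency(flat_log(7, per_day = 2), w7)
  expect_identical(r$thresholds_used$step1, 14L)        # 28 * 7/14
  expect_identical(r$thresholds_used$activation, 18L)   # 72 * 7/28
  r10 <- assess_sufficiency(flat_log(10, per_day = 2),
                            default_window(n_days = 10))
  expect_identical(r10$thresholds_used$step1, 20L)      # ceil(28*10/14)
  expect_identical(r10$thresholds_used$activation, 26L) # ceil(72*10/28)
})

test_that("clamp_policy clamps the activation count into [30, 120]", {
  expect_warning(p <- clamp_policy(sufficiency_policy(min_tests_activation = 150)),
                 "clamped to 120")
  expect_identical(p$min_tests_activation, 120)
  expect_silent(p2 <- clamp_policy(sufficiency_policy(min_tests_activation = 72)))
  expect_identical(p2$min_tests_activation, 72)
  expect_warning(p3 <- clamp_policy(sufficiency_policy(min_tests_activation = 10)),
                 "clamped to 30")
  expect_identical(p3$min_tests_activation, 30)
})

test_that("zero readings give a valid all-false result; empty window errors", {
  w <- default_window(n_days = 14)
  empty <- flat_log(1)[0, ]; class(empty) <- c("smbg_log", "data.frame")
  r <- assess_sufficiency(empty, w)
  expect_false(r$quantity_ok); expect_false(r$quality_ok)
  expect_false(r$pattern_analysis_active)
  expect_identical(r$total_tests, 0L)
  expect_true(length(r$deficiencies) >= 2L)
})

test_that("adding a reading never flips a sufficiency gate true->false", {
  set.seed(21)
  w <- default_window(n_days = 14)
  for (rep in 1:10) {
    log <- random_log(n = sample(20:80, 1), n_days = 14)
    before <- assess_sufficiency(log, w)
    extra <- add_readings(log, "2024-03-10 11:13", 105,
                          tag = sample(smbg_tags(), 1))
    after <- assess_sufficiency(extra, w)
    expect_false(before$quantity_ok && !after$quantity_ok)
    expect_false(before$quality_ok && !after$quality_ok)
    expect_false(before$pattern_analysis_active &&
                 !after$pattern_analysis_active)
  }
})

test_that("per-block counts sum to the total", {
  w <- default_window(n_days = 14)
  set.seed(31)
  log <- random_log(n = 70, n_days = 14)
  r <- assess_sufficiency(log, w)
  expect_identical(sum(unlist(r$per_block_counts)), r$total_tests)
  expect_identical(sum(unlist(r$per_tag_counts)), r$total_tests)
})
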