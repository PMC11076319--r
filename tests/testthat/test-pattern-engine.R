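# Detector unit tests against the rule definitions. Fixtures place
# in-range background readings so that runs of analysis days are well
# defined; injected event values use 62 (hypo), 48 (very low), 205
# (hyper), 260 (very high).

hyper_days_log <- function(day_counts, start = "2024-03-04", value = 205) {
  # day_counts[i] hyper readings on day i, plus one in-range anchor per day
  ts <- character(); val <- numeric()
  for (i in seq_along(day_counts)) {
    d <- as.Date(start) + i - 1L
    ts <- c(ts, sprintf("%s 08:00", d)); val <- c(val, 110)
    k <- day_counts[i]
    if (k > 0) {
      ts <- c(ts, sprintf("%s 11:%02d", d, seq_len(k)))
      val <- c(val, rep(value, k))
    }
  }
  make_log(ts, val)
}

test_that("hyper trend fires on >=2 tests/day over 3 consecutive days", {
  w <- default_window(7)
  f <- detect_hyper_trend(hyper_days_log(c(0, 2, 2, 2, 0, 0, 0)), w)
  expect_identical(f$status, "red")
  expect_identical(nrow(f$evidence), 6L)
  expect_identical(unique(f$evidence$day),
                   c("2024-03-05", "2024-03-06", "2024-03-07"))

  expect_identical(detect_hyper_trend(
    hyper_days_log(c(2, 2, 0, 0, 0, 0, 0)), w)$status, "clear")
  expect_identical(detect_hyper_trend(
    hyper_days_log(c(0, 5, 0, 0, 0, 0, 0)), w)$status, "clear")
})

test_that("a day with no readings breaks a consecutive run", {
  w <- default_window(4)
  # qualifying days 1,2, an entirely silent day 3, qualifying day 4:
  # under "ignore silent days" semantics this would be a 3-day run
  log <- hyper_days_log(c(2, 2, 0, 2))
  log <- log[!(log$value == 110 & grepl("2024-03-06", format(log$timestamp))), ]
  class(log) <- c("smbg_log", "data.frame")
  expect_identical(detect_hyper_trend(log, w)$status, "clear")
})

test_that("hypo trend fires on >=1 event/day over 2 consecutive days", {
  w <- default_window(7)
  two_days <- make_log(c("2024-03-04 08:00", "2024-03-05 08:30"), c(62, 62))
  expect_identical(detect_hypo_trend(two_days, w)$status, "red")

  gap <- make_log(c("2024-03-04 08:00", "2024-03-06 08:30"), c(62, 62))
  expect_identical(detect_hypo_trend(gap, w)$status, "clear")

  one_day <- make_log(sprintf("2024-03-04 08:%02d", 1:3), rep(62, 3))
  expect_identical(detect_hypo_trend(one_day, w)$status, "clear")

  # very_low readings count as hypo events (class containment)
  vl <- make_log(c("2024-03-04 08:00", "2024-03-05 08:30"), c(48, 62))
  expect_identical(detect_hypo_trend(vl, w)$status, "red")
})

test_that("very-high trend counts strictly-above readings in the window", {
  w <- default_window(7)
  expect_identical(detect_very_high_trend(
    make_log("2024-03-04 12:00", 260), w)$status, "red")
  expect_identical(detect_very_high_trend(
    make_log(c("2024-03-04 12:00", "2024-03-05 12:00"), c(250, 240)),
    w)$status, "clear")
  # settable level
  expect_identical(detect_very_high_trend(
    make_log("2024-03-04 12:00", 260), w,
    params = list(tests = 1, level = 300))$status, "clear")
})

test_that("very-low trend uses strict below-level counting", {
  w <- default_window(7)
  expect_identical(detect_very_low_trend(
    make_log("2024-03-04 12:00", 50), w)$status, "red")
  expect_identical(detect_very_low_trend(
    make_log("2024-03-04 12:00", 54), w)$status, "clear")
  expect_identical(detect_very_low_trend(
    make_log(c("2024-03-04 12:00", "2024-03-05 12:00"), c(70, 70)), w,
    params = list(tests = 3, level = 80))$status, "clear")
})

test_that("hypo time-block uses a sliding span in the same block", {
  w <- default_window(14)
  # two night hypos 5 days apart: inside a 7-day span
  f <- detect_hypo_time_block(
    make_log(c("2024-03-04 02:00", "2024-03-09 03:00"), c(62, 62)), w)
  expect_identical(f$status, "red")
  expect_identical(f$time_block, "night")
  # different blocks on the same day do not pair
  expect_identical(detect_hypo_time_block(
    make_log(c("2024-03-04 02:00", "2024-03-04 12:00"), c(62, 62)),
    w)$status, "clear")
  # 8 days apart: outside every 7-day span
  expect_identical(detect_hypo_time_block(
    make_log(c("2024-03-04 02:00", "2024-03-12 03:00"), c(62, 62)),
    w)$status, "clear")
})

test_that("overcorrection pair detectors respect order, window, interruption", {
  w <- default_window(7)
  p <- list(pairing_window_hours = 5, pattern_count = 1, enabled = TRUE)
  hyper_then_hypo <- make_log(c("2024-03-04 12:00", "2024-03-04 15:00"),
                              c(280, 60))
  f <- detect_hypo_after_hyper(hyper_then_hypo, w, p)
  expect_identical(f$status, "red")
  expect_identical(f$n_pairs, 1L)
  expect_identical(f$note, "heuristic")
  # ordering matters
  expect_identical(detect_hypo_after_hyper(
    make_log(c("2024-03-04 12:00", "2024-03-04 15:00"), c(60, 280)),
    w, p)$status, "clear")
  # an in-range reading between them interrupts the pair
  expect_identical(detect_hypo_after_hyper(
    make_log(c("2024-03-04 12:00", "2024-03-04 13:30", "2024-03-04 15:00"),
             c(280, 110, 60)), w, p)$status, "clear")
  # outside the pairing window
  expect_identical(detect_hypo_after_hyper(
    make_log(c("2024-03-04 12:00", "2024-03-04 17:30"), c(280, 60)),
    w, p)$status, "clear")
  # mirrored detector
  expect_identical(detect_hyper_after_hypo(
    make_log(c("2024-03-04 12:00", "2024-03-04 15:00"), c(60, 280)),
    w, p)$status, "red")
  # disabled -> inactive
  expect_identical(detect_hypo_after_hyper(
    hyper_then_hypo, w, list(pairing_window_hours = 5, pattern_count = 1,
                             enabled = FALSE))$status, "inactive")
})

test_that("missed-bolus detector pairs post-meal hyper with unbolused pre-meal", {
  w <- default_window(7)
  p <- list(pattern_count = 1, enabled = TRUE)
  log <- smbg_log(c("2024-03-04 12:00", "2024-03-04 14:00"),
                  c(120, 240), tag = c("pre_lunch", "post_lunch"),
                  bolus_given = c(FALSE, NA))
  expect_identical(detect_missed_bolus_hyper(log, w, p)$status, "red")

  bolused <- smbg_log(c("2024-03-04 12:00", "2024-03-04 14:00"),
                      c(120, 240), tag = c("pre_lunch", "post_lunch"),
                      bolus_given = c(TRUE, NA))
  expect_identical(detect_missed_bolus_hyper(bolused, w, p)$status, "clear")

  unannotated <- smbg_log(c("2024-03-04 12:00", "2024-03-04 14:00"),
                          c(120, 240), tag = c("pre_lunch", "post_lunch"))
  f <- detect_missed_bolus_hyper(unannotated, w, p)
  expect_identical(f$status, "inactive")
  expect_match(f$reason, "no bolus annotations")
})

test_that("adherence fraction and red threshold behave as specified", {
  w <- default_window(14)
  full <- flat_log(14, per_day = 4)
  f <- assess_adherence(full, w, prescribed_tests_per_day = 4)
  expect_equal(f$adherence_fraction, 1)
  expect_identical(f$status, "clear")

  half <- flat_log(14, per_day = 2)
  f2 <- assess_adherence(half, w, prescribed_tests_per_day = 4)
  expect_equal(f2$adherence_fraction, 0.5)
  expect_identical(f2$status, "red")

  none <- full[0, ]; class(none) <- c("smbg_log", "data.frame")
  f3 <- assess_adherence(none, w, prescribed_tests_per_day = 4)
  expect_equal(f3$adherence_fraction, 0)
  expect_identical(f3$status, "red")
})

test_that("run_all_patterns yields one finding per detector in block order", {
  log <- background_log()
  w <- default_window()
  findings <- run_all_patterns(log, w)
  expect_identical(names(findings),
                   c("hypo_trend", "hypo_time_block", "very_low_trend",
                     "hypo_after_hyper", "hyper_trend", "hyper_time_block",
                     "very_high_trend", "hyper_after_hypo",
                     "missed_bolus_hyper", "high_variability",
                     "smbg_frequency"))
  blocks <- vapply(findings, `[[`, "", "block")
  expect_identical(unique(unname(blocks)),
                   c("hypoglycemia", "hyperglycemia", "variability",
                     "adherence"))
  # sufficiency gate failed -> everything inactive
  inactive <- run_all_patterns(log, w, active = FALSE)
  expect_true(all(vapply(inactive, `[[`, "", "status") == "inactive"))
})

test_that("raising a count parameter never turns clear into red", {
  set.seed(41)
  w <- default_window(14)
  for (rep in 1:15) {
    log <- random_log(n = 60, n_days = 14)
    for (tpd in 1:4) {
      lo <- detect_hyper_trend(log, w, params = list(
        tests_per_day = tpd, consecutive_days = 2))
      hi <- detect_hyper_trend(log, w, params = list(
        tests_per_day = tpd + 1, consecutive_days = 2))
      expect_false(lo$status == "clear" && hi$status == "red")
    }
    for (days in 2:5) {
      lo <- detect_hypo_time_block(log, w, params = list(
        events_in_block = 2, days = days + 1))
      hi <- detect_hypo_time_block(log, w, params = list(
        events_in_block = 2, days = days))
      # a narrower span is a stricter rule
      expect_false(hi$status == "red" && lo$status == "clear")
    }
  }
})

test_that("red findings carry evidence satisfying the rule; earliest run wins", {
  w <- default_window(10)
  log <- hyper_days_log(c(0, 2, 2, 2, 0, 3, 3, 3, 0, 0))
  f <- detect_hyper_trend(log, w)
  expect_identical(f$status, "red")
  # earliest of the two qualifying runs is reported
  expect_identical(min(f$evidence$day), "2024-03-05")
  expect_true(all(f$evidence$value > 130))
  f_all <- detect_hyper_trend(log, w, all_evidence = TRUE)
  expect_identical(length(f_all$all_occurrences), 2L)
})
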