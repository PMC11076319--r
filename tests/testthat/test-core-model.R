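test_that("classify_reading follows the strict threshold semantics", {
  th <- glycemic_thresholds()
  # boundary table: value, tag, expected class
  cases <- list(
    list(53, "other", "very_low"),
    list(54, "other", "hypo"),          # not strictly below 54
    list(69.9, "other", "hypo"),
    list(70, "other", "in_range"),      # value == hypo_limit stays in range
    list(130, "other", "in_range"),
    list(131, "other", "hyper"),
    list(131, "post_lunch", "in_range"),  # post-meal limit is 180
    list(181, "post_lunch", "hyper"),
    list(250, "other", "hyper"),
    list(251, "other", "very_high"))
  for (cs in cases) {
    expect_identical(as.character(classify_reading(cs[[1]], cs[[2]], th)),
                     cs[[3]],
                     info = sprintf("value %s tag %s", cs[[1]], cs[[2]]))
  }
})

test_that("classification is monotone in value for fixed tag", {
  th <- glycemic_thresholds()
  for (tag in c("other", "post_lunch", "pre_breakfast")) {
    v <- seq(30, 400, by = 0.5)
    cls <- classify_reading(v, tag, th)
    expect_true(all(diff(as.integer(cls)) >= 0), info = tag)
  }
})

test_that("very_low/very_high are contained in hypo/hyper semantics", {
  cls <- classify_reading(c(40, 60, 100, 200, 300), "other")
  expect_identical(is_hypo_class(cls), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(is_hyper_class(cls), c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("invalid threshold orderings and values are rejected", {
  expect_error(glycemic_thresholds(hypo_limit = 50), "thresholds must satisfy")
  expect_error(glycemic_thresholds(hyper_postmeal_limit = 120),
               "thresholds must satisfy")
  expect_error(classify_reading(0, "other"), "finite")
  expect_error(classify_reading(1000, "other"), "finite")
})

test_that("assign_block is total with half-open boundary convention", {
  s <- time_block_scheme()
  ts <- function(clock) as.POSIXct(paste("2024-03-04", clock), tz = "UTC")
  expect_identical(assign_block(ts("07:30"), s), "breakfast")
  expect_identical(assign_block(ts("06:00"), s), "breakfast")  # boundary
  expect_identical(assign_block(ts("05:59"), s), "night")
  expect_identical(assign_block(ts("02:00"), s), "night")
  expect_identical(assign_block(ts("23:59"), s), "bedtime")
  expect_identical(assign_block(ts("00:00"), s), "night")
})

test_that("malformed block schemes are rejected", {
  expect_error(time_block_scheme(data.frame(
    name = c("a", "b"), start = c("00:00", "13:00"),
    end = c("12:00", "24:00"))), "no gap")
  expect_error(time_block_scheme(data.frame(
    name = "a", start = "01:00", end = "24:00")), "cover the day")
  expect_error(time_block_scheme(data.frame(
    name = c("a", "a"), start = c("00:00", "12:00"),
    end = c("12:00", "24:00"))), "duplicate")
})

test_that("group_by_day honours the configured day rollover", {
  log <- make_log(c("2024-03-04 23:50", "2024-03-05 01:00",
                    "2024-03-05 09:00"), c(100, 100, 100))
  # midnight rollover: 23:50 belongs to its calendar day
  g0 <- group_by_day(log, 0L)
  expect_identical(names(g0), c("2024-03-04", "2024-03-05"))
  expect_identical(vapply(g0, nrow, 1L), c("2024-03-04" = 1L,
                                           "2024-03-05" = 2L))
  # 03:00 rollover: 23:50 and the following 01:00 share an analysis day
  g3 <- group_by_day(log, 3L * 60L)
  expect_identical(vapply(g3, nrow, 1L), c("2024-03-04" = 2L,
                                           "2024-03-05" = 1L))
  expect_identical(group_by_day(log[0, ], 0L),
                   structure(list(), names = character()))
})

test_that("per-day and per-block partitions preserve total counts", {
  set.seed(11)
  for (rep in 1:5) {
    log <- random_log(n = 50)
    s <- time_block_scheme()
    expect_identical(sum(vapply(group_by_day(log, 0L), nrow, 1L)), nrow(log))
    expect_identical(sum(table(assign_block(log$timestamp, s))),
                     as.integer(nrow(log)))
    # every reading maps to exactly one block
    expect_false(anyNA(assign_block(log$timestamp, s)))
  }
})

test_that("analysis_window validates and counts days inclusively", {
  w <- analysis_window("2024-03-04", "2024-03-31")
  expect_identical(w$n_days, 28L)
  expect_identical(analysis_window("2024-03-04", "2024-03-04")$n_days, 1L)
  expect_error(analysis_window("2024-03-05", "2024-03-04"), "end >= start")
  expect_error(analysis_window("not-a-date", "2024-03-04"))
})
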