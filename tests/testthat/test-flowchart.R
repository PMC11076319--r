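test_that("insufficient data takes the Step-1 branch", {
  w <- default_window(28)
  sparse <- flat_log(5, per_day = 2)   # 10 readings in 4 weeks
  rep <- run_flowchart(sparse, w)
  expect_false(rep$sufficiency$pattern_analysis_active)
  expect_true(all(vapply(rep$patterns, `[[`, "", "status") == "inactive"))
  expect_null(rep$variability)
  codes <- vapply(rep$actions, `[[`, "", "code")
  expect_true(all(c("investigate_low_adherence", "plan_education_session",
                    "review_single_events") %in% codes))
})

test_that("red hypo pattern with low CV maps to de-intensification", {
  sim <- simulate_smbg(simulation_spec(
    seed = 5, injections = list(injection("hypo_trend", 10))))
  rep <- run_flowchart(sim$readings, sim$window)
  expect_identical(rep$patterns$hypo_trend$status, "red")
  expect_identical(rep$variability$cv_class, "low")
  codes <- vapply(rep$actions, `[[`, "", "code")
  expect_true("consider_deintensify_treatment" %in% codes)
  expect_true("review_correction_rules" %in% codes)
  # hypo-derived flags sort first
  expect_identical(codes[1], "review_correction_rules")
})

test_that("high variability suppresses treatment changes, demands more SMBG", {
  # high-CV world with an injected hyper pattern: build from a sweep log
  sw <- sweep_cv(simulation_spec(seed = 11, missingness = 0), 45)[[1]]
  log <- add_readings(sw$readings,
                      sprintf("2024-03-%02d 11:%02d", rep(10:12, each = 2),
                              rep(c(0, 10), 3)),
                      rep(205, 6))
  rep <- run_flowchart(log, sw$window)
  expect_identical(rep$patterns$hyper_trend$status, "red")
  expect_identical(rep$variability$cv_class, "high")
  codes <- vapply(rep$actions, `[[`, "", "code")
  expect_true("intensify_smbg_before_change" %in% codes)
  expect_false(any(c("consider_intensify_treatment",
                     "consider_deintensify_treatment") %in% codes))
})

test_that("every action flag references findings present in the report", {
  sim <- simulate_smbg(simulation_spec(
    seed = 23, injections = list(injection("hypo_trend", 4),
                                 injection("very_high_trend", 20))))
  rep <- run_flowchart(sim$readings, sim$window)
  valid_refs <- c(names(rep$patterns), "sufficiency_gate", "variability_gate")
  for (a in rep$actions) {
    expect_true(all(a$triggered_by %in% valid_refs), info = a$code)
    # red triggers must actually be red findings
    det <- intersect(a$triggered_by, names(rep$patterns))
    for (d in det)
      expect_identical(rep$patterns[[d]]$status, "red",
                       info = paste(a$code, d))
  }
})

test_that("reports are deterministic and serialize losslessly", {
  sim <- simulate_smbg(simulation_spec(seed = 31))
  r1 <- run_flowchart(sim$readings, sim$window)
  r2 <- run_flowchart(sim$readings, sim$window)
  expect_identical(report_to_json(r1), report_to_json(r2))

  p <- tempfile(fileext = ".json")
  write_report(r1, p)
  back <- read_report(p)
  expect_identical(render_text_report(back), render_text_report(r1))
})

test_that("compare_periods reports deltas and status transitions", {
  # same generative world in both windows -> near-zero deltas, no transitions
  simA <- simulate_smbg(simulation_spec(seed = 41, n_days = 14,
                                        start_date = "2024-03-04",
                                        missingness = 0))
  simB <- simulate_smbg(simulation_spec(seed = 41, n_days = 14,
                                        start_date = "2024-03-18",
                                        missingness = 0))
  log <- smbg_log(
    c(format(simA$readings$timestamp, "%Y-%m-%d %H:%M"),
      format(simB$readings$timestamp, "%Y-%m-%d %H:%M")),
    c(simA$readings$value, simB$readings$value),
    c(simA$readings$tag, simB$readings$tag))
  cmp <- compare_periods(log, simA$window, simB$window)
  # identical seed and regimen: every metric delta is exactly zero
  for (m in c("mean_glucose", "sd", "cv_percent", "lbgi", "hbgi"))
    expect_equal(cmp$deltas[[m]], 0, tolerance = 1e-9, label = m)
  expect_true(all(unlist(cmp$transitions) %in%
                  c("clear->clear", "red->red", "inactive->inactive")))

  # injected hypo pattern only in window B -> clear->red transition
  simB2 <- simulate_smbg(simulation_spec(
    seed = 41, n_days = 14, start_date = "2024-03-18", missingness = 0,
    injections = list(injection("hypo_trend", 5))))
  log2 <- smbg_log(
    c(format(simA$readings$timestamp, "%Y-%m-%d %H:%M"),
      format(simB2$readings$timestamp, "%Y-%m-%d %H:%M")),
    c(simA$readings$value, simB2$readings$value),
    c(simA$readings$tag, simB2$readings$tag))
  cmp2 <- compare_periods(log2, simA$window, simB$window)
  expect_identical(cmp2$transitions$hypo_trend, "clear->red")
})

test_that("compare_periods rejects overlapping and empty windows", {
  log <- background_log(28)
  wa <- default_window(14)
  overlapping <- analysis_window("2024-03-10", "2024-03-24")
  expect_error(compare_periods(log, wa, overlapping), "disjoint")
  empty_b <- analysis_window("2025-01-01", "2025-01-14")
  expect_error(compare_periods(log, wa, empty_b), "fewer than 2")
})
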