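#' Construct a pattern finding
#'
#' One detector's outcome: `status` is `"red"` (rule satisfied, evidence
#' non-empty), `"clear"`, or `"inactive"` (detector not applicable —
#' sufficiency gate failed, heuristic disabled, or required annotations
#' absent). `evidence` holds the triggering readings with their analysis
#' day and time block; `row_id` references rows of the input CSV.
#'
#' @param detector Detector id string.
#' @param block Pattern block: `"hypoglycemia"`, `"hyperglycemia"`,
#'   `"variability"`, or `"adherence"`.
#' @param status `"red"`, `"clear"`, or `"inactive"`.
#' @param evidence Data frame of triggering readings (may have zero rows).
#' @param window [analysis_window()].
#' @param params_used Named list of the parameter values applied.
#' @param ... Extra scalar fields (e.g. `adherence_fraction`, `note`).
#' @param require_evidence Enforce non-empty evidence for red findings.
#'   The adherence detector turns red on the *absence* of tests, so it is
#'   the one detector exempt from the rule.
#' @return Object of class `pattern_finding`.
#' @export
pattern_finding <- function(detector, block, status, evidence, window,
                            params_used, ..., require_evidence = TRUE) {
  stopifnot(status %in% c("red", "clear", "inactive"),
            block %in% c("hypoglycemia", "hyperglycemia", "variability",
                         "adherence"))
  if (require_evidence && status == "red" && nrow(evidence) == 0L)
    stop("internal error: red finding for ", detector, " without evidence")
  structure(c(list(detector = detector, block = block, status = status,
                   evidence = evidence,
                   window = list(start = format(window$start),
                                 end = format(window$end)),
                   params_used = params_used),
              list(...)),
            class = "pattern_finding")
}

#' @export
print.pattern_finding <- function(x, ...) {
  cat(sprintf("[%s] %s: %s", x$block, x$detector, toupper(x$status)))
  if (nrow(x$evidence)) cat(sprintf(" (%d evidence readings)", nrow(x$evidence)))
  cat("\n")
  invisible(x)
}

.empty_evidence <- function() {
  data.frame(row_id = integer(), timestamp = character(), day = character(),
             block = character(), value = numeric(), tag = character(),
             stringsAsFactors = FALSE)
}

# Evidence rows for a subset of readings, annotated with day and block.
.evidence_of <- function(readings, scheme) {
  if (nrow(readings) == 0L) return(.empty_evidence())
  data.frame(
    row_id = readings$row_id,
    timestamp = format(readings$timestamp, "%Y-%m-%dT%H:%M", tz = .SMBG_TZ),
    day = format(analysis_day(readings$timestamp, scheme$day_start_min)),
    block = assign_block(readings$timestamp, scheme),
    value = readings$value,
    tag = readings$tag,
    stringsAsFactors = FALSE)
}

# Earliest maximal run of TRUE of length >= len over a logical vector;
# returns c(start, end) indices or NULL.
.first_run <- function(ok, len) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (!length(hit)) return(NULL)
  c(starts[hit[1L]], ends[hit[1L]])
}

# Shared machinery for the two consecutive-day trend detectors. A day with
# no readings has count 0 and therefore breaks a run (absence of evidence
# breaks runs).
.detect_trend <- function(readings, window, scheme, qualifying,
                          per_day_min, run_len, detector, block, params,
                          all_evidence = FALSE) {
  days <- seq(window$start, window$end, by = "day")
  q <- readings[qualifying, , drop = FALSE]
  qday <- analysis_day(q$timestamp, scheme$day_start_min)
  counts <- as.integer(table(factor(format(qday), levels = format(days))))
  ok <- counts >= per_day_min
  run <- .first_run(ok, run_len)
  occurrences <- NULL
  if (all_evidence) {
    r <- rle(ok); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hits <- which(r$values & r$lengths >= run_len)
    occurrences <- lapply(hits, function(h) {
      sel <- qday >= days[starts[h]] & qday <= days[ends[h]]
      .evidence_of(q[sel, , drop = FALSE], scheme)
    })
  }
  if (is.null(run)) {
    pattern_finding(detector, block, "clear", .empty_evidence(), window,
                    params)
  } else {
    sel <- qday >= days[run[1L]] & qday <= days[run[2L]]
    f <- pattern_finding(detector, block, "red",
                         .evidence_of(q[sel, , drop = FALSE], scheme),
                         window, params)
    if (!is.null(occurrences)) f$all_occurrences <- occurrences
    f
  }
}

#' Hyperglycemia trend detector
#'
#' Red when some run of at least `consecutive_days` calendar-consecutive
#' analysis days each contains at least `tests_per_day` readings in the
#' hyperglycemic range (tag-dependent limit; very-high readings count).
#' Platform default: 2 tests/day on 3 consecutive days. Evidence lists
#' every qualifying reading in the earliest such run.
#'
#' @param readings [smbg_log()] restricted to the window.
#' @param window [analysis_window()].
#' @param params List with `tests_per_day`, `consecutive_days` (see
#'   [pattern_params()]).
#' @param thresholds [glycemic_thresholds()].
#' @param scheme [time_block_scheme()].
#' @param all_evidence Also report every qualifying run, not just the
#'   earliest.
#' @return A [pattern_finding()].
#' @export
detect_hyper_trend <- function(readings, window,
                               params = pattern_params()$hyper_trend,
                               thresholds = glycemic_thresholds(),
                               scheme = time_block_scheme(),
                               all_evidence = FALSE) {
  cls <- classify_reading(readings$value, readings$tag, thresholds)
  .detect_trend(readings, window, scheme, is_hyper_class(cls),
                params$tests_per_day, params$consecutive_days,
                "hyper_trend", "hyperglycemia", params, all_evidence)
}

#' Hypoglycemia trend detector
#'
#' Red when at least `events_per_day` hypoglycemic events (below the hypo
#' limit; very-low readings count) occur per day on `consecutive_days`
#' consecutive analysis days. Platform default: 1 event/day on 2
#' consecutive days.
#'
#' @inheritParams detect_hyper_trend
#' @param params List with `events_per_day`, `consecutive_days`.
#' @return A [pattern_finding()].
#' @export
detect_hypo_trend <- function(readings, window,
                              params = pattern_params()$hypo_trend,
                              thresholds = glycemic_thresholds(),
                              scheme = time_block_scheme(),
                              all_evidence = FALSE) {
  cls <- classify_reading(readings$value, readings$tag, thresholds)
  .detect_trend(readings, window, scheme, is_hypo_class(cls),
                params$events_per_day, params$consecutive_days,
                "hypo_trend", "hypoglycemia", params, all_evidence)
}

#' Very-high hyperglycemia trend detector
#'
#' Red when at least `tests` readings strictly above `level` (default
#' 1 test above 250 mg/dL) occur in the analysis window.
#'
#' @inheritParams detect_hyper_trend
#' @param params List with `tests`, `level`.
#' @return A [pattern_finding()].
#' @export
detect_very_high_trend <- function(readings, window,
                                   params = pattern_params()$very_high_trend,
                                   scheme = time_block_scheme()) {
  q <- readings[readings$value > params$level, , drop = FALSE]
  status <- if (nrow(q) >= params$tests) "red" else "clear"
  ev <- if (status == "red") .evidence_of(q, scheme) else .empty_evidence()
  pattern_finding("very_high_trend", "hyperglycemia", status, ev, window,
                  params)
}

#' Very-low hypoglycemia trend detector
#'
#' Red when at least `tests` readings strictly below `level` (default
#' 1 test below 54 mg/dL) occur in the analysis window.
#'
#' @inheritParams detect_very_high_trend
#' @return A [pattern_finding()].
#' @export
detect_very_low_trend <- function(readings, window,
                                  params = pattern_params()$very_low_trend,
                                  scheme = time_block_scheme()) {
  q <- readings[readings$value < params$level, , drop = FALSE]
  status <- if (nrow(q) >= params$tests) "red" else "clear"
  ev <- if (status == "red") .evidence_of(q, scheme) else .empty_evidence()
  pattern_finding("very_low_trend", "hypoglycemia", status, ev, window,
                  params)
}

# Shared sliding-window time-block recurrence rule. "Over N days" is a
# sliding span of N consecutive analysis days anywhere in the window, not
# fixed calendar weeks. Earliest qualifying (start day, then scheme block
# order) wins ties.
.detect_time_block <- function(readings, window, scheme, qualifying,
                               events_needed, span_days, detector, block,
                               params, all_evidence = FALSE) {
  q <- readings[qualifying, , drop = FALSE]
  qday <- analysis_day(q$timestamp, scheme$day_start_min)
  qblock <- if (nrow(q)) assign_block(q$timestamp, scheme) else character()
  best <- NULL   # list(start_day, block_idx, evidence)
  occurrences <- list()
  for (bi in seq_len(nrow(scheme$blocks))) {
    bname <- scheme$blocks$name[bi]
    sel <- which(qblock == bname)
    if (length(sel) < events_needed) next
    d <- sort(qday[sel])
    for (i in seq_len(length(d) - events_needed + 1L)) {
      if (as.integer(d[i + events_needed - 1L] - d[i]) <= span_days - 1L) {
        in_span <- sel[qday[sel] >= d[i] & qday[sel] <= d[i] + span_days - 1L]
        ev <- .evidence_of(q[in_span, , drop = FALSE], scheme)
        if (all_evidence) occurrences[[length(occurrences) + 1L]] <- ev
        if (is.null(best) || d[i] < best$start_day ||
            (d[i] == best$start_day && bi < best$block_idx))
          best <- list(start_day = d[i], block_idx = bi, evidence = ev)
        if (!all_evidence) break
      }
    }
  }
  if (is.null(best)) {
    pattern_finding(detector, block, "clear", .empty_evidence(), window,
                    params)
  } else {
    f <- pattern_finding(detector, block, "red", best$evidence, window,
                         params,
                         time_block = scheme$blocks$name[best$block_idx])
    if (all_evidence) f$all_occurrences <- occurrences
    f
  }
}

#' Hypoglycemia-in-time-block detector
#'
#' Red when at least `events_in_block` hypoglycemic events fall in the same
#' time block within some span of `days` consecutive analysis days
#' (default 2 events over 7 days, evaluated as a sliding window).
#'
#' @inheritParams detect_hyper_trend
#' @param params List with `events_in_block`, `days`.
#' @return A [pattern_finding()]; when red, carries the `time_block` name.
#' @export
detect_hypo_time_block <- function(readings, window,
                                   params = pattern_params()$hypo_time_block,
                                   thresholds = glycemic_thresholds(),
                                   scheme = time_block_scheme(),
                                   all_evidence = FALSE) {
  cls <- classify_reading(readings$value, readings$tag, thresholds)
  .detect_time_block(readings, window, scheme, is_hypo_class(cls),
                     params$events_in_block, params$days,
                     "hypo_time_block", "hypoglycemia", params, all_evidence)
}

#' Hyperglycemia-in-time-block detector
#'
#' Mirror of [detect_hypo_time_block()] for hyperglycemic readings; the
#' platform details only the hypoglycemia variant, the hyper variant is
#' the minimal consistent extension using the same rule and ranges.
#'
#' @inheritParams detect_hypo_time_block
#' @return A [pattern_finding()].
#' @export
detect_hyper_time_block <- function(readings, window,
                                    params = pattern_params()$hyper_time_block,
                                    thresholds = glycemic_thresholds(),
                                    scheme = time_block_scheme(),
                                    all_evidence = FALSE) {
  cls <- classify_reading(readings$value, readings$tag, thresholds)
  .detect_time_block(readings, window, scheme, is_hyper_class(cls),
                     params$events_in_block, params$days,
                     "hyper_time_block", "hyperglycemia", params, all_evidence)
}

# Ordered overcorrection pairs: a `to_cls` reading that follows a
# `from_cls` reading within window_hours with no in-range reading between
# them (an in-range reading interrupts the pair). Returns integer matrix
# with one row per (from, to) index pair.
.overcorrection_pairs <- function(cls, timestamp, from_is, to_is,
                                  window_hours) {
  n <- length(cls)
  pairs <- NULL
  in_range <- as.character(cls) == "in_range"
  for (i in seq_len(n)) {
    if (!from_is[i]) next
    j <- i + 1L
    while (j <= n) {
      dt <- as.numeric(difftime(timestamp[j], timestamp[i], units = "hours"))
      if (dt > window_hours) break
      if (in_range[j]) break
      if (to_is[j]) pairs <- rbind(pairs, c(i, j))
      j <- j + 1L
    }
  }
  pairs
}

#' Hypoglycemia-after-hyperglycemia (overcorrection) detector
#'
#' Declared heuristic (the platform names this pattern without publishing a
#' rule): red when at least `pattern_count` pairs exist where a
#' hypoglycemic reading follows a hyperglycemic one within
#' `pairing_window_hours` with no in-range reading between them. Inactive
#' unless heuristic detectors are enabled in the config.
#'
#' @inheritParams detect_hyper_trend
#' @param params List with `pairing_window_hours`, `pattern_count`,
#'   `enabled`.
#' @return A [pattern_finding()] with `note = "heuristic"`.
#' @export
detect_hypo_after_hyper <- function(readings, window,
                                    params = list(pairing_window_hours = 5,
                                                  pattern_count = 1,
                                                  enabled = TRUE),
                                    thresholds = glycemic_thresholds(),
                                    scheme = time_block_scheme()) {
  .detect_overcorrection(readings, window, params, thresholds, scheme,
                         from = "hyper", to = "hypo",
                         detector = "hypo_after_hyper",
                         block = "hypoglycemia")
}

#' Hyperglycemia-after-hypoglycemia (overcorrection) detector
#'
#' Mirror of [detect_hypo_after_hyper()] with the roles swapped.
#'
#' @inheritParams detect_hypo_after_hyper
#' @return A [pattern_finding()] with `note = "heuristic"`.
#' @export
detect_hyper_after_hypo <- function(readings, window,
                                    params = list(pairing_window_hours = 5,
                                                  pattern_count = 1,
                                                  enabled = TRUE),
                                    thresholds = glycemic_thresholds(),
                                    scheme = time_block_scheme()) {
  .detect_overcorrection(readings, window, params, thresholds, scheme,
                         from = "hypo", to = "hyper",
                         detector = "hyper_after_hypo",
                         block = "hyperglycemia")
}

.detect_overcorrection <- function(readings, window, params, thresholds,
                                   scheme, from, to, detector, block) {
  if (!isTRUE(params$enabled))
    return(pattern_finding(detector, block, "inactive", .empty_evidence(),
                           window, params, note = "heuristic"))
  cls <- classify_reading(readings$value, readings$tag, thresholds)
  from_is <- if (from == "hyper") is_hyper_class(cls) else is_hypo_class(cls)
  to_is <- if (to == "hypo") is_hypo_class(cls) else is_hyper_class(cls)
  pairs <- .overcorrection_pairs(cls, readings$timestamp, from_is, to_is,
                                 params$pairing_window_hours)
  n_pairs <- if (is.null(pairs)) 0L else nrow(pairs)
  if (n_pairs >= params$pattern_count) {
    idx <- sort(unique(as.vector(pairs)))
    pattern_finding(detector, block, "red",
                    .evidence_of(readings[idx, , drop = FALSE], scheme),
                    window, params, note = "heuristic", n_pairs = n_pairs)
  } else {
    pattern_finding(detector, block, "clear", .empty_evidence(), window,
                    params, note = "heuristic", n_pairs = n_pairs)
  }
}

# meal tag pairs for the missed-bolus rule
.meal_pairs <- data.frame(
  pre = c("pre_breakfast", "pre_lunch", "pre_dinner"),
  post = c("post_breakfast", "post_lunch", "post_dinner"),
  stringsAsFactors = FALSE)

#' Missed-intake-bolus hyperglycemia detector
#'
#' Declared heuristic: red when at least `pattern_count` post-meal
#' hyperglycemic readings have a same-day, same-meal pre-meal reading with
#' `bolus_given = FALSE`. Inactive when heuristics are disabled or when the
#' log carries no bolus annotations at all (missing-data contract).
#'
#' @inheritParams detect_hypo_after_hyper
#' @return A [pattern_finding()] with `note = "heuristic"`.
#' @export
detect_missed_bolus_hyper <- function(readings, window,
                                      params = list(pattern_count = 1,
                                                    enabled = TRUE),
                                      thresholds = glycemic_thresholds(),
                                      scheme = time_block_scheme()) {
  det <- "missed_bolus_hyper"
  if (!isTRUE(params$enabled))
    return(pattern_finding(det, "hyperglycemia", "inactive",
                           .empty_evidence(), window, params,
                           note = "heuristic"))
  if (nrow(readings) == 0L || all(is.na(readings$bolus_given)))
    return(pattern_finding(det, "hyperglycemia", "inactive",
                           .empty_evidence(), window, params,
                           note = "heuristic",
                           reason = "no bolus annotations in log"))
  cls <- classify_reading(readings$value, readings$tag, thresholds)
  day <- format(analysis_day(readings$timestamp, scheme$day_start_min))
  hits <- integer()
  for (k in seq_len(nrow(.meal_pairs))) {
    post_i <- which(readings$tag == .meal_pairs$post[k] & is_hyper_class(cls))
    for (i in post_i) {
      pre_i <- which(readings$tag == .meal_pairs$pre[k] & day == day[i])
      if (length(pre_i) && any(!is.na(readings$bolus_given[pre_i]) &
                               !readings$bolus_given[pre_i]))
        hits <- c(hits, pre_i[which(!is.na(readings$bolus_given[pre_i]) &
                                    !readings$bolus_given[pre_i])[1L]], i)
    }
  }
  n_events <- length(hits) / 2L
  if (n_events >= params$pattern_count) {
    idx <- sort(unique(hits))
    pattern_finding(det, "hyperglycemia", "red",
                    .evidence_of(readings[idx, , drop = FALSE], scheme),
                    window, params, note = "heuristic", n_events = n_events)
  } else {
    pattern_finding(det, "hyperglycemia", "clear", .empty_evidence(),
                    window, params, note = "heuristic", n_events = n_events)
  }
}

#' Testing-frequency adherence detector
#'
#' Adherence fraction = performed / prescribed tests over the window,
#' capped at 1; the finding turns red when the fraction falls below the
#' red threshold (default 0.7).
#'
#' @inheritParams detect_hyper_trend
#' @param prescribed_tests_per_day Prescribed SMBG frequency.
#' @param red_threshold Fraction below which the finding is red.
#' @return A [pattern_finding()] carrying `adherence_fraction`.
#' @export
assess_adherence <- function(readings, window, prescribed_tests_per_day = 4,
                             red_threshold = 0.7,
                             scheme = time_block_scheme()) {
  readings <- clip_to_window(readings, window, scheme$day_start_min)
  prescribed <- prescribed_tests_per_day * window$n_days
  fraction <- min(1, nrow(readings) / prescribed)
  params <- list(prescribed_tests_per_day = prescribed_tests_per_day,
                 red_threshold = red_threshold)
  if (fraction < red_threshold) {
    # evidence for an absence-of-testing pattern is the whole (sparse) log,
    # possibly empty
    pattern_finding("smbg_frequency", "adherence", "red",
                    .evidence_of(readings, scheme), window, params,
                    adherence_fraction = fraction, require_evidence = FALSE)
  } else {
    pattern_finding("smbg_frequency", "adherence", "clear",
                    .empty_evidence(), window, params,
                    adherence_fraction = fraction)
  }
}

#' Run every configured pattern detector
#'
#' Produces exactly one finding per detector in a deterministic order,
#' grouped by the four pattern blocks (hypoglycemia first, then
#' hyperglycemia, variability, adherence). When `active = FALSE` (the
#' sufficiency gate failed) every finding has status `"inactive"`.
#'
#' @param readings [smbg_log()] (clipped to the window internally).
#' @param window [analysis_window()].
#' @param config [analysis_config()].
#' @param active Did the sufficiency gate pass?
#' @param all_evidence Report all qualifying occurrences, not just the
#'   earliest.
#' @return Named list of [pattern_finding()] objects.
#' @export
run_all_patterns <- function(readings, window, config = default_config(),
                             active = TRUE, all_evidence = FALSE) {
  scheme <- config$scheme
  readings <- clip_to_window(readings, window, scheme$day_start_min)
  th <- config$thresholds
  pp <- config$patterns
  hp <- c(config$heuristics,
          list(pattern_count = config$heuristics$pattern_count))

  findings <- list(
    hypo_trend = detect_hypo_trend(readings, window, pp$hypo_trend, th,
                                   scheme, all_evidence),
    hypo_time_block = detect_hypo_time_block(readings, window,
                                             pp$hypo_time_block, th, scheme,
                                             all_evidence),
    very_low_trend = detect_very_low_trend(readings, window,
                                           pp$very_low_trend, scheme),
    hypo_after_hyper = detect_hypo_after_hyper(readings, window, hp, th,
                                               scheme),
    hyper_trend = detect_hyper_trend(readings, window, pp$hyper_trend, th,
                                     scheme, all_evidence),
    hyper_time_block = detect_hyper_time_block(readings, window,
                                               pp$hyper_time_block, th,
                                               scheme, all_evidence),
    very_high_trend = detect_very_high_trend(readings, window,
                                             pp$very_high_trend, scheme),
    hyper_after_hypo = detect_hyper_after_hypo(readings, window, hp, th,
                                               scheme),
    missed_bolus_hyper = detect_missed_bolus_hyper(readings, window, hp, th,
                                                   scheme),
    high_variability = .detect_high_variability(readings, window, config),
    smbg_frequency = assess_adherence(readings, window,
                                      config$adherence$prescribed_tests_per_day,
                                      config$adherence$red_threshold, scheme))
  if (!active) {
    findings <- lapply(findings, function(f) {
      f$status <- "inactive"
      f$evidence <- .empty_evidence()
      f["all_occurrences"] <- NULL
      f
    })
  }
  findings
}

# Variability pattern-block finding: red iff the gate CV exceeds the high
# cutpoint. The platform's variability block lists SD/LBGI/HBGI without a
# red rule; this finding operationalizes the CV gate so the block reports
# a status like the other three.
.detect_high_variability <- function(readings, window, config) {
  params <- config$variability
  if (nrow(readings) < 2L)
    return(pattern_finding("high_variability", "variability", "inactive",
                           .empty_evidence(), window, params,
                           reason = "fewer than 2 readings"))
  rep <- variability_report(readings, config)
  cv <- if (params$gate_metric == "daily_means" &&
            !is.na(rep$daily_means$cv_percent))
    rep$daily_means$cv_percent else rep$cv_percent
  if (cv > params$cv_high) {
    pattern_finding("high_variability", "variability", "red",
                    .evidence_of(readings, config$scheme), window, params,
                    cv_percent = cv)
  } else {
    pattern_finding("high_variability", "variability", "clear",
                    .empty_evidence(), window, params, cv_percent = cv)
  }
}
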