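# Settable ranges and platform defaults for each pattern detector.
# Defaults are the "how the platform works" constants: 2 tests/day on 3
# consecutive days (hyper trend), 1 test above 250 (very high), 1 event/day
# on 2 consecutive days (hypo trend), 2 events in a block over 7 days
# (time block), 1 test below 54 (very low). The hyper time-block detector
# mirrors the hypo one (minimal consistent extension; same ranges).
.pattern_ranges <- list(
  hyper_trend     = list(tests_per_day = c(1, 5),  consecutive_days = c(1, 10)),
  very_high_trend = list(tests = c(1, 10),         level = c(140, 300)),
  hypo_trend      = list(events_per_day = c(1, 5), consecutive_days = c(2, 10)),
  hypo_time_block = list(events_in_block = c(2, 10), days = c(2, 10)),
  hyper_time_block = list(events_in_block = c(2, 10), days = c(2, 10)),
  very_low_trend  = list(tests = c(1, 10),         level = c(50, 80))
)

.pattern_defaults <- list(
  hyper_trend     = list(tests_per_day = 2, consecutive_days = 3),
  very_high_trend = list(tests = 1, level = 250),
  hypo_trend      = list(events_per_day = 1, consecutive_days = 2),
  hypo_time_block = list(events_in_block = 2, days = 7),
  hyper_time_block = list(events_in_block = 2, days = 7),
  very_low_trend  = list(tests = 1, level = 54)
)

#' Pattern-detector parameters with settable-range clamping
#'
#' Returns the full parameter set for every detector, starting from the
#' platform defaults and applying any overrides. Requested values outside a
#' parameter's settable range are clamped to the nearest bound with a
#' warning, never rejected (same contract as [clamp_policy()]).
#'
#' @param ... Named per-detector override lists, e.g.
#'   `hyper_trend = list(tests_per_day = 3)`.
#' @return Named list of class `pattern_params`.
#' @export
pattern_params <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]]))
    overrides <- overrides[[1L]]
  unknown <- setdiff(names(overrides), names(.pattern_defaults))
  if (length(unknown))
    stop("unknown pattern detector(s): ", paste(unknown, collapse = ", "))
  params <- .pattern_defaults
  for (det in names(overrides)) {
    ov <- overrides[[det]]
    bad <- setdiff(names(ov), names(.pattern_defaults[[det]]))
    if (length(bad))
      stop("unknown parameter(s) for ", det, ": ", paste(bad, collapse = ", "))
    params[[det]][names(ov)] <- ov
  }
  for (det in names(params)) {
    for (p in names(params[[det]])) {
      rng <- .pattern_ranges[[det]][[p]]
      v <- params[[det]][[p]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop(det, "$", p, " must be a single finite number")
      cl <- min(max(v, rng[1L]), rng[2L])
      if (cl != v)
        warning(sprintf("%s$%s = %g outside settable range [%g, %g]; clamped to %g",
                        det, p, v, rng[1L], rng[2L], cl))
      params[[det]][[p]] <- cl
    }
  }
  structure(params, class = "pattern_params")
}

#' Settable ranges for pattern parameters
#' @return Nested list detector -> parameter -> `c(min, max)`.
#' @export
pattern_settable_ranges <- function() .pattern_ranges

#' Data-sufficiency policy (flowchart Step 1 and activation gate)
#'
#' Pattern analysis activates only when at least `min_tests_activation`
#' tests (default 72 per 4 weeks, settable 30-120) were performed in the
#' window; Step 1 additionally checks quantity against
#' `min_tests_step1` (default 28 per 2 weeks) and quality as tag coverage:
#' each tag in `required_tag_coverage` must appear at least `min_per_tag`
#' times per 2 weeks. Thresholds are pro-rated linearly by window length
#' and rounded up, preserving the stated test densities.
#'
#' @param min_tests_activation Activation count per 4 weeks (clamped to
#'   30-120 by [clamp_policy()]).
#' @param min_tests_step1 Step-1 quantity minimum per 2 weeks.
#' @param required_tag_coverage Tags that must each be covered.
#' @param min_per_tag Minimum appearances of each required tag per 2 weeks.
#' @return Object of class `sufficiency_policy`.
#' @export
sufficiency_policy <- function(min_tests_activation = 72,
                               min_tests_step1 = 28,
                               required_tag_coverage = c("pre_breakfast",
                                 "post_breakfast", "pre_dinner",
                                 "post_dinner", "bedtime"),
                               min_per_tag = 3) {
  stopifnot(min_tests_step1 >= 1, min_per_tag >= 0)
  bad <- setdiff(required_tag_coverage, smbg_tags())
  if (length(bad)) stop("unknown tag(s) in coverage: ", paste(bad, collapse = ", "))
  structure(list(min_tests_activation = min_tests_activation,
                 activation_settable_range = c(30, 120),
                 min_tests_step1 = min_tests_step1,
                 required_tag_coverage = required_tag_coverage,
                 min_per_tag = min_per_tag),
            class = "sufficiency_policy")
}

#' Clamp a sufficiency policy into its settable range
#'
#' The activation count is clamped into \[30, 120\] with a warning; the
#' policy is never rejected.
#'
#' @param policy A [sufficiency_policy()].
#' @return The clamped policy.
#' @export
clamp_policy <- function(policy) {
  rng <- policy$activation_settable_range
  v <- policy$min_tests_activation
  cl <- min(max(v, rng[1L]), rng[2L])
  if (cl != v) {
    warning(sprintf("min_tests_activation = %g outside settable range [%g, %g]; clamped to %g",
                    v, rng[1L], rng[2L], cl))
    policy$min_tests_activation <- cl
  }
  policy
}

#' Full analysis configuration
#'
#' One object holding every tunable of the pipeline: glycemic thresholds,
#' time-block scheme, sufficiency policy, pattern parameters, variability
#' cutpoints and gate choice, adherence settings, and the off-by-default
#' heuristic detectors (overcorrection pairing, missed bolus).
#'
#' @param thresholds [glycemic_thresholds()].
#' @param scheme [time_block_scheme()].
#' @param sufficiency [sufficiency_policy()] (clamped on construction).
#' @param patterns [pattern_params()].
#' @param cv_low,cv_high CV classification cutpoints in percent: CV below
#'   `cv_low` is low (additionally protective), up to and including
#'   `cv_high` acceptable, above `cv_high` high variability.
#' @param cv_gate_metric Which CV feeds the variability gate: `"overall"`
#'   (all readings pooled, default) or `"daily_means"` (CV of mean daily
#'   glucose).
#' @param prescribed_tests_per_day Prescribed SMBG frequency for the
#'   adherence detector.
#' @param adherence_red_threshold Adherence fraction below which the
#'   adherence finding turns red.
#' @param heuristics_enabled Enable the declared-heuristic detectors
#'   (overcorrection pairs, missed bolus). Off by default.
#' @param pairing_window_hours Max hours between a hyper and a following
#'   hypo (or vice versa) to count as an overcorrection pair.
#' @param heuristic_pattern_count Pairs/events needed to turn a heuristic
#'   detector red.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = glycemic_thresholds(),
                            scheme = time_block_scheme(),
                            sufficiency = sufficiency_policy(),
                            patterns = pattern_params(),
                            cv_low = 33, cv_high = 36,
                            cv_gate_metric = c("overall", "daily_means"),
                            prescribed_tests_per_day = 4,
                            adherence_red_threshold = 0.7,
                            heuristics_enabled = FALSE,
                            pairing_window_hours = 5,
                            heuristic_pattern_count = 1) {
  cv_gate_metric <- match.arg(cv_gate_metric)
  stopifnot(inherits(thresholds, "glycemic_thresholds"),
            inherits(scheme, "time_block_scheme"),
            inherits(sufficiency, "sufficiency_policy"),
            inherits(patterns, "pattern_params"),
            cv_low < cv_high, prescribed_tests_per_day > 0,
            adherence_red_threshold >= 0, adherence_red_threshold <= 1,
            pairing_window_hours > 0, heuristic_pattern_count >= 1)
  structure(list(
    thresholds = thresholds, scheme = scheme,
    sufficiency = clamp_policy(sufficiency), patterns = patterns,
    variability = list(cv_low = cv_low, cv_high = cv_high,
                       gate_metric = cv_gate_metric),
    adherence = list(prescribed_tests_per_day = prescribed_tests_per_day,
                     red_threshold = adherence_red_threshold),
    heuristics = list(enabled = heuristics_enabled,
                      pairing_window_hours = pairing_window_hours,
                      pattern_count = heuristic_pattern_count)),
    class = "analysis_config")
}

#' Default analysis configuration
#' @return [analysis_config()] with all platform defaults.
#' @export
default_config <- function() analysis_config()

# ---- JSON config loading ----------------------------------------------------

.config_known_keys <- c("thresholds", "scheme", "day_start", "sufficiency",
                        "patterns", "variability", "adherence", "heuristics")

#' Read an analysis configuration from JSON
#'
#' Any subset of keys may be present; missing keys take defaults. Unknown
#' top-level keys are rejected (listed in the error) so typos never pass
#' silently. Pattern parameters and the activation count are clamped to
#' their settable ranges with warnings.
#'
#' @param path JSON file path.
#' @return [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config JSON must be an object")
  unknown <- setdiff(names(raw), .config_known_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  args <- list()
  if (!is.null(raw$thresholds))
    args$thresholds <- do.call(glycemic_thresholds, as.list(raw$thresholds))
  day_start <- if (!is.null(raw$day_start)) raw$day_start else "00:00"
  if (!is.null(raw$scheme)) {
    args$scheme <- time_block_scheme(as.data.frame(raw$scheme),
                                     day_start = day_start)
  } else if (!identical(day_start, "00:00")) {
    args$scheme <- time_block_scheme(day_start = day_start)
  }
  if (!is.null(raw$sufficiency))
    args$sufficiency <- do.call(sufficiency_policy, as.list(raw$sufficiency))
  if (!is.null(raw$patterns))
    args$patterns <- pattern_params(lapply(raw$patterns, as.list))
  if (!is.null(raw$variability)) {
    v <- raw$variability
    if (!is.null(v$cv_low)) args$cv_low <- v$cv_low
    if (!is.null(v$cv_high)) args$cv_high <- v$cv_high
    if (!is.null(v$gate_metric)) args$cv_gate_metric <- v$gate_metric
  }
  if (!is.null(raw$adherence)) {
    a <- raw$adherence
    if (!is.null(a$prescribed_tests_per_day))
      args$prescribed_tests_per_day <- a$prescribed_tests_per_day
    if (!is.null(a$red_threshold))
      args$adherence_red_threshold <- a$red_threshold
  }
  if (!is.null(raw$heuristics)) {
    h <- raw$heuristics
    if (!is.null(h$enabled)) args$heuristics_enabled <- h$enabled
    if (!is.null(h$pairing_window_hours))
      args$pairing_window_hours <- h$pairing_window_hours
    if (!is.null(h$pattern_count))
      args$heuristic_pattern_count <- h$pattern_count
  }
  do.call(analysis_config, args)
}

# Serializable plain-list echo of a config (for the report JSON).
.config_echo <- function(config) {
  sch <- config$scheme
  list(
    thresholds = unclass(config$thresholds),
    scheme = list(blocks = data.frame(
      name = sch$blocks$name,
      start = .format_clock_min(sch$blocks$start_min),
      end = .format_clock_min(sch$blocks$end_min),
      stringsAsFactors = FALSE),
      day_start = .format_clock_min(sch$day_start_min)),
    sufficiency = unclass(config$sufficiency),
    patterns = lapply(unclass(config$patterns), unclass),
    variability = config$variability,
    adherence = config$adherence,
    heuristics = config$heuristics)
}
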