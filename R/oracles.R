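# Brute-force reference implementations of every detector rule, written as
# exhaustive enumerations (all candidate day-runs, all sliding windows,
# all reading pairs). They deliberately share no code with the detectors
# in pattern-engine.R: the simulator self-checks injected logs against
# them, and the test suite asserts detector/oracle agreement on random
# logs. Inner counting uses vectorized sum()/any() for speed; the
# enumeration over runs/windows/pairs stays explicit.

#' Brute-force detector oracles
#'
#' Naive reference evaluation of a detector rule by exhaustive
#' enumeration. Used by [simulate_smbg()] to verify injected ground truth
#' and by the test suite as the independent route in detector-equivalence
#' checks. Returns a bare logical (rule fires / does not), never a
#' finding.
#'
#' @param readings [smbg_log()].
#' @param window [analysis_window()].
#' @param params Parameter list for the detector (see [pattern_params()]).
#' @param thresholds [glycemic_thresholds()].
#' @param scheme [time_block_scheme()].
#' @return Logical: does the rule fire on this log?
#' @name oracles
NULL

.oracle_day_classes <- function(readings, thresholds, scheme) {
  list(day = analysis_day(readings$timestamp, scheme$day_start_min),
       cls = as.character(classify_reading(readings$value, readings$tag,
                                           thresholds)))
}

.oracle_run <- function(readings, window, per_day_min, run_len, classes,
                        thresholds, scheme) {
  dc <- .oracle_day_classes(readings, thresholds, scheme)
  all_days <- seq(window$start, window$end, by = "day")
  if (length(all_days) < run_len) return(FALSE)
  hit <- dc$cls %in% classes
  for (s in seq_len(length(all_days) - run_len + 1L)) {
    run_ok <- TRUE
    for (k in seq_len(run_len)) {
      d <- all_days[s + k - 1L]
      if (sum(hit & dc$day == d) < per_day_min) { run_ok <- FALSE; break }
    }
    if (run_ok) return(TRUE)
  }
  FALSE
}

#' @rdname oracles
#' @export
oracle_hyper_trend <- function(readings, window, params,
                               thresholds = glycemic_thresholds(),
                               scheme = time_block_scheme()) {
  .oracle_run(readings, window, params$tests_per_day,
              params$consecutive_days, c("hyper", "very_high"),
              thresholds, scheme)
}

#' @rdname oracles
#' @export
oracle_hypo_trend <- function(readings, window, params,
                              thresholds = glycemic_thresholds(),
                              scheme = time_block_scheme()) {
  .oracle_run(readings, window, params$events_per_day,
              params$consecutive_days, c("hypo", "very_low"),
              thresholds, scheme)
}

#' @rdname oracles
#' @export
oracle_very_high_trend <- function(readings, window, params) {
  sum(readings$value > params$level) >= params$tests
}

#' @rdname oracles
#' @export
oracle_very_low_trend <- function(readings, window, params) {
  sum(readings$value < params$level) >= params$tests
}

.oracle_time_block <- function(readings, window, params, thresholds, scheme,
                               classes) {
  dc <- .oracle_day_classes(readings, thresholds, scheme)
  blk <- if (nrow(readings)) assign_block(readings$timestamp, scheme)
         else character()
  all_days <- seq(window$start, window$end, by = "day")
  hit <- dc$cls %in% classes
  for (bname in scheme$blocks$name) {
    in_block <- hit & blk == bname
    if (sum(in_block) < params$events_in_block) next
    for (s in seq_along(all_days)) {
      lo <- all_days[s]; hi <- lo + params$days - 1L
      if (sum(in_block & dc$day >= lo & dc$day <= hi) >=
          params$events_in_block)
        return(TRUE)
    }
  }
  FALSE
}

#' @rdname oracles
#' @export
oracle_hypo_time_block <- function(readings, window, params,
                                   thresholds = glycemic_thresholds(),
                                   scheme = time_block_scheme()) {
  .oracle_time_block(readings, window, params, thresholds, scheme,
                     c("hypo", "very_low"))
}

#' @rdname oracles
#' @export
oracle_hyper_time_block <- function(readings, window, params,
                                    thresholds = glycemic_thresholds(),
                                    scheme = time_block_scheme()) {
  .oracle_time_block(readings, window, params, thresholds, scheme,
                     c("hyper", "very_high"))
}

.oracle_pairs <- function(readings, params, thresholds, from_cls, to_cls) {
  cls <- as.character(classify_reading(readings$value, readings$tag,
                                       thresholds))
  n <- nrow(readings)
  n_pairs <- 0L
  for (i in seq_len(n)) {
    if (!(cls[i] %in% from_cls)) next
    for (j in seq_len(n)) {
      if (j <= i || !(cls[j] %in% to_cls)) next
      dt <- as.numeric(difftime(readings$timestamp[j], readings$timestamp[i],
                                units = "hours"))
      if (dt > params$pairing_window_hours) next
      between <- setdiff(seq(i, j), c(i, j))
      if (!any(cls[between] == "in_range")) n_pairs <- n_pairs + 1L
    }
  }
  n_pairs >= params$pattern_count
}

#' @rdname oracles
#' @export
oracle_hypo_after_hyper <- function(readings, window, params,
                                    thresholds = glycemic_thresholds(),
                                    scheme = time_block_scheme()) {
  .oracle_pairs(readings, params, thresholds,
                c("hyper", "very_high"), c("hypo", "very_low"))
}

#' @rdname oracles
#' @export
oracle_hyper_after_hypo <- function(readings, window, params,
                                    thresholds = glycemic_thresholds(),
                                    scheme = time_block_scheme()) {
  .oracle_pairs(readings, params, thresholds,
                c("hypo", "very_low"), c("hyper", "very_high"))
}

# named lookup used by the simulator's self-check
.oracle_for <- function(detector) {
  switch(detector,
         hyper_trend = oracle_hyper_trend,
         hypo_trend = oracle_hypo_trend,
         very_high_trend = function(r, w, p, ...) oracle_very_high_trend(r, w, p),
         very_low_trend = function(r, w, p, ...) oracle_very_low_trend(r, w, p),
         hypo_time_block = oracle_hypo_time_block,
         hyper_time_block = oracle_hyper_time_block,
         hypo_after_hyper = oracle_hypo_after_hyper,
         hyper_after_hypo = oracle_hyper_after_hypo,
         stop("no oracle for detector: ", detector))
}
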