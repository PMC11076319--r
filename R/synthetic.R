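#' Structured-SMBG regimen templates
#'
#' `"7point"` is the classic structured-testing profile (pre/post each main
#' meal plus bedtime) performed daily; `"5point"` is a lighter staggered
#' regimen. Custom templates supply `times` ("HH:MM") and matching `tags`.
#'
#' @param name `"7point"`, `"5point"`, or `"custom"`.
#' @param times,tags For custom templates: clock times and tags, equal
#'   length, 1 to 10 points per day.
#' @return Object of class `regimen_template` (data frame `time`, `tag`).
#' @export
regimen_template <- function(name = c("7point", "5point", "custom"),
                             times = NULL, tags = NULL) {
  name <- match.arg(name)
  if (name == "7point") {
    times <- c("07:00", "09:30", "12:00", "14:00", "18:00", "20:00", "22:30")
    tags <- c("pre_breakfast", "post_breakfast", "pre_lunch", "post_lunch",
              "pre_dinner", "post_dinner", "bedtime")
  } else if (name == "5point") {
    times <- c("07:00", "12:00", "14:00", "18:00", "22:30")
    tags <- c("pre_breakfast", "pre_lunch", "post_lunch", "pre_dinner",
              "bedtime")
  }
  stopifnot(!is.null(times), !is.null(tags), length(times) == length(tags),
            length(times) >= 1L, length(times) <= 10L,
            all(tags %in% smbg_tags()))
  structure(data.frame(time = times, tag = tags, stringsAsFactors = FALSE),
            name = name, class = c("regimen_template", "data.frame"))
}

#' Declare a pattern injection for the simulator
#'
#' `magnitude = 0` shapes readings to meet the detector's default trigger
#' exactly; `magnitude = -1` misses it by one unit (one fewer day or
#' event, or a value exactly on a strict threshold).
#'
#' @param pattern Detector id: one of `hypo_trend`, `hyper_trend`,
#'   `very_low_trend`, `very_high_trend`, `hypo_time_block`,
#'   `hyper_time_block`, `hypo_after_hyper`, `hyper_after_hypo`.
#' @param start_day 1-based day index at which the injected pattern starts.
#' @param magnitude 0 (at trigger) or a negative integer (units below).
#' @return Injection descriptor list.
#' @export
injection <- function(pattern, start_day = 8L, magnitude = 0L) {
  stopifnot(pattern %in% c("hypo_trend", "hyper_trend", "very_low_trend",
                           "very_high_trend", "hypo_time_block",
                           "hyper_time_block", "hypo_after_hyper",
                           "hyper_after_hypo"),
            start_day >= 1L, magnitude <= 0L)
  list(pattern = pattern, start_day = as.integer(start_day),
       magnitude = as.integer(magnitude))
}

#' Simulation specification for synthetic SMBG logs
#'
#' The stated world of the generator: a structured regimen followed for
#' `n_days`, glucose drawn lognormally around time-of-day means
#' (`base_mean`, plus `meal_offset` after meals), day-level multiplicative
#' variation targeting `interday_cv_target` percent, additive intraday
#' meter noise, and independent per-reading missingness. All randomness
#' flows from `seed`; runs are bit-reproducible.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_days Number of analysis days (default 28, the activation
#'   horizon).
#' @param start_date First analysis day.
#' @param regimen A [regimen_template()].
#' @param base_mean Baseline mean glucose, mg/dL (default 130, a typical
#'   insulin-treated T2D level).
#' @param meal_offset Post-meal mean increment, mg/dL (default +40).
#' @param interday_cv_target Target interday CV in percent (default 25).
#' @param intraday_noise_sd Additive intraday noise SD, mg/dL (default 15).
#' @param missingness Probability each scheduled test is skipped
#'   (default 0.05).
#' @param injections List of [injection()] descriptors; when any are
#'   present the background is clamped into the in-range band so injected
#'   ground truth is unambiguous.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed, n_days = 28L, start_date = "2024-03-04",
                            regimen = regimen_template("7point"),
                            base_mean = 130, meal_offset = 40,
                            interday_cv_target = 25,
                            intraday_noise_sd = 15,
                            missingness = 0.05,
                            injections = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n_days >= 1L,
            inherits(regimen, "regimen_template"),
            base_mean > 0, meal_offset >= 0, interday_cv_target >= 0,
            intraday_noise_sd >= 0, missingness >= 0, missingness < 1)
  structure(list(seed = as.integer(seed), n_days = as.integer(n_days),
                 start_date = as.Date(start_date), regimen = regimen,
                 base_mean = base_mean, meal_offset = meal_offset,
                 interday_cv_target = interday_cv_target,
                 intraday_noise_sd = intraday_noise_sd,
                 missingness = missingness, injections = injections),
            class = "simulation_spec")
}

# run code under a local, seeded RNG without touching global RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

# value levels used by injections: unambiguous w.r.t. default thresholds
.inject_values <- list(hypo = 62, very_low = 48, hyper = 205,
                       very_high = 260, in_range = 110)

# Materialize one injection as extra readings. `imin` offsets clock
# minutes so multiple injections never collide on a timestamp.
.injection_rows <- function(inj, spec, imin) {
  d0 <- spec$start_date + (inj$start_day - 1L)
  v <- .inject_values
  at <- function(day, clock, value, tag = "other")
    data.frame(timestamp = paste0(format(day), " ", clock),
               value = value, tag = tag, stringsAsFactors = FALSE)
  clock <- function(h, m) sprintf("%02d:%02d", h, m + imin)
  defaults <- .pattern_defaults
  rows <- NULL
  last_day <- d0
  p <- inj$pattern
  if (p %in% c("hypo_trend", "hyper_trend")) {
    def <- defaults[[p]]
    run_len <- def$consecutive_days + inj$magnitude
    per_day <- if (p == "hypo_trend") def$events_per_day else def$tests_per_day
    if (run_len < 1L)
      stop("infeasible injection: run length ", run_len, " for ", p)
    val <- if (p == "hypo_trend") v$hypo else v$hyper
    for (k in seq_len(run_len)) {
      day <- d0 + (k - 1L)
      for (e in seq_len(per_day))
        rows <- rbind(rows, at(day, clock(11L, (e - 1L) * 7L), val))
      last_day <- day
    }
  } else if (p %in% c("very_low_trend", "very_high_trend")) {
    def <- defaults[[p]]
    # magnitude 0: strictly past the level; magnitude < 0: exactly on the
    # strict threshold (does not qualify)
    val <- if (inj$magnitude < 0L) def$level
           else if (p == "very_low_trend") v$very_low else v$very_high
    for (e in seq_len(def$tests))
      rows <- rbind(rows, at(d0, clock(11L, (e - 1L) * 7L), val))
  } else if (p %in% c("hypo_time_block", "hyper_time_block")) {
    def <- defaults[[p]]
    gap <- def$days - 1L - inj$magnitude   # magnitude 0 -> span == days
    val <- if (p == "hypo_time_block") v$hypo else v$hyper
    days <- c(d0, rep(d0 + gap, def$events_in_block - 1L))
    for (e in seq_along(days)) {
      rows <- rbind(rows, at(days[e], clock(3L, (e - 1L) * 7L), val,
                             tag = "night"))
      last_day <- max(last_day, days[e])
    }
  } else if (p %in% c("hypo_after_hyper", "hyper_after_hypo")) {
    first <- if (p == "hypo_after_hyper") v$hyper else v$hypo
    second <- if (p == "hypo_after_hyper") v$hypo else v$hyper
    rows <- rbind(at(d0, clock(1L, 0L), first, "night"),
                  at(d0, clock(3L, 0L), second, "night"))
    if (inj$magnitude < 0L)   # interrupting in-range reading breaks the pair
      rows <- rbind(rows, at(d0, clock(2L, 0L), v$in_range, "night"))
  }
  if (as.integer(last_day - spec$start_date) + 1L > spec$n_days ||
      inj$start_day > spec$n_days)
    stop("infeasible injection: ", p, " starting day ", inj$start_day,
         " does not fit in ", spec$n_days, " days")
  rows
}

#' Simulate a structured SMBG log with known ground truth
#'
#' Generates the regimen's scheduled readings under the spec's noise
#' model, applies missingness, then materializes every injection as
#' additional readings (never dropped). When injections are present the
#' background readings are clamped into the in-range band
#' (90-125 mg/dL) so that the injected patterns are the only pattern
#' evidence in the log; the returned labels state, for each injectable
#' detector, whether its rule must fire. Labels are verified against the
#' brute-force oracles before returning — a label mismatch is a bug and
#' raises an error.
#'
#' @param spec A [simulation_spec()].
#' @param config An [analysis_config()]; injections and the self-check use
#'   its thresholds and scheme with the default pattern parameters.
#' @return List with `readings` (an [smbg_log()]), `window`
#'   ([analysis_window()]), `labels` (named logical; zero-length when the
#'   spec has no injections), and `spec`.
#' @export
simulate_smbg <- function(spec, config = default_config()) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$seed, {
    reg <- spec$regimen
    n_pts <- nrow(reg)
    days <- spec$start_date + seq_len(spec$n_days) - 1L
    sigma_d <- sqrt(log(1 + (spec$interday_cv_target / 100)^2))
    day_mult <- exp(stats::rnorm(spec$n_days, -sigma_d^2 / 2, sigma_d))

    ts <- character(0); val <- numeric(0); tag <- character(0)
    for (di in seq_along(days)) {
      for (pi in seq_len(n_pts)) {
        if (stats::runif(1) < spec$missingness) next
        mu <- spec$base_mean +
          spec$meal_offset * (reg$tag[pi] %in% post_meal_tags())
        x <- day_mult[di] * mu + stats::rnorm(1, 0, spec$intraday_noise_sd)
        ts <- c(ts, paste0(format(days[di]), " ", reg$time[pi]))
        val <- c(val, max(40, min(500, x)))
        tag <- c(tag, reg$tag[pi])
      }
    }

    labels <- logical(0)
    if (length(spec$injections)) {
      # clamp background into the in-range band so injections carry the
      # only pattern evidence
      val <- pmin(pmax(val, 90), 125)
      inj_rows <- NULL
      for (ii in seq_along(spec$injections))
        inj_rows <- rbind(inj_rows,
                          .injection_rows(spec$injections[[ii]], spec,
                                          ii - 1L))
      ts <- c(ts, inj_rows$timestamp)
      val <- c(val, inj_rows$value)
      tag <- c(tag, inj_rows$tag)
      injected <- setNames(rep(FALSE, 0L), character())
      for (inj in spec$injections)
        injected[inj$pattern] <- isTRUE(injected[inj$pattern]) ||
          inj$magnitude == 0L
    }

    log <- smbg_log(timestamp = ts, value = val, tag = tag)
    window <- analysis_window(spec$start_date,
                              spec$start_date + spec$n_days - 1L)

    if (length(spec$injections)) {
      # Intent labels for the targeted patterns are asserted against the
      # brute-force oracles (a mismatch is a generator bug). The remaining
      # injectable detectors get their label *from* the oracle: an
      # injection may fire a sibling rule as a legitimate side effect
      # (e.g. two same-block hyper tests on consecutive days satisfy both
      # the trend and the time-block rule).
      injectable <- c("hypo_trend", "hyper_trend", "very_low_trend",
                      "very_high_trend", "hypo_time_block",
                      "hyper_time_block", "hypo_after_hyper",
                      "hyper_after_hypo")
      pp <- pattern_params()
      hp <- list(pairing_window_hours = config$heuristics$pairing_window_hours,
                 pattern_count = config$heuristics$pattern_count,
                 enabled = TRUE)
      labels <- setNames(rep(FALSE, length(injectable)), injectable)
      for (det in injectable) {
        params <- if (det %in% names(pp)) pp[[det]] else hp
        fired <- .oracle_for(det)(log, window, params, config$thresholds,
                                  config$scheme)
        if (det %in% names(injected) &&
            !identical(unname(fired), unname(injected[[det]])))
          stop("simulator self-check failed: oracle says ", det,
               if (fired) " fires" else " does not fire",
               " but the injection intended otherwise (seed ",
               spec$seed, ")")
        labels[det] <- fired
      }
    }
    list(readings = log, window = window, labels = labels, spec = spec)
  })
}

#' Generate logs matching target CV values
#'
#' For each target, rescales the spec's stochastic amplitude (interday and
#' intraday noise) and resamples until the realized overall CV is within
#' `tol` percentage points of the target, up to `max_retries` attempts.
#' Structural variation that the scale cannot remove (e.g. the post-meal
#' offset) or create (all noise sources zero) can make a target
#' unreachable, which is an error.
#'
#' @param spec A [simulation_spec()] without injections.
#' @param targets Numeric vector of CV targets in percent.
#' @param tol Tolerance in percentage points (default 1).
#' @param max_retries Attempts per target (default 40).
#' @return List with one element per target: `target`, `realized_cv`,
#'   `readings`, `window`, `scale`.
#' @export
sweep_cv <- function(spec, targets, tol = 1, max_retries = 40L) {
  stopifnot(length(spec$injections) == 0L)
  lapply(targets, function(target) {
    stopifnot(target >= 0)
    scale <- if (spec$interday_cv_target > 0) target / spec$interday_cv_target
             else 1
    for (try in seq_len(max_retries)) {
      sp <- spec
      sp$seed <- spec$seed + 7919L * (try - 1L)
      sp$interday_cv_target <- spec$interday_cv_target * scale
      sp$intraday_noise_sd <- spec$intraday_noise_sd * scale
      sim <- simulate_smbg(sp)
      realized <- if (nrow(sim$readings) >= 2L)
        compute_sd_cv(sim$readings$value)$cv_percent else 0
      if (abs(realized - target) <= tol)
        return(list(target = target, realized_cv = realized,
                    readings = sim$readings, window = sim$window,
                    scale = scale))
      if (realized > 0 && target > 0) {
        scale <- scale * target / realized
      } else if (target > 0) {
        scale <- max(scale * 2, 0.5)   # try to create variability
      }
    }
    stop("sweep_cv: could not realize CV target ", target,
         "% within ", max_retries, " attempts (structural variability ",
         "floor/ceiling of the spec)")
  })
}
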