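# Fixture builders shared across test files. All fixtures are built in
# code; no data files.

# quick log builder: vectors of "YYYY-MM-DD HH:MM" stamps and values
make_log <- function(ts, value, tag = "other", bolus = NA) {
  smbg_log(timestamp = ts, value = value, tag = tag, bolus_given = bolus)
}

# n readings/day at fixed value over consecutive days starting start;
# clock times spread through the day
flat_log <- function(n_days, per_day = 4, value = 110,
                     start = "2024-03-04", tag = "other") {
  days <- as.Date(start) + seq_len(n_days) - 1L
  hours <- round(seq(7, 21, length.out = per_day))
  ts <- as.vector(vapply(format(days), function(d)
    sprintf("%s %02d:%02d", d, hours, seq_along(hours)), character(per_day)))
  make_log(ts, rep(value, n_days * per_day), tag)
}

# a sufficiency-passing background log: 7-point regimen, in-range values
background_log <- function(n_days = 28, start = "2024-03-04") {
  sim <- simulate_smbg(simulation_spec(seed = 99, n_days = n_days,
                                       start_date = start,
                                       interday_cv_target = 10,
                                       intraday_noise_sd = 5,
                                       missingness = 0))
  sim$readings
}

# merge extra readings into a log (re-validates, keeps ordering)
add_readings <- function(log, ts, value, tag = "other", bolus = NA) {
  extra <- data.frame(timestamp = ts, value = value, tag = tag,
                      bolus = bolus, stringsAsFactors = FALSE)
  smbg_log(timestamp = c(format(log$timestamp, "%Y-%m-%d %H:%M"), extra$timestamp),
           value = c(log$value, extra$value),
           tag = c(log$tag, extra$tag),
           bolus_given = c(log$bolus_given, extra$bolus))
}

default_window <- function(n_days = 28, start = "2024-03-04") {
  analysis_window(start, as.Date(start) + n_days - 1L)
}

# a random log for property tests: n readings over n_days, values across
# the whole glycemic range, random tags
random_log <- function(n = 60, n_days = 14, start = "2024-03-04") {
  days <- sample(seq_len(n_days), n, replace = TRUE)
  mins <- sample(0:1439, n, replace = TRUE)
  # regenerate on timestamp collision
  key <- paste(days, mins)
  while (anyDuplicated(key)) {
    i <- which(duplicated(key))
    mins[i] <- sample(0:1439, length(i), replace = TRUE)
    key <- paste(days, mins)
  }
  ts <- sprintf("%s %02d:%02d", as.Date(start) + days - 1L,
                mins %/% 60, mins %% 60)
  value <- round(runif(n, 40, 320), 1)
  tag <- sample(smbg_tags(), n, replace = TRUE)
  make_log(ts, value, tag)
}

# random detector params inside the settable ranges
random_params <- function() {
  rng <- pattern_settable_ranges()
  pick <- function(det, p) sample(seq(rng[[det]][[p]][1], rng[[det]][[p]][2]), 1)
  pattern_params(
    hyper_trend = list(tests_per_day = pick("hyper_trend", "tests_per_day"),
                       consecutive_days = pick("hyper_trend", "consecutive_days")),
    very_high_trend = list(tests = pick("very_high_trend", "tests"),
                           level = pick("very_high_trend", "level")),
    hypo_trend = list(events_per_day = pick("hypo_trend", "events_per_day"),
                      consecutive_days = pick("hypo_trend", "consecutive_days")),
    hypo_time_block = list(events_in_block = pick("hypo_time_block", "events_in_block"),
                           days = pick("hypo_time_block", "days")),
    hyper_time_block = list(events_in_block = pick("hyper_time_block", "events_in_block"),
                            days = pick("hyper_time_block", "days")),
    very_low_trend = list(tests = pick("very_low_trend", "tests"),
                          level = pick("very_low_trend", "level")))
}
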