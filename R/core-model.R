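#' Measurement-context tags recognised in an SMBG log
#'
#' Enumerated testing-time contexts for a fingerstick measurement: fasting,
#' pre/post each main meal, bedtime, night, pre-exercise, or other.
#'
#' @format Character vector of valid tag names.
#' @export
smbg_tags <- function() {
  c("fasting", "pre_breakfast", "post_breakfast", "pre_lunch", "post_lunch",
    "pre_dinner", "post_dinner", "bedtime", "night", "pre_exercise", "other")
}

#' Tags that denote a post-prandial measurement
#' @return Character vector (subset of [smbg_tags()]).
#' @export
post_meal_tags <- function() {
  c("post_breakfast", "post_lunch", "post_dinner")
}

# glycemic classes in increasing glucose order; monotone in value for fixed tag
.glycemic_classes <- c("very_low", "hypo", "in_range", "hyper", "very_high")

#' Glycemic classification thresholds (mg/dL)
#'
#' The very-low (54 mg/dL) and very-high (250 mg/dL) limits are the platform
#' rule constants; the hypoglycemia limit and the tag-dependent
#' hyperglycemia limits default to consensus clinical targets
#' (70 / 130 pre-meal / 180 post-meal) and are fully configurable.
#' All comparisons are strict: a value below `hypo_limit` is hypoglycemic,
#' a value above the applicable hyper limit is hyperglycemic.
#'
#' @param hypo_limit Below this value a reading is a hypoglycemic event.
#' @param very_low_limit Below this value a reading is very low.
#' @param hyper_premeal_limit Above this value a pre-meal/other reading is
#'   hyperglycemic.
#' @param hyper_postmeal_limit Above this value a post-meal reading is
#'   hyperglycemic.
#' @param very_high_limit Above this value a reading is very high.
#' @return An object of class `glycemic_thresholds`.
#' @export
glycemic_thresholds <- function(hypo_limit = 70, very_low_limit = 54,
                                hyper_premeal_limit = 130,
                                hyper_postmeal_limit = 180,
                                very_high_limit = 250) {
  t <- list(hypo_limit = hypo_limit, very_low_limit = very_low_limit,
            hyper_premeal_limit = hyper_premeal_limit,
            hyper_postmeal_limit = hyper_postmeal_limit,
            very_high_limit = very_high_limit)
  for (nm in names(t)) {
    if (!is.numeric(t[[nm]]) || length(t[[nm]]) != 1L || !is.finite(t[[nm]]))
      stop("threshold '", nm, "' must be a single finite number")
  }
  if (!(t$very_low_limit < t$hypo_limit &&
        t$hypo_limit < t$hyper_premeal_limit &&
        t$hyper_premeal_limit <= t$hyper_postmeal_limit &&
        t$hyper_postmeal_limit < t$very_high_limit))
    stop("thresholds must satisfy very_low < hypo < hyper_premeal <= ",
         "hyper_postmeal < very_high")
  structure(t, class = "glycemic_thresholds")
}

#' Classify glucose readings into glycemic classes
#'
#' Assigns each reading exactly one of `very_low`, `hypo`, `in_range`,
#' `hyper`, `very_high` (an ordered factor). The hyperglycemia limit is
#' tag-dependent: post-meal tags use `hyper_postmeal_limit`, everything else
#' uses `hyper_premeal_limit`. All comparisons are strict, so a value equal
#' to a limit stays in the lower-severity class.
#'
#' @param value Numeric vector of glucose values, mg/dL.
#' @param tag Character vector of measurement tags (recycled if length 1).
#' @param thresholds A [glycemic_thresholds()] object.
#' @return Ordered factor with levels
#'   `very_low < hypo < in_range < hyper < very_high`.
#' @export
classify_reading <- function(value, tag = "other",
                             thresholds = glycemic_thresholds()) {
  if (length(tag) == 1L) tag <- rep(tag, length(value))
  stopifnot(length(tag) == length(value))
  if (any(!is.finite(value) | value <= 0 | value >= 1000))
    stop("glucose values must be finite and in (0, 1000) mg/dL")
  hi_limit <- ifelse(tag %in% post_meal_tags(),
                     thresholds$hyper_postmeal_limit,
                     thresholds$hyper_premeal_limit)
  cls <- rep("in_range", length(value))
  cls[value > hi_limit] <- "hyper"
  cls[value > thresholds$very_high_limit] <- "very_high"
  cls[value < thresholds$hypo_limit] <- "hypo"
  cls[value < thresholds$very_low_limit] <- "very_low"
  factor(cls, levels = .glycemic_classes, ordered = TRUE)
}

#' Is a glycemic class a hypoglycemic event?
#'
#' Very-low readings also count as hypoglycemic events (class containment),
#' and very-high readings as hyperglycemic.
#' @param cls Factor/character vector of glycemic classes.
#' @return Logical vector.
#' @export
is_hypo_class <- function(cls) as.character(cls) %in% c("very_low", "hypo")

#' @rdname is_hypo_class
#' @export
is_hyper_class <- function(cls) as.character(cls) %in% c("hyper", "very_high")

# ---- time blocks ------------------------------------------------------------

.parse_clock_min <- function(x) {
  # "HH:MM" -> minutes since midnight; "24:00" allowed as day end
  if (is.numeric(x)) return(as.integer(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed clock time: ", paste(x[bad], collapse = ", "))
  h <- as.integer(vapply(m, `[`, "", 2L))
  mi <- as.integer(vapply(m, `[`, "", 3L))
  if (any(h > 24L | mi > 59L | (h == 24L & mi != 0L)))
    stop("clock time out of range: ", paste(x[h > 24L | mi > 59L], collapse = ", "))
  h * 60L + mi
}

.format_clock_min <- function(m) sprintf("%02d:%02d", m %/% 60L, m %% 60L)

#' Partition of the 24-hour day into named time blocks
#'
#' Blocks are half-open intervals `[start, end)` on the clock that must
#' cover the full day with no gap or overlap, so every reading maps to
#' exactly one block. The default scheme is
#' night \[00:00, 06:00), breakfast \[06:00, 10:30), midday \[10:30, 15:00),
#' dinner \[15:00, 21:00), bedtime \[21:00, 24:00).
#'
#' @param blocks Data frame with columns `name`, `start`, `end`
#'   ("HH:MM" strings or minutes since midnight), ordered by start time.
#' @param day_start Clock time at which the analysis day rolls over
#'   (default "00:00"; relevant because nocturnal readings straddle midnight).
#' @return An object of class `time_block_scheme`.
#' @export
time_block_scheme <- function(blocks = NULL, day_start = "00:00") {
  if (is.null(blocks)) {
    blocks <- data.frame(
      name  = c("night", "breakfast", "midday", "dinner", "bedtime"),
      start = c("00:00", "06:00", "10:30", "15:00", "21:00"),
      end   = c("06:00", "10:30", "15:00", "21:00", "24:00"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(blocks), all(c("name", "start", "end") %in% names(blocks)))
  b <- data.frame(name = as.character(blocks$name),
                  start_min = .parse_clock_min(blocks$start),
                  end_min = .parse_clock_min(blocks$end),
                  stringsAsFactors = FALSE)
  b <- b[order(b$start_min), , drop = FALSE]
  if (anyDuplicated(b$name)) stop("duplicate block names")
  if (b$start_min[1L] != 0L || b$end_min[nrow(b)] != 1440L)
    stop("blocks must cover the day from 00:00 to 24:00")
  if (nrow(b) > 1L && any(b$start_min[-1L] != b$end_min[-nrow(b)]))
    stop("blocks must tile the day with no gap or overlap")
  if (any(b$end_min <= b$start_min)) stop("each block must have end > start")
  structure(list(blocks = b, day_start_min = .parse_clock_min(day_start)),
            class = "time_block_scheme")
}

#' @export
print.time_block_scheme <- function(x, ...) {
  cat("Time-block scheme (day starts ", .format_clock_min(x$day_start_min),
      "):\n", sep = "")
  for (i in seq_len(nrow(x$blocks)))
    cat(sprintf("  %-10s [%s, %s)\n", x$blocks$name[i],
                .format_clock_min(x$blocks$start_min[i]),
                .format_clock_min(x$blocks$end_min[i])))
  invisible(x)
}

#' Assign readings to time blocks
#'
#' Total and deterministic: a reading exactly on a boundary goes to the
#' block whose start equals the boundary (half-open convention).
#'
#' @param timestamp POSIXct vector.
#' @param scheme A [time_block_scheme()].
#' @return Character vector of block names.
#' @export
assign_block <- function(timestamp, scheme = time_block_scheme()) {
  lt <- as.POSIXlt(timestamp, tz = .SMBG_TZ)
  minute_of_day <- lt$hour * 60L + lt$min
  idx <- findInterval(minute_of_day, scheme$blocks$start_min)
  scheme$blocks$name[idx]
}

#' Analysis day of each reading
#'
#' The analysis "day" runs from `day_start` to the next `day_start`; with a
#' 03:00 day start a 01:00 reading belongs to the previous calendar day.
#'
#' @param timestamp POSIXct vector.
#' @param day_start_min Minutes after midnight at which the day rolls over.
#' @return `Date` vector.
#' @export
analysis_day <- function(timestamp, day_start_min = 0L) {
  as.Date(as.POSIXct(timestamp, tz = .SMBG_TZ) - day_start_min * 60,
          tz = .SMBG_TZ)
}

#' Group readings by analysis day
#'
#' @param readings An `smbg_log` data frame.
#' @param day_start_min Day rollover in minutes after midnight.
#' @return Named list (ISO date -> readings data frame); empty input gives
#'   an empty list.
#' @export
group_by_day <- function(readings, day_start_min = 0L) {
  if (nrow(readings) == 0L) return(structure(list(), names = character()))
  d <- analysis_day(readings$timestamp, day_start_min)
  split(readings, format(d, "%Y-%m-%d"))
}

# ---- analysis window --------------------------------------------------------

#' Inclusive date window for an analysis run
#'
#' @param start,end `Date` (or coercible) first and last analysis day.
#' @return Object of class `analysis_window` with `$start`, `$end`,
#'   `$n_days`.
#' @export
analysis_window <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("window dates must parse as dates")
  if (end < start) stop("analysis window must have end >= start")
  structure(list(start = start, end = end,
                 n_days = as.integer(end - start) + 1L),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("Analysis window %s .. %s (%d days)\n",
              format(x$start), format(x$end), x$n_days))
  invisible(x)
}

#' Restrict a log to an analysis window
#'
#' @param readings `smbg_log` data frame.
#' @param window [analysis_window()].
#' @param day_start_min Day rollover in minutes after midnight.
#' @return The subset of `readings` whose analysis day falls inside the
#'   window.
#' @export
clip_to_window <- function(readings, window, day_start_min = 0L) {
  if (nrow(readings) == 0L) return(readings)
  d <- analysis_day(readings$timestamp, day_start_min)
  readings[d >= window$start & d <= window$end, , drop = FALSE]
}
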