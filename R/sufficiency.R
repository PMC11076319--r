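# Pro-rate a count threshold stated for a reference horizon to an arbitrary
# window length, preserving density; rounds up so short windows are never
# easier per day than the stated horizon.
.prorate <- function(count, horizon_days, window_days) {
  as.integer(ceiling(count * window_days / horizon_days))
}

#' Assess the quantity and quality of SMBG data (flowchart Step 1)
#'
#' Quantity passes when the window contains at least the pro-rated Step-1
#' minimum (28 tests per 2 weeks by default); quality passes when every
#' required tag reaches its pro-rated minimum coverage; the pattern-analysis
#' gate opens when the pro-rated activation count (72 per 4 weeks by
#' default, settable 30-120) is met. A log with zero readings yields a
#' valid result with all gates false — the insufficient branch is a normal
#' clinical outcome, not an error.
#'
#' @param readings An [smbg_log()]; readings outside `window` are ignored.
#' @param window An [analysis_window()].
#' @param policy A [sufficiency_policy()] (clamped before use).
#' @param scheme A [time_block_scheme()] for per-block counts.
#' @return Object of class `sufficiency_result` with fields `window`,
#'   `total_tests`, `mean_tests_per_day`, `per_block_counts`,
#'   `per_tag_counts`, `thresholds_used`, `quantity_ok`, `quality_ok`,
#'   `pattern_analysis_active`, `deficiencies`.
#' @export
assess_sufficiency <- function(readings, window,
                               policy = sufficiency_policy(),
                               scheme = time_block_scheme()) {
  stopifnot(inherits(window, "analysis_window"))
  if (window$n_days < 1L) stop("empty analysis window")
  policy <- suppressWarnings(clamp_policy(policy))
  readings <- clip_to_window(readings, window, scheme$day_start_min)

  n <- nrow(readings)
  blocks <- scheme$blocks$name
  per_block <- setNames(integer(length(blocks)), blocks)
  if (n > 0L) {
    tab <- table(factor(assign_block(readings$timestamp, scheme),
                        levels = blocks))
    per_block[names(tab)] <- as.integer(tab)
  }
  per_tag <- setNames(integer(length(smbg_tags())), smbg_tags())
  if (n > 0L) {
    tab <- table(factor(readings$tag, levels = smbg_tags()))
    per_tag[names(tab)] <- as.integer(tab)
  }

  need_step1 <- .prorate(policy$min_tests_step1, 14L, window$n_days)
  need_activation <- .prorate(policy$min_tests_activation, 28L, window$n_days)
  need_per_tag <- .prorate(policy$min_per_tag, 14L, window$n_days)

  quantity_ok <- n >= need_step1
  tag_short <- policy$required_tag_coverage[
    per_tag[policy$required_tag_coverage] < need_per_tag]
  quality_ok <- length(tag_short) == 0L
  active <- n >= need_activation

  deficiencies <- character()
  if (!quantity_ok)
    deficiencies <- c(deficiencies,
                      sprintf("too_few_tests:%d/%d", n, need_step1))
  if (!quality_ok)
    deficiencies <- c(deficiencies,
                      paste0("tag_coverage:", tag_short))
  if (!active)
    deficiencies <- c(deficiencies,
                      sprintf("below_activation_count:%d/%d", n, need_activation))

  structure(list(
    window = window,
    total_tests = n,
    mean_tests_per_day = n / window$n_days,
    per_block_counts = as.list(per_block),
    per_tag_counts = as.list(per_tag),
    thresholds_used = list(step1 = need_step1, activation = need_activation,
                           per_tag = need_per_tag),
    quantity_ok = quantity_ok,
    quality_ok = quality_ok,
    pattern_analysis_active = active,
    deficiencies = deficiencies),
    class = "sufficiency_result")
}

#' @export
print.sufficiency_result <- function(x, ...) {
  cat(sprintf("Sufficiency over %s .. %s: %d tests (%.2f/day)\n",
              format(x$window$start), format(x$window$end),
              x$total_tests, x$mean_tests_per_day))
  cat(sprintf("  quantity_ok=%s quality_ok=%s pattern_analysis_active=%s\n",
              x$quantity_ok, x$quality_ok, x$pattern_analysis_active))
  if (length(x$deficiencies))
    cat("  deficiencies:", paste(x$deficiencies, collapse = ", "), "\n")
  invisible(x)
}
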