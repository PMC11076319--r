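#' Mean, SD, and coefficient of variation of a glucose log
#'
#' Sample SD (n-1 denominator); CV = 100 * SD / mean in percent.
#'
#' @param values Numeric glucose values, mg/dL.
#' @return List with `mean`, `sd`, `cv_percent`.
#' @export
compute_sd_cv <- function(values) {
  if (length(values) < 2L)
    stop("variability is undefined for fewer than 2 readings")
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sd = s, cv_percent = 100 * s / m)
}

# Blood-glucose risk transform (mg/dL): f maps the skewed glucose scale
# onto a symmetric risk space with f = 0 at the risk-neutral glucose
# (~112.5 mg/dL); r = 10 f^2 is the per-reading risk.
.bg_risk_f <- function(bg) 1.509 * (log(bg)^1.084 - 5.381)

#' Risk-neutral glucose of the LBGI/HBGI transform
#'
#' The glucose value (mg/dL) at which the risk transform is exactly zero:
#' `exp(5.381^(1/1.084))`, about 112.5 mg/dL.
#' @return Single numeric, mg/dL.
#' @export
risk_neutral_glucose <- function() exp(5.381^(1 / 1.084))

#' Low and high blood glucose indices (LBGI / HBGI)
#'
#' Risk-space symmetrization of the glucose scale:
#' `f(BG) = 1.509 * ((ln BG)^1.084 - 5.381)` for BG in mg/dL,
#' `r(BG) = 10 * f(BG)^2`. LBGI is the mean of `r` over readings with
#' `f < 0` (0 contribution otherwise); HBGI the mean over readings with
#' `f > 0`. Both are non-negative and `lbgi + hbgi` equals the mean total
#' risk over all readings.
#'
#' @param values Numeric glucose values, mg/dL (all positive).
#' @return List with `lbgi`, `hbgi`.
#' @export
compute_lbgi_hbgi <- function(values) {
  if (length(values) < 1L) stop("LBGI/HBGI require at least one reading")
  if (any(values <= 0)) stop("glucose values must be positive")
  f <- .bg_risk_f(values)
  r <- 10 * f^2
  list(lbgi = mean(r * (f < 0)), hbgi = mean(r * (f > 0)))
}

#' Classify a CV value against the variability cutpoints
#'
#' `low` below the low cutpoint (default 33%, additionally protective
#' against hypoglycemia), `acceptable` up to and including the high
#' cutpoint (default 36%), `high` above it. Both boundary values fall in
#' `acceptable` (strict `< 33`, inclusive `<= 36`).
#'
#' @param cv_percent CV in percent.
#' @param cv_low,cv_high Cutpoints in percent.
#' @return One of `"low"`, `"acceptable"`, `"high"`.
#' @export
classify_cv <- function(cv_percent, cv_low = 33, cv_high = 36) {
  stopifnot(length(cv_percent) == 1L, is.finite(cv_percent))
  if (cv_percent < cv_low) "low"
  else if (cv_percent <= cv_high) "acceptable"
  else "high"
}

#' Full glycemic-variability report
#'
#' Computes mean, SD, CV, LBGI and HBGI over all readings in the log, plus
#' the interday view on daily means ("CV of mean daily glucose"): SD/CV of
#' the per-analysis-day mean glucose. The categorical `cv_class` applies
#' the configured cutpoints to the gate metric chosen in the config
#' (overall CV by default).
#'
#' @param readings An [smbg_log()] with at least 2 readings.
#' @param config An [analysis_config()] (cutpoints, gate metric, scheme).
#' @return Object of class `variability_report`.
#' @export
variability_report <- function(readings, config = default_config()) {
  basic <- compute_sd_cv(readings$value)
  risk <- compute_lbgi_hbgi(readings$value)
  day <- analysis_day(readings$timestamp, config$scheme$day_start_min)
  daily_mean <- tapply(readings$value, format(day), mean)
  if (length(daily_mean) >= 2L) {
    dm <- compute_sd_cv(as.numeric(daily_mean))
    daily <- list(mean = dm$mean, sd = dm$sd, cv_percent = dm$cv_percent)
  } else {
    daily <- list(mean = as.numeric(daily_mean)[1L], sd = NA_real_,
                  cv_percent = NA_real_)
  }
  v <- config$variability
  gate_cv <- if (v$gate_metric == "daily_means" && !is.na(daily$cv_percent))
    daily$cv_percent else basic$cv_percent
  structure(list(
    n_readings = nrow(readings),
    mean_glucose = basic$mean,
    sd = basic$sd,
    cv_percent = basic$cv_percent,
    lbgi = risk$lbgi,
    hbgi = risk$hbgi,
    daily_means = daily,
    gate_metric = v$gate_metric,
    gate_cv_percent = gate_cv,
    cv_class = classify_cv(gate_cv, v$cv_low, v$cv_high)),
    class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf(
    "Variability (n=%d): mean %.1f, SD %.1f, CV %.1f%% (%s), LBGI %.2f, HBGI %.2f\n",
    x$n_readings, x$mean_glucose, x$sd, x$cv_percent, x$cv_class,
    x$lbgi, x$hbgi))
  invisible(x)
}
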