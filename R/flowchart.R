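# Canonical priority order of action flags: hypoglycemia-derived flags
# first (Priority 1 - Hypoglycemia), then hyperglycemia, then the
# variability gate and adherence/education flags.
.flag_priority <- c(
  "review_correction_rules",
  "consider_deintensify_treatment",
  "consider_intensify_treatment",
  "review_isf_carb_ratio",
  "intensify_smbg_before_change",
  "reinforce_lifestyle",
  "investigate_low_adherence",
  "plan_education_session",
  "review_single_events")

.flag_rationale <- c(
  review_correction_rules =
    "Hypoglycemic pattern detected: review the rules used to correct low and high glucose.",
  consider_deintensify_treatment =
    "Hypoglycemic pattern detected: consider de-intensifying ongoing treatment.",
  consider_intensify_treatment =
    "Hyperglycemic pattern detected: consider intensifying ongoing treatment.",
  review_isf_carb_ratio =
    "Missed-bolus hyperglycemia detected: review insulin sensitivity factor and carb ratio.",
  intensify_smbg_before_change =
    "High glycemic variability: intensify SMBG before changing therapy (treatment-change flags suppressed).",
  reinforce_lifestyle =
    "Pattern detected: reinforce lifestyle measures (balanced diet, regular exercise, no skipped meals).",
  investigate_low_adherence =
    "Quantity/quality of SMBG data insufficient: investigate reasons for low adherence to the testing prescription.",
  plan_education_session =
    "Insufficient SMBG data: plan an educational session on the value of structured testing.",
  review_single_events =
    "Before the next visit, examine single hypoglycemic and hyperglycemic events.")

.treatment_change_flags <- c("consider_intensify_treatment",
                             "consider_deintensify_treatment")

.action_flag <- function(code, triggered_by) {
  list(code = code, triggered_by = sort(unique(triggered_by)),
       rationale = unname(.flag_rationale[[code]]))
}

# assemble, dedupe (merging triggered_by) and priority-sort a flag list
.finalize_flags <- function(flags) {
  codes <- vapply(flags, `[[`, "", "code")
  out <- lapply(unique(codes), function(cd) {
    trig <- unlist(lapply(flags[codes == cd], `[[`, "triggered_by"))
    .action_flag(cd, trig)
  })
  ord <- order(match(vapply(out, `[[`, "", "code"), .flag_priority))
  out[ord]
}

# Step-3 mapping from findings + variability class to categorical flags.
.derive_actions <- function(findings, cv_class) {
  red <- names(findings)[vapply(findings, function(f) f$status == "red",
                                TRUE)]
  flags <- list()
  hypo_red <- red[vapply(findings[red], function(f)
    f$block == "hypoglycemia", TRUE)]
  hyper_red <- red[vapply(findings[red], function(f)
    f$block == "hyperglycemia", TRUE)]
  if (length(hypo_red)) {
    flags <- c(flags, list(.action_flag("review_correction_rules", hypo_red),
                           .action_flag("consider_deintensify_treatment",
                                        hypo_red)))
  }
  if (length(hyper_red))
    flags <- c(flags, list(.action_flag("consider_intensify_treatment",
                                        hyper_red)))
  if ("missed_bolus_hyper" %in% red)
    flags <- c(flags, list(.action_flag("review_isf_carb_ratio",
                                        "missed_bolus_hyper")))
  if ("smbg_frequency" %in% red)
    flags <- c(flags, list(.action_flag("investigate_low_adherence",
                                        "smbg_frequency")))
  pattern_red <- setdiff(red, "smbg_frequency")
  if (length(pattern_red))
    flags <- c(flags, list(.action_flag("reinforce_lifestyle", pattern_red)))
  if (identical(cv_class, "high")) {
    # variability gate: intensify SMBG first; therapy-change flags are
    # unsafe under high variability and are suppressed
    flags <- Filter(function(f) !(f$code %in% .treatment_change_flags),
                    flags)
    flags <- c(flags, list(.action_flag("intensify_smbg_before_change",
                                        "variability_gate")))
  }
  .finalize_flags(flags)
}

.insufficient_actions <- function(deficiencies) {
  .finalize_flags(list(
    .action_flag("investigate_low_adherence", "sufficiency_gate"),
    .action_flag("plan_education_session", "sufficiency_gate"),
    .action_flag("review_single_events", "sufficiency_gate")))
}

# per-analysis-day x per-block reading-count matrix (the text analogue of
# the platform's distribution chart)
.day_block_matrix <- function(readings, window, scheme) {
  days <- format(seq(window$start, window$end, by = "day"))
  blocks <- scheme$blocks$name
  m <- matrix(0L, nrow = length(days), ncol = length(blocks),
              dimnames = list(days, blocks))
  if (nrow(readings)) {
    d <- format(analysis_day(readings$timestamp, scheme$day_start_min))
    b <- assign_block(readings$timestamp, scheme)
    tab <- table(factor(d, levels = days), factor(b, levels = blocks))
    m[] <- as.integer(tab)
  }
  df <- data.frame(day = days, m, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  df
}

#' Run the full 3-step SMBG analysis flowchart
#'
#' Step 1 gates on data sufficiency; if the gate fails, every detector is
#' reported inactive and the low-adherence actions are emitted (examine
#' single events, plan education, investigate adherence). Otherwise Step 2
#' runs all pattern detectors and Step 3 computes glycemic variability and
#' maps red findings to categorical action flags, with the variability
#' gate: under high CV the treatment-change flags are suppressed in favour
#' of `intensify_smbg_before_change`.
#'
#' @param readings An [smbg_log()].
#' @param window An [analysis_window()].
#' @param config An [analysis_config()].
#' @param all_evidence Report every qualifying occurrence per detector.
#' @return Object of class `analysis_report` with fields `schema_version`,
#'   `window`, `sufficiency`, `patterns`, `variability` (NULL when
#'   inactive), `actions`, `day_block_matrix`, `config`, `provenance`.
#' @export
run_flowchart <- function(readings, window, config = default_config(),
                          all_evidence = FALSE) {
  stopifnot(inherits(readings, "smbg_log"),
            inherits(window, "analysis_window"),
            inherits(config, "analysis_config"))
  scheme <- config$scheme
  inwin <- clip_to_window(readings, window, scheme$day_start_min)

  suff <- assess_sufficiency(inwin, window, config$sufficiency, scheme)
  # the pattern stage runs only when the activation count is met and the
  # Step-1 quantity/quality checks pass
  active <- suff$pattern_analysis_active && suff$quantity_ok && suff$quality_ok
  findings <- run_all_patterns(inwin, window, config, active = active,
                               all_evidence = all_evidence)
  if (active) {
    vr <- variability_report(inwin, config)
    actions <- .derive_actions(findings, vr$cv_class)
  } else {
    vr <- NULL
    actions <- .insufficient_actions(suff$deficiencies)
  }
  structure(list(
    schema_version = 1L,
    window = list(start = format(window$start), end = format(window$end),
                  n_days = window$n_days),
    sufficiency = suff,
    patterns = findings,
    variability = vr,
    actions = actions,
    day_block_matrix = .day_block_matrix(inwin, window, scheme),
    config = .config_echo(config),
    provenance = list(tool = "smbgflow",
                      version = as.character(utils::packageVersion("smbgflow")),
                      n_readings_input = nrow(readings),
                      n_readings_in_window = nrow(inwin),
                      input_digest = .log_digest(readings))),
    class = "analysis_report")
}

# md5 of the canonical CSV serialization of the input log (no timestamps
# anywhere in the report, so repeated runs are byte-identical)
.log_digest <- function(readings) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_smbg_csv(readings, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_text_report(x))
  invisible(x)
}

#' Compare two disjoint analysis periods
#'
#' Runs the flowchart on both windows and reports per-metric deltas
#' (B minus A) for mean, SD, CV, LBGI, HBGI, per-block hypoglycemic and
#' hyperglycemic counts, and the pattern status transition of every
#' detector (e.g. `"clear->red"`). Both windows must contain readings;
#' an empty window is an error, distinct from a zero delta.
#'
#' @param readings An [smbg_log()].
#' @param window_a,window_b Disjoint [analysis_window()]s.
#' @param config An [analysis_config()].
#' @return Object of class `period_comparison` with `report_a`, `report_b`,
#'   `deltas`, `transitions`.
#' @export
compare_periods <- function(readings, window_a, window_b,
                            config = default_config()) {
  if (!(window_a$end < window_b$start || window_b$end < window_a$start))
    stop("comparison windows must be disjoint")
  ds <- config$scheme$day_start_min
  ra <- clip_to_window(readings, window_a, ds)
  rb <- clip_to_window(readings, window_b, ds)
  if (nrow(ra) < 2L) stop("window A has fewer than 2 readings; nothing to compare")
  if (nrow(rb) < 2L) stop("window B has fewer than 2 readings; nothing to compare")

  rep_a <- run_flowchart(readings, window_a, config)
  rep_b <- run_flowchart(readings, window_b, config)

  va <- variability_report(ra, config)
  vb <- variability_report(rb, config)
  deltas <- list(mean_glucose = vb$mean_glucose - va$mean_glucose,
                 sd = vb$sd - va$sd,
                 cv_percent = vb$cv_percent - va$cv_percent,
                 lbgi = vb$lbgi - va$lbgi,
                 hbgi = vb$hbgi - va$hbgi)

  blocks <- config$scheme$blocks$name
  block_counts <- function(r) {
    cls <- classify_reading(r$value, r$tag, config$thresholds)
    b <- factor(assign_block(r$timestamp, config$scheme), levels = blocks)
    list(hypo = as.list(as.integer(table(b[is_hypo_class(cls)]))),
         hyper = as.list(as.integer(table(b[is_hyper_class(cls)]))))
  }
  ca <- block_counts(ra); cb <- block_counts(rb)
  deltas$per_block_hypo <- setNames(
    as.list(unlist(cb$hypo) - unlist(ca$hypo)), blocks)
  deltas$per_block_hyper <- setNames(
    as.list(unlist(cb$hyper) - unlist(ca$hyper)), blocks)

  transitions <- lapply(names(rep_a$patterns), function(d) {
    paste0(rep_a$patterns[[d]]$status, "->", rep_b$patterns[[d]]$status)
  })
  names(transitions) <- names(rep_a$patterns)

  structure(list(report_a = rep_a, report_b = rep_b, deltas = deltas,
                 transitions = transitions),
            class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat("Period comparison (B - A):\n")
  for (m in c("mean_glucose", "sd", "cv_percent", "lbgi", "hbgi"))
    cat(sprintf("  %-14s %+0.2f\n", m, x$deltas[[m]]))
  changed <- Filter(function(t) {
    p <- strsplit(t, "->", fixed = TRUE)[[1L]]
    p[1L] != p[2L]
  }, x$transitions)
  if (length(changed)) {
    cat("  pattern transitions:\n")
    for (d in names(changed)) cat(sprintf("    %s: %s\n", d, changed[[d]]))
  } else cat("  no pattern status changes\n")
  invisible(x)
}
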