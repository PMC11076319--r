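# Convert an analysis_report (S3 objects throughout) into the plain-list
# payload that is serialized to JSON. render_text_report() also works on
# this payload so that a report read back from JSON renders identically.
.report_payload <- function(report) {
  if (!inherits(report, "analysis_report")) return(report)
  suff <- unclass(report$sufficiency)
  suff$window <- list(start = format(suff$window$start),
                      end = format(suff$window$end),
                      n_days = suff$window$n_days)
  patterns <- lapply(report$patterns, function(f) {
    f <- unclass(f)
    f$params_used <- lapply(f$params_used, function(p) p)
    f
  })
  vr <- if (is.null(report$variability)) NULL else unclass(report$variability)
  list(schema_version = report$schema_version,
       window = report$window,
       sufficiency = suff,
       patterns = patterns,
       variability = vr,
       actions = report$actions,
       day_block_matrix = report$day_block_matrix,
       config = report$config,
       provenance = report$provenance)
}

#' Serialize an analysis report to JSON
#'
#' Deterministic serialization: stable key order, fixed number formatting
#' (10 significant digits), `dataframe = "rows"` for evidence tables.
#' Identical inputs and config yield byte-identical JSON.
#'
#' @param report An `analysis_report` (or `period_comparison`).
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  payload <- if (inherits(report, "period_comparison")) {
    list(schema_version = 1L,
         report_a = .report_payload(report$report_a),
         report_b = .report_payload(report$report_b),
         deltas = report$deltas,
         transitions = report$transitions)
  } else .report_payload(report)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                   na = "null", null = "null", dataframe = "rows")
}

#' Write a report JSON file atomically
#'
#' Writes to a temporary file in the target directory and renames it into
#' place, so a failed run never leaves a partial report.
#'
#' @param report An `analysis_report` or `period_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- report_to_json(report)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  writeLines(json, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not write report to ", path)
  }
  invisible(path)
}

#' Read a report JSON file back into a payload list
#'
#' @param path Report JSON path.
#' @return Plain-list report payload (renderable by
#'   [render_text_report()]).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

.fmt_num <- function(x, digits = 2) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return("NA")
  formatC(as.numeric(x), format = "f", digits = digits)
}

#' Render a report as human-readable text
#'
#' A plain-text account of the analysis: mean tests/day, the per-day x
#' per-block count matrix, detector statuses grouped by pattern block,
#' variability metrics, and action flags in priority order. Deterministic
#' for a fixed report; rendering a report read back from its JSON gives
#' the identical text.
#'
#' @param report An `analysis_report` or a payload from [read_report()].
#' @return A single string.
#' @export
render_text_report <- function(report) {
  r <- .report_payload(report)
  out <- character()
  push <- function(...) out <<- c(out, sprintf(...))

  push("SMBG pattern analysis report (schema v%d)", r$schema_version)
  push("Window: %s .. %s (%d days)", r$window$start, r$window$end,
       as.integer(r$window$n_days))
  push("")
  s <- r$sufficiency
  push("== Step 1: data sufficiency ==")
  push("Total tests: %d (mean %s/day)", as.integer(s$total_tests),
       .fmt_num(s$mean_tests_per_day))
  push("quantity_ok: %s   quality_ok: %s   pattern_analysis_active: %s",
       s$quantity_ok, s$quality_ok, s$pattern_analysis_active)
  defs <- unlist(s$deficiencies)
  if (length(defs)) push("deficiencies: %s", paste(defs, collapse = ", "))
  push("")
  push("Tests per day and time block:")
  m <- as.data.frame(r$day_block_matrix, stringsAsFactors = FALSE)
  blocks <- setdiff(names(m), "day")
  push("  %-12s %s", "day", paste(sprintf("%9s", blocks), collapse = " "))
  for (i in seq_len(nrow(m)))
    push("  %-12s %s", m$day[i],
         paste(sprintf("%9d", as.integer(m[i, blocks])), collapse = " "))
  push("")

  push("== Step 2: pattern analysis ==")
  pats <- r$patterns
  statuses <- vapply(pats, function(f) as.character(f$status), "")
  if (!any(statuses == "red")) push("no patterns detected")
  for (blk in c("hypoglycemia", "hyperglycemia", "variability",
                "adherence")) {
    in_blk <- names(pats)[vapply(pats, function(f)
      identical(as.character(f$block), blk), TRUE)]
    if (!length(in_blk)) next
    push("[%s]", blk)
    for (d in in_blk) {
      f <- pats[[d]]
      extra <- ""
      if (!is.null(f$note)) extra <- paste0(extra, " (", f$note, ")")
      if (!is.null(f$time_block))
        extra <- paste0(extra, " block=", f$time_block)
      if (!is.null(f$adherence_fraction))
        extra <- paste0(extra, " fraction=", .fmt_num(f$adherence_fraction))
      push("  %-20s %s%s", d, toupper(as.character(f$status)), extra)
      ev <- f$evidence
      if (identical(as.character(f$status), "red") && length(ev) &&
          NROW(ev) > 0L) {
        ev <- as.data.frame(ev, stringsAsFactors = FALSE)
        for (i in seq_len(nrow(ev)))
          push("      row %d  %s  %s mg/dL  [%s/%s]",
               as.integer(ev$row_id[i]), ev$timestamp[i],
               .fmt_num(ev$value[i], 0), ev$day[i], ev$block[i])
      }
    }
  }
  push("")

  push("== Step 3: variability and actions ==")
  v <- r$variability
  if (is.null(v) || length(v) == 0L) {
    push("variability: not computed (pattern analysis inactive)")
  } else {
    push("mean %s mg/dL  SD %s  CV %s%%  LBGI %s  HBGI %s",
         .fmt_num(v$mean_glucose, 1), .fmt_num(v$sd, 1),
         .fmt_num(v$cv_percent, 1), .fmt_num(v$lbgi), .fmt_num(v$hbgi))
    dmcv <- v$daily_means$cv_percent
    push("CV of mean daily glucose: %s%%",
         if (is.null(dmcv) || is.na(dmcv)) "NA" else .fmt_num(dmcv, 1))
    push("variability class (%s CV): %s", v$gate_metric, v$cv_class)
  }
  push("")
  acts <- r$actions
  if (length(acts) == 0L) {
    push("actions: none")
  } else {
    push("actions (priority order):")
    # actions may arrive as a list of lists or a simplified data frame
    if (is.data.frame(acts)) {
      for (i in seq_len(nrow(acts))) {
        trig <- acts$triggered_by[[i]]
        push("  %d. %s  [%s]", i, acts$code[i], paste(trig, collapse = ","))
        push("     %s", acts$rationale[i])
      }
    } else {
      for (i in seq_along(acts)) {
        push("  %d. %s  [%s]", i, acts[[i]]$code,
             paste(acts[[i]]$triggered_by, collapse = ","))
        push("     %s", acts[[i]]$rationale)
      }
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
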