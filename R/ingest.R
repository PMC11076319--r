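#' Construct a validated SMBG log
#'
#' An `smbg_log` is a data frame with one row per fingerstick measurement:
#' `timestamp` (POSIXct, minute resolution, UTC clock), `value` (mg/dL),
#' `tag` (one of [smbg_tags()]), optional `bolus_given` / `carbs_logged`
#' logicals (NA = not recorded), and `row_id`, the 1-based row index of the
#' source CSV used to reference evidence in reports.
#'
#' Validation rejects physically impossible values (outside (0, 1000) mg/dL),
#' unknown tags, and duplicate timestamps (meters never produce true
#' duplicates; a double import does), identifying the offending rows.
#'
#' @param timestamp POSIXct vector (or parseable strings).
#' @param value Numeric glucose values in mg/dL.
#' @param tag Character tags; defaults to "other".
#' @param bolus_given,carbs_logged Optional logical vectors (NA allowed).
#' @param row_id Optional integer row references; defaults to 1..n.
#' @return Data frame of class `smbg_log`, sorted by timestamp.
#' @export
smbg_log <- function(timestamp, value, tag = "other",
                     bolus_given = NA, carbs_logged = NA, row_id = NULL) {
  timestamp <- .parse_timestamp(timestamp)
  n <- length(timestamp)
  if (length(tag) == 1L) tag <- rep(tag, n)
  if (length(bolus_given) == 1L) bolus_given <- rep(bolus_given, n)
  if (length(carbs_logged) == 1L) carbs_logged <- rep(carbs_logged, n)
  if (is.null(row_id)) row_id <- seq_len(n)
  stopifnot(length(value) == n, length(tag) == n, length(row_id) == n)

  bad_val <- !is.finite(value) | value <= 0 | value >= 1000
  if (any(bad_val))
    stop("invalid glucose value (must be in (0, 1000) mg/dL) at row(s): ",
         paste(row_id[bad_val], collapse = ", "))
  bad_tag <- !(tag %in% smbg_tags())
  if (any(bad_tag))
    stop("unknown measurement tag '", tag[which(bad_tag)[1L]],
         "' at row(s): ", paste(row_id[bad_tag], collapse = ", "))
  dup <- duplicated(timestamp)
  if (any(dup))
    stop("duplicate timestamp(s) in log at row(s): ",
         paste(row_id[dup], collapse = ", "),
         " (duplicates are rejected at ingest)")

  out <- data.frame(timestamp = timestamp, value = as.numeric(value),
                    tag = as.character(tag),
                    bolus_given = as.logical(bolus_given),
                    carbs_logged = as.logical(carbs_logged),
                    row_id = as.integer(row_id),
                    stringsAsFactors = FALSE)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("smbg_log", "data.frame")
  out
}

.parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = .SMBG_TZ),
                                                tz = .SMBG_TZ))
  x <- as.character(x)
  # accept ISO-8601 with 'T' or space separator, seconds optional
  x2 <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x2, tz = .SMBG_TZ,
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  if (anyNA(out))
    stop("unparseable timestamp(s): ",
         paste(utils::head(x[is.na(out)], 5L), collapse = ", "))
  out
}

#' Read an SMBG readings CSV
#'
#' Expected RFC-4180 CSV with header
#' `timestamp,value_mgdl,tag,bolus_given,carbs_logged`; timestamps ISO-8601
#' local time, booleans `true`/`false`/empty (empty = unknown). Values may
#' alternatively be supplied in mmol/L via `unit = "mmol"`; they are
#' converted once at ingest (factor 18.016) and mg/dL is the only internal
#' unit.
#'
#' @param path CSV file path.
#' @param unit `"mgdl"` (default) or `"mmol"`.
#' @return An [smbg_log()].
#' @export
read_smbg_csv <- function(path, unit = c("mgdl", "mmol")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("timestamp", "value_mgdl", "tag")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("readings CSV is missing column(s): ", paste(missing, collapse = ", "))
  n <- nrow(df)
  val <- suppressWarnings(as.numeric(df$value_mgdl))
  if (anyNA(val))
    stop("non-numeric glucose value at CSV row(s): ",
         paste(which(is.na(val)), collapse = ", "))
  if (unit == "mmol") val <- val * 18.016
  parse_bool <- function(col) {
    if (is.null(col)) return(rep(NA, n))
    col <- tolower(trimws(col))
    out <- rep(NA, n)
    out[col %in% c("true", "1")] <- TRUE
    out[col %in% c("false", "0")] <- FALSE
    out
  }
  smbg_log(timestamp = df$timestamp, value = val, tag = df$tag,
           bolus_given = parse_bool(df$bolus_given),
           carbs_logged = parse_bool(df$carbs_logged),
           row_id = seq_len(n))
}

#' Write an SMBG log in the canonical CSV dialect
#'
#' @param readings An [smbg_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smbg_csv <- function(readings, path) {
  fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))
  out <- data.frame(
    timestamp = format(readings$timestamp, "%Y-%m-%dT%H:%M", tz = .SMBG_TZ),
    value_mgdl = readings$value,
    tag = readings$tag,
    bolus_given = fmt_bool(readings$bolus_given),
    carbs_logged = fmt_bool(readings$carbs_logged),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.smbg_log <- function(x, ...) {
  cat(sprintf("SMBG log: %d readings", nrow(x)))
  if (nrow(x))
    cat(sprintf(" (%s .. %s), mean %.1f mg/dL",
                format(min(x$timestamp), "%Y-%m-%d %H:%M"),
                format(max(x$timestamp), "%Y-%m-%d %H:%M"),
                mean(x$value)))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
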