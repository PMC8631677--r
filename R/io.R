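# Delimited-text readers/writers for the pipeline's table formats.
# All tables are comma-separated with a required header; timestamps are ISO
# 8601 local clock time ("2018-06-02T14:05:10" or with a space separator) and
# no timezone arithmetic is applied.

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  x <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop_buzz("row", sprintf("unparseable timestamp(s) at row(s): %s",
                             paste(utils::head(bad, 5), collapse = ", ")))
  out
}

check_columns <- function(df, needed, what) {
  miss <- setdiff(needed, colnames(df))
  if (length(miss))
    stop_buzz("schema", sprintf("%s is missing column(s): %s", what,
                                paste(miss, collapse = ", ")))
  invisible(df)
}

#' Read a click-train table
#'
#' Reads a CSV with one row per click (columns `train_id`, `source_id`,
#' `context`, `click_time_s`, optional `timestamp` giving the absolute time
#' of the train's first click) and assembles [click_train()] objects grouped
#' by `train_id`, clicks sorted by time. Duplicate `(train_id, click_time_s)`
#' rows are collapsed with a warning.
#'
#' @param path Path to the CSV file.
#' @return A named list of [click_train()] objects (in first-appearance
#'   order of `train_id`).
#' @export
read_click_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("train_id", "source_id", "context", "click_time_s"),
                basename(path))
  if (nrow(df) == 0L) {
    warning(sprintf("%s holds no clicks; returning an empty dataset",
                    basename(path)))
    return(structure(list(), names = character(0)))
  }
  dup <- duplicated(df[, c("train_id", "click_time_s")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate (train_id, click_time_s) row(s)",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  ids <- unique(df$train_id)
  trains <- lapply(ids, function(id) {
    sub <- df[df$train_id == id, , drop = FALSE]
    sub <- sub[order(sub$click_time_s), , drop = FALSE]
    t0 <- if ("timestamp" %in% colnames(sub) && !all(is.na(sub$timestamp)))
      parse_timestamp(sub$timestamp[1L]) else NULL
    click_train(id, sub$click_time_s, source_id = sub$source_id[1L],
                context = sub$context[1L], t0 = t0)
  })
  names(trains) <- ids
  trains
}

#' Write a click-train table
#'
#' Inverse of [read_click_table()].
#'
#' @param trains List of [click_train()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_click_table <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    # %.17g so that re-read click times (hence features) are bit-identical
    data.frame(train_id = tr$train_id, source_id = tr$source_id,
               context = tr$context,
               click_time_s = sprintf("%.17g", tr$click_times),
               timestamp = if (is.null(tr$t0)) NA_character_
                           else format(tr$t0, "%Y-%m-%dT%H:%M:%OS3"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a detection-event table
#'
#' CSV with columns `timestamp`, `signal_type` (`echolocation`, `call`,
#' `whistle`), `instrument` (`broadband_recorder`, `click_logger`).
#'
#' @param path Path to the CSV file.
#' @return Data frame with a parsed `POSIXct` `timestamp` column.
#' @export
read_detection_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("timestamp", "signal_type", "instrument"),
                basename(path))
  df$timestamp <- parse_timestamp(df$timestamp)
  df
}

#' Read a weir-count table
#'
#' CSV with columns `date` (ISO 8601), `species`, `count`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with `date` parsed as `Date`.
#' @export
read_weir_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("date", "species", "count"), basename(path))
  df$date <- as.Date(df$date)
  if (any(df$count < 0)) stop_buzz("input", "negative weir counts")
  df
}

#' Read travel-time samples
#'
#' CSV with a single `lag_days` column, one fish per row.
#'
#' @param path Path to the CSV file.
#' @return Integer vector of lags in days.
#' @export
read_travel_times <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, "lag_days", basename(path))
  as.integer(df$lag_days)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored. Values that parse as numbers or as
#' TRUE/FALSE are coerced.
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop_buzz("schema", sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(m[2L])
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (toupper(val) %in% c("TRUE", "FALSE"))
                    as.logical(toupper(val))
                  else val
  }
  out
}

#' Write a verdict table
#'
#' @param verdicts A `verdict_table` from [classify_stream()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_verdict_table <- function(verdicts, path) {
  df <- as.data.frame(verdicts)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%OS3")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
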