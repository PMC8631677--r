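#' Detection positive hours per day
#'
#' An hour is detection positive (DPH) when at least one beluga acoustic
#' detection of any signal type (echolocation, call, whistle) falls in it,
#' counted once regardless of how many events or types occur.
#'
#' @param events Data frame with a `timestamp` column (`POSIXct` or parseable
#'   text, local clock time).
#' @param days Optional `Date` vector of monitored days to report (gaps
#'   filled with 0); defaults to the full range of the event dates.
#' @return Data frame with columns `date`, `dph` (integer 0-24).
#' @export
detection_positive_hours <- function(events, days = NULL) {
  positive_bins_per_day(events, days, "%Y-%m-%d %H", "dph")
}

#' Detection positive minutes per day
#'
#' Companion to [detection_positive_hours()] at minute resolution; used as
#' the denominator when splitting detection minutes into feeding vs
#' non-feeding (see [monthly_summary()]).
#'
#' @inheritParams detection_positive_hours
#' @return Data frame with columns `date`, `dpm` (integer 0-1440).
#' @export
detection_positive_minutes <- function(events, days = NULL) {
  positive_bins_per_day(events, days, "%Y-%m-%d %H:%M", "dpm")
}

positive_bins_per_day <- function(events, days, fmt, colname) {
  ts <- parse_timestamp(events$timestamp)
  if (is.null(days)) {
    if (length(ts) == 0L) stop_buzz("input", "no events and no `days` given")
    days <- seq(min(as.Date(ts)), max(as.Date(ts)), by = "day")
  }
  bins <- unique(format(ts, fmt))
  day_of <- as.Date(substr(bins, 1L, 10L))
  counts <- table(factor(as.character(day_of), levels = as.character(days)))
  out <- data.frame(date = as.Date(names(counts)),
                    count = as.integer(counts))
  names(out)[2L] <- colname
  out
}

#' Centered running average of a daily series
#'
#' Centered moving mean with an odd window (default 7 days); at the edges the
#' window shrinks to the available days.
#'
#' @param x Numeric daily series (contiguous; fill unmonitored days upstream).
#' @param window Odd positive integer window width.
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' running_average(c(0, 0, 0, 7, 0, 0, 0))[4]  # 1
running_average <- function(x, window = 7) {
  if (length(x) == 0L) stop_buzz("input", "empty series")
  if (window < 1 || window %% 2 != 1)
    stop_buzz("config", "`window` must be an odd positive integer")
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n),
         function(i) mean(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

#' Foraging positive minutes per day
#'
#' A clock minute is foraging positive (FPM) when at least one click train
#' with a feeding verdict starts in it; each train is assigned to the minute
#' of its first click.
#'
#' @param verdicts A `verdict_table` from [classify_stream()] (needs
#'   `timestamp` and `verdict` columns).
#' @param days Optional `Date` vector of monitored days (default: range of
#'   verdict dates).
#' @return Data frame with columns `date`, `fpm`.
#' @export
foraging_positive_minutes <- function(verdicts, days = NULL) {
  feeding <- verdicts[verdicts$verdict == "feeding" &
                        !is.na(verdicts$timestamp), , drop = FALSE]
  if (is.null(days)) {
    ts_all <- verdicts$timestamp[!is.na(verdicts$timestamp)]
    if (length(ts_all) == 0L)
      stop_buzz("input", "no timestamped verdicts and no `days` given")
    days <- seq(min(as.Date(ts_all)), max(as.Date(ts_all)), by = "day")
  }
  out <- positive_bins_per_day(feeding, days, "%Y-%m-%d %H:%M", "fpm")
  out
}

#' Daily presence and feeding series
#'
#' Convenience assembly of the daily monitoring series: detection positive
#' hours, their centered running average, detection positive minutes, and
#' foraging positive minutes, on a common contiguous calendar.
#'
#' @param events Detection-event data frame (`timestamp`, `signal_type`,
#'   `instrument`).
#' @param verdicts A `verdict_table` from [classify_stream()].
#' @param days Optional `Date` vector; defaults to the union range of events
#'   and verdicts.
#' @param window Running-average window (odd, days).
#' @return Data frame of class `presence_series` with columns `date`, `dph`,
#'   `dph_smoothed`, `dpm`, `fpm`.
#' @export
presence_series <- function(events, verdicts, days = NULL, window = 7) {
  if (is.null(days)) {
    ts <- c(as.Date(parse_timestamp(events$timestamp)),
            as.Date(verdicts$timestamp[!is.na(verdicts$timestamp)]))
    if (length(ts) == 0L) stop_buzz("input", "no timestamps available")
    days <- seq(min(ts), max(ts), by = "day")
  }
  dph <- detection_positive_hours(events, days)
  dpm <- detection_positive_minutes(events, days)
  fpm <- foraging_positive_minutes(verdicts, days)
  out <- data.frame(date = days, dph = dph$dph,
                    dph_smoothed = running_average(dph$dph, window),
                    dpm = dpm$dpm, fpm = fpm$fpm)
  if (any(out$fpm > out$dpm))
    warning("FPM exceeds detection-positive minutes on some days; ",
            "the event table is probably missing echolocation events")
  class(out) <- c("presence_series", class(out))
  out
}

#' Monthly feeding summary
#'
#' For each calendar month: the number of days with at least one foraging
#' positive minute, and — over those days only — the summed FPM and the
#' summed non-FPM (detection-positive minutes in which belugas were present
#' but no feeding was called).
#'
#' @param presence A [presence_series()] data frame (needs `date`, `fpm`,
#'   `dpm`).
#' @return Data frame with columns `month` (`"YYYY-MM"`), `days_with_fpm`,
#'   `fpm`, `non_fpm`.
#' @export
monthly_summary <- function(presence) {
  month <- format(presence$date, "%Y-%m")
  out <- do.call(rbind, lapply(unique(month), function(m) {
    sub <- presence[month == m & presence$fpm >= 1, , drop = FALSE]
    data.frame(month = m,
               days_with_fpm = nrow(sub),
               fpm = sum(sub$fpm),
               non_fpm = sum(sub$dpm - sub$fpm))
  }))
  rownames(out) <- NULL
  out
}
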