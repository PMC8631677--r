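#' Smoothed travel-time (lag) distribution
#'
#' Turns individual fish travel times (whole days from an upriver tagging
#' site to a weir) into a normalized lag distribution: an integer-day
#' histogram over the observed lag range, smoothed with a centered moving
#' average (window shrinking at the edges), then normalized to sum to 1.
#'
#' @param samples Integer vector of individual travel times in days (>= 0).
#' @param window Odd moving-average window in days (default 5).
#' @return An object of class `travel_time_dist`: list with `lags` (integer
#'   support), `weights` (probabilities summing to 1), `raw` (histogram
#'   counts), `window`.
#' @export
#' @examples
#' travel_time_distribution(c(3, 3, 3, 3, 3))  # point mass at lag 3
travel_time_distribution <- function(samples, window = 5) {
  if (length(samples) == 0L) stop_buzz("input", "no travel-time samples")
  samples <- as.integer(round(samples))
  if (any(samples < 0)) stop_buzz("input", "negative travel times")
  if (window < 1 || window %% 2 != 1)
    stop_buzz("config", "`window` must be an odd positive integer")
  lags <- seq(min(samples), max(samples))
  raw <- as.integer(table(factor(samples, levels = lags)))
  smoothed <- running_average(raw, window)
  weights <- smoothed / sum(smoothed)
  structure(list(lags = lags, weights = weights, raw = raw, window = window),
            class = "travel_time_dist")
}

#' @export
print.travel_time_dist <- function(x, ...) {
  cat(sprintf("<travel_time_dist> lags %d-%d days, %d fish, window %d\n",
              min(x$lags), max(x$lags), sum(x$raw), x$window))
  invisible(x)
}

#' Predict daily fish counts at the tagging site from weir counts
#'
#' Back-shifts the daily weir counts by the travel-time lag distribution:
#' a fish counted at the weir on day `d + lag` was at the downriver tagging
#' site on day `d`, so
#' `predicted(d) = sum_lag weight(lag) * weir_count(d + lag)`.
#' The predicted calendar extends earlier than the weir series by the
#' maximum lag; total predicted count equals total weir count.
#'
#' @param weir Data frame with columns `date` (`Date` or parseable) and
#'   `count` (one species; filter upstream). Missing dates in the range are
#'   treated as zero counts.
#' @param dist A [travel_time_distribution()].
#' @return Data frame with columns `date`, `predicted`.
#' @export
predict_counts_at_site <- function(weir, dist) {
  stopifnot(inherits(dist, "travel_time_dist"))
  dates <- as.Date(weir$date)
  full <- seq(min(dates), max(dates), by = "day")
  counts <- numeric(length(full))
  counts[match(dates, full)] <- weir$count
  out_dates <- seq(min(full) - max(dist$lags), max(full) - min(dist$lags),
                   by = "day")
  lookup <- function(d) {
    i <- match(d, full)
    ifelse(is.na(i), 0, counts[i])
  }
  predicted <- vapply(out_dates, function(d) {
    sum(dist$weights * lookup(d + dist$lags))
  }, numeric(1))
  data.frame(date = out_dates, predicted = predicted)
}

#' Peak period of a spawning run
#'
#' Computes the q-th percentile (linear interpolation of order statistics,
#' over days with a positive predicted count) of the predicted daily fish
#' counts, and defines the peak period as the span from the first to the
#' last date at or above that threshold. Interior days dipping below the
#' threshold are reported in `interior_below`.
#'
#' @param predicted Data frame from [predict_counts_at_site()] (`date`,
#'   `predicted`).
#' @param q Percentile in (0, 1); default 0.90.
#' @param species Optional species label carried through to the result.
#' @return An object of class `run_peak`: list with `species`, `threshold`,
#'   `start`, `end`, `dates` (qualifying dates), `interior_below`.
#' @export
peak_period <- function(predicted, q = 0.90, species = NA_character_) {
  stopifnot(q > 0, q < 1)
  pos <- predicted$predicted > 0
  if (!any(pos)) stop_buzz("no_run", "all predicted counts are zero")
  threshold <- unname(stats::quantile(predicted$predicted[pos], q, type = 7))
  qualifying <- predicted$date[predicted$predicted >= threshold]
  span <- seq(min(qualifying), max(qualifying), by = "day")
  structure(list(species = species, threshold = threshold,
                 start = min(qualifying), end = max(qualifying),
                 dates = qualifying,
                 interior_below = setdiff_dates(span, qualifying)),
            class = "run_peak")
}

setdiff_dates <- function(a, b) a[!a %in% b]

#' @export
print.run_peak <- function(x, ...) {
  cat(sprintf("<run_peak> %s: threshold %.1f fish/day, %s to %s (%d sub-threshold interior day(s))\n",
              if (is.na(x$species)) "(unspecified)" else x$species,
              x$threshold, format(x$start), format(x$end),
              length(x$interior_below)))
  invisible(x)
}

#' Beluga presence and feeding within run peak periods
#'
#' Aggregates the daily monitoring series over each spawning-run peak
#' period: total foraging positive minutes and both the sum and the mean of
#' the 7-day running-average detection positive hours across the peak days.
#'
#' @param peaks A `run_peak` or list of them.
#' @param presence A [presence_series()] data frame (`date`, `fpm`,
#'   `dph_smoothed`).
#' @return Data frame with one row per peak: `species`, `threshold`,
#'   `start`, `end`, `n_days`, `fpm`, `dph7_sum`, `dph7_mean`.
#' @export
overlap_summary <- function(peaks, presence) {
  if (inherits(peaks, "run_peak")) peaks <- list(peaks)
  out <- do.call(rbind, lapply(peaks, function(p) {
    span <- seq(p$start, p$end, by = "day")
    sub <- presence[presence$date %in% span, , drop = FALSE]
    if (nrow(sub) < length(span))
      warning(sprintf("peak period of %s extends beyond the monitored range; aggregating %d of %d days",
                      p$species, nrow(sub), length(span)))
    data.frame(species = p$species, threshold = p$threshold,
               start = p$start, end = p$end, n_days = nrow(sub),
               fpm = if (nrow(sub)) sum(sub$fpm) else 0,
               dph7_sum = if (nrow(sub)) sum(sub$dph_smoothed) else 0,
               dph7_mean = if (nrow(sub)) mean(sub$dph_smoothed) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
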