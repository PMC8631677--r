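#' Acoustic feature vector of a buzz
#'
#' Computes the five ICI-based acoustic variables used to discriminate
#' feeding from social buzzes:
#' \describe{
#'   \item{minICI, maxICI}{minimum and maximum inter-click interval of the
#'     full train, milliseconds.}
#'   \item{ICIr}{ICI range, `maxICI - minICI`.}
#'   \item{slope}{ordinary-least-squares slope of ICI (ms) regressed on the
#'     peak time (s) of the click opening each interval; ms per second.
#'     With `slope_on = "index"` the regressor is the interval index instead.}
#'   \item{ICIir}{ICI increment range: the maximum of the consecutive-ICI
#'     differences within the buzz section. For `feeding` and `unknown`
#'     trains the buzz section runs from the first ICI at or below
#'     `onset_threshold_ms` to the end of the train; social buzzes are
#'     buzzing throughout, so the section is the entire train. A steadily
#'     decreasing feeding buzz therefore has a negative ICIir, while an
#'     irregular social buzz has a positive one.}
#' }
#'
#' `ICIir` is `NA` when the train has no buzz section (no ICI at or below the
#' onset threshold, for feeding/unknown contexts) or when the section holds a
#' single ICI so that no increment exists.
#'
#' @param train A [click_train()] with at least 3 clicks.
#' @param onset_threshold_ms Buzz-onset threshold in ms (inclusive).
#' @param slope_on Regressor for the slope: elapsed time (default) or
#'   interval index.
#'
#' @return An object of class `buzz_features`: a list with `train_id`,
#'   `minICI`, `maxICI`, `ICIr`, `ICIir`, `slope`, `buzz_onset_index`,
#'   `n_clicks`, `context`, and `t0`.
#' @export
#' @examples
#' tr <- click_train("f1", cumsum(c(0, 20, 15, 12, 9, 7, 5, 3)) / 1000,
#'                   context = "feeding")
#' extract_features(tr)
extract_features <- function(train, onset_threshold_ms = 9,
                             slope_on = c("time", "index")) {
  slope_on <- match.arg(slope_on)
  stopifnot(inherits(train, "click_train"))
  if (length(train$click_times) < 3L)
    stop_buzz("degenerate_train",
              sprintf("train '%s' has fewer than 3 clicks; no ICI increment exists",
                      train$train_id))
  s <- compute_ici(train)
  ici <- s$ici
  reg <- if (slope_on == "time") {
    train$click_times[seq_along(ici)] - train$click_times[1L]
  } else {
    seq_along(ici)
  }
  slope <- unname(stats::coef(stats::lm(ici ~ reg))[2L])

  onset <- detect_buzz_onset(s, onset_threshold_ms)
  section <- if (train$context == "social") ici
             else if (is.na(onset)) numeric(0)
             else ici[onset:length(ici)]
  iciir <- if (length(section) >= 2L) max(diff(section)) else NA_real_

  structure(
    list(train_id = train$train_id,
         minICI = min(ici), maxICI = max(ici), ICIr = max(ici) - min(ici),
         ICIir = iciir, slope = slope, buzz_onset_index = onset,
         n_clicks = length(train$click_times), context = train$context,
         t0 = train$t0),
    class = "buzz_features"
  )
}

#' @export
print.buzz_features <- function(x, ...) {
  cat(sprintf(
    "<buzz_features> %s (%s): minICI %.2f, maxICI %.2f, ICIr %.2f, ICIir %s, slope %.3f ms/s\n",
    x$train_id, x$context, x$minICI, x$maxICI, x$ICIr,
    if (is.na(x$ICIir)) "NA" else sprintf("%.2f", x$ICIir), x$slope))
  invisible(x)
}

#' Feature table for a set of click trains
#'
#' Applies [extract_features()] to every train and binds the results into a
#' data frame, one row per train. Trains that cannot be featurized (fewer
#' than 3 clicks) are skipped with a warning; the number skipped is attached
#' as attribute `n_skipped`.
#'
#' @param trains A list of [click_train()] objects.
#' @inheritParams extract_features
#' @return A data frame with columns `train_id`, `context`, `n_clicks`,
#'   `minICI`, `maxICI`, `ICIr`, `ICIir`, `slope`, `buzz_onset_index`.
#' @export
feature_table <- function(trains, onset_threshold_ms = 9,
                          slope_on = c("time", "index")) {
  slope_on <- match.arg(slope_on)
  rows <- list()
  skipped <- character(0)
  for (tr in trains) {
    f <- tryCatch(extract_features(tr, onset_threshold_ms, slope_on),
                  buzz_error = function(e) NULL)
    if (is.null(f)) {
      skipped <- c(skipped, tr$train_id)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      train_id = f$train_id, context = f$context, n_clicks = f$n_clicks,
      minICI = f$minICI, maxICI = f$maxICI, ICIr = f$ICIr, ICIir = f$ICIir,
      slope = f$slope, buzz_onset_index = f$buzz_onset_index,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(sprintf("skipped %d train(s) with fewer than 3 clicks: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(train_id = character(0), context = character(0),
               n_clicks = integer(0), minICI = numeric(0), maxICI = numeric(0),
               ICIr = numeric(0), ICIir = numeric(0), slope = numeric(0),
               buzz_onset_index = integer(0), stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- length(skipped)
  out
}
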