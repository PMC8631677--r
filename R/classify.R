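#' Two-step feeding classification thresholds
#'
#' The constants of the two-step rule used to call feeding on click-train
#' detections from moored recorders: a train is a feeding event when its
#' minimum ICI is below `minICI_cut` AND the increment range of its buzz
#' section is below `ICIir_cut`. Trains with minimum ICI below
#' `multipath_floor` are excluded outright, because surface-reflected
#' duplicate arrivals (multipath) create spuriously short intervals.
#'
#' @param minICI_cut Minimum-ICI cut, ms (strict `<`). Default 8.976.
#' @param ICIir_cut ICI-increment-range cut, ms (strict `<`). Default 1.49.
#' @param multipath_floor Multipath exclusion floor, ms (strict `<`).
#'   Default 1.
#' @param onset_threshold Buzz-onset threshold used upstream when the buzz
#'   section is delimited, ms. Default 9.
#'
#' @return An object of class `threshold_rules`.
#' @export
#' @examples
#' threshold_rules()
threshold_rules <- function(minICI_cut = 8.976, ICIir_cut = 1.49,
                            multipath_floor = 1, onset_threshold = 9) {
  stopifnot(minICI_cut > 0, ICIir_cut > 0, multipath_floor > 0,
            onset_threshold > 0)
  if (!(multipath_floor < minICI_cut && minICI_cut < onset_threshold))
    stop_buzz("config",
              "need multipath_floor < minICI_cut < onset_threshold")
  structure(list(minICI_cut = minICI_cut, ICIir_cut = ICIir_cut,
                 multipath_floor = multipath_floor,
                 onset_threshold = onset_threshold),
            class = "threshold_rules")
}

#' @export
print.threshold_rules <- function(x, ...) {
  cat(sprintf(
    "<threshold_rules> feeding if minICI < %g ms and ICIir < %g ms; exclude minICI < %g ms (multipath); buzz onset <= %g ms\n",
    x$minICI_cut, x$ICIir_cut, x$multipath_floor, x$onset_threshold))
  invisible(x)
}

#' Classify one click train as feeding or not
#'
#' Applies the two-step threshold rule to a feature vector, in order:
#' \enumerate{
#'   \item `minICI < multipath_floor` — `excluded_multipath`;
#'   \item `minICI >= minICI_cut` — `not_feeding`;
#'   \item `ICIir` absent (no buzz section with at least two ICIs) —
#'     `not_feeding`;
#'   \item `ICIir < ICIir_cut` — `feeding`, otherwise `not_feeding`.
#' }
#' All comparisons are strict.
#'
#' @param features A `buzz_features` object from [extract_features()]
#'   (computed with `context = "unknown"` for mooring data), or any list/row
#'   carrying `minICI` and `ICIir`.
#' @param rules A [threshold_rules()] object.
#'
#' @return An object of class `train_verdict`: list with `train_id`,
#'   `verdict` (one of `"feeding"`, `"not_feeding"`, `"excluded_multipath"`),
#'   `minICI`, `ICIir`, `t0`.
#' @export
#' @examples
#' classify_train(list(train_id = "x", minICI = 5, ICIir = -1))$verdict
classify_train <- function(features, rules = threshold_rules()) {
  stopifnot(inherits(rules, "threshold_rules"))
  minICI <- features$minICI
  ICIir <- if (is.null(features$ICIir)) NA_real_ else features$ICIir
  verdict <-
    if (minICI < rules$multipath_floor) "excluded_multipath"
    else if (minICI >= rules$minICI_cut) "not_feeding"
    else if (is.na(ICIir)) "not_feeding"
    else if (ICIir < rules$ICIir_cut) "feeding"
    else "not_feeding"
  structure(
    list(train_id = if (is.null(features$train_id)) NA_character_
                    else features$train_id,
         verdict = verdict, minICI = minICI, ICIir = ICIir,
         t0 = features$t0),
    class = "train_verdict")
}

#' @export
print.train_verdict <- function(x, ...) {
  cat(sprintf("<train_verdict> %s: %s (minICI %.2f ms, ICIir %s ms)\n",
              x$train_id, x$verdict, x$minICI,
              if (is.na(x$ICIir)) "NA" else sprintf("%.2f", x$ICIir)))
  invisible(x)
}

#' Classify a stream of click trains
#'
#' Featurizes (with `context = "unknown"`) and classifies every train of a
#' mooring detection stream, in input order. Malformed trains (fewer than 3
#' clicks, non-monotonic times) are skipped with a warning and counted, never
#' silently dropped.
#'
#' @param trains List of [click_train()] objects, ideally carrying `t0`
#'   timestamps.
#' @param rules A [threshold_rules()] object.
#'
#' @return A data frame of class `verdict_table` with columns `train_id`,
#'   `timestamp` (`POSIXct`, `NA` when the train has no `t0`), `verdict`,
#'   `minICI`, `ICIir`; attribute `n_skipped` reports the skip count.
#' @export
classify_stream <- function(trains, rules = threshold_rules()) {
  rows <- list()
  skipped <- character(0)
  for (tr in trains) {
    v <- tryCatch({
      tr$context <- "unknown"
      f <- extract_features(tr, onset_threshold_ms = rules$onset_threshold)
      classify_train(f, rules)
    }, buzz_error = function(e) NULL)
    if (is.null(v)) {
      skipped <- c(skipped, tr$train_id)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      train_id = v$train_id,
      timestamp = if (is.null(v$t0)) as.POSIXct(NA, tz = "UTC") else v$t0,
      verdict = v$verdict, minICI = v$minICI, ICIir = v$ICIir,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(sprintf("skipped %d malformed train(s): %s", length(skipped),
                    paste(skipped, collapse = ", ")))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(train_id = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"),
               verdict = character(0), minICI = numeric(0), ICIir = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- length(skipped)
  class(out) <- c("verdict_table", class(out))
  out
}
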