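#' Construct a click train
#'
#' A click train is an ordered sequence of echolocation click peak times
#' emitted by one animal (or attributed to one source by a moored click
#' logger), together with an identifier and an optional behavioral context.
#'
#' @param train_id Character scalar identifying the train.
#' @param click_times Numeric vector of click peak times in seconds from an
#'   arbitrary epoch; must be strictly increasing with at least 2 clicks.
#' @param source_id Character scalar identifying the whale or mooring.
#' @param context One of `"feeding"`, `"social"`, `"unknown"`. The context
#'   controls how the buzz section is delimited when computing the ICI
#'   increment range (see [extract_features()]).
#' @param t0 Optional absolute timestamp (`POSIXct`) of the first click, used
#'   when trains come from a moored recorder and verdicts must be placed on a
#'   calendar.
#'
#' @return An object of class `click_train`.
#' @seealso [compute_ici()], [extract_features()]
#' @export
#' @examples
#' tr <- click_train("t1", c(0, 0.010, 0.025))
#' compute_ici(tr)
click_train <- function(train_id, click_times, source_id = "unknown",
                        context = c("unknown", "feeding", "social"),
                        t0 = NULL) {
  context <- match.arg(context)
  if (!is.character(train_id) || length(train_id) != 1L || is.na(train_id))
    stop("`train_id` must be a single non-missing string")
  click_times <- as.numeric(click_times)
  if (length(click_times) < 2L)
    stop_buzz("degenerate_train",
              sprintf("train '%s' has %d click(s); at least 2 are required",
                      train_id, length(click_times)))
  if (anyNA(click_times))
    stop_buzz("input_order", sprintf("train '%s' has missing click times",
                                     train_id))
  if (any(diff(click_times) <= 0))
    stop_buzz("input_order",
              sprintf("click times of train '%s' are not strictly increasing",
                      train_id))
  if (!is.null(t0)) t0 <- as.POSIXct(t0, tz = "UTC")
  structure(
    list(train_id = train_id, source_id = source_id, context = context,
         click_times = click_times, t0 = t0),
    class = "click_train"
  )
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf("<click_train> %s (source %s, context %s): %d clicks over %.3f s\n",
              x$train_id, x$source_id, x$context, length(x$click_times),
              diff(range(x$click_times))))
  invisible(x)
}

#' Inter-click intervals of a click train
#'
#' Computes the inter-click-interval (ICI) series — the time difference
#' between consecutive click peak times, in milliseconds — and its first
#' differences (ICI increments).
#'
#' @param train A [click_train()] object, or a numeric vector of click peak
#'   times in seconds.
#'
#' @return An object of class `ici_series`: a list with components `ici`
#'   (milliseconds, length `n_clicks - 1`) and `increments` (consecutive ICI
#'   differences, length `n_clicks - 2`).
#' @export
#' @examples
#' compute_ici(c(0, 0.010, 0.025))  # ici 10, 15 ms; increment 5 ms
compute_ici <- function(train) {
  times <- if (inherits(train, "click_train")) train$click_times
           else as.numeric(train)
  if (length(times) < 2L)
    stop_buzz("degenerate_train", "at least 2 clicks are needed to form an ICI")
  if (any(diff(times) <= 0))
    stop_buzz("input_order", "click times must be strictly increasing")
  ici <- diff(times) * 1000
  structure(list(ici = ici, increments = diff(ici)), class = "ici_series")
}

#' @export
print.ici_series <- function(x, ...) {
  cat(sprintf("<ici_series> %d ICIs, range [%.2f, %.2f] ms\n",
              length(x$ici), min(x$ici), max(x$ici)))
  invisible(x)
}

#' Detect the onset of a terminal buzz
#'
#' Terminal buzzing is taken to start at the first inter-click interval at or
#' below the onset threshold (9 ms by default): the high-repetition-rate
#' ending of a feeding click train during final prey approach.
#'
#' @param ici An `ici_series` from [compute_ici()], or a numeric vector of
#'   ICIs in milliseconds.
#' @param onset_threshold_ms Onset threshold in milliseconds; the comparison
#'   is inclusive (`<=`).
#'
#' @return Integer index into the ICI sequence of the first qualifying ICI,
#'   or `NA_integer_` if no ICI qualifies.
#' @export
#' @examples
#' detect_buzz_onset(c(20, 15, 12, 9, 7, 5))  # 4: the 9-ms interval
detect_buzz_onset <- function(ici, onset_threshold_ms = 9) {
  v <- if (inherits(ici, "ici_series")) ici$ici else as.numeric(ici)
  if (length(v) == 0L)
    stop_buzz("degenerate_train", "empty ICI series")
  # 1e-9 ms of slack so that float dust from differencing click times
  # cannot push a boundary ICI off the inclusive threshold
  idx <- which(v <= onset_threshold_ms + 1e-9)
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

# classed condition helper so callers can catch specific failure modes
stop_buzz <- function(class, msg) {
  stop(errorCondition(msg, class = c(paste0("buzz_", class), "buzz_error")))
}
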