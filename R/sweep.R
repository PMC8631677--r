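#' Enumerate the 64-configuration cluster model grid
#'
#' Builds the full grid of cluster configurations evaluated against presumed
#' behavior: 16 partitioning-around-medoids (PAM) models and 48 hierarchical
#' models, all with k = 2.
#'
#' PAM (16): the five-variable set (minICI, maxICI, ICIr, ICIir, slope) and
#' the two-variable set (minICI, ICIir), each crossed with three distances
#' (Euclidean, squared Euclidean, Manhattan) and scaled/unscaled data (12);
#' plus the two single-variable sets (minICI alone, ICIir alone) crossed with
#' scaled/unscaled (4) — in one dimension the three distances are monotone
#' transformations of each other, so a single distance (Euclidean) is
#' recorded.
#'
#' Hierarchical (48): complete, single, average and weighted-average linkage
#' crossed with Euclidean/Manhattan distance, the two/five-variable sets and
#' scaled/unscaled (32); centroid linkage with squared Euclidean only (4);
#' median linkage with Euclidean only (4); Ward's method with Euclidean and
#' with squared Euclidean (8).
#'
#' @return A data frame with one row per configuration: `config_id`,
#'   `family`, `distance`, `linkage` (`NA` for PAM), `variables`
#'   (`+`-separated), `scaled`.
#' @export
cluster_configs <- function() {
  five <- "minICI+maxICI+ICIr+ICIir+slope"
  two <- "minICI+ICIir"
  rows <- list()
  add <- function(family, distance, linkage, variables, scaled) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, distance = distance, linkage = linkage,
      variables = variables, scaled = scaled, stringsAsFactors = FALSE)
  }
  for (vars in c(five, two))
    for (dist in c("euclidean", "squared_euclidean", "manhattan"))
      for (sc in c(FALSE, TRUE))
        add("pam", dist, NA_character_, vars, sc)
  for (vars in c("minICI", "ICIir"))
    for (sc in c(FALSE, TRUE))
      add("pam", "euclidean", NA_character_, vars, sc)
  for (link in c("complete", "single", "average", "weighted_average"))
    for (dist in c("euclidean", "manhattan"))
      for (vars in c(five, two))
        for (sc in c(FALSE, TRUE))
          add("hierarchical", dist, link, vars, sc)
  for (vars in c(five, two))
    for (sc in c(FALSE, TRUE))
      add("hierarchical", "squared_euclidean", "centroid", vars, sc)
  for (vars in c(five, two))
    for (sc in c(FALSE, TRUE))
      add("hierarchical", "euclidean", "median", vars, sc)
  for (dist in c("euclidean", "squared_euclidean"))
    for (vars in c(five, two))
      for (sc in c(FALSE, TRUE))
        add("hierarchical", dist, "ward", vars, sc)
  out <- do.call(rbind, rows)
  out <- cbind(config_id = seq_len(nrow(out)), out)
  out
}

#' Run the full cluster sweep and score it against presumed behavior
#'
#' Fits every configuration of [cluster_configs()] (or a subset) to the buzz
#' feature table, cuts each model at k = 2, and scores the agreement between
#' cluster assignments and the presumed behavioral labels with the
#' Fowlkes-Mallows index.
#'
#' @param features Data frame containing the five acoustic variables
#'   (`minICI`, `maxICI`, `ICIr`, `ICIir`, `slope`), e.g. from
#'   [feature_table()].
#' @param labels Presumed behavior per row (e.g. `"feeding"`/`"social"`).
#' @param configs Configuration grid; defaults to the full 64.
#' @param k Number of clusters (2 throughout the sweep).
#' @return An object of class `buzz_sweep`: the config data frame with an
#'   `fm_index` column, sorted by `fm_index` descending (ties keep config
#'   order), plus an `assignments` attribute — an n-by-nconfig integer matrix
#'   of cluster labels, columns in `config_id` order.
#' @export
run_sweep <- function(features, labels, configs = cluster_configs(), k = 2) {
  needed <- c("minICI", "maxICI", "ICIr", "ICIir", "slope")
  missing_vars <- setdiff(needed, colnames(features))
  if (length(missing_vars))
    stop_buzz("input", sprintf("feature table lacks column(s): %s",
                               paste(missing_vars, collapse = ", ")))
  if (nrow(features) != length(labels))
    stop_buzz("input", "labels length must match feature rows")
  if (anyNA(features[, needed]))
    stop_buzz("input", "missing values among the five acoustic variables")

  assignments <- matrix(NA_integer_, nrow(features), nrow(configs))
  fm <- numeric(nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, ]
    vars <- strsplit(cfg$variables, "+", fixed = TRUE)[[1L]]
    x <- as.matrix(features[, vars, drop = FALSE])
    if (cfg$scaled) x <- scale_features(x)
    a <- if (cfg$family == "pam") {
      pam_cluster(x, distance = cfg$distance, k = k)$assignments
    } else {
      hierarchical_cluster(x, distance = cfg$distance, linkage = cfg$linkage,
                           k = k)$assignments
    }
    assignments[, i] <- a
    fm[i] <- fowlkes_mallows(a, labels)
  }
  out <- cbind(configs, fm_index = fm)
  out <- out[order(-out$fm_index, out$config_id), ]
  rownames(out) <- NULL
  attr(out, "assignments") <- assignments
  class(out) <- c("buzz_sweep", class(out))
  out
}

#' @export
print.buzz_sweep <- function(x, n = 10, ...) {
  cat(sprintf("<buzz_sweep> %d configurations, fm_index in [%.3f, %.3f]\n",
              nrow(x), min(x$fm_index), max(x$fm_index)))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("  ... and %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Extract a one-split threshold rule from cluster assignments
#'
#' A decision stump summarizing which acoustic variable, at which cut value,
#' reproduces a two-cluster assignment: exhaustive search over all candidate
#' cuts (midpoints between consecutive sorted unique values of each
#' variable), minimizing the weighted Gini impurity of the two children.
#' Among equally pure splits across variables, the variable listed earliest
#' in `variable_order` wins; within a variable, the lowest cut wins.
#'
#' @param features Data frame of candidate explanatory variables.
#' @param classes Two-class assignment per row (cluster labels or behavior).
#' @param variable_order Character vector giving the priority order of
#'   variables; defaults to the column order of `features`.
#' @return An object of class `buzz_stump`: list with `variable`, `cut`,
#'   `left_class` (majority class where `variable < cut`), `right_class`,
#'   and `impurity` (weighted Gini of the children).
#' @export
#' @examples
#' x <- data.frame(minICI = c(2.3, 8.92, 9.03, 29.75))
#' fit_stump(x, c("feeding", "feeding", "social", "social"))
fit_stump <- function(features, classes, variable_order = colnames(features)) {
  features <- as.data.frame(features)
  classes <- as.character(classes)
  stopifnot(nrow(features) == length(classes))
  if (length(unique(classes)) < 2L)
    stop_buzz("no_split", "only one class present; no split possible")
  variable_order <- intersect(variable_order, colnames(features))

  gini <- function(cl) {
    p <- table(cl) / length(cl)
    1 - sum(p^2)
  }
  n <- length(classes)
  best <- list(impurity = Inf)
  for (v in variable_order) {
    vals <- features[[v]]
    u <- sort(unique(vals))
    if (length(u) < 2L) next
    cuts <- (u[-length(u)] + u[-1L]) / 2
    for (cut in cuts) {
      left <- vals < cut
      imp <- (sum(left) * gini(classes[left]) +
              sum(!left) * gini(classes[!left])) / n
      if (imp < best$impurity - 1e-12) {
        majority <- function(cl) names(which.max(table(cl)))
        best <- list(variable = v, cut = cut,
                     left_class = majority(classes[left]),
                     right_class = majority(classes[!left]),
                     impurity = imp)
      }
    }
  }
  if (!is.finite(best$impurity))
    stop_buzz("no_split", "no variable offers a candidate split")
  structure(best, class = "buzz_stump")
}

#' @export
print.buzz_stump <- function(x, ...) {
  cat(sprintf("<buzz_stump> %s < %g -> %s ; %s >= %g -> %s (Gini %.4f)\n",
              x$variable, x$cut, x$left_class, x$variable, x$cut,
              x$right_class, x$impurity))
  invisible(x)
}

#' @export
#' @rdname fit_stump
#' @param object A `buzz_stump`.
#' @param newdata Data frame containing the stump's variable.
#' @param ... Unused.
predict.buzz_stump <- function(object, newdata, ...) {
  v <- newdata[[object$variable]]
  ifelse(v < object$cut, object$left_class, object$right_class)
}
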