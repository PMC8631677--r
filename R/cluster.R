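#' Center and scale a feature matrix
#'
#' Centers each column on its mean and divides by its sample standard
#' deviation (n - 1 denominator), the scaling applied before the "scaled"
#' cluster configurations.
#'
#' @param x Numeric matrix or data frame with at least 2 rows and no missing
#'   values.
#' @return A numeric matrix; every column has mean 0 and sd 1.
#' @export
scale_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_buzz("input", "need at least 2 rows to scale")
  if (anyNA(x)) stop_buzz("input", "missing values in feature matrix")
  sds <- apply(x, 2L, stats::sd)
  zero <- sds == 0
  if (any(zero))
    stop_buzz("degenerate_scaling",
              sprintf("zero-variance column(s): %s",
                      paste(colnames(x)[zero], collapse = ", ")))
  scale(x, center = TRUE, scale = sds)
}

# Pairwise dissimilarity used throughout the sweep. squared_euclidean squares
# the euclidean distance matrix entrywise (the convention under which
# centroid linkage and classic Ward are defined).
buzz_dist <- function(x, distance = c("euclidean", "squared_euclidean",
                                      "manhattan")) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  switch(distance,
         euclidean = stats::dist(x),
         squared_euclidean = stats::dist(x)^2,
         manhattan = stats::dist(x, method = "manhattan"))
}

#' Partitioning around medoids (k-medoids)
#'
#' Deterministic PAM: greedy BUILD initialization (each medoid chosen to
#' maximize the drop in total dissimilarity) followed by SWAP refinement
#' (repeatedly take the single medoid/non-medoid exchange that most lowers
#' the total cost, until no exchange improves it). All ties are broken by the
#' lowest row index, so the result is reproducible without a seed.
#'
#' @param x Numeric matrix/data frame of observations (rows), or a `dist`.
#' @param distance Dissimilarity to use when `x` is a matrix.
#' @param k Number of clusters.
#' @return A list with `assignments` (integer cluster per row, labelled by
#'   medoid order), `medoids` (row indices, sorted), and `cost` (total
#'   dissimilarity of points to their medoids).
#' @export
#' @examples
#' pam_cluster(matrix(c(0, 0.1, 10, 10.1)), k = 2)$assignments
pam_cluster <- function(x, distance = "euclidean", k = 2) {
  d <- if (inherits(x, "dist")) as.matrix(x)
       else as.matrix(buzz_dist(x, distance))
  n <- nrow(d)
  if (n < k) stop_buzz("size", sprintf("n = %d < k = %d", n, k))

  cost_of <- function(med) sum(apply(d[, med, drop = FALSE], 1L, min))

  # BUILD: first medoid minimizes total dissimilarity; each further medoid
  # maximizes the total reduction. which.min/which.max take the first (lowest
  # index) position on ties.
  med <- which.min(colSums(d))
  while (length(med) < k) {
    nearest <- apply(d[, med, drop = FALSE], 1L, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% med) return(-Inf)
      sum(pmax(nearest - d[, j], 0))
    }, numeric(1))
    med <- c(med, which.max(gain))
  }

  # SWAP: steepest-descent exchanges to a local optimum.
  repeat {
    cur <- cost_of(med)
    best <- cur
    best_med <- med
    for (i in seq_along(med)) {
      for (h in seq_len(n)) {
        if (h %in% med) next
        cand <- med
        cand[i] <- h
        cc <- cost_of(cand)
        if (cc < best - 1e-12) {
          best <- cc
          best_med <- cand
        }
      }
    }
    if (best >= cur - 1e-12) break
    med <- best_med
  }

  med <- sort(unname(med))
  assignments <- apply(d[, med, drop = FALSE], 1L, which.min)
  list(assignments = as.integer(assignments), medoids = med,
       cost = cost_of(med))
}

#' Agglomerative hierarchical clustering cut at k clusters
#'
#' Agglomerative nesting via [stats::hclust()] with the seven linkage
#' criteria of the sweep, cut with [stats::cutree()]. Distance/linkage
#' combinations are restricted as in the model grid: centroid linkage
#' requires squared Euclidean distance, median linkage requires Euclidean,
#' and Ward's method accepts Euclidean or squared Euclidean (the squared
#' variant being classic Ward).
#'
#' @inheritParams pam_cluster
#' @param linkage One of `"complete"`, `"single"`, `"average"`,
#'   `"weighted_average"`, `"centroid"`, `"median"`, `"ward"`.
#' @return A list with `assignments` (integer cluster per row) and `tree`
#'   (the `hclust` object).
#' @export
hierarchical_cluster <- function(x, distance = "euclidean",
                                 linkage = c("complete", "single", "average",
                                             "weighted_average", "centroid",
                                             "median", "ward"),
                                 k = 2) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance,
                        c("euclidean", "squared_euclidean", "manhattan"))
  ok <- switch(linkage,
               centroid = distance == "squared_euclidean",
               median = distance == "euclidean",
               ward = distance %in% c("euclidean", "squared_euclidean"),
               TRUE)
  if (!ok)
    stop_buzz("config", sprintf("linkage '%s' is not defined for distance '%s'",
                                linkage, distance))
  method <- switch(linkage,
                   weighted_average = "mcquitty",
                   ward = "ward.D",
                   linkage)
  d <- buzz_dist(x, distance)
  if (attr(d, "Size") < 2L) stop_buzz("size", "need at least 2 observations")
  tree <- stats::hclust(d, method = method)
  list(assignments = as.integer(stats::cutree(tree, k = k)), tree = tree)
}

#' Fowlkes-Mallows index between two partitions
#'
#' Pair-counting agreement between a clustering and a reference labelling:
#' `B = T / sqrt(P * Q)` where, over all unordered pairs of observations,
#' `T` counts pairs co-clustered in both partitions, `P` pairs co-clustered
#' in the first, and `Q` pairs co-clustered in the second. `B` is 1 for
#' identical pair co-membership and 0 when no co-clustered pair agrees (or
#' when either partition has no co-clustered pair at all).
#'
#' @param assignments,labels Vectors of equal length giving the two
#'   partitions.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' fowlkes_mallows(c(1, 2, 1, 2), c("A", "A", "B", "B"))  # 0
fowlkes_mallows <- function(assignments, labels) {
  if (length(assignments) != length(labels))
    stop_buzz("input", "partition vectors differ in length")
  ct <- table(assignments, labels)
  T_ <- sum(choose(ct, 2))
  P <- sum(choose(rowSums(ct), 2))
  Q <- sum(choose(colSums(ct), 2))
  if (P == 0 || Q == 0) return(0)
  T_ / sqrt(P * Q)
}

#' Export a dendrogram as newick text
#'
#' Writes the merge tree of a hierarchical configuration as a
#' nested-parenthesis (newick) string with cophenetic merge heights as branch
#' lengths.
#'
#' @param tree An `hclust` object (e.g. `hierarchical_cluster(...)$tree`).
#' @param labels Optional tip labels (defaults to the tree's labels or row
#'   numbers).
#' @return A newick string (invisibly also usable with [ape::read.tree()]).
#' @export
dendrogram_newick <- function(tree, labels = NULL) {
  stopifnot(inherits(tree, "hclust"))
  if (!is.null(labels)) tree$labels <- as.character(labels)
  if (is.null(tree$labels))
    tree$labels <- as.character(seq_len(nrow(tree$merge) + 1L))
  ape::write.tree(ape::as.phylo(tree))
}
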