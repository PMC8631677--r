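# Independent reference implementations used to validate the package's
# clustering and index code, plus small fixture builders.

# build a click_train from an ICI sequence (ms)
train_from_ici <- function(ici, id = "t", context = "unknown", t0 = NULL) {
  click_train(id, cumsum(c(0, ici)) / 1000, context = context, t0 = t0)
}

# the sweep's dissimilarity conventions, restated independently
buzz_dist_test <- function(x, distance) {
  switch(distance,
         euclidean = stats::dist(x),
         squared_euclidean = stats::dist(x)^2,
         manhattan = stats::dist(x, method = "manhattan"))
}

# exhaustive k = 2 medoid search: minimal total dissimilarity over all pairs
brute_force_pam_cost <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      cost <- sum(pmin(d[, i], d[, j]))
      if (cost < best) best <- cost
    }
  }
  best
}

# Fowlkes-Mallows by direct enumeration of all unordered pairs
fm_pair_counting <- function(a, b) {
  n <- length(a)
  T_ <- P <- Q <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) T_ <- T_ + 1
      if (sa) P <- P + 1
      if (sb) Q <- Q + 1
    }
  }
  if (P == 0 || Q == 0) return(0)
  T_ / sqrt(P * Q)
}

# naive O(n^3) agglomeration: full Lance-Williams recursion on the supplied
# dissimilarity matrix, scanning every active pair at every step
naive_agglomerate <- function(d, linkage) {
  D <- as.matrix(d)
  n <- nrow(D)
  diag(D) <- Inf
  sizes <- rep(1, n)
  groups <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  heights <- numeric(0)
  lw <- function(ni, nj, nk) {
    switch(linkage,
      single = c(0.5, 0.5, 0, -0.5),
      complete = c(0.5, 0.5, 0, 0.5),
      average = c(ni / (ni + nj), nj / (ni + nj), 0, 0),
      weighted_average = c(0.5, 0.5, 0, 0),
      centroid = c(ni / (ni + nj), nj / (ni + nj),
                   -ni * nj / (ni + nj)^2, 0),
      median = c(0.5, 0.5, -0.25, 0),
      ward = c((ni + nk) / (ni + nj + nk), (nj + nk) / (ni + nj + nk),
               -nk / (ni + nj + nk), 0))
  }
  two_cluster_partition <- NULL
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && D[a, b] < best_d) {
        best_d <- D[a, b]
        best <- c(a, b)
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    for (k in idx) {
      if (k == i || k == j) next
      cf <- lw(sizes[i], sizes[j], sizes[k])
      D[i, k] <- D[k, i] <- cf[1] * D[i, k] + cf[2] * D[j, k] +
        cf[3] * best_d + cf[4] * abs(D[i, k] - D[j, k])
    }
    groups[[i]] <- c(groups[[i]], groups[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
    if (sum(active) == 2L) {
      part <- integer(n)
      live <- which(active)
      part[groups[[live[1]]]] <- 1L
      part[groups[[live[2]]]] <- 2L
      two_cluster_partition <- part
    }
  }
  list(heights = heights, partition2 = two_cluster_partition)
}

same_partition <- function(a, b) {
  isTRUE(all.equal(fm_pair_counting(a, b), 1))
}
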