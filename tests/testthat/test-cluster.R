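test_that("scaling centers to mean 0 and sample sd 1", {
  expect_equal(as.numeric(scale_features(matrix(1:3))), c(-1, 0, 1))
  expect_error(scale_features(matrix(c(5, 5, 5), dimnames = list(NULL, "v"))),
               class = "buzz_degenerate_scaling")
  set.seed(31)
  x <- matrix(rnorm(60, 10, 4), ncol = 3)
  z <- scale_features(x)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 3), tolerance = 1e-12)
})

test_that("PAM separates well-separated pairs and rejects n < k", {
  res <- pam_cluster(matrix(c(0, 0.1, 10, 10.1)), k = 2)
  expect_equal(res$assignments[1], res$assignments[2])
  expect_equal(res$assignments[3], res$assignments[4])
  expect_false(res$assignments[1] == res$assignments[3])
  expect_error(pam_cluster(matrix(1), k = 2), class = "buzz_size")
})

test_that("PAM solutions are swap-locally optimal", {
  set.seed(32)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    x <- matrix(rnorm(n * 2), ncol = 2)
    for (distance in c("euclidean", "squared_euclidean", "manhattan")) {
      res <- pam_cluster(x, distance = distance, k = 2)
      d <- as.matrix(buzz_dist_test(x, distance))
      # no single medoid/non-medoid exchange lowers the total cost
      for (i in 1:2) {
        for (h in setdiff(seq_len(n), res$medoids)) {
          cand <- res$medoids
          cand[i] <- h
          expect_gte(sum(apply(d[, cand, drop = FALSE], 1, min)),
                     res$cost - 1e-10)
        }
      }
    }
  }
})

test_that("PAM agrees with the reference k-medoids implementation", {
  skip_if_not_installed("cluster")
  set.seed(33)
  for (rep in 1:10) {
    x <- matrix(rnorm(30), ncol = 2)
    mine <- pam_cluster(x, k = 2)
    ref <- cluster::pam(dist(x), k = 2, diss = TRUE)
    ref_cost <- sum(apply(as.matrix(dist(x))[, ref$id.med, drop = FALSE],
                          1, min))
    expect_equal(mine$cost, ref_cost, tolerance = 1e-10)
    expect_true(same_partition(mine$assignments, ref$clustering))
  }
})

test_that("PAM separates clustered data at the exhaustive-search optimum", {
  # on data with genuine two-group structure (the regime the buzz features
  # live in), BUILD+SWAP lands on the globally best medoid pair
  set.seed(39)
  for (rep in 1:10) {
    n1 <- sample(3:5, 1)
    n2 <- sample(3:5, 1)
    x <- rbind(matrix(rnorm(n1 * 2, 0, 0.6), ncol = 2),
               matrix(rnorm(n2 * 2, 8, 0.6), ncol = 2))
    res <- pam_cluster(x, k = 2)
    expect_equal(res$cost, brute_force_pam_cost(dist(x)), tolerance = 1e-10)
    expect_true(same_partition(res$assignments,
                               rep(1:2, c(n1, n2))))
  }
})

test_that("duplicated identical points get the lowest-index medoids", {
  res <- pam_cluster(matrix(rep(1, 4)), k = 2)
  expect_equal(res$medoids, c(1L, 2L))
  expect_equal(res$cost, 0)
})

test_that("one-variable PAM is identical under euclidean and manhattan", {
  set.seed(34)
  for (rep in 1:10) {
    x <- matrix(runif(12, 0, 30))
    a <- pam_cluster(x, "euclidean", k = 2)$assignments
    b <- pam_cluster(x, "manhattan", k = 2)$assignments
    expect_equal(a, b)
  }
})

test_that("obvious merge orders are respected", {
  res <- hierarchical_cluster(matrix(c(0, 1, 10)), linkage = "single")
  expect_true(same_partition(res$assignments, c(1, 1, 2)))
})

test_that("every linkage matches a naive Lance-Williams recomputation", {
  set.seed(35)
  combos <- list(c("complete", "euclidean"), c("complete", "manhattan"),
                 c("single", "euclidean"), c("average", "manhattan"),
                 c("weighted_average", "euclidean"),
                 c("centroid", "squared_euclidean"), c("median", "euclidean"),
                 c("ward", "euclidean"), c("ward", "squared_euclidean"))
  for (rep in 1:4) {
    n <- sample(6:10, 1)
    x <- matrix(rnorm(n * 2), ncol = 2)
    for (cmb in combos) {
      d <- buzz_dist_test(x, cmb[2])
      res <- hierarchical_cluster(x, distance = cmb[2], linkage = cmb[1])
      oracle <- naive_agglomerate(d, cmb[1])
      expect_equal(res$tree$height, oracle$heights, tolerance = 1e-9,
                   info = paste(cmb, collapse = "/"))
      expect_true(same_partition(res$assignments, oracle$partition2))
    }
  }
})

test_that("Ward on separated Gaussian blobs recovers blob membership", {
  set.seed(36)
  x <- rbind(matrix(rnorm(20, 0, 0.5), ncol = 2),
             matrix(rnorm(20, 8, 0.5), ncol = 2))
  truth <- rep(1:2, each = 10)
  for (distance in c("euclidean", "squared_euclidean")) {
    res <- hierarchical_cluster(x, distance = distance, linkage = "ward")
    expect_true(same_partition(res$assignments, truth))
  }
})

test_that("invalid distance/linkage combinations are configuration errors", {
  x <- matrix(rnorm(10), ncol = 2)
  expect_error(hierarchical_cluster(x, "euclidean", "centroid"),
               class = "buzz_config")
  expect_error(hierarchical_cluster(x, "manhattan", "median"),
               class = "buzz_config")
  expect_error(hierarchical_cluster(x, "manhattan", "ward"),
               class = "buzz_config")
})

test_that("Fowlkes-Mallows matches direct pair counting and its bounds", {
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(fowlkes_mallows(c(1, 2, 1, 2), c("A", "A", "B", "B")), 0)
  expect_error(fowlkes_mallows(1:3, 1:4), class = "buzz_input")
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(c("x", "y"), n, replace = TRUE)
    fm <- fowlkes_mallows(a, b)
    expect_gte(fm, 0)
    expect_lte(fm, 1)
    expect_equal(fm, fm_pair_counting(a, b), tolerance = 1e-12)
  }
  # relabelling leaves the index unchanged
  expect_equal(fowlkes_mallows(c(2, 2, 1, 1), c("f", "f", "s", "s")), 1)
})

test_that("dendrograms export as readable newick with cophenetic heights", {
  set.seed(38)
  x <- matrix(rnorm(12), ncol = 2)
  tree <- hierarchical_cluster(x, linkage = "average")$tree
  nwk <- dendrogram_newick(tree, labels = paste0("b", 1:6))
  phy <- ape::read.tree(text = nwk)
  expect_equal(sort(phy$tip.label), sort(paste0("b", 1:6)))
})
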