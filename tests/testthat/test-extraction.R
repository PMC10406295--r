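test_that("PCA keeps the minimal component count reaching the target", {
  set.seed(41)
  # points exactly in a 2-D subspace of R^5
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  z <- matrix(rnorm(60 * 2), 60, 2) %*% t(basis)
  red <- pca_reduce(z, 0.95)
  expect_identical(red$p, 2L)
  expect_equal(sum(red$explained_variance_fractions), 1, tolerance = 1e-9)

  # full retention on full-rank input keeps every informative axis
  full <- matrix(rnorm(30 * 4), 30, 4)
  expect_identical(pca_reduce(full, 1.0)$p, 4L)
  expect_error(pca_reduce(full, 0), "variance_target")
  expect_error(pca_reduce(full, 1.2), "variance_target")

  # minimality: dropping the last kept component falls below the target
  set.seed(42)
  zz <- matrix(rnorm(80 * 10), 80, 10) %*% diag(c(5, 3, 2, 1.5, rep(0.3, 6)))
  r <- pca_reduce(zz, 0.95)
  cum <- cumsum(r$all_variance_fractions)
  expect_gte(cum[r$p], 0.95)
  if (r$p > 1) expect_lt(cum[r$p - 1], 0.95)
})

test_that("explained-variance fractions match the covariance eigendecomposition", {
  set.seed(43)
  z <- matrix(rnorm(100 * 10), 100, 10)
  red <- pca_reduce(z, 1.0)
  expect_equal(red$all_variance_fractions, oracle_pca_fractions(z),
               tolerance = 1e-9)
})

test_that("PCA reconstruction and sign convention are deterministic", {
  set.seed(44)
  z <- matrix(rnorm(40 * 6), 40, 6)
  red <- pca_reduce(z, 1.0)
  centered <- sweep(z, 2, red$center)
  expect_equal(red$coords %*% t(red$rotation), centered, tolerance = 1e-9)
  # each axis's largest-magnitude loading is positive
  for (j in seq_len(red$p)) {
    col <- red$rotation[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  expect_identical(pca_reduce(z, 1.0)$coords, red$coords)
})

test_that("k-means limits: k = 1 and k = n", {
  set.seed(45)
  x <- matrix(rnorm(20 * 3), 20, 3)
  one <- kmeans_cluster(x, k = 1, seed = 1)
  expect_true(all(one$labels == 1L))
  expect_equal(one$inertia, sum(sweep(x, 2, colMeans(x))^2),
               tolerance = 1e-9)
  all_own <- kmeans_cluster(x, k = 20, seed = 1)
  expect_identical(sort(unique(unname(all_own$labels))), 1:20)
  expect_equal(all_own$inertia, 0, tolerance = 1e-9)
  expect_error(kmeans_cluster(x, k = 21), "k must lie")
})

test_that("k-means recovers well-separated blobs and never beats stats::kmeans badly", {
  set.seed(46)
  truth <- rep(1:2, each = 25)
  x <- matrix(rnorm(50 * 2, sd = 1), 50, 2)
  x[truth == 2, ] <- x[truth == 2, ] + 20     # 20 sigma separation
  part <- kmeans_cluster(x, k = 2, seed = 3)
  expect_equal(evaluate_recovery(part, truth)$ari, 1)

  # an independent solver on the same data reaches the same objective
  ref <- stats::kmeans(x, 2, nstart = 10, algorithm = "Lloyd")
  expect_equal(part$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("k-means is seed-deterministic and its objective never increases", {
  set.seed(47)
  x <- matrix(rnorm(60 * 4), 60, 4)
  a <- kmeans_cluster(x, k = 5, seed = 9)
  b <- kmeans_cluster(x, k = 5, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$inertia, b$inertia)
  expect_true(all(diff(a$inertia_trace) <= 1e-9))
  expect_equal(utils::tail(a$inertia_trace, 1), a$inertia)
})

test_that("reference-network identification maximizes Jaccard overlap", {
  labels <- setNames(rep(1:3, each = 4), sprintf("ROI_%03d", 1:12))
  part <- structure(list(labels = labels, k = 3L, inertia = 0,
                         dmn_cluster = NA_integer_),
                    class = "network_partition")
  # reference exactly equals cluster 2
  got <- suppressMessages(identify_network(part, sprintf("ROI_%03d", 5:8)))
  expect_identical(got$dmn_cluster, 2L)
  expect_equal(got$dmn_jaccard, 1)

  # 3-vs-1 split between clusters 1 and 2 favours the majority holder
  ref <- sprintf("ROI_%03d", c(1, 2, 3, 5))
  expect_identical(suppressMessages(identify_network(part, ref))$dmn_cluster,
                   1L)
  expect_error(identify_network(part, "ROI_099"), "not in partition")

  # random partitions: equals an exhaustive max-Jaccard scan, and is
  # invariant to relabeling
  set.seed(48)
  for (i in 1:10) {
    lab <- setNames(sample(1:4, 30, replace = TRUE), sprintf("ROI_%03d", 1:30))
    lab[1:4] <- 1:4     # every cluster non-empty
    p <- structure(list(labels = lab, k = 4L, inertia = 0,
                        dmn_cluster = NA_integer_),
                   class = "network_partition")
    ref <- sample(names(lab), 6)
    want <- oracle_best_jaccard(lab, 4, ref, names(lab))
    got <- suppressMessages(identify_network(p, ref))
    expect_identical(got$dmn_cluster, want$cluster)
    expect_equal(got$dmn_jaccard, want$jaccard)

    perm <- sample(4)
    relab <- p; relab$labels <- setNames(perm[lab], names(lab))
    got2 <- suppressMessages(identify_network(relab, ref))
    expect_identical(got2$dmn_cluster, as.integer(perm[want$cluster]))
  }
})

test_that("recovery metrics behave like ARI/NMI should", {
  truth <- rep(1:4, each = 10)
  expect_equal(evaluate_recovery(truth, truth)$ari, 1)
  expect_equal(evaluate_recovery(truth, truth)$nmi, 1)
  # relabeling invariance
  permuted <- c(3, 1, 4, 2)[truth]
  expect_equal(evaluate_recovery(permuted, truth)$ari, 1)
  # independent balanced labels: ARI concentrates near 0
  set.seed(49)
  aris <- replicate(20, {
    a <- sample(rep(1:2, each = 500))
    b <- sample(rep(1:2, each = 500))
    evaluate_recovery(a, b)$ari
  })
  expect_lt(max(abs(aris)), 0.05)
  expect_error(evaluate_recovery(truth, truth[-1]), "length")
})
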