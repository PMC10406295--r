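# path, triangle, and star graphs used throughout
path2 <- function() toy_graph(2, cbind(1L, 2L))
triangle <- function() toy_graph(3, cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)))

test_that("neighbour sampling honours fan-out, fallback and exact mode", {
  g <- toy_graph(4, cbind(c(1L, 1L), c(2L, 3L)))   # node 4 isolated
  set.seed(1)
  expect_identical(sample_neighbors(g, 2, 5), rep(1L, 5))   # forced
  expect_identical(sample_neighbors(g, 4, 3), rep(4L, 3))   # self-fallback
  expect_identical(sample_neighbors(g, 1, 99, exact = TRUE), c(2L, 3L))
  expect_error(sample_neighbors(g, 7, 2), "unknown node")

  # uniformity: 3 neighbours, 300 draws, each expected 100 +- binomial noise
  tri_plus <- toy_graph(4, cbind(c(1L, 1L, 1L), c(2L, 3L, 4L)))
  set.seed(2)
  draws <- sample_neighbors(tri_plus, 1, 300)
  counts <- table(factor(draws, levels = 2:4))
  expect_true(all(abs(counts - 100) <= 35))
})

test_that("mean and pool aggregators match brute-force oracles", {
  expect_equal(aggregate_mean(list(c(1, 3), c(3, 5))), c(2, 4))
  expect_equal(aggregate_mean(list(c(7, 1))), c(7, 1))
  expect_equal(aggregate_pool(list(c(1, 3), c(3, 5))), c(3, 5))
  expect_equal(aggregate_pool(list(c(4, -2))), c(4, -2))

  set.seed(3)
  vecs <- lapply(1:50, function(i) rnorm(6))
  expect_equal(aggregate_mean(vecs), oracle_mean_agg(vecs),
               tolerance = 1e-12)
  expect_equal(aggregate_pool(vecs), oracle_max_agg(vecs),
               tolerance = 1e-12)

  # pool with a learned transform: sigma(pool_W h) then elementwise max
  W <- matrix(rnorm(18), 3, 6)
  man <- oracle_max_agg(lapply(vecs, function(v) pmax(W %*% v, 0)[, 1]))
  expect_equal(aggregate_pool(vecs, pool_W = W, sigma = function(x)
    pmax(x, 0)), man, tolerance = 1e-12)
  expect_error(aggregate_pool(vecs, pool_W = matrix(0, 3, 4)), "pool_W")
  expect_error(aggregate_mean(list()), "empty")
})

test_that("layer forward pass = concat, transform, nonlinearity, normalize", {
  W <- diag(4)
  out <- forward_layer(c(1, 0), c(0, 1), W, sigma = identity)
  expect_equal(out, c(1, 0, 0, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(4)
  for (i in 1:5) {
    W <- matrix(rnorm(5 * 8), 5, 8)
    hs <- rnorm(4); hn <- rnorm(4)
    got <- suppressWarnings(forward_layer(hs, hn, W))
    expect_equal(got, oracle_layer(hs, hn, W, function(x) max(x, 0)),
                 tolerance = 1e-12)
    nrm <- sqrt(sum(got^2))
    expect_true(abs(nrm - 1) < 1e-6 || nrm == 0)   # all-ReLU-dead stays zero
  }
  expect_error(forward_layer(c(1, NA), c(0, 1), diag(4)), "non-finite")
  expect_error(forward_layer(c(1, 0, 0), c(0, 1), diag(4)), "dimension")
})

test_that("random-walk pairs obey the walk contract", {
  set.seed(5)
  wp <- generate_walk_pairs(path2(), walks_per_node = 10, walk_length = 5)
  # on a two-node path every walk alternates, so the only pairs are (u, other)
  expect_setequal(unique(wp$pairs[wp$pairs[, "u"] == 1, "v"]), 2L)
  expect_setequal(unique(wp$pairs[wp$pairs[, "u"] == 2, "v"]), 1L)
  # each length-5 walk visits the other node twice
  expect_identical(nrow(wp$pairs), 2L * 10L * 2L)

  # walks start from every node
  set.seed(6)
  wp3 <- generate_walk_pairs(triangle(), 4, 3)
  expect_setequal(unique(wp3$pairs[, "u"]), 1:3)
  expect_true(all(wp3$pairs[, "u"] != wp3$pairs[, "v"]))

  expect_error(generate_walk_pairs(toy_graph(3,
    matrix(integer(0), 0, 2))), "no edges")
})

test_that("uniform walks pick each neighbour of a triangle equally often", {
  set.seed(7)
  wp <- generate_walk_pairs(triangle(), walks_per_node = 600,
                            walk_length = 2)
  # walk_length 2 => the single context node is the first uniform step
  from1 <- wp$pairs[wp$pairs[, "u"] == 1, "v"]
  frac <- mean(from1 == 2)
  expect_equal(frac, 0.5, tolerance = 0.08)
})

test_that("negative-sampling loss matches the scalar oracle and is nonnegative", {
  z <- c(1, 0)
  expect_equal(unsupervised_loss(c(1, 0), c(0, 1), list(c(0, 1))),
               2 * log(2), tolerance = 1e-12)
  # strongly aligned positive, strongly opposed negatives: loss -> 0
  big <- c(50, 0)
  expect_lt(unsupervised_loss(big, big, list(-big)), 1e-6)

  set.seed(8)
  for (i in 1:5) {
    zu <- rnorm(6); zu <- zu / sqrt(sum(zu^2))
    zv <- rnorm(6); zv <- zv / sqrt(sum(zv^2))
    negs <- lapply(1:5, function(j) {
      n <- rnorm(6); n / sqrt(sum(n^2))
    })
    got <- unsupervised_loss(zu, zv, negs, Q = 5)
    expect_equal(got, oracle_loss(zu, zv, negs, Q = 5), tolerance = 1e-12)
    expect_gte(got, 0)
  }
  expect_error(unsupervised_loss(z, z, list()), "empty")
})

test_that("exhaustive-mode mean aggregation equals the per-node oracle", {
  set.seed(9)
  n <- 20
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE]
  g <- toy_graph(n, cbind(keep[, 1], keep[, 2]),
                 features = matrix(rnorm(n * 4), n, 4))
  S <- rsnsage:::exact_agg_matrix(g)
  agg <- S %*% g$features
  for (v in seq_len(n)) {
    nb <- g$adj[[v]]
    if (!length(nb)) nb <- v
    expect_equal(agg[v, ],
                 oracle_mean_agg(lapply(nb, function(u) g$features[u, ])),
                 tolerance = 1e-12)
  }
})

test_that("training returns unit-norm, seed-deterministic embeddings", {
  co <- small_cohort()
  g <- small_graph(co)
  cfg <- sage_config(layer_sizes = c(30, 16), fanouts = c(10, 5),
                     epochs = 8, seed = 17)
  emb <- suppressWarnings(train_embeddings(g, cfg))
  expect_identical(dim(emb$z), c(g$n_nodes, 16L))
  nrm <- sqrt(rowSums(emb$z^2))
  # rows are unit-norm except nodes whose ReLU activations died entirely
  expect_true(all(abs(nrm - 1) < 1e-6 | nrm == 0))
  emb2 <- suppressWarnings(train_embeddings(g, cfg))
  expect_identical(emb$z, emb2$z)
  expect_identical(emb$history, emb2$history)
  expect_length(emb$history, 8)
  expect_true(all(is.finite(emb$history)))
})

test_that("pool-aggregator training runs and keeps the layer contracts", {
  co <- small_cohort()
  g <- small_graph(co)
  cfg <- sage_config(layer_sizes = c(20, 10), fanouts = c(8, 4),
                     epochs = 3, aggregator = "pool", seed = 21)
  emb <- suppressWarnings(train_embeddings(g, cfg))
  nrm <- sqrt(rowSums(emb$z^2))
  expect_true(all(abs(nrm - 1) < 1e-6 | nrm == 0))
  expect_identical(emb$z, suppressWarnings(train_embeddings(g, cfg))$z)
})

test_that("embeddings separate planted networks in cosine similarity", {
  # checked on the reference cohort, where training runs at full width
  res <- default_pipeline_run()
  co <- res$cohort
  emb <- res$embeddings
  cs <- emb$z %*% t(emb$z)
  same <- outer(co$true_labels, co$true_labels, "==")
  diag(same) <- NA
  within <- mean(cs[same & !is.na(same)])
  between <- mean(cs[!same & !is.na(same)])
  expect_gt(within, between)
})

test_that("config validation catches inconsistent shapes", {
  expect_error(sage_config(layer_sizes = c(10, 5), fanouts = 3), "length")
  expect_error(sage_config(dropout = 1), "dropout")
  expect_error(sage_config(batch_size = 0), "counts")
  expect_error(sage_config(learning_rate = -1), "positive")
})
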