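# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain loops and closed forms only.

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

oracle_corr_matrix <- function(ts) {
  n <- ncol(ts)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- if (i == j) 1 else oracle_pearson(ts[, i], ts[, j])
  out
}

oracle_elementwise_mean <- function(mats) {
  out <- mats[[1]] * 0
  for (m in mats) out <- out + m
  out / length(mats)
}

oracle_mean_agg <- function(vecs) {
  acc <- vecs[[1]] * 0
  for (v in vecs) acc <- acc + v
  acc / length(vecs)
}

oracle_max_agg <- function(vecs) {
  out <- vecs[[1]]
  for (v in vecs[-1]) out <- pmax(out, v)
  out
}

# step-by-step layer evaluation: concat, multiply, nonlinearity, L2 norm
oracle_layer <- function(h_self, h_neigh, W, sigma) {
  x <- c(h_self, h_neigh)
  h <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) h[i] <- sigma(sum(W[i, ] * x))
  nrm <- sqrt(sum(h^2))
  if (nrm == 0) h else h / nrm
}

# scalar, term-by-term negative-sampling loss
oracle_loss <- function(z_u, z_v, z_negs, Q = length(z_negs)) {
  sig <- function(x) 1 / (1 + exp(-x))
  total <- -log(sig(sum(z_u * z_v)))
  for (zn in z_negs) total <- total - (Q / length(z_negs)) *
      log(sig(-sum(z_u * zn)))
  total
}

# explained-variance fractions from an explicit covariance eigendecomposition
oracle_pca_fractions <- function(z) {
  ev <- eigen(stats::cov(z), symmetric = TRUE)$values
  ev / sum(ev)
}

oracle_best_jaccard <- function(labels, k, reference, ids) {
  best <- 0L; best_j <- -1
  for (cl in seq_len(k)) {
    members <- ids[labels == cl]
    j <- length(intersect(members, reference)) /
      length(union(members, reference))
    if (j > best_j) { best_j <- j; best <- cl }
  }
  list(cluster = best, jaccard = best_j)
}

oracle_t_stat <- function(z) {
  n <- length(z)
  mu <- sum(z) / n
  s <- sqrt(sum((z - mu)^2) / (n - 1))
  mu / (s / sqrt(n))
}
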