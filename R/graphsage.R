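#' GraphSAGE training configuration
#'
#' Defaults follow the pipeline's reference configuration: a two-layer
#' network with 200 then 100 hidden units, fan-outs of 50 (1-hop) and 10
#' (2-hop), 10 random walks of length 5 per node, minibatches of 10
#' positive pairs, learning rate 0.01 with Adam, 100 epochs, dropout 0.15.
#'
#' @param layer_sizes integer vector of hidden sizes, one per layer.
#' @param fanouts integer vector of neighbour sample sizes, one per layer
#'   (first entry = 1-hop fan-out).
#' @param walks_per_node random walks started from every node.
#' @param walk_length nodes per walk (a walk of length L takes L-1 steps).
#' @param batch_size positive pairs per gradient step.
#' @param learning_rate Adam step size.
#' @param epochs passes over the positive-pair set.
#' @param dropout input dropout rate for every weight matrix, in \[0, 1).
#' @param negatives_Q negative samples drawn per positive pair.
#' @param aggregator `"mean"` (neighbourhood average) or `"pool"`
#'   (elementwise max of a learned transform of each neighbour).
#' @param seed integer seed controlling walks, sampling, dropout and
#'   initialization.
#' @return An object of class `sage_config`.
#' @export
sage_config <- function(layer_sizes = c(200L, 100L), fanouts = c(50L, 10L),
                        walks_per_node = 10L, walk_length = 5L,
                        batch_size = 10L, learning_rate = 0.01,
                        epochs = 100L, dropout = 0.15, negatives_Q = 5L,
                        aggregator = c("mean", "pool"), seed = 42L) {
  aggregator <- match.arg(aggregator)
  layer_sizes <- as.integer(layer_sizes)
  fanouts <- as.integer(fanouts)
  if (length(layer_sizes) != length(fanouts))
    stop("layer_sizes and fanouts must have the same length", call. = FALSE)
  if (any(c(layer_sizes, fanouts, walks_per_node, walk_length, batch_size,
            epochs, negatives_Q) < 1L))
    stop("all counts must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)",
                                        call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(list(layer_sizes = layer_sizes, fanouts = fanouts,
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 dropout = dropout, negatives_Q = as.integer(negatives_Q),
                 aggregator = aggregator, seed = as.integer(seed)),
            class = "sage_config")
}

relu <- function(x) pmax(x, 0)

logistic <- function(x) 1 / (1 + exp(-x))

# Row-wise L2 normalization; all-zero rows are left at zero.
normalize_rows <- function(m, warn = TRUE) {
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  if (any(zero) && warn)
    warning(sum(zero), " zero vector(s) left unnormalized", call. = FALSE)
  nrm[zero] <- 1
  list(h = m / nrm, norm = nrm, zero = zero)
}

#' Sample a fixed-size neighbourhood of one node
#'
#' Draws exactly `fanout` neighbours uniformly with replacement from N(v).
#' An isolated node falls back to `fanout` copies of itself so every node
#' always has an aggregate. With `exact = TRUE` sampling is disabled and
#' the full neighbourhood is returned (the node itself if isolated).
#'
#' @param graph a `brain_graph`.
#' @param node 1-based node index.
#' @param fanout number of draws.
#' @param exact return N(v) exactly instead of sampling.
#' @return Integer vector of node indices (a multiset when sampling).
#' @export
sample_neighbors <- function(graph, node, fanout, exact = FALSE) {
  stopifnot(inherits(graph, "brain_graph"))
  node <- as.integer(node)
  if (node < 1L || node > graph$n_nodes)
    stop("unknown node index: ", node, call. = FALSE)
  nb <- graph$adj[[node]]
  if (!length(nb)) nb <- node
  if (exact) return(nb)
  nb[sample.int(length(nb), fanout, replace = TRUE)]
}

#' Mean aggregator
#'
#' Elementwise average of the neighbour representations,
#' \eqn{f(\{h_u\}) = \sum_{u \in N(v)} h_u / |N(v)|}.
#'
#' @param neighbor_vectors matrix with one neighbour vector per row, or a
#'   list of equal-length numeric vectors.
#' @return The aggregated vector.
#' @export
aggregate_mean <- function(neighbor_vectors) {
  m <- as_neighbor_matrix(neighbor_vectors)
  colMeans(m)
}

#' Max-pooling aggregator
#'
#' Elementwise maximum of `sigma(pool_W %*% h_u)` over the neighbour set.
#' With `pool_W = NULL` and `sigma = identity` this reduces to a plain
#' elementwise maximum.
#'
#' @param neighbor_vectors matrix (rows = neighbours) or list of vectors.
#' @param pool_W optional pre-pooling weight matrix (rows = output dims).
#' @param sigma elementwise nonlinearity applied before pooling.
#' @return The pooled vector.
#' @export
aggregate_pool <- function(neighbor_vectors, pool_W = NULL, sigma = identity) {
  m <- as_neighbor_matrix(neighbor_vectors)
  if (!is.null(pool_W)) {
    if (ncol(pool_W) != ncol(m))
      stop("pool_W column count must match neighbour vector length",
           call. = FALSE)
    m <- m %*% t(pool_W)
  }
  m <- sigma(m)
  apply(m, 2, max)
}

as_neighbor_matrix <- function(x) {
  if (is.list(x)) {
    if (!length(x)) stop("empty neighbour set", call. = FALSE)
    lens <- lengths(x)
    if (any(lens != lens[1]))
      stop("neighbour vectors must share one dimension", call. = FALSE)
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty neighbour set", call. = FALSE)
  x
}

#' One GraphSAGE layer for a single node
#'
#' Concatenates the node's own representation with its aggregated
#' neighbourhood, applies the layer weights and nonlinearity, and
#' L2-normalizes: \eqn{h_v = \sigma(W [h_v \| h_{N(v)}]) / \|\cdot\|_2}.
#' A vector that is all zero after the nonlinearity is left at zero.
#'
#' @param h_self node's current representation.
#' @param h_neigh aggregated neighbourhood representation.
#' @param W weight matrix, `ncol(W) == length(h_self) + length(h_neigh)`.
#' @param sigma elementwise nonlinearity (default ReLU).
#' @return The normalized layer output.
#' @export
forward_layer <- function(h_self, h_neigh, W, sigma = relu) {
  x <- c(h_self, h_neigh)
  if (!all(is.finite(x))) stop("non-finite layer input", call. = FALSE)
  if (ncol(W) != length(x))
    stop("W expects input dimension ", ncol(W), ", got ", length(x),
         call. = FALSE)
  h <- sigma(as.vector(W %*% x))
  normalize_rows(matrix(h, 1))$h[1, ]
}

#' Random-walk positive pairs
#'
#' Starts `walks_per_node` uniform random walks of `walk_length` nodes from
#' every node (walks are truncated at dead ends). Each walk contributes the
#' positive pairs (start node, every other node on the walk). The negative
#' distribution is uniform over all nodes.
#'
#' @param graph a `brain_graph` with at least one edge.
#' @param walks_per_node,walk_length walk parameters.
#' @return A `walk_pairs` object: integer matrix `pairs` with columns `u`,
#'   `v`, plus the walk parameters.
#' @export
generate_walk_pairs <- function(graph, walks_per_node = 10L,
                                walk_length = 5L) {
  stopifnot(inherits(graph, "brain_graph"))
  if (!nrow(graph$edges)) stop("graph has no edges; cannot walk",
                               call. = FALSE)
  n <- graph$n_nodes
  us <- vector("list", n * walks_per_node)
  vs <- vector("list", n * walks_per_node)
  w <- 0L
  for (start in seq_len(n)) {
    for (rep in seq_len(walks_per_node)) {
      walk <- integer(walk_length)
      walk[1] <- start
      len <- 1L
      while (len < walk_length) {
        nb <- graph$adj[[walk[len]]]
        if (!length(nb)) break
        walk[len + 1L] <- nb[sample.int(length(nb), 1L)]
        len <- len + 1L
      }
      ctx <- walk[seq_len(len)][-1L]
      ctx <- ctx[ctx != start]
      w <- w + 1L
      if (length(ctx)) {
        us[[w]] <- rep(start, length(ctx))
        vs[[w]] <- ctx
      }
    }
  }
  pairs <- cbind(u = unlist(us), v = unlist(vs))
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2,
                                      dimnames = list(NULL, c("u", "v")))
  structure(list(pairs = pairs, n_nodes = n,
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length)),
            class = "walk_pairs")
}

#' Negative-sampling loss for one positive pair
#'
#' \deqn{J = -\log\sigma(z_u^\top z_v)
#'        - Q \cdot \mathbb{E}_{v_n \sim P_n}\log\sigma(-z_u^\top z_{v_n}),}
#' with the expectation replaced by the mean over the supplied negative
#' samples and \eqn{\sigma} the logistic sigmoid. Always nonnegative.
#'
#' @param z_u,z_v embeddings of the positive pair.
#' @param z_negs matrix (rows = negatives) or list of negative embeddings.
#' @param Q weight on the negative expectation; defaults to the number of
#'   negatives supplied, which turns the term into a plain sum.
#' @return The scalar loss.
#' @export
unsupervised_loss <- function(z_u, z_v, z_negs, Q = NULL) {
  zn <- as_neighbor_matrix(z_negs)
  if (is.null(Q)) Q <- nrow(zn)
  if (Q > 0 && !nrow(zn)) stop("Q > 0 requires negative samples",
                               call. = FALSE)
  pos <- -log(logistic(sum(z_u * z_v)))
  neg <- -Q * mean(log(logistic(-as.vector(zn %*% z_u))))
  pos + neg
}

# --- full-graph sampled forward pass -------------------------------------

# Neighbour-sampling matrix: row v holds the empirical frequencies of
# `fanout` uniform draws (with replacement) from N(v); isolated nodes
# average over themselves.
sample_agg_matrix <- function(graph, fanout) {
  n <- graph$n_nodes
  deg <- lengths(graph$adj)
  flat <- unlist(graph$adj, use.names = FALSE)
  off <- c(0L, cumsum(deg))
  rows <- rep(seq_len(n), each = fanout)
  pick <- floor(stats::runif(n * fanout) * deg[rows]) + 1L + off[rows]
  cols <- integer(n * fanout)
  has <- deg[rows] > 0L
  cols[has] <- flat[pick[has]]
  cols[!has] <- rows[!has]           # isolated-node self-fallback
  counts <- tabulate(rows + n * (cols - 1L), nbins = n * n)
  matrix(counts, n, n) / fanout
}

# Exact mean-aggregation matrix (full neighbourhoods).
exact_agg_matrix <- function(graph) {
  n <- graph$n_nodes
  s <- matrix(0, n, n)
  for (v in seq_len(n)) {
    nb <- graph$adj[[v]]
    if (!length(nb)) nb <- v
    s[v, nb] <- 1 / length(nb)
  }
  s
}

glorot <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

init_sage_params <- function(in_dim, config) {
  K <- length(config$layer_sizes)
  params <- vector("list", K)
  d_prev <- in_dim
  for (k in seq_len(K)) {
    p <- list(W = glorot(config$layer_sizes[k], 2L * d_prev))
    if (config$aggregator == "pool") p$pool_W <- glorot(d_prev, d_prev)
    params[[k]] <- p
    d_prev <- config$layer_sizes[k]
  }
  params
}

# Per-layer pooled aggregation over sampled neighbour ids.
# samp: n x fanout matrix of neighbour indices. Returns aggregate plus the
# bookkeeping needed for backprop (argmax indices, ReLU mask input).
pool_aggregate_sampled <- function(h, samp, pool_W) {
  q_pre <- h %*% t(pool_W)
  q <- relu(q_pre)
  n <- nrow(h); d <- ncol(q)
  agg <- matrix(0, n, d)
  amax <- matrix(0L, n, d)
  for (v in seq_len(n)) {
    block <- q[samp[v, ], , drop = FALSE]
    j <- max.col(t(block), ties.method = "first")
    amax[v, ] <- samp[v, j]
    agg[v, ] <- block[cbind(j, seq_len(d))]
  }
  list(agg = agg, amax = amax, q_pre = q_pre)
}

# Forward pass over every node. sampling = "sampled" draws fresh fan-out
# neighbourhoods (training); "exact" uses full neighbourhoods (inference
# and the exhaustive-mode tests). Returns all intermediates for backprop.
sage_forward <- function(graph, params, config,
                         sampling = c("sampled", "exact"),
                         dropout_active = FALSE) {
  sampling <- match.arg(sampling)
  K <- length(params)
  h <- graph$features
  layers <- vector("list", K)
  for (k in seq_len(K)) {
    st <- list()
    if (config$aggregator == "mean") {
      st$S <- if (sampling == "sampled")
        sample_agg_matrix(graph, config$fanouts[k]) else
        exact_agg_matrix(graph)
      agg <- st$S %*% h
    } else {
      if (sampling == "sampled") {
        st$samp <- t(vapply(seq_len(graph$n_nodes), function(v)
          sample_neighbors(graph, v, config$fanouts[k]),
          integer(config$fanouts[k])))
      } else {
        maxdeg <- max(lengths(graph$adj), 1L)
        st$samp <- t(vapply(seq_len(graph$n_nodes), function(v) {
          nb <- graph$adj[[v]]
          if (!length(nb)) nb <- v
          nb[c(seq_along(nb), rep(1L, maxdeg - length(nb)))]
        }, integer(maxdeg)))
      }
      pl <- pool_aggregate_sampled(h, st$samp, params[[k]]$pool_W)
      st$pool <- pl
      agg <- pl$agg
    }
    a <- cbind(h, agg)
    if (dropout_active && config$dropout > 0) {
      st$mask <- matrix(stats::runif(length(a)) >= config$dropout,
                        nrow(a), ncol(a)) / (1 - config$dropout)
      a_d <- a * st$mask
    } else a_d <- a
    pre <- tcrossprod(a_d, params[[k]]$W)
    act <- relu(pre)
    nm <- normalize_rows(act, warn = FALSE)
    st$h_in <- h; st$a_d <- a_d; st$pre <- pre; st$act <- act
    st$norm <- nm$norm; st$zero <- nm$zero
    layers[[k]] <- st
    h <- nm$h
  }
  list(z = h, layers = layers)
}

# Backward pass: gradient of the (already averaged) loss wrt each W (and
# pool_W). dz is n x d_K.
sage_backward <- function(graph, params, config, fwd, dz) {
  K <- length(params)
  grads <- vector("list", K)
  for (k in rev(seq_len(K))) {
    st <- fwd$layers[[k]]
    # through row normalization (zero rows pass no gradient)
    zrow <- st$act / st$norm
    dact <- (dz - zrow * rowSums(dz * zrow)) / st$norm
    dact[st$zero, ] <- 0
    dpre <- dact * (st$pre > 0)
    gW <- crossprod(dpre, st$a_d)
    da <- dpre %*% params[[k]]$W
    if (!is.null(st$mask)) da <- da * st$mask
    d_in <- ncol(st$h_in)
    dh <- da[, seq_len(d_in), drop = FALSE]
    dagg <- da[, d_in + seq_len(ncol(da) - d_in), drop = FALSE]
    if (config$aggregator == "mean") {
      dh <- dh + crossprod(st$S, dagg)
      grads[[k]] <- list(W = gW)
    } else {
      # gradient reaches only the argmax neighbour of each output unit
      pl <- st$pool
      n <- nrow(dagg); d <- ncol(dagg)
      dq <- matrix(0, n, d)
      for (j in seq_len(d)) {
        acc <- rowsum(dagg[, j], group = pl$amax[, j])
        dq[as.integer(rownames(acc)), j] <-
          dq[as.integer(rownames(acc)), j] + acc
      }
      dq_pre <- dq * (pl$q_pre > 0)
      gPool <- t(dq_pre) %*% st$h_in
      dh <- dh + dq_pre %*% params[[k]]$pool_W
      grads[[k]] <- list(W = gW, pool_W = gPool)
    }
    dz <- dh
  }
  grads
}

adam_state <- function(params) {
  lapply(params, function(p) lapply(p, function(w)
    list(m = w * 0, v = w * 0)))
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in seq_along(params)) {
    for (nm in names(params[[k]])) {
      g <- grads[[k]][[nm]]
      s <- state[[k]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      params[[k]][[nm]] <- params[[k]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[k]][[nm]] <- s
    }
  }
  list(params = params, state = state)
}

draw_negatives <- function(n_nodes, u, v, Q) {
  neg <- sample.int(n_nodes, Q, replace = TRUE)
  bad <- neg == u | neg == v
  while (any(bad)) {
    neg[bad] <- sample.int(n_nodes, sum(bad), replace = TRUE)
    bad <- neg == u | neg == v
  }
  neg
}

#' Train unsupervised GraphSAGE node embeddings
#'
#' Learns embeddings by minibatch Adam on the random-walk negative-sampling
#' loss. Each gradient step draws fresh fixed-fan-out neighbourhoods,
#' applies input dropout to every weight matrix (training only), and
#' updates the layer weights from `batch_size` positive pairs with
#' `negatives_Q` uniform negatives each (negatives colliding with the pair
#' are redrawn). The returned embeddings are computed with dropout off and
#' exact (full-neighbourhood) aggregation, so they are deterministic given
#' the seed; every row has unit L2 norm unless a node's activation is
#' identically zero.
#'
#' @param graph a `brain_graph` with node features.
#' @param config a [sage_config()].
#' @return A `node_embeddings` object: `z` (n_nodes x last layer size,
#'   rows named by ROI id), `roi_ids`, `history` (per-epoch mean minibatch
#'   loss), and the `config`.
#' @export
train_embeddings <- function(graph, config = sage_config()) {
  stopifnot(inherits(graph, "brain_graph"), inherits(config, "sage_config"))
  withr_seed_eval(config$seed, {
    params <- init_sage_params(ncol(graph$features), config)
    wp <- generate_walk_pairs(graph, config$walks_per_node,
                              config$walk_length)
    pairs <- wp$pairs
    if (!nrow(pairs)) stop("no positive pairs generated", call. = FALSE)
    state <- adam_state(params)
    n <- graph$n_nodes
    Q <- config$negatives_Q
    B <- config$batch_size
    history <- numeric(config$epochs)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(pairs))
      starts <- seq(1L, nrow(pairs), by = B)
      ep_loss <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + B - 1L, nrow(pairs))]
        b <- length(idx)
        u <- pairs[idx, 1L]; v <- pairs[idx, 2L]
        negs <- t(vapply(seq_len(b),
                         function(i) draw_negatives(n, u[i], v[i], Q),
                         integer(Q)))
        fwd <- sage_forward(graph, params, config, "sampled",
                            dropout_active = TRUE)
        z <- fwd$z
        zu <- z[u, , drop = FALSE]; zv <- z[v, , drop = FALSE]
        s_pos <- rowSums(zu * zv)
        urep <- rep(u, times = Q)
        nidx <- as.vector(negs)
        zur <- z[urep, , drop = FALSE]; znd <- z[nidx, , drop = FALSE]
        s_neg <- rowSums(zur * znd)
        loss <- mean(-log(logistic(s_pos))) * 1 +
          sum(-log(logistic(-s_neg))) / b
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch, "; step ", step,
               call. = FALSE)
        g_pos <- -logistic(-s_pos) / b
        g_neg <- logistic(s_neg) / b
        tgt <- c(u, v, urep, nidx)
        contrib <- rbind(zv * g_pos, zu * g_pos, znd * g_neg, zur * g_neg)
        acc <- rowsum(contrib, group = tgt)
        dz <- matrix(0, n, ncol(z))
        dz[as.integer(rownames(acc)), ] <- acc
        grads <- sage_backward(graph, params, config, fwd, dz)
        step <- step + 1L
        upd <- adam_update(params, grads, state, config$learning_rate, step)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss
      }
      history[epoch] <- ep_loss / length(starts)
    }
    z_final <- sage_forward(graph, params, config, "exact",
                            dropout_active = FALSE)$z
    dead <- rowSums(z_final^2) == 0
    if (any(dead))
      warning(sum(dead), " node(s) have all-zero embeddings ",
              "(dead ReLU activations); consider wider layers",
              call. = FALSE)
    rownames(z_final) <- graph$roi_ids
    structure(list(z = z_final, roi_ids = graph$roi_ids, history = history,
                   params = params, config = config),
              class = "node_embeddings")
  })
}

#' @export
print.node_embeddings <- function(x, ...) {
  cat(sprintf("<node_embeddings> %d nodes x %d dims; final mean loss %.4f\n",
              nrow(x$z), ncol(x$z), utils::tail(x$history, 1)))
  invisible(x)
}
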