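#' PCA reduction at a retained-variance target
#'
#' Centers the embedding matrix and projects it onto the smallest number of
#' principal axes whose cumulative explained-variance fraction reaches
#' `variance_target` (default 95%). Axis signs are fixed by making each
#' axis's largest-magnitude loading positive, so the result is fully
#' deterministic.
#'
#' @param z a `node_embeddings` object or a plain numeric matrix
#'   (rows = nodes).
#' @param variance_target fraction of total variance to retain, in (0, 1\].
#' @return A `reduced_embeddings` object: `coords` (n x p scores),
#'   `explained_variance_fractions` (length p, fractions of the total),
#'   `rotation`, `center`, `p`.
#' @export
pca_reduce <- function(z, variance_target = 0.95) {
  if (inherits(z, "node_embeddings")) z <- z$z
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("non-finite embedding entries", call. = FALSE)
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must lie in (0, 1]", call. = FALSE)
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  cum <- cumsum(frac)
  p <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(p)) p <- length(frac)
  rot <- pc$rotation[, seq_len(p), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each axis made positive
  for (j in seq_len(p)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  coords <- sweep(z, 2, pc$center) %*% rot
  structure(list(coords = coords,
                 explained_variance_fractions = frac[seq_len(p)],
                 all_variance_fractions = frac,
                 rotation = rot, center = pc$center, p = p),
            class = "reduced_embeddings")
}

# Squared Euclidean distances from every row of x to every centroid row.
sq_dist_to_centroids <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- pmax(sq_dist_to_centroids(x, centers[1, , drop = FALSE])[, 1], 0)
  for (j in seq_len(k - 1L)) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j + 1L, ] <- x[pick, ]
    d2 <- pmin(d2, pmax(sq_dist_to_centroids(
      x, centers[j + 1L, , drop = FALSE])[, 1], 0))
  }
  centers
}

lloyd_once <- function(x, k, max_iter) {
  centers <- kmeanspp_init(x, k)
  labels <- integer(nrow(x))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- pmax(sq_dist_to_centroids(x, centers), 0)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty cluster: re-seed its centroid from the farthest point
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        mind2 <- d2[cbind(seq_len(nrow(x)), new_labels)]
        far <- which.max(mind2)
        centers[j, ] <- x[far, ]
        new_labels[far] <- j
        d2 <- pmax(sq_dist_to_centroids(x, centers), 0)
      }
    }
    trace <- c(trace, sum(d2[cbind(seq_len(nrow(x)), new_labels)]))
    converged <- it > 1L && all(new_labels == labels)
    labels <- new_labels
    if (converged) break
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
  }
  d2 <- pmax(sq_dist_to_centroids(x, centers), 0)
  inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  trace <- c(trace, inertia)
  list(labels = labels, centers = centers, inertia = inertia, trace = trace)
}

#' Partition node coordinates with Lloyd k-means
#'
#' k-means++ seeding, Lloyd assignment/update iterations until assignments
#' stop changing (or `max_iter`), `n_restarts` independent restarts keeping
#' the lowest within-cluster sum of squares. An emptied cluster is
#' re-seeded from the point farthest from its current centroid.
#'
#' @param coords numeric matrix (rows = nodes) or a `reduced_embeddings`.
#' @param k number of clusters (default 7).
#' @param seed integer seed; the result is deterministic given it.
#' @param n_restarts independent k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @param roi_ids optional ROI identifiers for the partition.
#' @return A `network_partition`: `labels` (1..k, named by ROI id when
#'   known), `k`, `inertia`, `centers`, `inertia_trace` (per-iteration
#'   objective of the winning restart), `dmn_cluster` (NA until
#'   [identify_network()] is run).
#' @export
kmeans_cluster <- function(coords, k = 7L, seed = 42L, n_restarts = 10L,
                           max_iter = 300L, roi_ids = NULL) {
  if (inherits(coords, "reduced_embeddings")) {
    if (is.null(roi_ids)) roi_ids <- rownames(coords$coords)
    coords <- coords$coords
  }
  coords <- as.matrix(coords)
  k <- as.integer(k)
  if (k < 1L || k > nrow(coords))
    stop("k must lie in [1, number of nodes]", call. = FALSE)
  if (is.null(roi_ids)) roi_ids <- rownames(coords)
  best <- withr_seed_eval(seed, {
    b <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(coords, k, max_iter)
      if (is.null(b) || fit$inertia < b$inertia) b <- fit
    }
    b
  })
  labels <- best$labels
  if (!is.null(roi_ids)) names(labels) <- roi_ids
  structure(list(labels = labels, k = k, inertia = best$inertia,
                 centers = best$centers, inertia_trace = best$trace,
                 dmn_cluster = NA_integer_),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d ROIs in %d clusters, inertia %.4f%s\n",
              length(x$labels), x$k, x$inertia,
              if (is.na(x$dmn_cluster)) "" else
                sprintf(", DMN = cluster %d", x$dmn_cluster)))
  invisible(x)
}

#' Identify the cluster matching a reference network
#'
#' Scores every cluster by Jaccard overlap with a reference ROI set (for
#' the default mode network: PCC, precuneus, MPFC, inferior parietal
#' regions of the atlas in use) and returns the best-scoring cluster.
#' Ties break toward the lower cluster index.
#'
#' @param partition a `network_partition` with named labels.
#' @param reference_rois character vector of reference ROI ids.
#' @return The partition with `dmn_cluster` and `dmn_jaccard` filled in.
#' @export
identify_network <- function(partition, reference_rois) {
  stopifnot(inherits(partition, "network_partition"))
  ids <- names(partition$labels)
  if (is.null(ids)) stop("partition labels carry no ROI ids", call. = FALSE)
  reference_rois <- as.character(reference_rois)
  if (!length(reference_rois)) stop("empty reference set", call. = FALSE)
  missing <- setdiff(reference_rois, ids)
  if (length(missing))
    stop("reference ROIs not in partition: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  jac <- vapply(seq_len(partition$k), function(j) {
    members <- ids[partition$labels == j]
    length(intersect(members, reference_rois)) /
      length(union(members, reference_rois))
  }, numeric(1))
  best <- which.max(jac)          # which.max takes the first (lowest) index
  partition$dmn_cluster <- as.integer(best)
  partition$dmn_jaccard <- jac[best]
  message(sprintf("DMN cluster = %d (Jaccard %.3f)", best, jac[best]))
  partition
}

#' Score recovery of planted network labels
#'
#' Adjusted Rand index and normalized mutual information between a
#' partition and ground-truth labels. Both are invariant to cluster
#' relabeling; ARI is 1 exactly when the partitions agree up to renaming.
#'
#' @param partition a `network_partition` (or a bare label vector).
#' @param true_labels integer vector of planted network labels, same
#'   length and ROI order.
#' @return List with `ari` and `nmi`.
#' @export
evaluate_recovery <- function(partition, true_labels) {
  labels <- if (inherits(partition, "network_partition"))
    partition$labels else partition
  if (length(labels) != length(true_labels))
    stop("label vectors differ in length", call. = FALSE)
  labels <- as.integer(factor(labels))
  truth <- as.integer(factor(true_labels))
  ari <- mclust::adjustedRandIndex(labels, truth)
  nmi <- igraph::compare(labels, truth, method = "nmi")
  list(ari = ari, nmi = nmi)
}
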