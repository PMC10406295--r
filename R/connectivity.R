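#' Pearson correlation between two time series
#'
#' Thin, strict wrapper around the product-moment correlation
#' \deqn{r_{xy} = \frac{\sum_t (x_t-\bar x)(y_t-\bar y)}
#'   {\sqrt{\sum_t (x_t-\bar x)^2}\sqrt{\sum_t (y_t-\bar y)^2}}.}
#' Unlike [stats::cor()], a constant series is an error rather than `NA`:
#' a flat ROI signal has no defined connectivity.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A single correlation value in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("series lengths differ: ", length(x), " vs ", length(y),
         call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  stats::cor(x, y)
}

#' Correlation matrix of one subject's ROI time series
#'
#' @param ts numeric matrix, time points in rows and ROIs in columns.
#' @return A `corr_matrix` object: list with `values` (symmetric, unit
#'   diagonal) and `roi_ids`.
#' @export
subject_correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points", call. = FALSE)
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    ids <- colnames(ts)
    bad <- which(v == 0)[1]
    stop("constant ROI column: ",
         if (is.null(ids)) bad else ids[bad], call. = FALSE)
  }
  m <- stats::cor(ts)
  # enforce exact symmetry / unit diagonal against rounding
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ids <- colnames(ts)
  if (is.null(ids)) ids <- roi_names(ncol(ts))
  corr_matrix(m, ids)
}

corr_matrix <- function(values, roi_ids) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values),
            length(roi_ids) == nrow(values))
  if (max(abs(values - t(values))) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (any(values > 1 + 1e-8 | values < -1 - 1e-8))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  dimnames(values) <- list(roi_ids, roi_ids)
  structure(list(values = values, roi_ids = as.character(roi_ids)),
            class = "corr_matrix")
}

#' Per-subject correlation matrices for a cohort
#'
#' @param cohort a [cohort_ts()].
#' @return List of `corr_matrix`, one per subject.
#' @export
cohort_correlation_matrices <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_ts"))
  lapply(cohort$subjects, function(ts) {
    colnames(ts) <- cohort$roi_ids
    subject_correlation_matrix(ts)
  })
}

#' Elementwise mean of subject correlation matrices
#'
#' @param mats list of `corr_matrix` with identical ROI ids and order.
#' @return A `corr_matrix` holding the group-mean correlations.
#' @export
group_mean_correlation <- function(mats) {
  if (!length(mats)) stop("need at least one matrix", call. = FALSE)
  ids <- mats[[1]]$roi_ids
  for (m in mats) {
    if (!inherits(m, "corr_matrix")) stop("inputs must be corr_matrix objects",
                                          call. = FALSE)
    if (!identical(m$roi_ids, ids))
      stop("ROI ids/order differ across subjects", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats)
  corr_matrix(avg, ids)
}

#' Build the thresholded brain graph
#'
#' Starts from the complete graph on the ROIs and drops every edge whose
#' group-mean correlation is below `threshold` (signed comparison, so
#' negative correlations are dropped). The feature vector of node i is row i
#' of the thresholded correlation matrix: entries below the threshold and
#' the diagonal are zeroed, so features vanish exactly where edges do.
#'
#' @param mean_corr a `corr_matrix` of group-mean correlations.
#' @param threshold edge-retention cutoff in (-1, 1); default 0.1.
#' @param feature_mode `"thresholded"` (default) uses the zeroed rows as
#'   node features; `"raw"` keeps the untouched correlation rows
#'   (diagonal still zeroed).
#' @return A `brain_graph` object: `n_nodes`, two-column `edges` matrix
#'   (i < j, 1-based indices), adjacency list `adj`, `features`
#'   (n_nodes x n_nodes), `roi_ids`.
#' @export
build_graph <- function(mean_corr, threshold = 0.1,
                        feature_mode = c("thresholded", "raw")) {
  stopifnot(inherits(mean_corr, "corr_matrix"))
  feature_mode <- match.arg(feature_mode)
  if (!is.numeric(threshold) || threshold <= -1 || threshold >= 1)
    stop("threshold must lie in (-1, 1)", call. = FALSE)
  m <- mean_corr$values
  n <- nrow(m)
  keep <- m >= threshold
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE])
  feat <- m
  if (feature_mode == "thresholded") feat[m < threshold] <- 0
  diag(feat) <- 0
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    both <- rbind(edges, edges[, 2:1, drop = FALSE])
    sp <- split(both[, 2], factor(both[, 1], levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(as.integer(v)))
  }
  iso <- which(lengths(adj) == 0L)
  if (length(iso))
    warning(sprintf("%d isolated node(s) after thresholding: %s",
                    length(iso),
                    paste(mean_corr$roi_ids[utils::head(iso, 5)],
                          collapse = ", ")), call. = FALSE)
  structure(list(n_nodes = n, edges = edges, adj = adj,
                 features = unname(feat), roi_ids = mean_corr$roi_ids),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> %d nodes, %d edges, %d-dim node features\n",
              x$n_nodes, nrow(x$edges), ncol(x$features)))
  invisible(x)
}

#' Number of edges in the complete (unthresholded) graph on n nodes
#'
#' Every pair of distinct ROIs makes one undirected edge, so the count is
#' n(n-1)/2 — e.g. 319,600 for an 800-ROI parcellation.
#'
#' @param n_nodes node count.
#' @return Edge count of the complete graph.
#' @export
complete_graph_edge_count <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 1L)
  n_nodes * (n_nodes - 1) / 2
}
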