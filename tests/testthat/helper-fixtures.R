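# Shared fixtures, built in code at test time.

# A tiny graph from an explicit edge list, with identity-ish features.
toy_graph <- function(n, edges, features = NULL) {
  if (is.null(features)) features <- diag(n)
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    both <- rbind(edges, edges[, 2:1, drop = FALSE])
    for (v in seq_len(n)) adj[[v]] <- sort(both[both[, 1] == v, 2])
  }
  structure(list(n_nodes = n, edges = edges, adj = adj,
                 features = features, roi_ids = sprintf("ROI_%03d", 1:n)),
            class = "brain_graph")
}

# Small cohort used across modules (fast, clearly separated blocks).
small_cohort <- function(seed = 11) {
  simulate_cohort(synthetic_config(n_rois = 24, n_networks = 3,
                                   n_subjects = 4, n_timepoints = 150,
                                   rho = 0.7, seed = seed))
}

small_graph <- function(cohort = small_cohort()) {
  suppressWarnings(build_graph(group_mean_correlation(
    cohort_correlation_matrices(cohort))))
}

# The reference-condition cohort (70 ROIs, 7 planted networks, 10 subjects,
# 180 time points, rho = 0.6) run through the full pipeline once and cached
# for every test that needs it — training dominates the suite's runtime.
default_pipeline_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(run_pipeline(pipeline_config(seed = 1)))
    cache
  }
})
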