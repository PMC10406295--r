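#' Write a cohort to disk
#'
#' One TSV per subject (header row = ROI ids, one row per time point) plus
#' a `manifest.json` echoing the configuration, the file list, and the
#' planted labels when known. Numeric values are written with 9
#' significant digits.
#'
#' @param cohort a [cohort_ts()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_ts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    files[s] <- sprintf("subject_%03d.tsv", s)
    write_tsv_matrix(cohort$subjects[[s]], file.path(dir, files[s]),
                     col_ids = cohort$roi_ids)
  }
  manifest <- list(
    n_subjects = length(cohort$subjects),
    n_timepoints = nrow(cohort$subjects[[1]]),
    n_rois = length(cohort$roi_ids),
    roi_ids = cohort$roi_ids,
    files = files,
    true_labels = cohort$true_labels,
    config = if (!is.null(cohort$config)) unclass(cohort$config))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

write_tsv_matrix <- function(m, path, col_ids = colnames(m),
                             row_ids = NULL, row_label = "roi_id") {
  fm <- format(m, digits = 9, trim = TRUE, scientific = FALSE)
  df <- as.data.frame(fm, stringsAsFactors = FALSE)
  names(df) <- col_ids
  if (!is.null(row_ids)) {
    df <- cbind(stats::setNames(data.frame(row_ids,
                                           stringsAsFactors = FALSE),
                                row_label), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_cohort()].
#' @return A validated [cohort_ts()]; ROI order is taken from the first
#'   subject's header and enforced on all others.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  subjects <- vector("list", length(man$files))
  roi_ids <- NULL
  for (s in seq_along(man$files)) {
    path <- file.path(dir, man$files[s])
    if (!file.exists(path))
      stop("subject file missing: ", man$files[s], call. = FALSE)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
    if (is.null(roi_ids)) roi_ids <- colnames(df)
    if (!identical(colnames(df), roi_ids))
      stop("ROI header mismatch in ", man$files[s], call. = FALSE)
    if (nrow(df) != man$n_timepoints)
      stop("unexpected row count in ", man$files[s],
           " (file truncated?)", call. = FALSE)
    subjects[[s]] <- as.matrix(df)
  }
  labels <- man$true_labels
  if (!is.null(labels) && !length(labels)) labels <- NULL
  cohort_ts(subjects, roi_ids = roi_ids,
            true_labels = if (!is.null(labels)) as.integer(labels))
}

#' Write / read a graph edge list and node features
#'
#' Edge list: TSV with columns `roi_id_u`, `roi_id_v`. Features: TSV with
#' `roi_id` plus one column per feature dimension.
#'
#' @param graph a `brain_graph`.
#' @param dir output directory.
#' @return Invisibly, the two file paths.
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "brain_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- file.path(dir, "edges.tsv")
  el <- data.frame(roi_id_u = graph$roi_ids[graph$edges[, 1]],
                   roi_id_v = graph$roi_ids[graph$edges[, 2]])
  utils::write.table(el, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- file.path(dir, "features.tsv")
  write_tsv_matrix(graph$features, fp,
                   col_ids = paste0("f", seq_len(ncol(graph$features))),
                   row_ids = graph$roi_ids)
  invisible(c(edges = ep, features = fp))
}

#' Write node embeddings as TSV
#'
#' @param emb a `node_embeddings`.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "node_embeddings"))
  write_tsv_matrix(emb$z, path,
                   col_ids = paste0("dim", seq_len(ncol(emb$z))),
                   row_ids = emb$roi_ids)
  invisible(path)
}

#' Write a network partition as TSV
#'
#' Columns: `roi_id`, `cluster`, and `network` ("DMN" for the identified
#' default-mode cluster, empty otherwise).
#'
#' @param partition a `network_partition`.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "network_partition"))
  net <- rep("", length(partition$labels))
  if (!is.na(partition$dmn_cluster))
    net[partition$labels == partition$dmn_cluster] <- "DMN"
  df <- data.frame(roi_id = names(partition$labels),
                   cluster = unname(partition$labels), network = net)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a thresholded seed map as TSV
#'
#' Columns: `roi_id`, `mean_z`, `t`, `significant`.
#'
#' @param map a thresholded `seed_map`.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_seed_map <- function(map, path) {
  stopifnot(inherits(map, "seed_map"))
  df <- data.frame(roi_id = names(map$t_values),
                   mean_z = format(map$mean_z, digits = 9, trim = TRUE),
                   t = format(map$t_values, digits = 9, trim = TRUE),
                   significant = if (is.null(map$significant)) NA else
                     unname(map$significant))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Full pipeline configuration
#'
#' Bundles every stage's parameters. Per-stage seeds are derived from the
#' global seed by fixed offsets so any stage can be rerun in isolation.
#'
#' @param synthetic a [synthetic_config()], or NULL when `manifest` is
#'   given.
#' @param manifest path to a cohort manifest, or NULL when `synthetic` is
#'   given. Exactly one of the two must be set.
#' @param threshold edge-retention correlation cutoff.
#' @param sage a [sage_config()]; its seed is overridden by the derived
#'   stage seed.
#' @param variance_target PCA retained-variance target.
#' @param cluster_components number of leading principal components to
#'   cluster on; NULL (default) clusters on all retained components, 2
#'   clusters on the same coordinates a 2-D embedding plot shows.
#' @param k number of k-means clusters.
#' @param reference_rois ROI ids of the reference (DMN) network, or NULL
#'   to fall back to the planted first block when labels are known.
#' @param sbc_seed_roi seed ROI for the baseline, or NULL to use the first
#'   reference ROI.
#' @param alpha two-sided per-test level for the baseline.
#' @param fwer_mode Bonferroni-correct `alpha` across ROIs.
#' @param run_sbc run the seed-based baseline stage.
#' @param seed global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), manifest = NULL,
                            threshold = 0.1, sage = sage_config(),
                            variance_target = 0.95,
                            cluster_components = NULL, k = 7L,
                            reference_rois = NULL, sbc_seed_roi = NULL,
                            alpha = 0.0001, fwer_mode = FALSE,
                            run_sbc = TRUE, seed = 42L) {
  if (is.null(synthetic) == is.null(manifest))
    stop("exactly one of `synthetic` and `manifest` must be set",
         call. = FALSE)
  structure(list(synthetic = synthetic, manifest = manifest,
                 threshold = threshold, sage = sage,
                 variance_target = variance_target,
                 cluster_components = cluster_components,
                 k = as.integer(k),
                 reference_rois = reference_rois,
                 sbc_seed_roi = sbc_seed_roi, alpha = alpha,
                 fwer_mode = fwer_mode, run_sbc = isTRUE(run_sbc),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, offset) (config$seed %% 100003L) * 10000L + offset

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full extraction pipeline
#'
#' Correlation matrices -> group mean -> thresholded graph -> GraphSAGE
#' embeddings -> PCA -> k-means -> reference-network identification ->
#' (optionally) the seed-based correlation baseline. When `out_dir` is
#' given, all artifacts (cohort echo, edge list, embeddings, partition,
#' seed map, metrics JSON, run log) are written there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return A `pipeline_result` list: `cohort`, `graph`, `embeddings`,
#'   `reduced`, `partition`, `seed_map` (or NULL), and `metrics`
#'   (edge_count, p, inertia, dmn_jaccard, and ari/nmi when ground truth
#'   is known).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- run_stage("cohort", {
    if (!is.null(config$manifest)) read_cohort(config$manifest) else {
      syn <- config$synthetic
      syn$seed <- stage_seed(config, 1L)
      simulate_cohort(syn)
    }
  })
  graph <- run_stage("graph", {
    mats <- cohort_correlation_matrices(cohort)
    build_graph(group_mean_correlation(mats), threshold = config$threshold)
  })
  emb <- run_stage("embed", {
    sc <- config$sage
    sc$seed <- stage_seed(config, 2L)
    train_embeddings(graph, sc)
  })
  red <- run_stage("pca", pca_reduce(emb, config$variance_target))
  coords <- red$coords
  if (!is.null(config$cluster_components))
    coords <- coords[, seq_len(min(config$cluster_components, red$p)),
                     drop = FALSE]
  part <- run_stage("cluster",
                    kmeans_cluster(coords, k = config$k,
                                   seed = stage_seed(config, 3L),
                                   roi_ids = cohort$roi_ids))
  ref <- config$reference_rois
  if (is.null(ref) && !is.null(cohort$true_labels))
    ref <- cohort$roi_ids[cohort$true_labels == cohort$true_labels[1]]
  if (!is.null(ref))
    part <- run_stage("identify",
                      suppressMessages(identify_network(part, ref)))
  seed_map <- NULL
  if (config$run_sbc) {
    seed_roi <- config$sbc_seed_roi
    if (is.null(seed_roi)) {
      if (is.null(ref)) stop("pipeline stage 'sbc' failed: no seed ROI ",
                             "and no reference network to take one from",
                             call. = FALSE)
      seed_roi <- ref[1]
    }
    seed_map <- run_stage("sbc",
                          sbc_baseline(cohort, seed_roi,
                                       alpha = config$alpha,
                                       fwer_mode = config$fwer_mode))
  }
  metrics <- list(edge_count = nrow(graph$edges),
                  p = red$p,
                  explained_variance = sum(red$explained_variance_fractions),
                  inertia = part$inertia,
                  dmn_jaccard = if (!is.null(part$dmn_jaccard))
                    part$dmn_jaccard)
  if (!is.null(cohort$true_labels)) {
    rec <- evaluate_recovery(part, cohort$true_labels)
    metrics$ari <- rec$ari
    metrics$nmi <- rec$nmi
  }
  result <- structure(list(cohort = cohort, graph = graph,
                           embeddings = emb, reduced = red,
                           partition = part, seed_map = seed_map,
                           metrics = metrics, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_graph(result$graph, out_dir)
  write_embeddings(result$embeddings, file.path(out_dir, "embeddings.tsv"))
  write_partition(result$partition, file.path(out_dir, "partition.tsv"))
  if (!is.null(result$seed_map))
    write_seed_map(result$seed_map, file.path(out_dir, "seed_map.tsv"))
  jsonlite::write_json(result$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log <- list(seed = result$config$seed,
              threshold = result$config$threshold,
              k = result$config$k,
              sage = unclass(result$config$sage),
              synthetic = if (!is.null(result$config$synthetic))
                unclass(result$config$synthetic),
              manifest = result$config$manifest,
              metrics = result$metrics)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<pipeline_result> %d edges, %d PCA components, ",
                     "inertia %.4f%s%s\n"),
              m$edge_count, m$p, m$inertia,
              if (!is.null(m$ari)) sprintf(", ARI %.3f", m$ari) else "",
              if (!is.null(m$dmn_jaccard))
                sprintf(", DMN Jaccard %.3f", m$dmn_jaccard) else ""))
  invisible(x)
}
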