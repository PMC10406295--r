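#' Synthetic cohort configuration
#'
#' Bundles the parameters of the block-structured cohort simulator. ROIs are
#' partitioned into `n_networks` contiguous blocks (or per `block_sizes`);
#' every ROI in block k follows the shared-signal model
#' \deqn{x_i(t) = \sqrt{\rho}\, s_k(t) + \sqrt{1-\rho}\, e_i(t),}
#' with \eqn{s_k(t)} a latent network signal (standard normal) and
#' \eqn{e_i(t)} independent noise with standard deviation `noise_sd`. The
#' expected within-network Pearson correlation is therefore
#' \eqn{\rho / (\rho + (1-\rho)\,\mathrm{noise\_sd}^2)} and the expected
#' between-network correlation is 0.
#'
#' @param n_rois number of ROIs (graph nodes).
#' @param n_networks number of planted networks; the first block plays the
#'   role of the default mode network.
#' @param n_subjects number of independent subjects.
#' @param n_timepoints time points per subject (>= 3).
#' @param rho within-network shared-signal fraction in \[0, 1\].
#' @param noise_sd standard deviation of the idiosyncratic noise term.
#' @param block_sizes optional integer vector of block sizes summing to
#'   `n_rois`; defaults to blocks as equal as possible.
#' @param seed integer seed; identical seeds reproduce identical cohorts.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_rois = 70L, n_networks = 7L, n_subjects = 10L,
                             n_timepoints = 180L, rho = 0.6, noise_sd = 1,
                             block_sizes = NULL, seed = 42L) {
  n_rois <- as.integer(n_rois)
  n_networks <- as.integer(n_networks)
  n_subjects <- as.integer(n_subjects)
  n_timepoints <- as.integer(n_timepoints)
  if (n_networks < 1L || n_networks > n_rois)
    stop("n_networks must satisfy 1 <= n_networks <= n_rois", call. = FALSE)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (n_timepoints < 3L)
    stop("n_timepoints must be >= 3 for correlations to be defined",
         call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop("rho must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  if (is.null(block_sizes)) {
    base <- n_rois %/% n_networks
    block_sizes <- rep(base, n_networks)
    extra <- n_rois - base * n_networks
    if (extra > 0L) block_sizes[seq_len(extra)] <- block_sizes[seq_len(extra)] + 1L
  }
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) != n_networks || any(block_sizes < 1L) ||
      sum(block_sizes) != n_rois)
    stop("block_sizes must contain n_networks positive counts summing to n_rois",
         call. = FALSE)
  structure(list(n_rois = n_rois, n_networks = n_networks,
                 n_subjects = n_subjects, n_timepoints = n_timepoints,
                 rho = rho, noise_sd = noise_sd, block_sizes = block_sizes,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Network labels implied by a synthetic configuration
#'
#' @param config a [synthetic_config()].
#' @return Integer vector of length `n_rois`; label k marks membership in
#'   planted network k (contiguous blocks, block 1 = planted DMN).
#' @export
planted_labels <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rep(seq_len(config$n_networks), times = config$block_sizes)
}

# Derive a per-subject seed from the cohort seed by a fixed counter offset,
# so adding subjects never perturbs earlier subjects. Kept below 2^31.
subject_seed <- function(config, subject_index) {
  (config$seed %% 1000003L) * 1000L + as.integer(subject_index)
}

#' Simulate one subject's ROI time-series matrix
#'
#' @param config a [synthetic_config()].
#' @param subject_index 1-based subject counter; determines the RNG stream.
#' @return `n_timepoints` x `n_rois` numeric matrix; columns named by ROI id.
#' @export
simulate_subject <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- planted_labels(config)
  tp <- config$n_timepoints
  x <- withr_seed_eval(subject_seed(config, subject_index), {
    latent <- matrix(stats::rnorm(tp * config$n_networks), tp,
                     config$n_networks)
    noise <- matrix(stats::rnorm(tp * config$n_rois, sd = config$noise_sd),
                    tp, config$n_rois)
    sqrt(config$rho) * latent[, labels, drop = FALSE] +
      sqrt(1 - config$rho) * noise
  })
  # rho = 1 collapses the noise term; guard against exactly-constant columns
  # (impossible with continuous draws, but checked for the contract).
  colnames(x) <- roi_names(config$n_rois)
  x
}

roi_names <- function(n) sprintf("ROI_%03d", seq_len(n))

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
withr_seed_eval <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a multi-subject cohort with planted network structure
#'
#' All subjects share the ROI ordering and ground-truth labels; subject
#' matrices are independent draws from the shared-signal model.
#'
#' @param config a [synthetic_config()].
#' @return A `cohort_ts` object: list with `subjects` (list of
#'   timepoints x ROIs matrices), `roi_ids`, `true_labels`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  subjects <- lapply(seq_len(config$n_subjects),
                     function(s) simulate_subject(config, s))
  cohort_ts(subjects, roi_ids = roi_names(config$n_rois),
            true_labels = planted_labels(config), config = config)
}

#' Construct and validate a cohort container
#'
#' @param subjects list of numeric matrices (time points x ROIs), identical
#'   shapes and column order.
#' @param roi_ids character vector of ROI identifiers.
#' @param true_labels optional integer vector of network labels per ROI.
#' @param config optional originating [synthetic_config()].
#' @return A validated object of class `cohort_ts`.
#' @export
cohort_ts <- function(subjects, roi_ids, true_labels = NULL, config = NULL) {
  if (!length(subjects)) stop("cohort needs at least one subject", call. = FALSE)
  dims <- vapply(subjects, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all subject matrices must share the same shape", call. = FALSE)
  if (dims[2, 1] != length(roi_ids))
    stop("roi_ids length must equal the ROI (column) count", call. = FALSE)
  for (s in seq_along(subjects)) {
    v <- apply(subjects[[s]], 2, stats::var)
    if (any(v <= 0))
      stop(sprintf("constant ROI column in subject %d: %s", s,
                   roi_ids[which(v <= 0)[1]]), call. = FALSE)
  }
  if (!is.null(true_labels) && length(true_labels) != length(roi_ids))
    stop("true_labels must have one entry per ROI", call. = FALSE)
  structure(list(subjects = subjects, roi_ids = as.character(roi_ids),
                 true_labels = true_labels, config = config),
            class = "cohort_ts")
}

#' Discard initial volumes from every subject
#'
#' Scanner signal needs several repetition times to reach a steady state,
#' so the first few volumes of an acquisition are conventionally dropped
#' before computing correlations — e.g. 192 acquired time points leave 182
#' usable ones after removing the first ten.
#'
#' @param cohort a [cohort_ts()].
#' @param n_drop number of leading time points to remove (default 10).
#' @return The cohort with `n_drop` fewer time points per subject.
#' @export
drop_initial_volumes <- function(cohort, n_drop = 10L) {
  stopifnot(inherits(cohort, "cohort_ts"))
  n_drop <- as.integer(n_drop)
  tp <- nrow(cohort$subjects[[1]])
  if (n_drop < 0L || tp - n_drop < 3L)
    stop("dropping ", n_drop, " volumes leaves fewer than 3 time points",
         call. = FALSE)
  if (n_drop > 0L)
    cohort$subjects <- lapply(cohort$subjects, function(m)
      m[-seq_len(n_drop), , drop = FALSE])
  cohort
}

#' @export
print.cohort_ts <- function(x, ...) {
  d <- dim(x$subjects[[1]])
  cat(sprintf("<cohort_ts> %d subjects, %d time points x %d ROIs%s\n",
              length(x$subjects), d[1], d[2],
              if (is.null(x$true_labels)) "" else
                sprintf(", %d planted networks",
                        length(unique(x$true_labels)))))
  invisible(x)
}
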