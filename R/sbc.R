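#' Per-subject seed-to-ROI correlations
#'
#' Correlates the seed ROI's time course with every ROI separately within
#' each subject. The seed column equals 1 by definition.
#'
#' @param cohort a [cohort_ts()].
#' @param seed_roi ROI id (or 1-based index) of the seed, e.g. the
#'   posterior cingulate cortex for the default mode network.
#' @return `n_subjects` x `n_rois` matrix of correlations, columns named
#'   by ROI id.
#' @export
seed_correlation_map <- function(cohort, seed_roi) {
  stopifnot(inherits(cohort, "cohort_ts"))
  si <- resolve_roi(cohort$roi_ids, seed_roi)
  out <- t(vapply(cohort$subjects, function(ts) {
    seed <- ts[, si]
    vapply(seq_len(ncol(ts)), function(j)
      if (j == si) 1 else pearson_correlation(seed, ts[, j]), numeric(1))
  }, numeric(length(cohort$roi_ids))))
  colnames(out) <- cohort$roi_ids
  out
}

resolve_roi <- function(roi_ids, roi) {
  if (is.numeric(roi)) {
    roi <- as.integer(roi)
    if (roi < 1L || roi > length(roi_ids))
      stop("seed index out of range", call. = FALSE)
    return(roi)
  }
  i <- match(as.character(roi), roi_ids)
  if (is.na(i)) stop("seed ROI not found: ", roi, call. = FALSE)
  i
}

#' Fisher z transform
#'
#' `atanh(r)` — variance-stabilizes correlations before group-level
#' testing. Values with `|r| >= 1` are clamped to ±(1 - 1e-7) with a
#' warning rather than mapped to ±Inf.
#'
#' @param r correlation value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  clip <- abs(r) >= 1
  if (any(clip)) {
    warning(sum(clip), " correlation(s) with |r| >= 1 clamped",
            call. = FALSE)
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Group t map against a seed
#'
#' One-sample t statistic per ROI of the (by default Fisher-z-transformed)
#' seed correlations against zero: \eqn{t = \bar z / (s_z/\sqrt{n})} with
#' df = n_subjects - 1. The seed itself is excluded from testing. An ROI
#' with zero across-subject standard deviation gets an infinite t with the
#' sign of its mean (or NaN at mean zero) and is flagged.
#'
#' @param corr_rows subjects x ROIs correlation matrix from
#'   [seed_correlation_map()].
#' @param seed_roi ROI id or index of the seed (excluded from the map).
#' @param use_fisher_z apply [fisher_z()] before testing (default TRUE);
#'   FALSE tests the raw correlations.
#' @return A `seed_map`: `seed_roi`, `t_values` (named, seed excluded),
#'   `mean_z`, `df`, `degenerate` (zero-sd flags), plus empty significance
#'   fields until [threshold_seed_map()] is applied.
#' @export
group_t_map <- function(corr_rows, seed_roi, use_fisher_z = TRUE) {
  corr_rows <- as.matrix(corr_rows)
  n <- nrow(corr_rows)
  if (n < 2L) stop("need at least 2 subjects for a group t map",
                   call. = FALSE)
  ids <- colnames(corr_rows)
  if (is.null(ids)) ids <- roi_names(ncol(corr_rows))
  si <- resolve_roi(ids, seed_roi)
  vals <- corr_rows[, -si, drop = FALSE]
  z <- if (use_fisher_z) fisher_z(vals) else vals
  mu <- colMeans(z)
  sdv <- apply(z, 2, stats::sd)
  degen <- sdv == 0
  t_stat <- ifelse(degen, ifelse(mu == 0, NaN, sign(mu) * Inf),
                   mu / (sdv / sqrt(n)))
  if (any(degen))
    warning(sum(degen), " ROI(s) with zero across-subject variance flagged",
            call. = FALSE)
  names(t_stat) <- names(mu) <- ids[-si]
  structure(list(seed_roi = ids[si], t_values = t_stat, mean_z = mu,
                 df = n - 1L, degenerate = degen,
                 critical_t = NA_real_, alpha = NA_real_,
                 significant = NULL),
            class = "seed_map")
}

#' Two-sided Student-t critical value
#'
#' Inverse Student-t CDF at `1 - alpha/2`. At alpha = 0.0001 and df = 83
#' this gives 4.09 (2 d.p.), the classic uncorrected voxelwise threshold
#' for an 84-subject cohort.
#'
#' @param alpha_two_sided two-sided significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return The positive critical value.
#' @export
critical_t <- function(alpha_two_sided, df) {
  if (!is.numeric(alpha_two_sided) || alpha_two_sided <= 0 ||
      alpha_two_sided >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stats::qt(1 - alpha_two_sided / 2, df)
}

#' Threshold a seed map
#'
#' Marks ROI i significant when `|t_i| > critical_t(alpha, df)` (strict
#' inequality). In FWER mode the per-test level is Bonferroni-corrected:
#' `alpha_fwer / n_tests`.
#'
#' @param map a `seed_map` from [group_t_map()].
#' @param alpha per-test two-sided level (default 0.0001).
#' @param fwer_mode treat `alpha` as a familywise error rate and divide it
#'   by the number of tested ROIs.
#' @return The map with `critical_t`, `alpha`, and logical `significant`
#'   filled in.
#' @export
threshold_seed_map <- function(map, alpha = 0.0001, fwer_mode = FALSE) {
  stopifnot(inherits(map, "seed_map"))
  n_tests <- length(map$t_values)
  level <- if (fwer_mode) alpha / n_tests else alpha
  crit <- critical_t(level, map$df)
  map$critical_t <- crit
  map$alpha <- level
  map$significant <- abs(map$t_values) > crit
  map$significant[map$degenerate & is.nan(map$t_values)] <- FALSE
  map
}

#' @export
print.seed_map <- function(x, ...) {
  cat(sprintf("<seed_map> seed %s, %d ROIs tested, df = %d%s\n",
              x$seed_roi, length(x$t_values), x$df,
              if (is.null(x$significant)) "" else
                sprintf(", %d significant at |t| > %.2f",
                        sum(x$significant), x$critical_t)))
  invisible(x)
}

#' Run the full seed-based correlation baseline
#'
#' Convenience wrapper: [seed_correlation_map()] then [group_t_map()] then
#' [threshold_seed_map()].
#'
#' @inheritParams seed_correlation_map
#' @inheritParams group_t_map
#' @inheritParams threshold_seed_map
#' @return A thresholded `seed_map`.
#' @export
sbc_baseline <- function(cohort, seed_roi, alpha = 0.0001,
                         fwer_mode = FALSE, use_fisher_z = TRUE) {
  rows <- seed_correlation_map(cohort, seed_roi)
  map <- group_t_map(rows, seed_roi, use_fisher_z = use_fisher_z)
  threshold_seed_map(map, alpha = alpha, fwer_mode = fwer_mode)
}
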