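#' Correlation distance between two vectors
#'
#' One minus the Pearson correlation of the mean-centred vectors; the
#' pairwise dissimilarity used for voxel activity patterns. Ranges over
#' \code{[0, 2]}. Constant vectors have no defined correlation and raise a
#' degenerate-input error.
#'
#' @param u,v Numeric vectors of equal length >= 2.
#' @return Correlation distance.
#' @export
correlation_distance <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("degenerate input: constant vector has no correlation distance",
         call. = FALSE)
  1 - stats::cor(u, v)
}

#' Pattern RDM from a trial-by-voxel matrix
#'
#' Pairwise correlation distances between the rows (trials) of a pattern
#' matrix. Rows with zero variance yield undefined distances; those cells
#' are recorded as NA (with a warning) and dropped downstream.
#'
#' @param patterns Numeric matrix, trials x voxels (>= 2 rows).
#' @param labels Trial labels; default rownames.
#' @return An \code{\link{rdm}} (possibly with NA cells).
#' @export
pattern_rdm <- function(patterns, labels = rownames(patterns)) {
  stopifnot(is.matrix(patterns), nrow(patterns) >= 2)
  sds <- apply(patterns, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(patterns)))
  d <- 1 - cc
  if (any(sds == 0)) {
    warning("constant pattern row(s): ",
            paste(which(sds == 0), collapse = ", "),
            "; their distances are recorded as NA")
    d[sds == 0, ] <- NA_real_
    d[, sds == 0] <- NA_real_
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  rdm(d, labels = labels, allow_na = TRUE)
}

#' Condition-pair cell masks for trial RDMs
#'
#' Builds a logical matrix over the main trials of a schedule selecting the
#' RDM cells belonging to a condition pairing. Same-sequence repeat pairs
#' (distance-0 cells under the chunk model) are included by default;
#' \code{include_same_sequence = FALSE} excludes them.
#'
#' @param schedule Schedule data.frame.
#' @param which One of "all", "novel-novel", "novel-repeating",
#'   "repeating-repeating".
#' @param include_same_sequence Keep cells whose two trials show the same
#'   sequence.
#' @return Symmetric logical matrix (main trials x main trials).
#' @export
rdm_mask <- function(schedule,
                     which = c("all", "novel-novel", "novel-repeating",
                               "repeating-repeating"),
                     include_same_sequence = TRUE) {
  which <- match.arg(which)
  main <- schedule[schedule$segment == "main", , drop = FALSE]
  cond <- main$condition
  n <- nrow(main)
  novel <- cond == "novel"
  mask <- switch(which,
    "all" = matrix(TRUE, n, n),
    "novel-novel" = outer(novel, novel, "&"),
    "repeating-repeating" = outer(!novel, !novel, "&"),
    "novel-repeating" = outer(novel, !novel, "&") | outer(!novel, novel, "&"))
  if (!include_same_sequence)
    mask <- mask & outer(main$sequence, main$sequence, "!=")
  diag(mask) <- FALSE
  mask
}

#' Spearman correlation between a model RDM and a data RDM
#'
#' The model fit statistic: Spearman's rank-order correlation (average ranks
#' for ties) over the selected lower-triangle cells. Cells that are missing
#' in either RDM are dropped pairwise before ranking.
#'
#' @param model,data "rdm" objects (or matrices) of matching dimension.
#' @param mask Optional logical cell mask (see \code{\link{rdm_mask}}).
#' @return Spearman r in \code{[-1, 1]}.
#' @export
rsa_correlation <- function(model, data, mask = NULL) {
  stopifnot(all(dim(model) == dim(data)))
  x <- rdm_lower(model, mask)
  y <- rdm_lower(data, mask)
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3)
    stop("fewer than 3 usable masked cells", call. = FALSE)
  stats::cor(x[keep], y[keep], method = "spearman")
}

#' Noise ceiling for a group of subject RDMs
#'
#' Upper bound: the mean over subjects of the Spearman correlation between
#' each subject's RDM and the group-mean RDM (which contains the subject, so
#' it slightly overestimates the true ceiling). Lower bound: the same with
#' the leave-one-out group mean. Degenerate subject RDMs (zero cell
#' variance) are excluded with a warning.
#'
#' @param rdms List of subject RDMs (matching dimensions).
#' @param mask Optional cell mask.
#' @return Named vector c(lower, upper).
#' @export
noise_ceiling <- function(rdms, mask = NULL) {
  stopifnot(is.list(rdms), length(rdms) >= 2)
  cells <- lapply(rdms, rdm_lower, mask = mask)
  ok <- vapply(cells, function(v) stats::sd(v, na.rm = TRUE) > 0, logical(1))
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " degenerate subject RDM(s)")
    cells <- cells[ok]
  }
  n <- length(cells)
  stopifnot(n >= 2)
  mat <- do.call(cbind, cells)
  grand <- rowMeans(mat, na.rm = TRUE)
  upper <- mean(vapply(seq_len(n), function(i)
    stats::cor(mat[, i], grand, method = "spearman", use = "complete.obs"),
    numeric(1)))
  lower <- mean(vapply(seq_len(n), function(i)
    stats::cor(mat[, i], rowMeans(mat[, -i, drop = FALSE], na.rm = TRUE),
               method = "spearman", use = "complete.obs"),
    numeric(1)))
  c(lower = lower, upper = upper)
}

#' One-sided test that lower-ceiling correlations exceed zero
#'
#' Fisher-transforms per-subject Spearman correlations and performs a
#' one-sided one-sample t-test of the mean against zero, at a 5% threshold
#' Bonferroni-corrected for the number of regions examined. Zero-variance
#' inputs (all subjects identical) leave the t statistic undefined and are
#' flagged rather than tested.
#'
#' @param r_values Per-subject correlations (length >= 2).
#' @param n_regions Number of regions for the Bonferroni correction.
#' @return List with t, df, p, alpha, significant, flag.
#' @export
ceiling_positive_test <- function(r_values, n_regions = 1) {
  stopifnot(length(r_values) >= 2, n_regions >= 1)
  z <- atanh(pmin(pmax(r_values, -1 + 1e-12), 1 - 1e-12))
  alpha <- 0.05 / n_regions
  if (stats::sd(z) == 0)
    return(list(t = NA_real_, df = length(z) - 1L, p = NA_real_,
                alpha = alpha, significant = NA,
                flag = "zero variance across subjects: t undefined"))
  tt <- stats::t.test(z, mu = 0, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, alpha = alpha, significant = tt$p.value < alpha,
       flag = NULL)
}

#' @keywords internal
permute_within_groups <- function(n, groups) {
  idx <- seq_len(n)
  for (g in unique(groups)) {
    at <- which(groups == g)
    idx[at] <- at[sample.int(length(at))]
  }
  idx
}

#' Permutation distribution of per-subject RSA correlations
#'
#' For each subject, the true-label Spearman fit plus \code{n_perm} fits
#' under random relabelling of the trials (a joint row/column permutation of
#' the data RDM, preserving its geometry). When a schedule is supplied,
#' labels are shuffled within condition so masked condition-pair cells keep
#' their meaning.
#'
#' @param model Model RDM.
#' @param data_rdms List of per-subject data RDMs.
#' @param schedule Optional schedule (condition-respecting shuffles).
#' @param mask Optional cell mask.
#' @param n_perm Number of permutations per subject (default 1000).
#' @param seed RNG seed.
#' @return List with \code{true_r} (vector) and \code{perm_r}
#'   (subjects x n_perm matrix).
#' @export
rsa_permutations <- function(model, data_rdms, schedule = NULL, mask = NULL,
                             n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(model)
  groups <- if (is.null(schedule)) rep(1L, n) else
    schedule$condition[schedule$segment == "main"]
  true_r <- vapply(data_rdms, function(d) rsa_correlation(model, d, mask),
                   numeric(1))
  perm_r <- matrix(NA_real_, length(data_rdms), n_perm)
  for (s in seq_along(data_rdms)) {
    d <- unclass(data_rdms[[s]])
    for (p in seq_len(n_perm)) {
      idx <- permute_within_groups(n, groups)
      perm_r[s, p] <- rsa_correlation(model, d[idx, idx], mask)
    }
  }
  list(true_r = true_r, perm_r = perm_r)
}

#' Group-level permutation/bootstrap significance
#'
#' Implements the bootstrap-over-permutations group test: the true-label
#' score is appended to each subject's permuted distribution; group-mean
#' scores are then formed by resampling (with replacement) one value per
#' subject, \code{10 / alpha} times -- an order of magnitude beyond the
#' resolution the threshold requires -- and the empirical p-value is the
#' proportion of resampled group means at or above the observed group mean
#' (floored at the distribution's resolution).
#'
#' @param perm_r Subjects x n_perm matrix of permuted correlations.
#' @param true_r Per-subject true-label correlations.
#' @param alpha Significance threshold (> 0); determines the number of
#'   resamples.
#' @param seed RNG seed.
#' @return List with p, observed (group mean), n_draws, significant.
#' @export
group_significance <- function(perm_r, true_r, alpha = 1e-4, seed = NULL) {
  if (!is.numeric(alpha) || alpha <= 0)
    stop("alpha must be positive", call. = FALSE)
  stopifnot(is.matrix(perm_r), nrow(perm_r) == length(true_r))
  if (!is.null(seed)) set.seed(seed)
  n_draws <- ceiling(10 / alpha)
  pool <- cbind(perm_r, true_r)
  draws <- vapply(seq_len(nrow(pool)), function(s)
    sample(pool[s, ], n_draws, replace = TRUE), numeric(n_draws))
  null_means <- rowMeans(draws)
  observed <- mean(true_r)
  p <- max(mean(null_means >= observed), 1 / n_draws)
  list(p = p, observed = observed, n_draws = n_draws,
       significant = p < alpha)
}

#' Full RSA group test for one model
#'
#' Convenience wrapper: per-subject fits, permutation distributions and the
#' group-level bootstrap p-value.
#'
#' @inheritParams rsa_permutations
#' @param alpha Significance threshold.
#' @return List with per-subject r, group mean, p, significant, and the
#'   permutation object.
#' @export
rsa_group_test <- function(model, data_rdms, schedule = NULL, mask = NULL,
                           n_perm = 1000, alpha = 1e-4, seed = NULL) {
  perms <- rsa_permutations(model, data_rdms, schedule, mask, n_perm, seed)
  sig <- group_significance(perms$perm_r, perms$true_r, alpha)
  list(r = perms$true_r, group_r = mean(perms$true_r), p = sig$p,
       significant = sig$significant, permutations = perms)
}

#' Cross-condition RSA: the associative noise-reduction test
#'
#' If learning merely reduces noise in an unchanged (item-position) code,
#' repeating-sequence patterns are less noisy than novel ones and the model
#' fit across novel x repeating cells (r_UR) should exceed the fit within
#' novel cells (r_U). The outcome falls in one of three categories:
#' "no-correlation" (r_UR not significant: repeating sequences are not
#' represented with the novel code at all, so the noise comparison is
#' meaningless), "repeating-noisier" (significant, r_UR < r_U) and
#' "repeating-less-noisy" (significant, r_UR > r_U).
#'
#' @param model Model RDM over main trials (typically the Hamming trial RDM).
#' @param data_rdms List of per-subject pattern RDMs over main trials.
#' @param schedule Schedule data.frame.
#' @param n_perm Permutations per subject for the r_UR significance test.
#' @param alpha Significance threshold.
#' @param seed RNG seed.
#' @return Object of class "cross_condition_result": list with
#'   r_within_novel, r_novel_vs_repeating (per-subject vectors), their group
#'   means, p (for r_UR) and category.
#' @export
cross_condition_rsa <- function(model, data_rdms, schedule, n_perm = 1000,
                                alpha = 1e-4, seed = NULL) {
  cond <- schedule$condition[schedule$segment == "main"]
  if (min(table(cond)) < 2)
    stop("each condition needs at least 2 trials", call. = FALSE)
  mask_u <- rdm_mask(schedule, "novel-novel")
  mask_ur <- rdm_mask(schedule, "novel-repeating")
  r_u <- vapply(data_rdms, function(d) rsa_correlation(model, d, mask_u),
                numeric(1))
  test_ur <- rsa_group_test(model, data_rdms, schedule, mask_ur,
                            n_perm = n_perm, alpha = alpha, seed = seed)
  category <- if (!isTRUE(test_ur$significant)) "no-correlation"
    else if (test_ur$group_r < mean(r_u)) "repeating-noisier"
    else "repeating-less-noisy"
  structure(list(r_within_novel = r_u,
                 r_novel_vs_repeating = test_ur$r,
                 group_r_within_novel = mean(r_u),
                 group_r_novel_vs_repeating = test_ur$group_r,
                 p = test_ur$p, category = category),
            class = "cross_condition_result")
}

#' @export
print.cross_condition_result <- function(x, ...) {
  cat(sprintf(
    "cross-condition RSA: r_U = %.3f, r_UR = %.3f (p = %.2g) -> %s\n",
    x$group_r_within_novel, x$group_r_novel_vs_repeating, x$p, x$category))
  invisible(x)
}
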