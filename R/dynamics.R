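#' Cosine distance between two patterns
#'
#' 1 - u.v / (||u|| ||v||). Used for the model-free distance trajectories
#' (deliberately distinct from the correlation distance the RSA uses).
#'
#' @param u,v Numeric vectors of equal length; nonzero norm.
#' @return Cosine distance in \code{[0, 2]}.
#' @export
cosine_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("zero-norm vector has no cosine distance", call. = FALSE)
  1 - sum(u * v) / (nu * nv)
}

#' Model-free pattern distance series for one subject
#'
#' The four trajectory analyses over a subject's main-trial patterns:
#' \itemize{
#'   \item "between-repeating": d_n = distance(R1^n, R2^n), the n-th
#'     presentations of the two repeating sequences.
#'   \item "within-repeating": d_n = distance(R^n, R^(n-1)), consecutive
#'     presentations of the same repeating sequence, averaged over the two.
#'   \item "repeating-vs-novel": d_n = mean distance of the n-th repetition
#'     of a repeating sequence to the run's novel-trial patterns, averaged
#'     over the two repeating sequences.
#'   \item "within-novel": distances between consecutive novel trials.
#' }
#' Repetition index n is counted within run by default (the per-run series
#' are concatenated and slopes fitted per run); \code{per_run = FALSE}
#' counts presentations across the whole experiment as one series.
#'
#' @param patterns Matrix (main trials x voxels), rows aligned with the main
#'   trials of \code{schedule}.
#' @param schedule Schedule data.frame.
#' @param kind One of the four series kinds.
#' @param per_run Count repetition index within run (default) or across the
#'   experiment.
#' @return data.frame of class "distance_series" with columns run, n, d.
#' @export
build_series <- function(patterns,
                         schedule,
                         kind = c("between-repeating", "within-repeating",
                                  "repeating-vs-novel", "within-novel"),
                         per_run = TRUE) {
  kind <- match.arg(kind)
  main <- schedule[schedule$segment == "main", , drop = FALSE]
  stopifnot(nrow(patterns) == nrow(main))
  reps <- unique(main$sequence[main$condition == "repeating"])
  stopifnot(length(reps) == 2)
  runs <- if (per_run) sort(unique(main$run)) else NA_integer_
  out <- NULL
  for (r in runs) {
    rows <- if (per_run) which(main$run == r) else seq_len(nrow(main))
    sub <- main[rows, , drop = FALSE]
    P <- patterns[rows, , drop = FALSE]
    idx_of <- function(s) which(sub$sequence == s)
    d <- switch(kind,
      "between-repeating" = {
        i1 <- idx_of(reps[1]); i2 <- idx_of(reps[2])
        n <- min(length(i1), length(i2))
        if (n < 1) stop("insufficient repeating trials", call. = FALSE)
        vapply(seq_len(n), function(k)
          cosine_distance(P[i1[k], ], P[i2[k], ]), numeric(1))
      },
      "within-repeating" = {
        per_seq <- lapply(reps, function(s) {
          i <- idx_of(s)
          if (length(i) < 2) stop("insufficient repeating trials", call. = FALSE)
          vapply(2:length(i), function(k)
            cosine_distance(P[i[k], ], P[i[k - 1L], ]), numeric(1))
        })
        n <- min(lengths(per_seq))
        (per_seq[[1]][seq_len(n)] + per_seq[[2]][seq_len(n)]) / 2
      },
      "repeating-vs-novel" = {
        novels <- which(sub$condition == "novel")
        per_seq <- lapply(reps, function(s) {
          i <- idx_of(s)
          vapply(seq_along(i), function(k)
            mean(vapply(novels, function(j)
              cosine_distance(P[i[k], ], P[j, ]), numeric(1))), numeric(1))
        })
        n <- min(lengths(per_seq))
        (per_seq[[1]][seq_len(n)] + per_seq[[2]][seq_len(n)]) / 2
      },
      "within-novel" = {
        i <- which(sub$condition == "novel")
        if (length(i) < 2) stop("insufficient novel trials", call. = FALSE)
        vapply(2:length(i), function(k)
          cosine_distance(P[i[k], ], P[i[k - 1L], ]), numeric(1))
      })
    out <- rbind(out, data.frame(run = if (per_run) r else NA_integer_,
                                 n = seq_along(d), d = d))
  }
  class(out) <- c("distance_series", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' Group slope test on per-subject distance series
#'
#' Fits an ordinary least-squares slope of distance against repetition index
#' for each subject (averaging per-run slopes when series carry a run
#' column), then tests the subjects' slopes against zero with a two-sided
#' one-sample t-test at a Bonferroni-corrected threshold
#' \code{alpha / n_regions}. Zero-variance slope sets are flagged instead of
#' tested.
#'
#' @param series_list List of per-subject "distance_series" data.frames
#'   (>= 3 points per subject).
#' @param alpha Uncorrected threshold (default 0.05).
#' @param n_regions Number of regions examined (Bonferroni divisor).
#' @return List with slopes (per subject), t, df, p, alpha (corrected),
#'   significant, flag.
#' @export
slope_test <- function(series_list, alpha = 0.05, n_regions = 1) {
  slopes <- vapply(series_list, function(s) {
    stopifnot(nrow(s) >= 3)
    by_run <- split(s, if (all(is.na(s$run))) rep(1L, nrow(s)) else s$run)
    mean(vapply(by_run, function(chunk) {
      if (nrow(chunk) < 2 || stats::sd(chunk$n) == 0) return(NA_real_)
      unname(stats::coef(stats::lm(d ~ n, data = chunk))[2])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  alpha_corr <- alpha / n_regions
  if (stats::sd(slopes) == 0) {
    return(list(slopes = slopes, t = NA_real_, df = length(slopes) - 1L,
                p = NA_real_, alpha = alpha_corr, significant = NA,
                flag = "zero variance across subject slopes"))
  }
  tt <- stats::t.test(slopes, mu = 0)
  list(slopes = slopes, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, alpha = alpha_corr,
       significant = tt$p.value < alpha_corr, flag = NULL)
}
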