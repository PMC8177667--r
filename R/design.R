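#' Design constraints for the sequence set
#'
#' Two hard criteria govern the 14-sequence set (2 repeating, 12 unique):
#' pairwise dissimilarity in Hamming space, and the repeating-pair rules (the
#' two repeating sequences share no item at a common position and no common
#' n-gram with n > 1, so that they can only be chunk-encoded as two distinct
#' four-grams).
#'
#' The Hamming criterion has two scopes. Scope "repeating" (the default)
#' applies \code{min_pairwise_hamming} to every pair involving a repeating
#' sequence. Scope "all" applies it to every pair; for 14 permutations of 4
#' items this literal reading is provably unsatisfiable -- a Hamming distance
#' of 2 corresponds to a transposition, so the "too close" graph is bipartite
#' between even and odd permutations and at most 12 sequences (one parity
#' class) can be mutually >= 3 apart. The vignette works through the
#' argument; \code{\link{monte_carlo_search}} under scope "all" therefore
#' fails explicitly.
#'
#' @param min_pairwise_hamming Minimum Hamming distance (default 3).
#' @param scope "repeating" or "all" (see Details).
#' @return Object of class "design_constraints".
#' @export
design_constraints <- function(min_pairwise_hamming = 3,
                               scope = c("repeating", "all")) {
  scope <- match.arg(scope)
  stopifnot(min_pairwise_hamming >= 0)
  structure(list(min_pairwise_hamming = min_pairwise_hamming, scope = scope),
            class = "design_constraints")
}

#' Check a candidate sequence set against the design constraints
#'
#' @param seqs Character vector of sequences (default set size 14), each a
#'   permutation of the alphabet.
#' @param repeating Character vector of length 2: the designated repeating
#'   sequences (must be members of \code{seqs}).
#' @param constraints A \code{\link{design_constraints}} object.
#' @param n_required Required set size (default 14; NULL to skip).
#' @param alphabet Item alphabet.
#' @return List with \code{pass} (logical) and \code{violations} (character).
#' @export
check_constraints <- function(seqs, repeating,
                              constraints = design_constraints(),
                              n_required = 14,
                              alphabet = default_alphabet()) {
  violations <- character(0)
  if (!is.null(n_required) && length(seqs) != n_required)
    stop("wrong set size: expected ", n_required, " sequences, got ",
         length(seqs), call. = FALSE)
  if (length(repeating) != 2 || !all(repeating %in% seqs))
    stop("exactly two repeating sequences from the set must be designated",
         call. = FALSE)
  L <- length(alphabet)
  for (s in seqs) {
    items <- check_sequence(s, alphabet = alphabet, L = L)
    if (anyDuplicated(items))
      violations <- c(violations, paste0("sequence ", s, " repeats an item"))
  }
  if (anyDuplicated(seqs))
    violations <- c(violations, "duplicated sequence in set (Hamming 0)")
  # pairwise Hamming
  m <- length(seqs)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    involved <- seqs[i] %in% repeating || seqs[j] %in% repeating
    if (constraints$scope == "all" || involved) {
      d <- hamming_distance(seqs[i], seqs[j])
      if (d < constraints$min_pairwise_hamming)
        violations <- c(violations, paste0(
          "pair (", seqs[i], ", ", seqs[j], ") at Hamming distance ", d))
    }
  }
  # repeating-pair rules
  if (hamming_distance(repeating[1], repeating[2]) < L)
    violations <- c(violations,
                    "repeating pair shares an item at a common position")
  for (n in 2:L) {
    shared <- intersect(extract_ngrams(repeating[1], n),
                        extract_ngrams(repeating[2], n))
    if (length(shared) > 0)
      violations <- c(violations, paste0(
        "repeating pair shares ", n, "-gram(s): ",
        paste(shared, collapse = ", ")))
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Statistical power scores of a sequence set
#'
#' Two measures drive the design search: the plug-in entropy (natural log) of
#' the distribution of the C(m, 2) lower-triangle pairwise Hamming distances
#' -- higher entropy spreads the predictor over more distance levels -- and
#' the Pearson correlation between the item-position (Hamming) and item-item
#' (bi-gram) model RDMs of the set, which the search drives toward zero so
#' the two models remain dissociable. Hamming distances between permutations
#' are discrete, so no binning is involved.
#'
#' @param seqs Character vector of sequences.
#' @return List with \code{distance_entropy}, \code{model_cross_correlation}
#'   and \code{n_cells}.
#' @export
score_set <- function(seqs) {
  h <- rdm_lower(model_rdm(seqs, "hamming"))
  b <- rdm_lower(model_rdm(seqs, "bigram"))
  p <- as.numeric(table(h)) / length(h)
  entropy <- -sum(p * log(p))
  xcor <- if (stats::sd(h) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(h, b)
  list(distance_entropy = entropy, model_cross_correlation = xcor,
       n_cells = length(h))
}

#' @keywords internal
all_permutation_sequences <- function(alphabet = default_alphabet()) {
  rec <- function(v) {
    if (length(v) == 1L) return(v)
    unlist(lapply(seq_along(v), function(i)
      paste0(v[i], rec(v[-i]))))
  }
  rec(alphabet)
}

#' Monte-Carlo search for a constraint-satisfying sequence set
#'
#' Draws \code{n_samples} random candidates from the space of 14-subsets of
#' the 4! = 24 distinct-item permutations (about 2e6 subsets): each draw
#' samples a repeating pair, checks the repeating-pair rules, and fills the
#' unique slots by sampling from the permutations compatible with the
#' Hamming constraint (under the default scope, a pair admits at most 12
#' compatible uniques, so the unique set is nearly forced by the pair
#' choice; uniform subset sampling would almost never land on a passing
#' set). Passing sets are ranked by distance entropy (maximised) with the
#' absolute model cross-correlation as tie-breaker (minimised).
#'
#' @param n_samples Number of random candidate sets (default 1e4).
#' @param seed RNG seed for reproducibility (NULL: use current RNG state).
#' @param n_sequences Set size (default 14).
#' @param constraints A \code{\link{design_constraints}} object.
#' @param alphabet Item alphabet.
#' @return List with \code{sequences}, \code{repeating}, \code{score},
#'   \code{n_pass} (passing candidates seen) and \code{trace} (data.frame of
#'   passing candidates' scores). Fails with an explicit error when no
#'   sampled set passes.
#' @export
monte_carlo_search <- function(n_samples = 1e4, seed = NULL,
                               n_sequences = 14,
                               constraints = design_constraints(),
                               alphabet = default_alphabet()) {
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  perms <- all_permutation_sequences(alphabet)
  L <- length(alphabet)
  np <- length(perms)
  H <- matrix(0L, np, np)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np)
    H[i, j] <- H[j, i] <- hamming_distance(perms[i], perms[j])
  # repeating-pair admissibility: Hamming L and disjoint n-grams for n > 1
  pair_ok <- matrix(FALSE, np, np)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    ok <- H[i, j] == L
    if (ok) for (n in 2:L) {
      if (length(intersect(extract_ngrams(perms[i], n),
                           extract_ngrams(perms[j], n))) > 0) { ok <- FALSE; break }
    }
    pair_ok[i, j] <- pair_ok[j, i] <- ok
  }
  B <- matrix(0, np, np)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np)
    B[i, j] <- B[j, i] <- ngram_distance(perms[i], perms[j], 2)

  best <- NULL
  trace <- vector("list", 0L)
  n_pass <- 0L
  min_h <- constraints$min_pairwise_hamming
  n_unique <- n_sequences - 2L
  for (k in seq_len(n_samples)) {
    pair <- sample.int(np, 2L)
    if (!pair_ok[pair[1], pair[2]]) next
    compatible <- which(H[pair[1], ] >= min_h & H[pair[2], ] >= min_h)
    compatible <- setdiff(compatible, pair)
    if (length(compatible) < n_unique) next
    uniq <- if (length(compatible) == n_unique) compatible else
      sample(compatible, n_unique)
    idx <- c(pair, uniq)
    sub <- H[idx, idx]
    if (constraints$scope == "all" &&
        any(sub[lower.tri(sub)] < min_h)) next
    rep_pair <- c(1L, 2L)
    n_pass <- n_pass + 1L
    hv <- sub[lower.tri(sub)]
    p <- as.numeric(table(hv)) / length(hv)
    entropy <- -sum(p * log(p))
    bsub <- B[idx, idx]
    xcor <- stats::cor(hv, bsub[lower.tri(bsub)])
    cand <- list(idx = idx, rep = idx[rep_pair], entropy = entropy,
                 xcor = xcor)
    trace[[n_pass]] <- data.frame(sample = k, entropy = entropy, xcor = xcor)
    if (is.null(best) || entropy > best$entropy + 1e-12 ||
        (abs(entropy - best$entropy) <= 1e-12 &&
         abs(xcor) < abs(best$xcor) - 1e-12))
      best <- cand
  }
  if (is.null(best))
    stop("no constraint-passing sequence set found in ", n_samples,
         " samples", if (constraints$scope == "all")
           " (the all-pairs Hamming criterion is unsatisfiable for 14 permutations of 4 items; see ?design_constraints)",
         call. = FALSE)
  list(sequences = perms[best$idx], repeating = perms[best$rep],
       score = list(distance_entropy = best$entropy,
                    model_cross_correlation = best$xcor),
       n_pass = n_pass,
       trace = do.call(rbind, trace))
}

#' Build the trial schedule
#'
#' A practice prefix presents each repeating sequence \code{practice_reps}
#' times (shuffled), after which the main experiment runs
#' \code{runs x trials_per_run} trials organised in sub-blocks of three: one
#' unique (novel) sequence and two repeating trials per sub-block, in random
#' order, with each repeating sequence appearing trials_per_run/3 times per
#' run (balanced) and each unique sequence exactly once per run. A response
#' cue is present on 3/4 of the main trials; the no-response quarter is
#' assigned uniformly at random.
#'
#' @param seqs The 14-sequence set.
#' @param repeating The two repeating sequences (members of \code{seqs}).
#' @param runs Number of scanning runs (default 2).
#' @param trials_per_run Trials per run (default 36; divisible by 3).
#' @param practice_reps Practice presentations per repeating sequence
#'   (default 12).
#' @param prop_response Proportion of main trials with a response cue.
#' @param seed RNG seed (NULL: current RNG state).
#' @return data.frame of class "trial_schedule" with columns trial_index,
#'   segment ("practice"/"main"), run (0 for practice), block, sequence,
#'   condition ("repeating"/"novel"), response_cue (logical). Timing metadata
#'   (2.4 s per item, 4.8 s delay, 7.2 s response window) is carried in
#'   attributes.
#' @export
build_schedule <- function(seqs, repeating, runs = 2, trials_per_run = 36,
                           practice_reps = 12, prop_response = 3/4,
                           seed = NULL) {
  if (trials_per_run %% 3 != 0)
    stop("trials_per_run must be divisible by 3 (sub-blocks of three trials)",
         call. = FALSE)
  stopifnot(length(repeating) == 2, all(repeating %in% seqs))
  uniques <- setdiff(seqs, repeating)
  n_blocks <- trials_per_run / 3
  if (length(uniques) != n_blocks)
    stop("need exactly ", n_blocks, " unique sequences for ", trials_per_run,
         " trials per run; got ", length(uniques), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  practice <- sample(rep(repeating, each = practice_reps))
  rows <- data.frame(segment = "practice", run = 0L,
                     block = NA_integer_, sequence = practice,
                     condition = "repeating")
  for (r in seq_len(runs)) {
    novel_order <- sample(uniques)
    rep_slots <- sample(rep(repeating, each = n_blocks)) # balanced per run
    for (b in seq_len(n_blocks)) {
      trio <- sample(c(novel_order[b], rep_slots[2 * b - 1L], rep_slots[2 * b]))
      rows <- rbind(rows, data.frame(
        segment = "main", run = r, block = b, sequence = trio,
        condition = ifelse(trio %in% repeating, "repeating", "novel")))
    }
  }
  rows$trial_index <- seq_len(nrow(rows))
  rows$response_cue <- TRUE
  main_idx <- which(rows$segment == "main")
  n_silent <- round((1 - prop_response) * length(main_idx))
  rows$response_cue[sample(main_idx, n_silent)] <- FALSE
  rows <- rows[, c("trial_index", "segment", "run", "block", "sequence",
                   "condition", "response_cue")]
  attr(rows, "timing") <- c(item_s = 2.4, delay_s = 4.8, response_s = 7.2)
  attr(rows, "repeating") <- repeating
  class(rows) <- c("trial_schedule", "data.frame")
  rows
}

#' Write / read a trial schedule as CSV
#'
#' @param schedule A "trial_schedule" data.frame.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$response_cue <- as.logical(df$response_cue)
  attr(df, "repeating") <-
    unique(df$sequence[df$condition == "repeating"])
  class(df) <- c("trial_schedule", "data.frame")
  df
}
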