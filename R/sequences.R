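#' Default item alphabet
#'
#' The experiments modelled here use four items (Gabor patches differing only
#' in orientation), conventionally labelled \code{A}-\code{D}. An alphabet is
#' an ordered character vector of distinct single-character item symbols.
#'
#' @param n_items Number of items (>= 2).
#' @return Character vector of item symbols.
#' @export
default_alphabet <- function(n_items = 4) {
  stopifnot(n_items >= 2, n_items <= 26)
  LETTERS[seq_len(n_items)]
}

#' Split a sequence string into its items
#'
#' Sequences are serialised as contiguous item-symbol strings ("ABCD");
#' positions are 1-based.
#'
#' @param s A single sequence string.
#' @return Character vector of item symbols, one per position.
#' @export
seq_items <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  strsplit(s, "", fixed = TRUE)[[1L]]
}

#' @keywords internal
check_sequence <- function(s, alphabet = NULL, L = NULL) {
  items <- seq_items(s)
  if (!is.null(L) && length(items) != L)
    stop("sequence '", s, "' does not have length ", L, call. = FALSE)
  if (!is.null(alphabet) && !all(items %in% alphabet))
    stop("sequence '", s, "' contains items outside the alphabet", call. = FALSE)
  items
}

#' Hamming distance between two equal-length sequences
#'
#' The item-position model's dissimilarity: the number of positions at which
#' the two sequences hold different items. Two sequences sharing two
#' item-position associations out of four (e.g. "ABCD" and "CBAD") are at
#' distance 2.
#'
#' @param a,b Sequence strings of equal length.
#' @return Integer count of mismatched positions, in \code{[0, L]}.
#' @export
#' @examples
#' hamming_distance("ABCD", "CBAD") # 2
hamming_distance <- function(a, b) {
  ia <- seq_items(a); ib <- seq_items(b)
  if (length(ia) != length(ib))
    stop("length mismatch: sequences must have equal length", call. = FALSE)
  sum(ia != ib)
}

#' Extract the adjacent n-grams of a sequence
#'
#' Contiguous windows of n consecutive items, in order of their start
#' position. A sequence of length L has L - (n - 1) such windows.
#'
#' @param s Sequence string.
#' @param n n-gram length, \code{1 <= n <= nchar(s)}.
#' @return Character vector of n-gram strings, in order.
#' @export
#' @examples
#' extract_ngrams("ABCD", 2) # "AB" "BC" "CD"
extract_ngrams <- function(s, n) {
  items <- seq_items(s)
  L <- length(items)
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n > L)
    stop("n must be between 1 and the sequence length (", L, ")", call. = FALSE)
  n <- as.integer(n)
  vapply(seq_len(L - n + 1L),
         function(i) paste(items[i:(i + n - 1L)], collapse = ""),
         character(1))
}

#' n-gram (item-item) distance between two sequences
#'
#' One minus the normalised number of common adjacent n-grams, with
#' normaliser \code{gamma = 1 / (k - (n - 1))} so identical sequences are at
#' distance 0 and sequences with disjoint n-gram sets at distance 1. With
#' n = 2 this is the item-item association model's dissimilarity. Common
#' members are counted with multiplicity (multiset intersection): for
#' permutations -- the experimental stimuli -- this coincides with plain set
#' intersection, and it keeps the identity d(s, s) = 0 on repeated-item
#' sequences of the enumeration space, whose n-gram lists can contain
#' duplicates.
#'
#' @inheritParams hamming_distance
#' @param n n-gram length.
#' @return Distance in \code{[0, 1]}.
#' @export
#' @examples
#' ngram_distance("FBI", "BIN", 2) # 0.5: shared bi-gram set {"BI"}
ngram_distance <- function(a, b, n = 2) {
  ia <- seq_items(a); ib <- seq_items(b)
  if (length(ia) != length(ib))
    stop("length mismatch: sequences must have equal length", call. = FALSE)
  ta <- table(extract_ngrams(a, n))
  tb <- table(extract_ngrams(b, n))
  common <- intersect(names(ta), names(tb))
  n_common <- sum(pmin(ta[common], tb[common]))
  gamma <- 1 / (length(ia) - (n - 1))
  1 - gamma * n_common
}

#' Create an item-by-position association count matrix
#'
#' Rows are items, columns are 1-based positions. Entries hold Dirichlet
#' pseudo-counts plus observed item-position occurrences; the default
#' pseudo-count is 0, keeping the weight estimator purely empirical.
#'
#' @param alphabet Item alphabet.
#' @param L Sequence length (number of positions).
#' @param pseudo_count Non-negative Dirichlet pseudo-count added to every cell.
#' @return An items x positions numeric matrix of class "association_counts".
#' @export
association_counts <- function(alphabet = default_alphabet(), L = 4,
                               pseudo_count = 0) {
  stopifnot(pseudo_count >= 0, L >= 1)
  m <- matrix(pseudo_count, nrow = length(alphabet), ncol = L,
              dimnames = list(item = alphabet, position = seq_len(L)))
  class(m) <- c("association_counts", class(m))
  m
}

#' Update association counts with observed sequences
#'
#' Each observed (item, position) pairing increments its cell by 1; the
#' conjugate Dirichlet-multinomial update tracking the item-position
#' occurrence history.
#'
#' @param counts An "association_counts" matrix.
#' @param seqs Character vector of observed sequences.
#' @return The updated counts.
#' @export
update_association_counts <- function(counts, seqs) {
  stopifnot(inherits(counts, "association_counts"))
  for (s in seqs) {
    items <- check_sequence(s, alphabet = rownames(counts), L = ncol(counts))
    for (pos in seq_along(items))
      counts[items[pos], pos] <- counts[items[pos], pos] + 1
  }
  counts
}

#' Association weights (mu) from counts
#'
#' Normalises each item row to sum to one, giving the probability of the item
#' occurring at each position. Rows with no observations are left all-zero
#' and reported in the "zero_rows" attribute rather than being made uniform.
#'
#' @param counts An "association_counts" matrix.
#' @return An items x positions matrix of class "association_weights" with
#'   attribute \code{zero_rows}.
#' @export
association_weights <- function(counts) {
  stopifnot(inherits(counts, "association_counts"))
  totals <- rowSums(counts)
  if (all(totals == 0))
    stop("at least one item must have a nonzero row", call. = FALSE)
  mu <- counts / ifelse(totals > 0, totals, 1)
  mu[totals == 0, ] <- 0
  mu <- unclass(mu)
  attr(mu, "zero_rows") <- rownames(counts)[totals == 0]
  class(mu) <- c("association_weights", class(mu))
  mu
}

#' Recency-weighted item-mixture coefficients
#'
#' The item-mixture control model represents a sequence as a weighted
#' superposition of its item representations, with the weight of the n-th
#' item growing along the sequence (a recency slope). The default
#' coefficients are beta = (0, 1/6, 1/3, 1/2): a linear recency ramp summing
#' to one, halfway between a flat profile (all mixtures identical) and a
#' vertical one (only the final item contributes). A primacy ramp of equal
#' absolute slope yields the same pairwise distances, so only the recency
#' form is provided.
#'
#' @param beta Numeric vector of mixing coefficients; must sum to 1 and be
#'   non-decreasing. beta[1] = 0 is accepted.
#' @return Object of class "mixture_weights".
#' @export
mixture_weights <- function(beta = c(0, 1/6, 1/3, 1/2)) {
  stopifnot(is.numeric(beta), length(beta) >= 2, all(beta >= 0))
  if (abs(sum(beta) - 1) > 1e-8)
    stop("mixture coefficients must sum to 1", call. = FALSE)
  if (any(diff(beta) < -1e-12))
    stop("mixture coefficients must be non-decreasing (recency form)",
         call. = FALSE)
  structure(list(beta = beta, L = length(beta)), class = "mixture_weights")
}

#' Item-mixture vector of a sequence
#'
#' Item representations are fixed orthonormal axes (one coordinate per
#' alphabet symbol), so the mixture of a sequence is the vector whose
#' coordinate for item i is the sum of the mixing coefficients over the
#' positions where i occurs.
#'
#' @param s Sequence string.
#' @param weights A \code{\link{mixture_weights}} object.
#' @param alphabet Item alphabet defining the coordinate axes.
#' @return Named numeric vector over the alphabet.
#' @export
mixture_vector <- function(s, weights = mixture_weights(),
                           alphabet = default_alphabet()) {
  stopifnot(inherits(weights, "mixture_weights"))
  items <- check_sequence(s, alphabet = alphabet, L = weights$L)
  v <- stats::setNames(numeric(length(alphabet)), alphabet)
  for (pos in seq_along(items))
    v[items[pos]] <- v[items[pos]] + weights$beta[pos]
  v
}

#' Item-mixture distance between two sequences
#'
#' Correlation distance (\code{\link{correlation_distance}}) between the two
#' mixture vectors. A flat coefficient profile makes every mixture vector of
#' a permutation constant and the distance undefined; this degenerate input
#' raises an error.
#'
#' @inheritParams hamming_distance
#' @param weights A \code{\link{mixture_weights}} object.
#' @param alphabet Item alphabet.
#' @return Correlation distance in \code{[0, 2]}.
#' @export
mixture_distance <- function(a, b, weights = mixture_weights(),
                             alphabet = default_alphabet()) {
  va <- mixture_vector(a, weights, alphabet)
  vb <- mixture_vector(b, weights, alphabet)
  correlation_distance(va, vb)
}
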