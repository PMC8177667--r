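#' Representational dissimilarity matrix (RDM)
#'
#' The common currency between representation models and measured activity
#' patterns: a labelled symmetric matrix of pairwise dissimilarities with a
#' zero diagonal. Labels may repeat (e.g. trial-level RDMs label each trial
#' with its sequence).
#'
#' @param d Symmetric numeric matrix with zero diagonal.
#' @param labels Row/column labels; defaults to existing dimnames.
#' @param allow_na Permit missing cells (recorded as NA, e.g. degenerate
#'   pattern pairs); otherwise all entries must be finite.
#' @return Object of class "rdm" (a classed matrix).
#' @export
rdm <- function(d, labels = rownames(d), allow_na = FALSE) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  stopifnot(length(labels) == nrow(d))
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-8)
    stop("RDM must be symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-8, na.rm = TRUE))
    stop("RDM diagonal must be zero", call. = FALSE)
  if (!allow_na && !all(is.finite(d)))
    stop("RDM entries must be finite", call. = FALSE)
  dimnames(d) <- list(labels, labels)
  class(d) <- c("rdm", "matrix", "array")
  d
}

#' @export
print.rdm <- function(x, ...) {
  cat("RDM over", nrow(x), "conditions;",
      sum(lower.tri(x)), "lower-triangle cells\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' @export
as.matrix.rdm <- function(x, ...) {
  class(x) <- c("matrix", "array")
  x
}

#' Lower-triangle cells of an RDM
#'
#' @param x An "rdm" (or plain symmetric matrix).
#' @param mask Optional logical matrix of the same dimension selecting cells;
#'   combined with the strict lower triangle.
#' @return Numeric vector of selected cells (column-major order).
#' @export
rdm_lower <- function(x, mask = NULL) {
  m <- unclass(x)
  keep <- lower.tri(m)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(m)))
    keep <- keep & (mask | t(mask))
  }
  m[keep]
}

#' Model RDM over a set of sequences
#'
#' Builds the pairwise dissimilarity matrix for one of the non-chunk sequence
#' representation models: "hamming" (item-position associations), "bigram"
#' (item-item associations; any n via \code{n}), or "mixture" (item-mixture
#' control model). Chunk-code RDMs are built by \code{\link{chunk_rdm}}.
#'
#' @param seqs Character vector of >= 2 sequences (labels of the RDM).
#' @param model One of "hamming", "bigram", "mixture".
#' @param n n-gram length for the bigram model.
#' @param weights Mixture coefficients for the mixture model.
#' @param alphabet Item alphabet (mixture model).
#' @param labels RDM labels; default the sequences themselves.
#' @return An \code{\link{rdm}}.
#' @export
#' @examples
#' r <- model_rdm(c("ABCD", "CBAD", "BADC"), "hamming")
#' r["ABCD", "CBAD"] # 2
model_rdm <- function(seqs, model = c("hamming", "bigram", "mixture"),
                      n = 2, weights = mixture_weights(),
                      alphabet = default_alphabet(), labels = seqs) {
  model <- match.arg(model)
  stopifnot(length(seqs) >= 2)
  fun <- switch(model,
    hamming = function(a, b) hamming_distance(a, b),
    bigram  = function(a, b) ngram_distance(a, b, n = n),
    mixture = function(a, b) mixture_distance(a, b, weights, alphabet))
  m <- length(seqs)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    d[i, j] <- d[j, i] <- fun(seqs[i], seqs[j])
  rdm(d, labels = labels)
}

#' Write / read an RDM as CSV
#'
#' Wide format: a label header row and a label first column. Long format:
#' columns \code{label_i, label_j, distance} over the strict lower triangle.
#'
#' @param x An "rdm".
#' @param path Output file path.
#' @param long Write the long (pairwise) format instead of the matrix.
#' @export
write_rdm <- function(x, path, long = FALSE) {
  stopifnot(inherits(x, "rdm"))
  if (long) {
    idx <- which(lower.tri(x), arr.ind = TRUE)
    df <- data.frame(label_i = rownames(x)[idx[, 1]],
                     label_j = colnames(x)[idx[, 2]],
                     distance = unclass(x)[idx])
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(label = rownames(x), unclass(x),
                                check.names = FALSE),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rdm(unname(m) * 1, labels = as.character(df[[1]]), allow_na = TRUE)
}
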