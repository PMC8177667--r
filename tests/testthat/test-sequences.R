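test_that("hamming distance matches worked examples and rejects bad input", {
  expect_identical(hamming_distance("ABCD", "CBAD"), 2L)
  expect_identical(hamming_distance("ABCD", "ABCD"), 0L)
  expect_identical(hamming_distance("ABCD", "BADC"), 4L)
  expect_error(hamming_distance("ABC", "ABCD"), "length mismatch")
})

test_that("hamming distance is a metric on the full length-4 space", {
  space <- enumerate_space()
  n <- length(space)
  D <- matrix(0L, n, n)
  items <- do.call(rbind, lapply(space, seq_items))
  for (pos in 1:4) D <- D + outer(items[, pos], items[, pos], "!=")
  # spot-check agreement with the scalar implementation
  idx <- cbind(sample.int(n, 50), sample.int(n, 50))
  for (r in seq_len(nrow(idx)))
    expect_identical(hamming_distance(space[idx[r, 1]], space[idx[r, 2]]),
                     as.integer(D[idx[r, 1], idx[r, 2]]))
  expect_true(all(diag(D) == 0))
  expect_true(all(D == t(D)))
  for (k in seq_len(n)) { # triangle inequality through every midpoint
    expect_true(all(D <= outer(D[, k], D[k, ], "+")))
  }
})

test_that("n-gram extraction returns ordered contiguous windows", {
  expect_identical(extract_ngrams("ABCD", 2), c("AB", "BC", "CD"))
  expect_identical(extract_ngrams("ABCD", 4), "ABCD")
  expect_identical(extract_ngrams("ABCD", 1), c("A", "B", "C", "D"))
  expect_error(extract_ngrams("ABCD", 5), "between 1 and")
  expect_error(extract_ngrams("ABCD", 0), "between 1 and")
})

test_that("n-gram distance counts common members with gamma normalisation", {
  expect_equal(ngram_distance("ABCD", "ABCD", 2), 0)
  expect_equal(ngram_distance("FBI", "BIN", 2), 0.5)
  expect_equal(ngram_distance("ABCD", "CBAD", 2), 1)
  # identity and range over a random sample of the repeats-allowed space
  space <- enumerate_space()
  set.seed(1)
  for (s in sample(space, 30)) expect_equal(ngram_distance(s, s, 2), 0)
  pairs <- cbind(sample(space, 200, TRUE), sample(space, 200, TRUE))
  d <- apply(pairs, 1, function(p) ngram_distance(p[1], p[2], 2))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("association counts track item-position history additively", {
  c0 <- association_counts()
  c1 <- update_association_counts(c0, "ABCD")
  expect_equal(unname(diag(unclass(c1))), rep(1, 4))
  expect_equal(sum(c1), 4)
  c2 <- update_association_counts(c1, "ABCD")
  expect_equal(unclass(c2), 2 * unclass(c1), ignore_attr = TRUE)
  c3 <- update_association_counts(c0, c("BACD", "CABD", "ABCD"))
  expect_equal(unclass(c3)["A", 2], 2)
})

test_that("association weights reproduce the empirical frequency matrix", {
  cnt <- update_association_counts(association_counts(),
                                   c("BACD", "CABD", "ABCD"))
  mu <- association_weights(cnt)
  printed <- rbind(c(1/3, 2/3, 0, 0),
                   c(1/3, 1/3, 1/3, 0),
                   c(1/3, 0, 2/3, 0),
                   c(0, 0, 0, 1))
  expect_equal(unclass(mu), printed, ignore_attr = TRUE)
  expect_equal(unname(rowSums(mu)), rep(1, 4))
  # single observation gives an indicator matrix
  mu1 <- association_weights(update_association_counts(association_counts(),
                                                       "ABCD"))
  expect_equal(unname(diag(unclass(mu1))), rep(1, 4))
  # empirical-frequency property on a random multiset
  set.seed(3)
  seqs <- sample(all_perms(), 40, replace = TRUE)
  mu2 <- association_weights(
    update_association_counts(association_counts(), seqs))
  tallies <- table(item = unlist(lapply(seqs, seq_items)),
                   position = rep(1:4, length(seqs)))
  expect_equal(unclass(mu2), unclass(tallies / rowSums(tallies)),
               ignore_attr = TRUE)
})

test_that("zero-observation item rows stay zero and are flagged", {
  cnt <- association_counts(alphabet = c("A", "B", "C", "D", "E"), L = 4)
  cnt <- update_association_counts(cnt, "ABCD")
  mu <- association_weights(cnt)
  expect_equal(attr(mu, "zero_rows"), "E")
  expect_equal(unname(unclass(mu)["E", ]), rep(0, 4))
})

test_that("mixture vectors and distances follow the recency weighting", {
  w <- mixture_weights()
  expect_equal(unname(mixture_vector("ABCD", w)), c(0, 1/6, 1/3, 1/2))
  expect_equal(mixture_distance("ABCD", "BACD", w), 0.2)
  expect_equal(mixture_distance("ABCD", "ABCD", w), 0)
  # all weight on the last position: one-hot at the last item
  w_last <- mixture_weights(c(0, 0, 0, 1))
  expect_equal(unname(mixture_vector("ABCD", w_last)), c(0, 0, 0, 1))
  # a flat profile is rejected at distance time (constant vectors)
  w_flat <- mixture_weights(rep(1/4, 4))
  expect_error(mixture_distance("ABCD", "BACD", w_flat), "degenerate")
  expect_error(mixture_weights(c(1/2, 1/3, 1/6, 0)), "non-decreasing")
  expect_error(mixture_weights(c(0, 0.2, 0.3, 0.4)), "sum to 1")
})

test_that("model RDMs are symmetric, zero-diagonal, with expected cells", {
  seqs <- c("ABCD", "CBAD", "BADC", "DCBA")
  for (m in c("hamming", "bigram", "mixture")) {
    r <- model_rdm(seqs, m)
    expect_s3_class(r, "rdm")
    expect_equal(unname(diag(unclass(r))), rep(0, 4))
    expect_equal(unclass(r), t(unclass(r)), ignore_attr = TRUE)
  }
  r <- model_rdm(seqs, "hamming")
  expect_equal(unclass(r)["ABCD", "CBAD"], 2)
  expect_error(model_rdm(seqs, "edit"))
  # 14 sequences give C(14,2) = 91 informative lower-triangle cells
  d14 <- test_design()
  expect_length(rdm_lower(model_rdm(d14$sequences, "hamming")), 91)
})

test_that("item-position and bi-gram RDMs are inversely correlated over the
           24 permutations", {
  perms <- all_perms()
  h <- rdm_lower(model_rdm(perms, "hamming"))
  b <- rdm_lower(model_rdm(perms, "bigram"))
  expect_lt(cor(h, b, method = "spearman"), 0)
})

test_that("RDM CSV round-trips in wide and long form", {
  r <- model_rdm(c("ABCD", "CBAD", "BADC"), "hamming")
  f <- withr::local_tempfile(fileext = ".csv")
  write_rdm(r, f)
  r2 <- read_rdm(f)
  expect_equal(unclass(r2), unclass(r), ignore_attr = TRUE)
  expect_identical(rownames(r2), rownames(r))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_rdm(r, f2, long = TRUE)
  long <- read.csv(f2)
  expect_identical(names(long), c("label_i", "label_j", "distance"))
  expect_equal(nrow(long), 3)
})
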