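test_that("parse enumeration counts follow 2^(L-1)", {
  expect_length(enumerate_parses(4), 8)
  expect_length(enumerate_parses(1), 1)
  expect_length(enumerate_parses(3), 4)
  # independent oracle: recursive composition count
  count_comp <- function(L) if (L == 0) 1 else
    sum(vapply(seq_len(L), function(f) count_comp(L - f), numeric(1)))
  for (L in 1:8) expect_length(enumerate_parses(L), count_comp(L))
  # every parse covers 1..L with disjoint in-order spans
  for (p in enumerate_parses(4)) {
    spans <- parse_spans(p)
    covered <- unlist(lapply(spans, function(sp) sp[1]:sp[2]))
    expect_identical(covered, 1:4)
  }
  expect_error(enumerate_parses(0), "positive")
})

test_that("inventory has 64 entries with the combinatorial priors", {
  inv <- build_inventory()
  expect_equal(nrow(inv$entries), 64)
  expect_equal(as.integer(table(inv$entries$k)), c(4, 12, 24, 24))
  expect_equal(sum(inv$entries$prior), 1)
  expect_equal(inv$entries["A", "prior"], 1 / 16)
  expect_equal(inv$entries["AB", "prior"], 1 / 48)
  expect_equal(inv$entries["A", "prior"] / inv$entries["AB", "prior"], 3)
  # no repeated item within an entry
  expect_false(any(vapply(inv$entries$ngram,
                          function(g) anyDuplicated(seq_items(g)) > 0,
                          logical(1))))
  expect_error(build_inventory(c("A", "B"), L = 3), "too small")
})

test_that("chunk-set and mapping log probabilities compose additively", {
  inv <- build_inventory()
  expect_equal(chunk_set_log_prob(character(0), inv), 0)
  expect_equal(chunk_set_log_prob(c("A", "B", "C", "D"), inv), 4 * log(1/16))
  s1 <- c("A", "AB"); s2 <- c("CD", "ABC")
  expect_equal(chunk_set_log_prob(c(s1, s2), inv),
               chunk_set_log_prob(s1, inv) + chunk_set_log_prob(s2, inv))
  expect_error(chunk_set_log_prob("AA", inv), "unknown chunk")
  expect_equal(mapping_log_prob(4L, eta = 0.1), log(0.1))
  expect_equal(mapping_log_prob(rep(1L, 4), eta = 0.1), 4 * log(0.1))
  expect_equal(mapping_log_prob(c(2L, 2L), eta = 0.1), 2 * log(0.1))
  expect_error(mapping_log_prob(c(2L, 2L), eta = 0), "eta")
  expect_error(mapping_log_prob(c(2L, 2L), eta = 1.5), "eta")
})

test_that("model evidence matches an independent brute-force oracle", {
  inv <- build_inventory()
  eta <- 0.1
  # single sequence encoded by one four-gram
  m <- chunk_model("ABCD", list(ABCD = list(parse = 4L)), eta, inv)
  ev <- model_evidence(m, "ABCD")
  expect_equal(ev$log_total, log(1/96) + log(eta))
  expect_equal(ev$log_total, ev$log_code + ev$log_encoding)
  # bi-gram vs uni-gram encodings of S = {ABCD, ABCD, CDAB}
  seqs <- c("ABCD", "ABCD", "CDAB")
  x <- c("AB", "CD", "A", "B", "C", "D")
  z1 <- chunk_model(x, list(ABCD = list(parse = c(2L, 2L)),
                            CDAB = list(parse = c(2L, 2L))), eta, inv)
  z2 <- chunk_model(x, list(ABCD = list(parse = rep(1L, 4)),
                            CDAB = list(parse = rep(1L, 4))), eta, inv)
  e1 <- model_evidence(z1, seqs); e2 <- model_evidence(z2, seqs)
  expect_equal(e1$log_code, e2$log_code)
  expect_gt(e1$log_total, e2$log_total)
  # appending presentations to a fixed model never raises its evidence
  grow <- vapply(seq_along(seqs), function(t)
    model_evidence(z1, seqs[seq_len(t)])$log_total, numeric(1))
  expect_true(all(diff(grow) <= 0))
  # oracle comparison on several hand-built models over <= 4 sequences
  cases <- list(
    list(seqs = c("ABCD", "CDAB"),
         parses = list(ABCD = c(2L, 2L), CDAB = c(2L, 2L))),
    list(seqs = c("ABCD", "ABCD", "BCDA", "DABC"),
         parses = list(ABCD = 4L, BCDA = c(1L, 3L), DABC = c(3L, 1L))),
    list(seqs = "DCBA", parses = list(DCBA = c(1L, 2L, 1L))))
  for (cs in cases) {
    assignments <- lapply(cs$parses, function(p) list(parse = p))
    chunks <- unique(unlist(Map(parse_chunks_for_test <- function(s, p) {
      items <- seq_items(s); ends <- cumsum(p); starts <- ends - p + 1
      mapply(function(a, b) paste(items[a:b], collapse = ""), starts, ends)
    }, names(cs$parses), cs$parses)))
    m <- chunk_model(chunks, assignments, eta, inv)
    ev <- model_evidence(m, cs$seqs)
    expect_equal(ev$log_total,
                 oracle_evidence(chunks, cs$parses, cs$seqs, eta))
  }
  # an assignment that fails to reproduce its sequence is rejected
  expect_error(chunk_model("ABDC", list(ABCD = list(parse = 4L)), eta, inv),
               "encoding mismatch|absent")
  expect_error(model_evidence(m, c("DCBA", "BBBB")), "encoding mismatch")
})

test_that("reference model ranking reproduces the practice-phase ordering", {
  practice <- rep(c("CADB", "DCBA"), each = 12)
  for (eta in c(1/4, 1/8, 1/10)) {
    tab <- reference_models(practice, eta = eta)
    expect_identical(tab$model_id[1], "4-gram")
    expect_identical(tab$model_id,
                     tab$model_id[order(-tab$log_total)])
    expect_gt(tab$log_total[tab$model_id == "2-gram"],
              tab$log_total[tab$model_id == "1-gram"])
  }
  # code-term cost ordering: uni-gram code cheapest per chunk-set size
  tab <- reference_models(practice, eta = 0.1)
  expect_gt(tab$log_code[tab$model_id == "1-gram"] / 4,
            tab$log_code[tab$model_id == "2-gram"] / 4)
  # a lone sequence: the dedicated four-gram wins on raw evidence, because
  # one long chunk is always cheaper than four uni-grams plus three links
  lone <- reference_models("ABCD", eta = 0.1)
  expect_identical(lone$model_id[1], "4-gram")
})

test_that("optimal model fits reproduce the designed-experiment chunk sets", {
  practice <- rep(c("CADB", "DCBA"), each = 12)
  m0 <- fit_optimal_model(practice)
  expect_setequal(m0$chunks, c("CADB", "DCBA"))
  m1 <- fit_optimal_model(c(practice, "ABCD"))
  expect_setequal(m1$chunks, c("CADB", "DCBA", "A", "B", "C", "D"))
  # a sequence seen once is never recoded: four uni-grams
  expect_setequal(fit_optimal_model("ABCD")$chunks, c("A", "B", "C", "D"))
})

test_that("fitted evidence dominates an exhaustive search over the
           licensed candidate space", {
  inv <- build_inventory(); eta <- 0.1
  sets <- list(rep("ABCD", 4),
               c(rep("ABCD", 3), rep("CDAB", 3)),
               c(rep("BADC", 3), "ABCD", "DCBA"))
  for (seqs in sets) {
    fit <- fit_optimal_model(seqs, inv, eta)
    best <- attr(fit, "evidence")$log_total
    tab <- table(seqs)
    licensed <- names(tab)[tab >= 3]
    opts <- lapply(names(tab), function(s)
      if (s %in% licensed) enumerate_parses(4) else list(rep(1L, 4)))
    names(opts) <- names(tab)
    grid <- expand.grid(lapply(opts, seq_along))
    for (r in seq_len(nrow(grid))) {
      parses <- lapply(names(tab), function(s) opts[[s]][[grid[r, s]]])
      names(parses) <- names(tab)
      chunks <- unique(unlist(Map(function(s, p) {
        items <- seq_items(s); ends <- cumsum(p); starts <- ends - p + 1
        mapply(function(a, b) paste(items[a:b], collapse = ""), starts, ends)
      }, names(parses), parses)))
      expect_gte(best + 1e-9, oracle_evidence(chunks, parses, seqs, eta))
    }
  }
})

test_that("planted chunk structure is recovered after three repetitions", {
  # sequences built by concatenating chunks from a planted set
  planted <- list(c("AB", "CD"), c("DC", "BA"))
  seqs <- rep(vapply(planted, paste, character(1), collapse = ""), each = 3)
  inv <- build_inventory(); eta <- 0.1
  fit <- fit_optimal_model(seqs, inv, eta)
  planted_assign <- lapply(stats::setNames(unique(seqs), unique(seqs)),
                           function(s) list(parse = c(2L, 2L)))
  planted_model <- chunk_model(unlist(planted), planted_assign, eta, inv)
  unigram_model <- chunk_model(
    c("A", "B", "C", "D"),
    lapply(stats::setNames(unique(seqs), unique(seqs)),
           function(s) list(parse = rep(1L, 4))), eta, inv)
  expect_gt(model_evidence(planted_model, seqs)$log_total,
            model_evidence(unigram_model, seqs)$log_total)
  expect_gte(attr(fit, "evidence")$log_total,
             model_evidence(planted_model, seqs)$log_total)
})

test_that("sequential optimal model is stationary on the designed schedule", {
  sched <- test_schedule()
  for (eta in c(1/4, 1/10)) {
    fit <- sequential_optimal_models(sched, eta = eta)
    main <- fit$trials[fit$trials$segment == "main", ]
    expect_true(all(main$n_chunks[main$condition == "repeating"] == 1))
    expect_true(all(main$n_chunks[main$condition == "novel"] == 4))
    # once encodings are stationary the evidence decreases trial by trial
    expect_true(all(diff(main$log_evidence) < 0))
  }
})

test_that("without practice the early trials are uni-gram coded and the
           four-gram code appears within 12 repetitions", {
  d <- test_design()
  sched <- test_schedule()
  no_practice <- sched[sched$segment == "main", , drop = FALSE]
  fit <- sequential_optimal_models(no_practice[1:12, , drop = FALSE])
  first_rep <- which(no_practice$condition[1:12] == "repeating")[1]
  expect_equal(fit$trials$n_chunks[first_rep], 4)
  # practice-style stream: the four-gram encoding takes over by rep <= 12
  stream <- data.frame(trial_index = 1:12, segment = "main",
                       sequence = rep(d$repeating[1], 12),
                       condition = "repeating")
  fitp <- sequential_optimal_models(stream)
  takeover <- which(fitp$trials$n_chunks == 1)[1]
  expect_lte(takeover, 12)
})

test_that("chunk RDM shows the three dissimilarity regimes", {
  sched <- test_schedule()
  r <- chunk_rdm(sched)
  main <- sched[sched$segment == "main", ]
  rep_seqs <- attr(sched, "repeating")
  same_rep <- which(main$sequence == rep_seqs[1])
  expect_equal(unclass(r)[same_rep[1], same_rep[2]], 0)
  nov <- which(main$condition == "novel")
  repi <- which(main$condition == "repeating")
  expect_equal(unclass(r)[repi[1], nov[1]], 1)
  # novel-novel cells equal Hamming / 4
  for (k in 1:5)
    expect_equal(unclass(r)[nov[k], nov[k + 1]],
                 hamming_distance(main$sequence[nov[k]],
                                  main$sequence[nov[k + 1]]) / 4)
  # sequential inference reproduces the stationary encodings
  fit <- sequential_optimal_models(sched)
  expect_equal(unclass(chunk_rdm(sched, fit)), unclass(r),
               ignore_attr = TRUE)
})

test_that("chunk models serialise to JSON and back", {
  inv <- build_inventory()
  m <- fit_optimal_model(c(rep("CADB", 3), "ABCD"), inv)
  f <- withr::local_tempfile(fileext = ".json")
  write_chunk_model(m, f)
  m2 <- read_chunk_model(f, inv)
  expect_setequal(m2$chunks, m$chunks)
  expect_equal(m2$eta, m$eta)
  expect_equal(model_evidence(m2, c(rep("CADB", 3), "ABCD"))$log_total,
               attr(m, "evidence")$log_total)
})
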