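#' Enumerate all parses of a length-L sequence
#'
#' A parse is an ordered tuple of contiguous position spans that jointly
#' cover positions 1..L; equivalently an ordered composition of L. There are
#' 2^(L-1) parses: 8 for a four-item sequence.
#'
#' @param L Sequence length (>= 1).
#' @return List of parses, each an integer vector of span lengths
#'   (e.g. c(1, 2, 1) for ((1), (2, 3), (4))).
#' @export
enumerate_parses <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    stop("L must be a positive integer", call. = FALSE)
  L <- as.integer(L)
  if (L == 1L) return(list(1L))
  out <- list()
  for (first in seq_len(L)) {
    if (first == L) out <- c(out, list(L)) else
      out <- c(out, lapply(enumerate_parses(L - first), function(p) c(first, p)))
  }
  out
}

#' Position spans of a parse
#'
#' @param parse Integer vector of span lengths.
#' @return List of c(start, end) integer pairs.
#' @export
parse_spans <- function(parse) {
  ends <- cumsum(parse)
  starts <- ends - parse + 1L
  Map(function(s, e) c(start = s, end = e), as.integer(starts), as.integer(ends))
}

#' @keywords internal
all_partial_permutations <- function(alphabet, k) {
  if (k == 1L) return(alphabet)
  shorter <- all_partial_permutations(alphabet, k - 1L)
  unlist(lapply(shorter, function(s) {
    used <- seq_items(s)
    paste0(s, setdiff(alphabet, used))
  }))
}

#' n-gram chunk inventory with combinatorial priors
#'
#' All n-grams of length 1..L over the alphabet with no repeated item within
#' an n-gram (experimental sequences are permutations). The prior of a
#' length-k entry is proportional to the reciprocal of the number of partial
#' permutations of the n items taken k at a time, p(c) = alpha * (n-k)!/n!,
#' with alpha normalising the priors over the whole inventory (alpha = 1/L,
#' since each length class carries equal total mass). For a 4-item alphabet
#' and L = 4 the inventory has 4 + 12 + 24 + 24 = 64 entries, a uni-gram has
#' prior 1/16 and a bi-gram 1/48: simple chunks are 3 times more likely than
#' two-item chunks, and so forth.
#'
#' @param alphabet Item alphabet (size >= L for the no-repeat rule).
#' @param L Maximum chunk length.
#' @return Object of class "ngram_inventory": list with \code{entries}
#'   (data.frame ngram/k/prior), \code{alpha}, \code{alphabet}, \code{L}.
#' @export
build_inventory <- function(alphabet = default_alphabet(), L = 4) {
  n <- length(alphabet)
  if (n < L) stop("alphabet too small for chunks of length ", L, call. = FALSE)
  entries <- do.call(rbind, lapply(seq_len(L), function(k) {
    grams <- all_partial_permutations(alphabet, k)
    data.frame(ngram = grams, k = k,
               weight = factorial(n - k) / factorial(n))
  }))
  alpha <- 1 / sum(entries$weight)
  entries$prior <- alpha * entries$weight
  entries$weight <- NULL
  rownames(entries) <- entries$ngram
  structure(list(entries = entries, alpha = alpha,
                 alphabet = alphabet, L = as.integer(L)),
            class = "ngram_inventory")
}

#' @export
print.ngram_inventory <- function(x, ...) {
  cat("n-gram inventory:", nrow(x$entries), "entries over alphabet {",
      paste(x$alphabet, collapse = ", "), "}, alpha =", x$alpha, "\n")
  print(table(k = x$entries$k))
  invisible(x)
}

#' Log prior probability of a chunk set
#'
#' Chunks are independent, so the log probability of a set is the sum of the
#' log priors of its members; the empty set has log probability 0.
#'
#' @param chunks Character vector of inventory entries (each listed once).
#' @param inventory An \code{\link{build_inventory}} result.
#' @return Log probability (<= 0).
#' @export
chunk_set_log_prob <- function(chunks, inventory = build_inventory()) {
  chunks <- unique(chunks)
  if (length(chunks) == 0L) return(0)
  unknown <- setdiff(chunks, inventory$entries$ngram)
  if (length(unknown) > 0L)
    stop("unknown chunk(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sum(log(inventory$entries[chunks, "prior"]))
}

#' Log probability of a parse (mapping)
#'
#' A mapping with F links (spans) has probability eta^F, where eta is the
#' constant per-link probability. The default eta = 1/10 reads eta as the
#' reciprocal of the number of distinct contiguous spans of a length-4
#' sequence (4 + 3 + 2 + 1 = 10); downstream model rankings are robust to
#' this choice (see the package vignette).
#'
#' @param parse Integer vector of span lengths (F = length(parse)).
#' @param eta Per-link probability in (0, 1].
#' @return F * log(eta).
#' @export
mapping_log_prob <- function(parse, eta = 0.1) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta > 1)
    stop("eta must be in (0, 1]", call. = FALSE)
  length(parse) * log(eta)
}

#' @keywords internal
parse_chunks <- function(s, parse) {
  items <- seq_items(s)
  vapply(parse_spans(parse),
         function(sp) paste(items[sp[1]:sp[2]], collapse = ""), character(1))
}

#' Construct a chunk model
#'
#' A chunking model is a chunk set \code{x} plus per-sequence parse
#' assignments \code{z}. Each assignment must reproduce its sequence exactly
#' from chunks present in the set.
#'
#' @param chunks Character vector: the chunk set (each chunk once).
#' @param assignments Named list (names = distinct sequences); each element a
#'   list with \code{parse} (span lengths). Chunk identities follow from the
#'   parse.
#' @param eta Per-link probability.
#' @param inventory Chunk inventory the chunks must belong to.
#' @return Object of class "chunk_model".
#' @export
chunk_model <- function(chunks, assignments, eta = 0.1,
                        inventory = build_inventory()) {
  chunks <- sort(unique(chunks))
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  for (s in names(assignments)) {
    a <- assignments[[s]]
    if (sum(a$parse) != nchar(s))
      stop("parse for '", s, "' does not cover the sequence", call. = FALSE)
    used <- parse_chunks(s, a$parse)
    missing <- setdiff(used, chunks)
    if (length(missing) > 0L)
      stop("encoding mismatch: assignment for '", s,
           "' uses chunks absent from the chunk set: ",
           paste(missing, collapse = ", "), call. = FALSE)
    assignments[[s]]$chunks <- used
  }
  chunk_set_log_prob(chunks, inventory) # validates membership
  structure(list(chunks = chunks, assignments = assignments,
                 eta = eta, inventory = inventory),
            class = "chunk_model")
}

#' @export
print.chunk_model <- function(x, ...) {
  cat("chunk model: x = {", paste(x$chunks, collapse = ", "),
      "}, eta =", x$eta, ",", length(x$assignments), "encoded sequence(s)\n")
  invisible(x)
}

#' Model evidence of a chunk model on a sequence multiset
#'
#' The evidence decomposes into a code term (log prior of the chunk set) and
#' an encoding term (sum over presented sequences of F * log(eta) for the
#' assigned parse). Every presentation of a sequence pays its mapping cost;
#' the chunk set is paid once. Each sequence must have an assignment that
#' reproduces it exactly.
#'
#' @param model A \code{\link{chunk_model}}.
#' @param seqs Character vector of sequence presentations (repetitions
#'   included).
#' @return Object of class "model_evidence": list with \code{log_code},
#'   \code{log_encoding}, \code{log_total}.
#' @export
model_evidence <- function(model, seqs) {
  stopifnot(inherits(model, "chunk_model"), length(seqs) >= 1)
  missing <- setdiff(unique(seqs), names(model$assignments))
  if (length(missing) > 0L)
    stop("encoding mismatch: no assignment for sequence(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  log_code <- chunk_set_log_prob(model$chunks, model$inventory)
  log_encoding <- sum(vapply(
    seqs, function(s) mapping_log_prob(model$assignments[[s]]$parse, model$eta),
    numeric(1)))
  structure(list(log_code = log_code, log_encoding = log_encoding,
                 log_total = log_code + log_encoding),
            class = "model_evidence")
}

#' @export
print.model_evidence <- function(x, ...) {
  cat(sprintf("model evidence: log code %.3f + log encoding %.3f = %.3f\n",
              x$log_code, x$log_encoding, x$log_total))
  invisible(x)
}

#' Evidence table for the fixed 1-gram, 2-gram and 4-gram models
#'
#' The three alternative chunking models that use only a single n-gram size:
#' the 1-gram model encodes every sequence with four single-item chunks, the
#' 2-gram model with two bi-grams, the 4-gram model with one four-gram. These
#' reference models chunk-encode every sequence they see, including
#' once-seen ones (no recurrence licensing), so their evidence can be traced
#' across an experiment for comparison against the optimal model.
#'
#' @param seqs Sequence presentations (length-L, L divisible by each n).
#' @param inventory Chunk inventory.
#' @param eta Per-link probability.
#' @param sizes n-gram sizes of the reference models.
#' @return data.frame with columns model_id, n_sequences, log_code,
#'   log_encoding, log_total, ordered by decreasing evidence.
#' @export
reference_models <- function(seqs, inventory = build_inventory(), eta = 0.1,
                             sizes = c(1, 2, 4)) {
  stopifnot(length(seqs) >= 1)
  L <- nchar(seqs[[1]])
  rows <- lapply(sizes, function(n) {
    if (L %% n != 0)
      stop("sequences of length ", L, " are not encodable with ", n,
           "-grams only", call. = FALSE)
    parse <- rep(as.integer(n), L / n)
    assignments <- stats::setNames(
      lapply(unique(seqs), function(s) list(parse = parse)), unique(seqs))
    chunks <- unique(unlist(lapply(unique(seqs), parse_chunks, parse = parse)))
    ev <- model_evidence(chunk_model(chunks, assignments, eta, inventory), seqs)
    data.frame(model_id = paste0(n, "-gram"), n_sequences = length(seqs),
               log_code = ev$log_code, log_encoding = ev$log_encoding,
               log_total = ev$log_total)
  })
  out <- do.call(rbind, rows)
  out[order(-out$log_total), , drop = FALSE]
}

#' @keywords internal
admissible_parses <- function(s, L) {
  items <- seq_items(s)
  Filter(function(p) {
    all(vapply(parse_spans(p), function(sp) {
      seg <- items[sp[1]:sp[2]]
      length(seg) == length(unique(seg))
    }, logical(1)))
  }, enumerate_parses(L))
}

#' Fit the optimal chunking model for a set of presentations
#'
#' Ranks candidate models by evidence over the space of chunk sets formed by
#' choosing one parse per distinct sequence (chunk set = union of the
#' parse-induced n-grams), searched exhaustively for up to
#' \code{max_exhaustive} recurring sequences and by greedy coordinate ascent
#' beyond that. Ties are broken toward fewer chunks, then lexicographically.
#'
#' Recurrence licensing: multi-item chunks are only considered for sequences
#' presented at least \code{min_occurrences} times; sequences seen fewer
#' times are encoded with uni-grams. This operationalises the recoding
#' premise that chunks are inferred from items that co-occur repeatedly --
#' under the raw evidence a once-seen sequence would always be assigned a
#' dedicated long chunk (the code cost log p(c) of one long chunk is smaller
#' than that of its uni-grams plus the extra links), which would make
#' recoding indistinguishable from mere storage. See the vignette for the
#' full rationale.
#'
#' @param seqs Character vector of sequence presentations (order irrelevant;
#'   multiplicity matters).
#' @param inventory Chunk inventory.
#' @param eta Per-link probability.
#' @param min_occurrences Minimum presentations before a sequence may be
#'   parsed into multi-item chunks (default 3).
#' @param max_exhaustive Maximum number of recurring distinct sequences for
#'   exhaustive parse-combination search.
#' @return A \code{\link{chunk_model}} with attribute "evidence" (the
#'   \code{\link{model_evidence}} on \code{seqs}).
#' @export
fit_optimal_model <- function(seqs, inventory = build_inventory(), eta = 0.1,
                              min_occurrences = 3, max_exhaustive = 5) {
  stopifnot(length(seqs) >= 1)
  tab <- table(seqs)
  distinct <- names(tab)
  L <- nchar(distinct[[1]])
  counts <- as.integer(tab)
  names(counts) <- distinct
  uni_parse <- rep(1L, L)
  licensed <- distinct[counts >= min_occurrences]
  parse_opts <- lapply(distinct, function(s) {
    if (s %in% licensed) admissible_parses(s, L) else list(uni_parse)
  })
  names(parse_opts) <- distinct

  evidence_of <- function(choice) { # choice: index into parse_opts per seq
    chunks <- character(0)
    log_encoding <- 0
    for (s in distinct) {
      p <- parse_opts[[s]][[choice[[s]]]]
      chunks <- c(chunks, parse_chunks(s, p))
      log_encoding <- log_encoding + counts[[s]] * length(p) * log(eta)
    }
    chunks <- unique(chunks)
    list(total = chunk_set_log_prob(chunks, inventory) + log_encoding,
         n_chunks = length(chunks), chunks = chunks)
  }

  n_opts <- vapply(parse_opts, length, integer(1))
  free <- distinct[n_opts > 1L]
  choice <- stats::setNames(rep(1L, length(distinct)), distinct)

  better <- function(a, b) { # is candidate a better than incumbent b?
    if (is.null(b)) return(TRUE)
    if (a$total > b$total + 1e-9) return(TRUE)
    if (a$total < b$total - 1e-9) return(FALSE)
    if (a$n_chunks != b$n_chunks) return(a$n_chunks < b$n_chunks)
    paste(sort(a$chunks), collapse = " ") < paste(sort(b$chunks), collapse = " ")
  }

  best <- NULL; best_choice <- choice
  if (length(free) <= max_exhaustive) {
    grid <- if (length(free) == 0L) matrix(integer(0), nrow = 1L) else
      as.matrix(expand.grid(lapply(free, function(s) seq_len(n_opts[[s]]))))
    for (r in seq_len(nrow(grid))) {
      ch <- choice
      if (length(free) > 0L) ch[free] <- grid[r, ]
      cand <- c(evidence_of(ch), list())
      if (better(cand, best)) { best <- cand; best_choice <- ch }
    }
  } else { # greedy coordinate ascent with restarts from the uni-gram parse
    best <- evidence_of(choice); best_choice <- choice
    repeat {
      improved <- FALSE
      for (s in free) {
        for (k in seq_len(n_opts[[s]])) {
          ch <- best_choice; ch[[s]] <- k
          cand <- evidence_of(ch)
          if (better(cand, best)) { best <- cand; best_choice <- ch; improved <- TRUE }
        }
      }
      if (!improved) break
    }
  }

  assignments <- stats::setNames(lapply(distinct, function(s)
    list(parse = parse_opts[[s]][[best_choice[[s]]]])), distinct)
  m <- chunk_model(best$chunks, assignments, eta, inventory)
  attr(m, "evidence") <- model_evidence(m, seqs)
  attr(m, "counts") <- counts
  m
}

#' Sequential optimal chunking models across a trial schedule
#'
#' Re-fits the optimal model after every trial (practice trials included), as
#' an ideal learner would, and records how the trial's sequence is encoded at
#' that point. On a schedule with a practice prefix the encoding is
#' stationary over the main experiment: every repeating trial is encoded with
#' one four-gram, every novel trial with four uni-grams.
#'
#' @param schedule A \code{\link{build_schedule}} data.frame.
#' @param inventory Chunk inventory.
#' @param eta Per-link probability.
#' @param min_occurrences Recurrence licensing threshold
#'   (see \code{\link{fit_optimal_model}}).
#' @return Object of class "sequential_chunk_fit": list with \code{trials}
#'   (data.frame trial_index/segment/sequence/condition/n_chunks/codes),
#'   \code{encodings} (per-trial character vectors of position-anchored codes
#'   "chunk@start"), \code{evidence} (per-trial log evidence) and
#'   \code{final_model}.
#' @export
sequential_optimal_models <- function(schedule, inventory = build_inventory(),
                                      eta = 0.1, min_occurrences = 3) {
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1)
  seqs <- schedule$sequence
  encodings <- vector("list", length(seqs))
  n_chunks <- integer(length(seqs))
  evid <- numeric(length(seqs))
  model <- NULL
  for (t in seq_along(seqs)) {
    model <- fit_optimal_model(seqs[seq_len(t)], inventory, eta,
                               min_occurrences)
    a <- model$assignments[[seqs[t]]]
    starts <- vapply(parse_spans(a$parse), `[[`, integer(1), 1L)
    encodings[[t]] <- paste0(a$chunks, "@", starts)
    n_chunks[t] <- length(a$parse)
    evid[t] <- attr(model, "evidence")$log_total
  }
  trials <- data.frame(
    trial_index = schedule$trial_index, segment = schedule$segment,
    sequence = seqs, condition = schedule$condition, n_chunks = n_chunks,
    codes = vapply(encodings, paste, character(1), collapse = ";"),
    log_evidence = evid)
  structure(list(trials = trials, encodings = encodings,
                 final_model = model),
            class = "sequential_chunk_fit")
}

#' @export
print.sequential_chunk_fit <- function(x, ...) {
  cat("sequential chunk fit over", nrow(x$trials), "trials; final model:\n")
  print(x$final_model)
  invisible(x)
}

#' Stationary chunk encodings for a designed schedule
#'
#' Shortcut for the designed experiment, where the optimal model is the same
#' on every main trial: repeating trials are encoded as one four-gram
#' anchored at position 1, novel trials as four uni-grams at their positions.
#' \code{\link{sequential_optimal_models}} recovers the same encodings by
#' explicit per-trial inference.
#'
#' @param schedule Schedule data.frame (main trials are used).
#' @return List of per-main-trial code vectors ("chunk@start").
#' @export
stationary_encodings <- function(schedule) {
  main <- schedule[schedule$segment == "main", , drop = FALSE]
  lapply(seq_len(nrow(main)), function(i) {
    s <- main$sequence[i]
    if (main$condition[i] == "repeating") paste0(s, "@1") else
      paste0(seq_items(s), "@", seq_len(nchar(s)))
  })
}

#' Chunk-code RDM over the main trials of a schedule
#'
#' Trial dissimilarity is position-anchored and max-normalised:
#' d(i, j) = 1 - |shared (chunk, start) codes| / max(|codes_i|, |codes_j|).
#' This degenerates to Hamming/L between novel trials (uni-gram codes at
#' matching positions), 0 between repeats of the same repeating sequence, and
#' 1 between a repeating and any novel trial (the design guarantees no shared
#' codes across conditions).
#'
#' @param schedule Schedule data.frame.
#' @param encodings Per-main-trial code vectors; default
#'   \code{\link{stationary_encodings}}. A "sequential_chunk_fit" may also be
#'   given (its main-trial encodings are used).
#' @return An \code{\link{rdm}} labelled by trial sequence.
#' @export
chunk_rdm <- function(schedule, encodings = NULL) {
  main <- schedule[schedule$segment == "main", , drop = FALSE]
  if (is.null(encodings)) {
    encodings <- stationary_encodings(schedule)
  } else if (inherits(encodings, "sequential_chunk_fit")) {
    encodings <- encodings$encodings[schedule$segment == "main"]
  }
  stopifnot(length(encodings) == nrow(main))
  m <- nrow(main)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    shared <- length(intersect(encodings[[i]], encodings[[j]]))
    d[i, j] <- d[j, i] <-
      1 - shared / max(length(encodings[[i]]), length(encodings[[j]]))
  }
  rdm(d, labels = main$sequence)
}

#' Write / read a chunk model as JSON
#'
#' @param model A \code{\link{chunk_model}}.
#' @param path File path.
#' @export
write_chunk_model <- function(model, path) {
  stopifnot(inherits(model, "chunk_model"))
  jsonlite::write_json(list(
    chunks = model$chunks,
    eta = model$eta,
    alpha = model$inventory$alpha,
    assignments = lapply(model$assignments, function(a)
      list(parse = a$parse, chunks = a$chunks))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chunk_model
#' @export
read_chunk_model <- function(path, inventory = build_inventory()) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignments <- lapply(x$assignments, function(a)
    list(parse = as.integer(a$parse)))
  chunk_model(unlist(x$chunks), assignments, eta = x$eta,
              inventory = inventory)
}
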