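# Shared fixtures: one designed experiment, built once per test session.
# All fixtures are generated in code under fixed seeds; nothing is stored.

.fixtures <- new.env(parent = emptyenv())

test_design <- function() {
  if (is.null(.fixtures$design))
    .fixtures$design <- monte_carlo_search(n_samples = 500, seed = 42)
  .fixtures$design
}

test_schedule <- function() {
  if (is.null(.fixtures$schedule)) {
    d <- test_design()
    .fixtures$schedule <- build_schedule(d$sequences, d$repeating, seed = 7)
  }
  .fixtures$schedule
}

# All 24 distinct-item permutations of the default alphabet
all_perms <- function() enumerate_space(allow_repeats = FALSE)

# Independent brute-force evidence oracle: recomputes Eqs-level quantities
# (priors from the factorial form, eta^F mappings) without touching the
# package's inventory/evidence code paths.
oracle_evidence <- function(chunks, parses_per_seq, seqs, eta, n_items = 4) {
  prior <- function(gram) {
    k <- nchar(gram)
    (1 / 4) * factorial(n_items - k) / factorial(n_items)
  }
  code <- prod(vapply(unique(chunks), prior, numeric(1)))
  enc <- prod(vapply(seqs, function(s) eta^length(parses_per_seq[[s]]),
                     numeric(1)))
  log(code) + log(enc)
}
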