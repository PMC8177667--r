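---
title: "Sequence recoding, chunk evidence and pattern-similarity analysis with seqchunk"
author: "seqchunk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence recoding, chunk evidence and pattern-similarity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqchunk)
```

`seqchunk` contrasts two accounts of how the brain learns short visual
sequences. Under *associative learning*, a sequence is a bundle of
item–position (or item–item) associations whose weights sharpen with
repetition: the code stays, the noise drops. Under *recoding*, repetition
leads an ideal learner to re-express the sequence with new latent codes —
chunks — so that a practised four-item sequence becomes a single unit.
The two accounts agree about novel sequences and disagree about the
similarity between novel and practised ones, which is what representational
similarity analysis (RSA) of trial-wise voxel patterns can measure. This
vignette documents the models as implemented, the parameters that matter,
the design decisions taken where the problem was genuinely open, and the
limits of what the synthetic cohorts can establish.

## Sequence representation models

Sequences are permutations of a small alphabet (default four items,
`A`–`D`, standing for four Gabor orientations), serialised as strings such
as `"ABCD"`; positions are 1-based.

**Item–position (Hamming).** `hamming_distance()` counts mismatched
positions. `"ABCD"` vs `"CBAD"` share `B@2` and `D@4`, so their distance
is 2 of a possible 4.

**Item–item (n-gram).** `ngram_distance()` compares the sets of adjacent
n-grams: `d = 1 − γ·|common n-grams|` with `γ = 1/(k − n + 1)`. With
bi-grams, `"FBI"` and `"BIN"` share `BI` and sit at distance 0.5 despite
sharing no item–position association — the two models make inversely
correlated predictions over the 24 permutations, which is what lets RSA
dissociate them. Two conventions are worth stating. First, common members
are counted by *multiset* intersection; for permutations this equals plain
set intersection, but it preserves the identity `d(s, s) = 0` on
repeated-item sequences of the 256-sequence enumeration space. Second, the
defining count is of *common* members (an intersection), not a union: the
normalisation by the number of n-grams per sequence only yields distances
in [0, 1] under the intersection reading.

**Item mixture (control).** A non-sequence account: the pattern is a
palimpsest of item representations weighted along the sequence,
`M = I β`. Item representations are fixed orthonormal axes — one
coordinate per alphabet symbol — so a mixture vector is just the per-item
sum of mixing coefficients, and distances depend only on the coefficient
profile and item placement. Only the recency profile is implemented, with
the linear ramp `β = (0, 1/6, 1/3, 1/2)` as default: distances depend only
on the absolute slope (a primacy ramp of equal magnitude gives the same
RDM), a flat profile makes all mixtures identical (degenerate, rejected at
distance time), and a vertical one reduces to the last item alone. The
ramp is the midpoint between those extremes. `β₁ = 0` is accepted even
though a strictly positive coefficient would be tidier formally — the
canonical printed values take precedence.

**Association learning.** `association_counts()` /
`association_weights()` implement the Dirichlet–multinomial bookkeeping:
counts of item–position occurrences, normalised per item row into weights
μ. Rows with no observations are reported as all-zero and flagged rather
than silently made uniform, keeping the estimator purely empirical; a
Dirichlet pseudo-count argument provides the conjugate-prior behaviour
when wanted (default 0). From `{BACD, CABD, ABCD}`, μ(A, 2) = 2/3.

## The chunking model and its evidence

A chunking model is a pair (x, z): a set of chunks (n-grams with no
repeated item; 64 possible entries for a four-item alphabet) and one parse
per encoded sequence. Its evidence decomposes into:

- a **code term**: each chunk's prior is inversely proportional to the
  number of partial permutations of its length, `p(c) = α (n−k)!/n!`. The
  normaliser α is fixed by summing over the whole inventory; each length
  class carries equal mass, so α = 1/L (= 1/4 here), giving uni-grams
  prior 1/16 and bi-grams 1/48 — the 3:1 ratio that makes simple chunks
  cheaper. The chunk set is paid for once.
- an **encoding term**: a parse with F spans costs `η^F`, paid on every
  presentation. η is "the reciprocal of the number of possible links"; the
  exact denominator is ambiguous (spans? parses? positions?), so η is a
  parameter, default 1/10 = one over the number of distinct contiguous
  spans of a four-item sequence. The model rankings the package asserts
  are verified in the tests for η ∈ {1/4, 1/8, 1/10}.

`enumerate_parses()` lists the 2^(L−1) = 8 parses of a four-item sequence;
`model_evidence()` checks that every assignment reproduces its sequence
exactly before scoring.

### Why the optimal fit needs a recurrence rule

Raw evidence maximisation has a degenerate preference: for a sequence seen
once, one dedicated four-gram (code `log 1/96`, one link) always beats
four uni-grams (code `4·log 1/16`, four links) — the uni-gram encoding
would need `3·log η > log 96`, impossible for η ≤ 1. Left unchecked, the
"optimal" learner would memorise every novel stimulus as a private chunk,
and recoding would be indistinguishable from storage. The recoding premise
is that chunks are inferred from *recurring* co-occurrence, so
`fit_optimal_model()` licenses multi-item chunks only for sequences
presented at least `min_occurrences` times (default 3). Novel sequences
(seen once or twice) are therefore always uni-gram coded; practised
sequences, licensed many times over, are chunked. With this rule the
sequential fit is exactly stationary on the designed schedule — every
repeating trial one four-gram, every novel trial four uni-grams — and
the practice-set fit returns the two four-grams alone, with the four
uni-grams joining at the first novel trial. The threshold of 3 is the
smallest count that separates "recurring" from the twice-per-experiment
exposure a novel sequence can reach; the model-recovery tests plant chunk
structure at exactly three repetitions and recover it.

The three fixed reference models (1-gram-only, 2-gram-only, 4-gram-only)
deliberately do *not* carry the licensing rule — the 4-gram reference
model chunk-encodes everything it sees, which is what makes it a useful
foil. After twelve practice repetitions of each repeating sequence the
4-gram model outranks the 2-gram and 1-gram models, at every η tested.
Note that refit evidence can *increase* at the trial where licensing first
applies (the candidate space grows); for a fixed model, appending
presentations never raises evidence, and once encodings are stationary the
refit evidence strictly decreases — both are tested.

### The chunk RDM

Trial-level chunk dissimilarity is position-anchored and max-normalised:
`d(i, j) = 1 − |shared (chunk, start) codes| / max(|codes_i|, |codes_j|)`.
This single formula degenerates to the three regimes the model predicts:
0 between repetitions of the same practised sequence, 1 between any
repeating and any novel trial (the design guarantees no shared codes
across conditions), and Hamming/4 between novel trials, where the
uni-gram codes coincide with item–position codes. That last regime is the
crux of the analysis: novel trials look identical under the chunk and
item–position models, and only the cross-condition cells separate the
accounts.

## Design generation

Two hard constraints govern the 14-sequence set: the two repeating
sequences must share no item at a common position and no common n-gram of
length > 1 (so their only efficient joint encoding is two distinct
four-grams), and sequences must be well separated in Hamming space
(threshold 3 by default).

A feasibility point the implementation has to face: *the separation
criterion cannot hold between all pairs of 14 permutations of four
items.* A Hamming distance of 2 between permutations corresponds to a
transposition, which flips permutation parity; the "too-close" graph is
therefore bipartite between the 12 even and 12 odd permutations, and a
mutually-≥3 set can contain at most one parity class — 12 sequences. (The
test suite verifies the maximum independent set size with igraph.)
Moreover an admissible repeating pair related by a four-cycle leaves only
10 permutations at distance ≥3 from both, while a pair related by a
double transposition leaves exactly 12 — just enough for the unique
slots. The default constraint scope therefore applies the threshold to
every pair involving a repeating sequence (scope `"repeating"`), which is
satisfiable, and leaves unique–unique separation to the search objective;
scope `"all"` implements the literal criterion and makes
`monte_carlo_search()` fail explicitly. Because the compatible unique set
is essentially forced by the pair, the search samples the repeating pair
first and fills the unique slots from the compatible permutations —
uniform sampling of 14-subsets would practically never pass.

Passing sets are ranked by the entropy of the 91 pairwise distances
(maximised; Hamming distances are discrete so the plug-in entropy over
observed values needs no binning, natural log) with the Pearson
correlation between the item–position and item–item RDMs as tie-breaker
(driven toward zero to keep the models dissociable). A 14×14 similarity
matrix has (196 − 14)/2 = 91 informative lower-triangle cells; the package
uses 91 throughout.

`build_schedule()` then produces the practice prefix (each repeating
sequence 12 times, shuffled) and two 36-trial runs in sub-blocks of three
(one novel + two repeating, shuffled; each repeating sequence balanced to
12 per run, each unique once per run). A quarter of main trials drop the
response cue, assigned uniformly at random; phase timings (2.4 s per item,
4.8 s delay, 7.2 s response) ride along as schedule metadata only.

## RSA, ceilings and group inference

Pattern dissimilarity is the correlation distance: `1 − r` of the
mean-centred patterns (each pattern centred by its own scalar mean). It is invariant to per-pattern
shifts and positive scalings — note this is *not* invariance to adding a
shared per-voxel offset vector, which changes row-wise correlations.
Model fit is Spearman's rank correlation over lower-triangle cells
(average ranks for ties — consequential, since the Hamming model takes at
most five distinct values), with condition-pair masks
(`rdm_mask()`): within-novel, novel×repeating, and so on. Same-sequence
repeat pairs (distance-0 cells) are included by default, per the all-pairs
definition of the pattern RDM; a switch excludes them, since their
inclusion is genuinely underdetermined for the model-fit step.

Noise ceilings: upper = mean Spearman of each subject's RDM with the
group-mean RDM (with-self, hence slightly optimistic — for pure noise it
still sits near 1/√n); lower = the same against the leave-one-out mean.
Ceiling positivity is a one-sided t-test on Fisher-transformed
correlations at 0.05 / (number of regions).

Group significance follows the permutation-plus-bootstrap scheme: trial
labels are shuffled within subject (a joint row/column permutation of the
data RDM, within condition when a schedule is supplied, so masked
condition cells keep their meaning), the true-label score joins each
subject's permuted distribution, and `10/α` group means are resampled (one
value per subject, with replacement); the p-value is the observed group
mean's position in that distribution, floored at the resolution. At the
study's corrected threshold α ≈ 10⁻⁴ this costs 10⁵ resamples; tests run
at reduced α and permutation counts to stay inside their time budget, and
the calibration test confirms the rejection rate stays at the nominal
level under a null generator.

The cross-condition analysis computes r_U (within-novel cells) and r_UR
(novel×repeating cells) for the item–position model and classifies the
outcome: no significant r_UR (repeating trials do not carry the novel
code; the noise comparison is meaningless), significant with r_UR < r_U
(repeating noisier), or significant with r_UR > r_U (repeating less noisy
— the associative prediction). One quantitative caveat the synthetic
experiments exposed: the design constraint compresses novel×repeating
Hamming cells to the values {3, 4}, so a mild noise reduction moves r_UR
very little; the associative scenario in the recovery experiment uses a
four-fold SD reduction (learning to criterion) to make its predicted
ordering visible.

## Model-free distance trajectories

`build_series()` implements the four cosine-distance trajectories
(between the two repeating sequences by repetition; within each repeating
sequence across consecutive repetitions; repeating vs the run's novel
patterns; consecutive novel trials), and `slope_test()` fits per-subject
OLS slopes and a two-sided group t-test at 0.05 / (number of regions).
Cosine distance — not correlation distance — is used here deliberately;
the two live in one module each under distinct names. Repetition is
indexed within run by default (12 points per run, slopes averaged across
runs); an across-experiment option exists, since the original analysis is
ambiguous on this point.

## Interference and capacity

Over the 256-sequence repeats-allowed space, shared-code histograms are
exact enumerations: a distinct-item reference shares exactly k
item–position codes with C(4, k)·3^(4−k) sequences — 54/256 (21%) at
k = 2, 12/256 (≈5%) at k = 3, 81/256 at k = 0 (31% after truncation).
The reference itself is included in the denominator (the k = 4 bin is
1/256); an exclusion switch exists, and the printed percentages survive
either choice after rounding. Capacity curves learn sequences uniformly
without replacement and report the mean proportion of the space unaffected
(sharing no code with anything learned). Learned sequences count as
affected and the denominator stays at the space size, which makes the
unaffected proportion non-increasing replicate by replicate — with an
"other sequences only" denominator the proportion can tick upward as the
denominator shrinks. The item–position store saturates by about five
learned sequences; the bi-gram chunk code stays above it at every step.
"About five" is a property of the random-learning-order ensemble, not an
exact constant, and is tested as such.

## The synthetic cohort generator

`simulate_cohort()` realises the additive model A = S + ν that the
analyses assume: a trial's pattern is the sum of its code vectors (item
at-position codes, chunk codes, or β-weighted item codes) times
`code_scale`, plus i.i.d. Gaussian noise with a per-condition SD. Code
vectors are independent N(0, 1) draws per subject — subjects share the
representational geometry, not the patterns — so the expected squared
distance between trials is proportional to the number of non-shared codes
(tested against the closed form), and the noiseless pattern RDM
rank-matches the generating model exactly.

Parameter defaults, chosen once: 200 voxels; noise SD 8 for both
conditions, calibrated so a 22-subject item-position cohort lands its
lower noise ceiling around 0.2 (the "moderate noise" regime in which model
recovery is demanded to succeed); `code_scale` 1. The associative
scenario lowers the repeating-condition SD four-fold, as discussed above.
All randomness flows from a single seed through R's stream, so a cohort
is reproducible from its provenance record.

What a green synthetic test does *not* establish: the generator has no
hemodynamics, no autocorrelated scanner noise, no trial-estimation (LS-S)
leakage, no between-region structure, and additive code superposition is
itself an assumption — real voxel patterns need not sum their codes. The
synthetic results validate the *pipeline* (that each analysis detects the
structure it is meant to detect and stays calibrated under the null), not
any empirical claim about cortex.

## Numerical conventions and edge cases

- Sequences serialise as contiguous symbol strings; positions are 1-based.
- Degenerate inputs fail loudly: constant vectors in correlation distance,
  zero-norm vectors in cosine distance, flat mixture profiles, parses that
  do not reproduce their sequence. Constant pattern rows yield NA RDM
  cells with a warning; NA cells are dropped pairwise before ranking.
- Evidence ties in the optimal-model search break toward fewer chunks,
  then lexicographically, so fits are deterministic.
- Spearman ties use average ranks; permutation p-values are floored at
  their resolution (never exactly zero).
- The exhaustive parse-combination search switches to greedy coordinate
  ascent beyond five recurring sequences; the designed experiment has two.

## Known limitations

- The optimal-model candidate space follows the main-text description
  (parse-induced chunk sets, one parse per distinct sequence); richer
  chunk inventories (e.g. chunks spanning different sequences' fragments)
  are out of scope, as are posterior-sampling schemes over chunkings.
- η's denominator is a modelling choice; conclusions are checked for
  robustness over {1/4, 1/8, 1/10} rather than derived.
- Short-term-memory limits on mapping length (relevant for L > 4) are not
  modelled; sequences longer than the alphabet cannot be chunk-encoded
  under the no-repeat rule.
- No neuroimaging-volume I/O, no GLM/LS-S estimation, no searchlight or
  whole-brain maps: region patterns arrive pre-extracted.
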