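---
title: "Exact-span NER evaluation and benchmarking: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact-span NER evaluation and benchmarking: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerbench)
```

# Scope and data model

`nerbench` evaluates span-level named-entity predictions against an
expert-curated gold standard on collections of identified documents, each a
title/abstract pair. The package works with four value types: a **corpus**
(documents), an **annotation set** (gold or curated mentions), a
**prediction run** (one system submission), and the derived results
(match partitions, scores, bootstrap tables, leaderboards). Everything is
plain-text TSV on disk and base-R data frames in memory.

A mention is `(doc_id, section, start, end, text, class, provenance)`. Two
invariants are enforced everywhere, because every downstream statistic
silently depends on them:

* **slice fidelity** — the stored surface text must equal the code-point
  slice `[start, end)` of the addressed section. A violation almost always
  means an offset-convention bug (1-based input, byte offsets, or
  title/abstract confusion), so readers fail loudly with the offending line.
* **no nesting or overlap** among gold annotations in one section. Classes
  are unique and exclusive, so one character position can belong to at most
  one gold mention; this also makes inline-HTML serialization well defined.
  Predictions, by contrast, may overlap freely — systems emit what they
  emit — and only exact duplicates (same document, section and offsets) are
  collapsed, with a warning.

## Offset and case conventions

Offsets are **0-based, half-open, in Unicode code points**, counted
separately per section. Code points rather than bytes: multi-byte
characters (µ, Greek letters, dashes) are routine in chemical text, and
byte-counting silently shifts every later annotation in a line. The
synthetic generator deliberately salts its filler text with Greek tokens so
that any byte/code-point confusion fails the slice-fidelity check
immediately.

Case-insensitive operations (term grouping, lexicon propagation, batch
operations) use one shared fold: a fixed, **locale-independent,
length-preserving lowercase map** over the ASCII, Latin-1, Greek and
Cyrillic blocks. Locale-dependent lowercasing is not reproducible across
machines, and folds that change string length (e.g. İ → i̇) would corrupt
offset arithmetic; restricting the fold to length-preserving blocks keeps
every folded string alignable with the original. The cost is that exotic
scripts fold to themselves — two Turkish-dotted-capital spellings would not
merge — which is acceptable for the chemical/biomedical text this targets.

# Matching and scores

A prediction is a true positive iff document, section, start and end all
match a gold mention exactly; with `class_strict = TRUE` the class must
match too. **Partial hits get no credit**: an overlapping-but-unequal
prediction is one FP *and* leaves its gold mention an FN. This double
penalty is intentional — exact-span evaluation treats boundary errors as
both a spurious prediction and a miss.

Because gold spans are disjoint and predicted spans are deduplicated, the
matching reduces to key intersection; no confidence or rank tie-breaking
can ever be needed (two predictions can only compete for a gold span by
having identical offsets, which the dedup forbids). Confidence and rank are
still parsed and carried for reporting.

Zero-denominator conventions, chosen so degenerate inputs behave sensibly:
precision is 1 when there are no predictions *and* no gold (perfect
agreement on emptiness) and 0 when predictions are empty against non-empty
gold; symmetrically for recall; F is 0 whenever precision + recall is 0.
These only matter per-document inside the macro average, where empty
documents are common.

**Macro scope.** The macro average runs over documents with at least one
gold annotation. Without this restriction, an unannotated document in which
a system predicts nothing would contribute a perfect score, and the mean
would be dominated by how many empty documents the corpus happens to carry.
Predictions falling in out-of-scope documents still count as micro FPs, and
`macro_scores()` flags their number in an attribute so the discrepancy is
visible.

**Mismatch analytics.** Term tables group FN/FP surface strings by the
case fold, rank by count with a lexicographic tie-break, and display the
most frequent original casing. Document tables rank by mismatch count with
a doc_id tie-break, suppressing zero rows. Cross-run tables average counts
over runs and rank on the unrounded average (display rounding must not
reorder entries).

# Bootstrap benchmarking

Teams submit up to five runs; each team's best run by micro F (ties to the
lower run number) enters the benchmark. Variability is estimated by a
document-level bootstrap with `n_samples = 2500` by default:

* the **sampling frame** is the set of annotated documents, mirroring the
  evaluation scope of the macro average;
* each sample draws `n` documents from the frame with replacement, and a
  document drawn twice contributes its per-document TP/FP/FN twice — the
  standard multinomial bootstrap;
* **all teams are scored on the same samples** (one shared seeded RNG
  stream produces a single draw matrix), so between-team comparisons are
  paired; `keep_draws = TRUE` retains the draw matrix for auditing;
* the reported SD is the sample standard deviation (n−1) of the 2500
  resampled micro F values.

The `observed_f` in the bootstrap table is the micro F over the sampling
frame, so the mean of the resampled scores converges to it by construction.
A system's leaderboard F (from `make_leaderboard()` / `place_new_run()`)
is the full-corpus micro F, which additionally counts FPs in unannotated
documents; on corpora where every document is annotated the two coincide.

**Significance grouping** uses an adjacent-chain rule: walking the ranking
top-down, consecutive teams stay in one group while their F gap is at most
`k_sd · max(sd_i, sd_j)`, with `k_sd = 2` by default. The chain rule is
deterministic, transitive in its displayed groups, and has the right
limits (`k_sd = 0` separates every distinct score; `k_sd = ∞` merges all).
Other readings of "grouped at two SD" exist — e.g. comparing every team to
its group's best — and the multiplier is configurable for that reason.

**Post-workshop placement** inserts a new system into a stored leaderboard
by F, stably after any tied entry, *without* recomputing stored entries
(the original submissions are not redistributable). Leaderboard files
carry an MD5 fingerprint of the canonical gold export; placement refuses a
gold standard whose fingerprint differs, because scores computed on
different gold sets are not comparable.

# Annotation propagation

The semi-automatic curation loop: build a lexicon from the manual
annotations (one entry per case-folded form, with class frequencies and a
display casing), scan every section for unlabelled exact case-insensitive
occurrences, have the curator delete or edit unwanted suggestions, and
implicitly accept the rest (`finalize_annotations()` marks them
`accepted`). The cycle is a fixed point: re-running the propagation on the
finalized set with the same lexicon suggests nothing.

Resolution rules, all deterministic:

* occurrences overlapping an existing annotation are skipped (nesting is
  forbidden);
* competing candidates are resolved greedily, longest form first, then
  leftmost — so "acetylsalicylic acid" beats its substring "acid" where
  they collide, and the outcome is independent of lexicon insertion order;
* a form annotated with several classes propagates its majority class,
  ties broken by the most recent contributing annotation in input order
  (classes are exclusive, so one must be chosen);
* `boundary = "word"` (default) requires matches to abut non-word
  characters or edges. The guidelines allow partial-word gold annotations,
  but *propagating* into substrings ("acid" inside "acidic") mass-produces
  noise, so word boundaries gate the automatic step only; `boundary =
  "none"` is available and is what the brute-force completeness tests
  exercise.

# The synthetic benchmark

`generate_corpus()` builds documents from whitespace-joined filler tokens
with vocabulary mentions embedded at recorded offsets, so the gold standard
is correct by construction. Defaults: 50 documents, 2–6 mentions each from
a five-class chemical-flavoured vocabulary, ~30 filler tokens per abstract,
Greek-salted filler. `degrade_to_predictions()` then applies the three
error mechanisms of exact-span evaluation — drops (`fn_rate`), one-point
boundary shifts (`shift_rate`, re-rolled so a shifted span never equals any
gold span), and Poisson spurious spans (`fp_rate`) — and
`expected_counts()` gives the closed-form expectations

```
TP = G(1 − fn)(1 − shift),  FN = G − TP,  FP = G(1 − fn)·shift + D·fp
```

against which observed micro statistics converge within binomial/Poisson
sampling error.

What the generator does **not** emulate: real patent language, chemical
name morphology, realistic class priors, inter-annotator disagreement, or
correlated system errors. Passing tests therefore demonstrate that the
*accounting* — offsets, matching, averaging, resampling — is correct, not
that any particular NER system performs well on real text.

Problem sizes used by the tests and the acceptance script are chosen to
make sampling error small relative to the tolerances: 1000 gold mentions
(200 documents × 5) for rate-recovery checks, ≤3-document corpora for
exhaustive bootstrap enumeration (27 ordered resamples), 2500 bootstrap
samples for SD estimates, and 10 000 where an empirical distribution is
compared to an exact one. The distribution comparison uses the multinomial
chi-squared goodness-of-fit test at the 3σ significance level, the joint
analogue of a per-value 3σ band.

# Known limitations

* The TSV dialects are a reconstruction of challenge-era exchange formats
  and are isolated in the I/O layer; a dialect change touches only
  readers/writers.
* The case fold covers ASCII, Latin-1, Greek and Cyrillic; other scripts
  compare byte-exactly.
* Significance grouping is one defensible reading of "grouped at two SD";
  the rule and multiplier are documented and configurable rather than
  canonical.
* No overlap-based or partial-credit scoring schemes, no
  confidence-threshold sweeps, and no recomputation of stored leaderboard
  entries.
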