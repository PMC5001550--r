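# nerbench

Exact-span evaluation, bootstrap benchmarking and annotation propagation for
span-level named-entity recognition (NER) on title/abstract document
collections — the batch tooling behind community challenge evaluations of
chemical and gene/protein mention recognition in patent corpora.

## Who this is for

Three kinds of users, mirroring the roles in a shared-task setting:

* **organizers / curators** building a gold standard: stand-off TSV and
  inline-HTML import/export, strict invariant checking (no nested or
  overlapping annotations, slice/offset fidelity), dictionary-based
  propagation of manual annotations with curator revision and implicit
  acceptance, and batch retype/delete operations;
* **system developers** analysing their predictions: exact-span matching
  with micro/macro precision–recall–F and a full mismatch report (per-class
  TP/FN distribution, top false-negative and false-positive terms, the
  documents with most mismatches, cross-run averages);
* **benchmark maintainers** ranking systems: best-run selection per team,
  document-level bootstrap resampling of the F-score, significance grouping
  at two standard deviations, and post-workshop placement of a new system
  into a stored leaderboard.

## The statistics at the core

A predicted mention is a **true positive** only when its document, section
(title `T` or abstract `A`), start and end offsets all equal a gold
annotation; *partial hits* — predictions that only in part overlap a gold
span — receive no credit and count as one false positive while the gold
mention stays a false negative. From the pooled counts,

```
recall    = TP / (TP + FN)
precision = TP / (TP + FP)
F         = 2 · precision · recall / (precision + recall)
```

**Micro** averages pool TP/FP/FN globally; **macro** averages compute the
three statistics per document and take the unweighted mean over the
documents that carry gold annotations.

Score variability is estimated by **bootstrap resampling**: 2500 samples of
the annotated documents drawn with replacement, every system scored on the
same samples, and the sample standard deviation of each system's resampled
micro F reported as its SD. Ranked systems whose F gap is within twice the
larger of the two SDs fall in the same significance group.

Offsets are 0-based, half-open, and counted in Unicode code points per
section. All case-insensitive operations use a fixed, locale-independent,
length-preserving fold.

## Worked example

```r
library(nerbench)

gen <- generate_corpus(synth_spec(n_docs = 50, seed = 42))
run <- degrade_to_predictions(gen$gold, gen$corpus,
                              degrade_spec(fn_rate = 0.15, fp_rate = 0.5,
                                           shift_rate = 0.05, seed = 43),
                              team_id = "sysA")
prediction_report(gen$gold, run, k = 3)
```

```
Prediction analysis — team sysA, run 1
counts: TP=141 FP=37 FN=40
micro-averaged: precision 0.7921  recall 0.7790  F-score 0.7855
macro-averaged: precision 0.8137  recall 0.7917  F-score 0.7832  (over 50 documents)

TP/FN distribution per annotation class:
         class tp fn
    SYSTEMATIC 22  6
       TRIVIAL 35  7
        FAMILY 30  7
       FORMULA 27  9
 ABBREVIATIONS 27 11

Top false negatives (terms):
  term count
  DMSO     7
 CaCO3     3
  EDTA     3
...
```

The corpus embeds 1000s of characters of filler around 181 gold mentions;
the degradation dropped 15% of them (the missing recall), shifted 5% of the
survivors by one code point (each scored as one FP *and* one FN — no partial
credit), and added Poisson(0.5) spurious spans per document (the missing
precision). Bootstrapping the run:

```r
bootstrap_fscores(gen$gold, list(sysA = run), n_samples = 2500, seed = 44)
#  rank team_id run_id observed_f     sd group
#     1    sysA      1     0.7855 0.0223     1
```

The SD of 0.022 says two systems this size need an F gap above ≈0.045 to be
separated at two SDs.

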