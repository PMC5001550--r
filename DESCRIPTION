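Package: nerbench
Title: Exact-Span Entity-Recognition Evaluation, Bootstrap Benchmarking and
    Annotation Propagation for Stand-Off Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Batch toolkit for curating and scoring span-level named-entity
    annotations on title/abstract document collections in challenge-style
    tab-separated stand-off formats. Reads and validates document, gold-standard
    and ranked prediction files; scores prediction runs by exact span matching
    with micro- and macro-averaged precision, recall and F-score and full
    mismatch analytics (per-class true-positive/false-negative distributions,
    top false-positive and false-negative terms and documents, cross-run
    averages); estimates F-score variability by document-level bootstrap
    resampling with significance grouping at a configurable number of standard
    deviations, and places new systems into a stored leaderboard; propagates
    manual annotations to unlabelled exact case-insensitive matches with
    curator revision and batch operations; and generates deterministic
    synthetic corpora and degraded prediction runs with known error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
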