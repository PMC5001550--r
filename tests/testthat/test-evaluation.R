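# Exact-span matching and the prediction-analysis report.

test_that("exact matching partitions into TP/FP/FN with partial-hit exclusion", {
  corp <- tiny_corpus()
  gold <- tiny_gold(corp)

  # identity
  m <- match_run(gold, pred_from_gold(gold))
  expect_equal(nrow(m$tp), 5L)
  expect_equal(nrow(m$fp), 0L)
  expect_equal(nrow(m$fn), 0L)

  # a boundary off by one is no credit: one FP and one FN
  p <- mentions_df("D1", "A", 10L, 16L, "aspiri", "TRIVIAL")
  m2 <- match_run(annotation_set(mentions_df("D1", "A", 10L, 17L, "aspirin",
                                             "TRIVIAL"), task = "CEMP",
                                 corpus = corp),
                  prediction_run(p))
  expect_equal(c(nrow(m2$tp), nrow(m2$fp), nrow(m2$fn)), c(0L, 1L, 1L))

  # wrong section is a miss even with identical offsets
  g3 <- annotation_set(mentions_df("D3", "T", 0L, 4L, "Form", "TRIVIAL"),
                       task = "CEMP", corpus = corp)
  m3 <- match_run(g3, prediction_run(mentions_df("D3", "A", 0L, 4L, "NaCl",
                                                 provenance = "predicted")))
  expect_equal(c(nrow(m3$tp), nrow(m3$fp), nrow(m3$fn)), c(0L, 1L, 1L))
})

test_that("class-strict matching requires the class to agree", {
  corp <- tiny_corpus()
  gold <- tiny_gold(corp)
  p <- gold$mentions
  p$class[1] <- "FORMULA"  # right span, wrong class
  run <- prediction_run(p)
  lax <- match_run(gold, run, class_strict = FALSE)
  strict <- match_run(gold, run, class_strict = TRUE)
  expect_equal(nrow(lax$tp), 5L)
  expect_equal(nrow(strict$tp), 4L)
  expect_lte(nrow(strict$tp), nrow(lax$tp))
  expect_equal(c(nrow(strict$fp), nrow(strict$fn)), c(1L, 1L))
})

test_that("micro scores follow the defining equations with zero conventions", {
  s <- micro_scores(c(tp = 8, fp = 2, fn = 2))
  expect_equal(s$precision, 0.8)
  expect_equal(s$recall, 0.8)
  expect_equal(s$fscore, 0.8)

  z <- micro_scores(c(tp = 0, fp = 5, fn = 5))
  expect_equal(c(z$precision, z$recall, z$fscore), c(0, 0, 0))

  perfect <- micro_scores(c(tp = 3, fp = 0, fn = 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$fscore), c(1, 1, 1))

  both_empty <- micro_scores(c(tp = 0, fp = 0, fn = 0))
  expect_equal(both_empty$precision, 1)
  expect_equal(both_empty$recall, 1)

  empty_pred <- micro_scores(c(tp = 0, fp = 0, fn = 4))
  expect_equal(empty_pred$precision, 0)
  expect_equal(empty_pred$recall, 0)
})

test_that("micro scores match the equation oracle on random count triples", {
  set.seed(42)
  for (i in 1:250) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    got <- micro_scores(c(tp = tp, fp = fp, fn = fn))
    exp <- oracle_micro(tp, fp, fn)
    expect_equal(got$precision, exp[["precision"]], tolerance = 1e-12)
    expect_equal(got$recall, exp[["recall"]], tolerance = 1e-12)
    expect_equal(got$fscore, exp[["fscore"]], tolerance = 1e-12)
    # F bounds
    expect_lte(got$fscore, max(got$precision, got$recall) + 1e-12)
    expect_gte(got$fscore, min(got$precision, got$recall) - 1e-12)
    expect_equal(got$fscore == 0, tp == 0)
  }
})

test_that("conservation and monotonicity hold on randomized fixtures", {
  gen <- generate_corpus(synth_spec(n_docs = 15, seed = 11))
  for (s in 1:5) {
    run <- degrade_to_predictions(gen$gold, gen$corpus,
                                  degrade_spec(fn_rate = 0.3, fp_rate = 1,
                                               shift_rate = 0.2, seed = s))
    m <- match_run(gen$gold, run)
    expect_equal(nrow(m$tp) + nrow(m$fn), nrow(gen$gold$mentions))
    expect_equal(nrow(m$tp) + nrow(m$fp), nrow(run$mentions))
    expect_equal(sum(m$per_doc$tp), nrow(m$tp))
    expect_equal(sum(m$per_doc$fp), nrow(m$fp))
    expect_equal(sum(m$per_doc$fn), nrow(m$fn))

    sc <- micro_scores(m)
    # adding a correct prediction never decreases recall
    if (nrow(m$fn)) {
      extra <- rbind(run$mentions, m$fn[1, , drop = FALSE])
      sc2 <- micro_scores(match_run(gen$gold, prediction_run(extra)))
      expect_gte(sc2$recall, sc$recall)
      # adding a spurious prediction never increases precision
      spur <- m$fn[1, , drop = FALSE]
      spur$start <- spur$start + 1L; spur$text <- NA_character_
      if (!any(gen$gold$mentions$doc_id == spur$doc_id &
               gen$gold$mentions$start == spur$start &
               gen$gold$mentions$end == spur$end)) {
        sc3 <- micro_scores(match_run(gen$gold,
                                      prediction_run(rbind(run$mentions, spur))))
        expect_lte(sc3$precision, sc$precision)
      }
    }
  }
})

test_that("macro averages per-document scores over documents with gold", {
  corp <- corpus(c("D1", "D2"), c("t one", "t two"),
                 c("aspirin here", "caffeine there"))
  gold <- annotation_set(
    mentions_df(c("D1", "D2"), "A", c(0L, 0L), c(7L, 8L),
                c("aspirin", "caffeine"), "TRIVIAL"),
    task = "CEMP", corpus = corp)
  # D1 perfect, D2 entirely missed with one spurious hit -> per-doc F 1 and 0
  run <- prediction_run(mentions_df(c("D1", "D2"), "A", c(0L, 9L), c(7L, 14L),
                                    c("aspirin", "there"),
                                    provenance = "predicted"))
  ma <- macro_scores(gold, run)
  expect_equal(ma$fscore, 0.5)
  expect_equal(ma$n_documents, 2L)

  # pred == gold on one doc: macro == micro == 1
  solo <- annotation_set(gold$mentions[1, ], task = "CEMP", corpus = corp)
  expect_equal(macro_scores(solo, prediction_run(solo$mentions))$fscore, 1)

  # no in-scope documents
  empty_gold <- annotation_set(gold$mentions[0, ], task = "CEMP")
  expect_error(macro_scores(empty_gold, run), "macro undefined")
})

test_that("macro equals a brute-force per-document mean, and equals micro on homogeneous corpora", {
  gen <- generate_corpus(synth_spec(n_docs = 25, seed = 7))
  run <- degrade_to_predictions(gen$gold, gen$corpus,
                                degrade_spec(fn_rate = 0.25, fp_rate = 0.7,
                                             shift_rate = 0.15, seed = 8))
  ma <- macro_scores(gen$gold, run)
  # brute force: split mentions by document, score each in isolation
  docs <- unique(gen$gold$mentions$doc_id)
  per <- sapply(docs, function(d) {
    g <- gen$gold$mentions[gen$gold$mentions$doc_id == d, , drop = FALSE]
    p <- run$mentions[run$mentions$doc_id == d, , drop = FALSE]
    gk <- paste(g$section, g$start, g$end)
    pk <- paste(p$section, p$start, p$end)
    oracle_micro(sum(gk %in% pk), sum(!(pk %in% gk)), sum(!(gk %in% pk)))
  })
  expect_equal(ma$precision, mean(per["precision", ]), tolerance = 1e-12)
  expect_equal(ma$recall, mean(per["recall", ]), tolerance = 1e-12)
  expect_equal(ma$fscore, mean(per["fscore", ]), tolerance = 1e-12)

  # identical per-document counts: macro == micro exactly
  corp <- corpus(paste0("H", 1:4), rep("t", 4),
                 rep("aspirin and caffeine mixed", 4))
  g <- annotation_set(
    mentions_df(rep(paste0("H", 1:4), each = 2), "A",
                rep(c(0L, 12L), 4), rep(c(7L, 20L), 4),
                rep(c("aspirin", "caffeine"), 4), "TRIVIAL"),
    task = "CEMP", corpus = corp)
  pm <- g$mentions[g$mentions$start == 0L, ]  # keep one of two per doc
  hom <- prediction_run(pm)
  expect_equal(macro_scores(g, hom)$fscore,
               micro_scores(match_run(g, hom))$fscore, tolerance = 1e-12)
})

test_that("class distribution partitions gold by class and reproduces totals", {
  corp <- tiny_corpus()
  gold <- tiny_gold(corp)
  run <- prediction_run(gold$mentions[c(1, 3), ])  # 2 TRIVIAL matched
  m <- match_run(gold, run)
  cd <- class_distribution(m, gold)
  expect_equal(cd$class, c("TRIVIAL", "FAMILY", "FORMULA"))  # inventory order
  expect_equal(cd$tp[cd$class == "TRIVIAL"], 2L)
  expect_equal(cd$fn[cd$class == "TRIVIAL"], 1L)
  expect_equal(cd$tp[cd$class == "FORMULA"], 0L)
  expect_equal(sum(cd$tp), nrow(m$tp))
  expect_equal(sum(cd$fn), nrow(m$fn))

  empty <- match_run(annotation_set(gold$mentions[0, ], task = "CEMP"),
                     prediction_run(gold$mentions[0, ]))
  expect_equal(nrow(class_distribution(empty,
                                       annotation_set(gold$mentions[0, ],
                                                      task = "CEMP"))), 0L)
})

test_that("top terms group case-insensitively and break ties lexicographically", {
  corp <- corpus("D1", "t",
                 "alkyl Alkyl acid ester acid ester junk junk junk junk")
  words <- strsplit("alkyl Alkyl acid ester acid ester", " ")[[1]]
  starts <- c(0L, 6L, 12L, 17L, 23L, 28L)
  gold <- annotation_set(
    mentions_df("D1", "A", starts, starts + nchar(words), words, "TRIVIAL"),
    task = "CEMP", corpus = corp)
  m <- match_run(gold, prediction_run(gold$mentions[0, ]))  # all FN
  tt <- top_terms(m, "fn", k = 10)
  expect_equal(tt$term[1:3], c("acid", "alkyl", "ester"))
  expect_equal(tt$count[1:3], c(2L, 2L, 2L))  # acid < alkyl < ester lexicographic
  expect_equal(top_terms(m, "fn", k = 1)$term, "acid")
  # display form is the most frequent casing (tie -> first seen)
  expect_true("alkyl" %in% tt$term)
  empty <- match_run(gold, prediction_run(gold$mentions))
  expect_equal(nrow(top_terms(empty, "fn", 5)), 0L)
})

test_that("top documents rank by mismatch count with doc_id tie-break and suppress zeros", {
  gen <- generate_corpus(synth_spec(n_docs = 10, seed = 2))
  run <- degrade_to_predictions(gen$gold, gen$corpus,
                                degrade_spec(fn_rate = 0.5, seed = 3))
  m <- match_run(gen$gold, run)
  td <- top_documents(m, "fn", k = 100)
  expect_true(all(diff(td$count) <= 0))
  expect_true(all(td$count > 0))
  expect_equal(sum(td$count), nrow(m$fn))
  expect_lte(nrow(top_documents(m, "fn", k = 2)), 2L)
  # tie-break on doc_id within equal counts
  for (cnt in unique(td$count)) {
    ids <- td$doc_id[td$count == cnt]
    expect_equal(ids, sort(ids))
  }
})

test_that("cross-run averages equal totals over runs divided by run count", {
  gen <- generate_corpus(synth_spec(n_docs = 8, seed = 5))
  runs <- lapply(1:2, function(s)
    degrade_to_predictions(gen$gold, gen$corpus,
                           degrade_spec(fn_rate = 0.4, fp_rate = 0.5, seed = s),
                           team_id = paste0("t", s)))
  cr <- cross_run_report(gen$gold, runs, k = 100)
  ms <- lapply(runs, function(r) match_run(gen$gold, r))
  # brute force document FN averages
  tot <- Reduce(`+`, lapply(ms, function(m) {
    v <- m$per_doc$fn; names(v) <- m$per_doc$doc_id
    v[sort(unique(gen$gold$mentions$doc_id))]
  }))
  avg <- tot / 2
  avg <- avg[avg > 0]
  got <- cr$fn_documents
  expect_equal(sort(got$doc_id), sort(names(avg)))
  expect_equal(got$avg_per_run[order(got$doc_id)], unname(avg[sort(names(avg))]))

  # single run: averages equal that run's counts
  one <- cross_run_report(gen$gold, runs[1], k = 100)
  m1 <- ms[[1]]
  expect_equal(sum(one$fn_documents$avg_per_run), nrow(m1$fn))
  expect_error(cross_run_report(gen$gold, list()), "at least one")
})

test_that("prediction report bundles all panels and serializes to JSON", {
  gen <- generate_corpus(synth_spec(n_docs = 12, seed = 9))
  run <- degrade_to_predictions(gen$gold, gen$corpus,
                                degrade_spec(fn_rate = 0.3, fp_rate = 0.8,
                                             shift_rate = 0.1, seed = 10),
                                team_id = "sys1")
  rep <- prediction_report(gen$gold, run, k = 5)
  expect_s3_class(rep$scores_micro, "ner_scores")
  expect_s3_class(rep$scores_macro, "ner_scores")
  expect_gt(nrow(rep$class_distribution), 0L)
  expect_gt(nrow(rep$top_fn_terms), 0L)
  p <- tempfile(fileext = ".json")
  write_report(rep, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$team_id, "sys1")
  expect_equal(parsed$scores_micro$fscore, rep$scores_micro$fscore)
  expect_equal(length(parsed$top_fn_terms), nrow(rep$top_fn_terms))
})
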