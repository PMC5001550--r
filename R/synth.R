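# Deterministic synthetic corpora with known gold standards, and degraded
# prediction runs with controlled error rates, so scoring, benchmarking and
# propagation can be exercised end-to-end without any external corpus.
# Filler text is whitespace-tokenised ASCII plus a multi-byte Unicode salt
# (Greek letters), which exercises code-point offset handling — the dominant
# failure mode in stand-off tooling.

default_vocab <- function() list(
  SYSTEMATIC = c("1,2-dimethylbenzene", "N-acetylcysteine",
                 "2-amino-3-methylbutanoate", "4-hydroxyphenylacetate"),
  TRIVIAL = c("aspirin", "caffeine", "docetaxel", "ibuprofen", "morphine"),
  FAMILY = c("alkyl", "ester", "opioid", "benzodiazepine"),
  FORMULA = c("C6H12O6", "NaCl", "H2SO4", "CaCO3"),
  ABBREVIATIONS = c("DMSO", "EDTA", "ATP"))

default_filler <- function() c(
  "the", "compound", "was", "tested", "against", "cultured", "cells",
  "showing", "marked", "activity", "in", "assay", "conditions", "with",
  "dose", "dependent", "response", "observed", "after", "treatment",
  "samples", "were", "measured", "at", "baseline", "and", "followup",
  "μM", "α-phase", "β-fold")

#' Specification for a synthetic corpus
#'
#' @param n_docs number of documents (>= 1).
#' @param vocab named list mapping annotation class to entity surface forms;
#'   forms must not contain tabs or newlines.
#' @param filler_words tokens used for non-entity text; they must not collide
#'   with vocabulary forms.
#' @param mentions_per_doc integer range `c(min, max)` of embedded mentions
#'   per document.
#' @param title_tokens number of filler tokens in each title.
#' @param abstract_tokens number of filler tokens around which mentions are
#'   embedded in each abstract.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_docs = 50L, vocab = default_vocab(),
                       filler_words = default_filler(),
                       mentions_per_doc = c(2L, 6L),
                       title_tokens = 4L, abstract_tokens = 30L,
                       seed = 1L) {
  stopifnot(n_docs >= 1L, length(vocab) >= 1L,
            length(mentions_per_doc) == 2L,
            mentions_per_doc[1] >= 0L,
            mentions_per_doc[2] >= mentions_per_doc[1])
  forms <- unlist(vocab, use.names = FALSE)
  if (!length(forms)) stop("vocab must contain at least one form", call. = FALSE)
  if (any(grepl("[\t\n]", forms)))
    stop("entity forms must not contain tab or newline", call. = FALSE)
  structure(list(n_docs = as.integer(n_docs), vocab = vocab,
                 filler_words = filler_words,
                 mentions_per_doc = as.integer(mentions_per_doc),
                 title_tokens = as.integer(title_tokens),
                 abstract_tokens = as.integer(abstract_tokens),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic corpus and its gold standard
#'
#' Documents are assembled from filler tokens with vocabulary mentions
#' embedded at recorded offsets, so the gold annotations are correct by
#' construction; the result passes every annotation-set invariant (slice
#' equality, no overlap). Identical seeds give bit-identical output.
#'
#' @param spec a [synth_spec()].
#' @return list with `corpus` (a [corpus()]) and `gold` (an
#'   [annotation_set()], task `"custom"` with the vocab classes).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  classes <- names(spec$vocab)
  with_seed(spec$seed, {
    ids <- sprintf("SYN%07d", seq_len(spec$n_docs))
    titles <- character(spec$n_docs)
    abstracts <- character(spec$n_docs)
    rows <- list()
    for (d in seq_len(spec$n_docs)) {
      titles[d] <- paste(sample(spec$filler_words, spec$title_tokens,
                                replace = TRUE), collapse = " ")
      k <- spec$mentions_per_doc[1] +
        sample.int(spec$mentions_per_doc[2] - spec$mentions_per_doc[1] + 1L,
                   1L) - 1L
      n_slots <- spec$abstract_tokens + k
      mention_slots <- if (k > 0) sort(sample.int(n_slots, k)) else integer()
      tokens <- character(n_slots)
      is_mention <- seq_len(n_slots) %in% mention_slots
      tokens[!is_mention] <- sample(spec$filler_words, sum(!is_mention),
                                    replace = TRUE)
      cls_draw <- sample(classes, k, replace = TRUE)
      for (j in seq_len(k))
        tokens[mention_slots[j]] <- sample(spec$vocab[[cls_draw[j]]], 1L)
      # offsets: tokens joined by single spaces
      lens <- cp_len(tokens)
      starts <- cumsum(c(0L, lens[-n_slots] + 1L))
      abstracts[d] <- paste(tokens, collapse = " ")
      for (j in seq_len(k)) {
        slot <- mention_slots[j]
        rows[[length(rows) + 1L]] <- mention_frame(
          doc_id = ids[d], section = "A", start = starts[slot],
          end = starts[slot] + lens[slot], text = tokens[slot],
          class = cls_draw[j], provenance = "manual")
      }
    }
    corp <- corpus(ids, titles, abstracts)
    gold <- annotation_set(
      if (length(rows)) do.call(rbind, rows) else mention_frame(),
      task = "custom", classes = classes, corpus = corp)
    list(corpus = corp, gold = gold)
  })
}

#' Specification for degrading a gold standard into predictions
#'
#' Models the three mismatch kinds of exact-span evaluation: misses (a gold
#' mention dropped with probability `fn_rate`), spurious predictions
#' (Poisson-distributed per document with mean `fp_rate`), and partial hits
#' (a kept mention's boundary perturbed by one code point with probability
#' `shift_rate`, which exact matching scores as one FP plus one FN).
#'
#' @param fn_rate probability in \[0,1\] that a gold mention is dropped.
#' @param fp_rate expected number of spurious predictions per document (>= 0).
#' @param shift_rate probability in \[0,1\] that a kept mention's boundary is
#'   perturbed.
#' @param seed integer seed.
#' @return a `degrade_spec` list.
#' @export
degrade_spec <- function(fn_rate = 0, fp_rate = 0, shift_rate = 0, seed = 1L) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0,
            shift_rate >= 0, shift_rate <= 1)
  structure(list(fn_rate = fn_rate, fp_rate = fp_rate,
                 shift_rate = shift_rate, seed = as.integer(seed)),
            class = "degrade_spec")
}

# Perturb [start,end) by +-1 on one side, clamped to the section, re-rolling
# until the result differs from every gold span in the same doc/section.
shift_span <- function(start, end, text_len, gold_spans) {
  for (attempt in 1:50) {
    delta <- sample(c(-1L, 1L), 1L)
    side <- sample(c("s", "e"), 1L)
    s <- start; e <- end
    if (side == "s") s <- s + delta else e <- e + delta
    if (s < 0L || e > text_len || s >= e) next
    if (!any(gold_spans$start == s & gold_spans$end == e))
      return(c(s, e))
  }
  NULL
}

#' Degrade a gold standard into a prediction run
#'
#' Each gold mention is independently dropped with probability `fn_rate`;
#' survivors have a boundary shifted with probability `shift_rate`
#' (guaranteed not to coincide with any gold span, so every shifted mention
#' scores as a partial hit: one FP plus one FN); spurious spans are added per
#' document (count Poisson with mean `fp_rate`), avoiding exact collisions
#' with gold spans. Deterministic under the spec's seed.
#'
#' @param gold an [annotation_set()].
#' @param corpus the [corpus()] the gold addresses.
#' @param spec a [degrade_spec()].
#' @param team_id,run_id identity for the returned run.
#' @return a [prediction_run()].
#' @export
degrade_to_predictions <- function(gold, corpus, spec,
                                   team_id = "synthetic", run_id = 1L) {
  stopifnot(inherits(spec, "degrade_spec"))
  g <- gold$mentions
  with_seed(spec$seed, {
    rows <- list()
    rank_ctr <- 0L
    keep <- if (nrow(g)) stats::runif(nrow(g)) >= spec$fn_rate else logical()
    for (i in which(keep)) {
      txt <- section_text(corpus, g$doc_id[i], g$section[i])
      s <- g$start[i]; e <- g$end[i]
      if (spec$shift_rate > 0 && stats::runif(1) < spec$shift_rate) {
        gs <- g[g$doc_id == g$doc_id[i] & g$section == g$section[i], ,
                drop = FALSE]
        sh <- shift_span(s, e, cp_len(txt), gs)
        if (!is.null(sh)) { s <- sh[1]; e <- sh[2] }
      }
      rank_ctr <- rank_ctr + 1L
      rows[[length(rows) + 1L]] <- mention_frame(
        doc_id = g$doc_id[i], section = g$section[i], start = s, end = e,
        text = cp_slice(txt, s, e), class = g$class[i],
        provenance = "predicted", confidence = stats::runif(1, 0.5, 1),
        rank = rank_ctr)
    }
    if (spec$fp_rate > 0) {
      for (d in seq_len(nrow(corpus))) {
        n_spur <- stats::rpois(1, spec$fp_rate)
        if (!n_spur) next
        id <- corpus$doc_id[d]
        txt <- corpus$abstract[d]
        tl <- cp_len(txt)
        if (tl < 2L) next
        gs <- g[g$doc_id == id & g$section == "A", , drop = FALSE]
        made <- 0L; tries <- 0L
        while (made < n_spur && tries < 50L * n_spur) {
          tries <- tries + 1L
          s <- sample.int(tl - 1L, 1L) - 1L
          len <- sample.int(min(8L, tl - s), 1L)
          e <- s + len
          if (any(gs$start == s & gs$end == e)) next
          dup <- length(rows) &&
            any(vapply(rows, function(r) r$doc_id == id && r$section == "A" &&
                         r$start == s && r$end == e, TRUE))
          if (dup) next
          rank_ctr <- rank_ctr + 1L
          rows[[length(rows) + 1L]] <- mention_frame(
            doc_id = id, section = "A", start = s, end = e,
            text = cp_slice(txt, s, e), provenance = "predicted",
            confidence = stats::runif(1, 0, 0.5), rank = rank_ctr)
          made <- made + 1L
        }
      }
    }
    prediction_run(if (length(rows)) do.call(rbind, rows) else mention_frame(),
                   team_id = team_id, run_id = run_id)
  })
}

#' Expected mismatch counts for a degraded run
#'
#' Closed-form expectations under the degradation model:
#' TP = gold_size (1 - fn_rate)(1 - shift_rate); FN = gold_size - TP;
#' FP = gold_size (1 - fn_rate) shift_rate + n_docs fp_rate. Precision and
#' recall follow from the expected counts.
#'
#' @param gold_size number of gold mentions.
#' @param spec a [degrade_spec()].
#' @param n_docs number of documents.
#' @return named list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
expected_counts <- function(gold_size, spec, n_docs) {
  tp <- gold_size * (1 - spec$fn_rate) * (1 - spec$shift_rate)
  fn <- gold_size - tp
  fp <- gold_size * (1 - spec$fn_rate) * spec$shift_rate + n_docs * spec$fp_rate
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else 1,
       recall = if (tp + fn > 0) tp / (tp + fn) else 1)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the standard documents/gold TSV dialects plus a JSON manifest
#' recording the generating specs and seeds.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory.
#' @param degrade optional named list of [degrade_spec()]s; one prediction
#'   TSV per entry is written, named `pred_<name>.tsv`.
#' @return list of paths written, invisibly.
#' @export
write_fixture <- function(spec, dir, degrade = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_corpus(spec)
  paths <- list(documents = file.path(dir, "documents.tsv"),
                gold = file.path(dir, "gold.tsv"))
  write_documents(gen$corpus, paths$documents)
  export_standoff(gen$gold, paths$gold)
  for (nm in names(degrade)) {
    run <- degrade_to_predictions(gen$gold, gen$corpus, degrade[[nm]],
                                  team_id = nm)
    p <- file.path(dir, paste0("pred_", nm, ".tsv"))
    write_prediction_run(run, p)
    paths[[paste0("pred_", nm)]] <- p
  }
  manifest <- list(
    generator = unclass(spec)[c("n_docs", "mentions_per_doc", "title_tokens",
                                "abstract_tokens", "seed")],
    classes = names(spec$vocab),
    degrade = lapply(degrade, unclass))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$manifest <- file.path(dir, "manifest.json")
  invisible(paths)
}

#' Write a prediction run in the ranked TSV dialect
#'
#' Emits the extended dialect (`doc_id, section:start:end, rank, confidence,
#' text, class`); confidence defaults to 0.5 and ranks are assigned in order
#' where absent.
#'
#' @param run a [prediction_run()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_run <- function(run, path) {
  m <- run$mentions
  conf <- ifelse(is.na(m$confidence), 0.5, m$confidence)
  rk <- m$rank
  rk[is.na(rk)] <- seq_len(nrow(m))[is.na(rk)]
  lines <- if (nrow(m))
    paste(m$doc_id, paste(m$section, m$start, m$end, sep = ":"),
          rk, format(conf, digits = 17, scientific = FALSE, trim = TRUE),
          m$text, ifelse(is.na(m$class), "", m$class), sep = "\t")
  else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}
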