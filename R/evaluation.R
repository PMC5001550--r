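# Exact-span scoring of prediction runs against a gold standard.
#
# A prediction is a true positive only when document, section, start and end
# all equal a gold annotation (and the class too, under class-strict
# matching). Partial hits — predictions that only in part overlap a gold
# annotation — receive no credit: they count as one false positive while the
# gold annotation they graze remains a false negative.

#' Match a prediction run against a gold standard
#'
#' @param gold an [annotation_set()].
#' @param run a [prediction_run()].
#' @param class_strict if `TRUE`, a true positive additionally requires the
#'   predicted class to equal the gold class; by default matching is
#'   class-agnostic (mention-level evaluation).
#' @return a `match_result` with components `tp` (data frame pairing gold and
#'   predicted row indices plus span fields), `fp` and `fn` (mention frames),
#'   and `per_doc` (per-document tp/fp/fn counts over all documents touched by
#'   gold or predictions).
#' @export
match_run <- function(gold, run, class_strict = FALSE) {
  g <- gold$mentions
  p <- run$mentions
  gkey <- span_key(g, with_class = class_strict)
  pkey <- span_key(p, with_class = class_strict)
  gi <- match(gkey, pkey)          # gold row -> pred row (spans are unique
  pi <- match(pkey, gkey)          # both sides, so match() is a bijection
  tp_g <- which(!is.na(gi))
  tp <- data.frame(
    gold_row = tp_g, pred_row = gi[tp_g],
    doc_id = g$doc_id[tp_g], section = g$section[tp_g],
    start = g$start[tp_g], end = g$end[tp_g],
    text = g$text[tp_g], class = g$class[tp_g],
    stringsAsFactors = FALSE)
  fn <- g[is.na(gi), , drop = FALSE]
  fp <- p[is.na(pi), , drop = FALSE]
  rownames(fn) <- rownames(fp) <- NULL
  docs <- unique(c(g$doc_id, p$doc_id))
  count_by <- function(ids) {
    t <- table(factor(ids, levels = docs))
    as.integer(t)
  }
  per_doc <- data.frame(
    doc_id = docs,
    tp = count_by(tp$doc_id), fp = count_by(fp$doc_id), fn = count_by(fn$doc_id),
    stringsAsFactors = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, per_doc = per_doc,
                 class_strict = class_strict),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: TP=%d FP=%d FN=%d over %d documents%s>\n",
              nrow(x$tp), nrow(x$fp), nrow(x$fn), nrow(x$per_doc),
              if (x$class_strict) ", class-strict" else ""))
  invisible(x)
}

# Precision/recall with the empty-set conventions: an empty prediction set
# against empty gold is perfect agreement (1); against non-empty gold it is 0.
prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) (if (fn == 0) 1 else 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) (if (fp == 0) 1 else 0) else tp / (tp + fn)
  fscore <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, fscore = fscore)
}

new_scores <- function(v, flavor, n_documents = NA_integer_) {
  structure(list(precision = unname(v["precision"]),
                 recall = unname(v["recall"]),
                 fscore = unname(v["fscore"]),
                 flavor = flavor, n_documents = n_documents),
            class = "ner_scores")
}

#' @export
print.ner_scores <- function(x, digits = 4, ...) {
  cat(sprintf("%s-averaged: precision %.*f  recall %.*f  F-score %.*f%s\n",
              x$flavor, digits, x$precision, digits, x$recall, digits,
              x$fscore,
              if (!is.na(x$n_documents))
                sprintf("  (over %d documents)", x$n_documents) else ""))
  invisible(x)
}

#' Micro-averaged precision, recall and F-score
#'
#' Statistics are computed globally from the pooled true-positive,
#' false-positive and false-negative counts: recall = TP/(TP+FN), precision =
#' TP/(TP+FP), and the F-score is their harmonic mean.
#'
#' @param m a [match_run()] result, or a list/vector with elements `tp`, `fp`,
#'   `fn` giving global counts.
#' @return a `ner_scores` object (flavor `"micro"`).
#' @export
micro_scores <- function(m) {
  if (inherits(m, "match_result")) {
    counts <- c(tp = nrow(m$tp), fp = nrow(m$fp), fn = nrow(m$fn))
  } else {
    counts <- c(tp = m[["tp"]], fp = m[["fp"]], fn = m[["fn"]])
  }
  new_scores(prf(counts[["tp"]], counts[["fp"]], counts[["fn"]]), "micro")
}

#' Macro-averaged precision, recall and F-score
#'
#' Counts true positives, false positives and false negatives per document,
#' computes precision/recall/F per document, and averages across documents so
#' each document weighs equally. The averaging scope is the documents with at
#' least one gold annotation; predictions falling in documents outside that
#' scope still count toward micro statistics, and their presence is flagged in
#' the `out_of_scope_fp` attribute.
#'
#' @inheritParams match_run
#' @return a `ner_scores` object (flavor `"macro"`) with `n_documents` set.
#' @export
macro_scores <- function(gold, run, class_strict = FALSE) {
  m <- match_run(gold, run, class_strict = class_strict)
  gold_docs <- unique(gold$mentions$doc_id)
  pd <- m$per_doc[m$per_doc$doc_id %in% gold_docs, , drop = FALSE]
  if (!nrow(pd))
    stop("macro undefined on empty scope (no documents with gold annotations)",
         call. = FALSE)
  per <- t(mapply(prf, pd$tp, pd$fp, pd$fn))
  out <- new_scores(colMeans(per), "macro", n_documents = nrow(pd))
  attr(out, "out_of_scope_fp") <-
    sum(m$per_doc$fp[!(m$per_doc$doc_id %in% gold_docs)])
  out
}

#' Per-class distribution of true positives and false negatives
#'
#' Each gold mention contributes to exactly one class row (classes are unique
#' and exclusive), split by whether it was matched. Row sums reproduce the
#' global TP and FN counts.
#'
#' @param m a [match_run()] result.
#' @param gold the [annotation_set()] it was computed from.
#' @return data frame with columns `class`, `tp`, `fn`, in inventory order
#'   (classes with no gold mentions are omitted).
#' @export
class_distribution <- function(m, gold) {
  g <- gold$mentions
  if (!nrow(g))
    return(data.frame(class = character(), tp = integer(), fn = integer(),
                      stringsAsFactors = FALSE))
  labels <- ifelse(is.na(g$class), "(unclassed)", g$class)
  lv <- c(gold$classes[gold$classes %in% labels],
          if (any(labels == "(unclassed)")) "(unclassed)")
  cls <- factor(labels, levels = lv)
  matched <- seq_len(nrow(g)) %in% m$tp$gold_row
  data.frame(class = lv,
             tp = as.integer(table(cls[matched])),
             fn = as.integer(table(cls[!matched])),
             stringsAsFactors = FALSE)
}

# Group surface strings by the case-folded form; returns count-ranked rows
# with a display form (the most frequent original casing, first-seen on tie).
rank_terms <- function(texts, k) {
  if (!length(texts))
    return(data.frame(term = character(), count = integer(),
                      stringsAsFactors = FALSE))
  folded <- fold_case(texts)
  cnt <- table(folded)
  display <- vapply(names(cnt), function(f) {
    orig <- texts[folded == f]
    t <- table(factor(orig, levels = unique(orig)))  # first-seen order on ties
    names(t)[which.max(t)]
  }, "")
  ord <- order(-as.integer(cnt), names(cnt))
  out <- data.frame(term = unname(display[ord]),
                    count = as.integer(cnt)[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Top false-negative or false-positive terms
#'
#' Mentions are grouped by case-folded surface text and ranked by count
#' descending, ties broken lexicographically on the folded form. These tables
#' surface the terms a system misses most (false negatives) or hallucinates
#' most (false positives).
#'
#' @param m a [match_run()] result.
#' @param direction `"fn"` or `"fp"`.
#' @param k number of rows to keep.
#' @return data frame with columns `term` (display casing) and `count`.
#' @export
top_terms <- function(m, direction = c("fn", "fp"), k = 10L) {
  direction <- match.arg(direction)
  stopifnot(k >= 1L)
  rank_terms(m[[direction]]$text, k)
}

#' Documents with the most mismatches
#'
#' @inheritParams top_terms
#' @return data frame with columns `doc_id` and `count`, count-descending with
#'   doc_id tie-break; zero-count documents are suppressed.
#' @export
top_documents <- function(m, direction = c("fn", "fp"), k = 10L) {
  direction <- match.arg(direction)
  stopifnot(k >= 1L)
  pd <- m$per_doc
  cnt <- pd[[direction]]
  keep <- cnt > 0L
  pd <- pd[keep, , drop = FALSE]; cnt <- cnt[keep]
  ord <- order(-cnt, pd$doc_id)
  utils::head(data.frame(doc_id = pd$doc_id[ord], count = cnt[ord],
                         stringsAsFactors = FALSE), k)
}

#' Cross-run mismatch averages
#'
#' Aggregates mismatches over several prediction runs to expose the terms and
#' documents that most systems get wrong: for each document and each term the
#' average false-negative and false-positive count per run (total across runs
#' divided by the number of runs). Ranking uses the unrounded average.
#'
#' @param gold an [annotation_set()].
#' @param runs list of [prediction_run()]s (at least one).
#' @param k rows per table.
#' @param class_strict passed to [match_run()].
#' @return list of four data frames: `fn_documents`, `fp_documents`,
#'   `fn_terms`, `fp_terms`, each with an `avg_per_run` column.
#' @export
cross_run_report <- function(gold, runs, k = 10L, class_strict = FALSE) {
  if (!length(runs)) stop("need at least one run", call. = FALSE)
  ms <- lapply(runs, function(r) match_run(gold, r, class_strict = class_strict))
  nr <- length(runs)
  doc_table <- function(direction) {
    tot <- list()
    for (m in ms) {
      pd <- m$per_doc
      for (i in seq_len(nrow(pd)))
        tot[[pd$doc_id[i]]] <- (tot[[pd$doc_id[i]]] %||% 0) + pd[[direction]][i]
    }
    if (!length(tot))
      return(data.frame(doc_id = character(), avg_per_run = numeric(),
                        stringsAsFactors = FALSE))
    avg <- unlist(tot) / nr
    avg <- avg[avg > 0]
    ord <- order(-avg, names(avg))
    utils::head(data.frame(doc_id = names(avg)[ord],
                           avg_per_run = unname(avg)[ord],
                           stringsAsFactors = FALSE), k)
  }
  term_table <- function(direction) {
    texts <- unlist(lapply(ms, function(m) m[[direction]]$text))
    tab <- rank_terms(texts, k = .Machine$integer.max)
    tab$avg_per_run <- tab$count / nr
    tab$count <- NULL
    utils::head(tab, k)
  }
  list(fn_documents = doc_table("fn"), fp_documents = doc_table("fp"),
       fn_terms = term_table("fn"), fp_terms = term_table("fp"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full prediction-analysis report
#'
#' Bundles everything a team needs to understand one run: micro and macro
#' scores, the per-class TP/FN distribution, the top false-negative and
#' false-positive terms, and the documents with the most mismatches.
#'
#' @inheritParams macro_scores
#' @param k rows per top table.
#' @return a `prediction_report` object; see [write_report()] for
#'   serialization.
#' @export
prediction_report <- function(gold, run, class_strict = FALSE, k = 10L) {
  m <- match_run(gold, run, class_strict = class_strict)
  structure(list(
    team_id = run$team_id, run_id = run$run_id,
    counts = c(tp = nrow(m$tp), fp = nrow(m$fp), fn = nrow(m$fn)),
    scores_micro = micro_scores(m),
    scores_macro = macro_scores(gold, run, class_strict = class_strict),
    class_distribution = class_distribution(m, gold),
    top_fn_terms = top_terms(m, "fn", k),
    top_fp_terms = top_terms(m, "fp", k),
    top_fn_documents = top_documents(m, "fn", k),
    top_fp_documents = top_documents(m, "fp", k),
    per_doc = m$per_doc), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Prediction analysis — team %s, run %d\n", x$team_id, x$run_id))
  cat(sprintf("counts: TP=%d FP=%d FN=%d\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"]))
  print(x$scores_micro); print(x$scores_macro)
  cat("\nTP/FN distribution per annotation class:\n")
  print(x$class_distribution, row.names = FALSE)
  cat("\nTop false negatives (terms):\n")
  print(x$top_fn_terms, row.names = FALSE)
  cat("\nTop false positives (terms):\n")
  print(x$top_fp_terms, row.names = FALSE)
  cat("\nDocuments with most false negatives:\n")
  print(x$top_fn_documents, row.names = FALSE)
  cat("\nDocuments with most false positives:\n")
  print(x$top_fp_documents, row.names = FALSE)
  invisible(x)
}

scores_as_list <- function(s)
  list(precision = s$precision, recall = s$recall, fscore = s$fscore,
       flavor = s$flavor,
       n_documents = if (!is.na(s$n_documents)) s$n_documents else NULL)

#' Serialize a prediction report to JSON
#'
#' @param report a [prediction_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    team_id = report$team_id, run_id = report$run_id,
    counts = as.list(report$counts),
    scores_micro = scores_as_list(report$scores_micro),
    scores_macro = scores_as_list(report$scores_macro),
    class_distribution = report$class_distribution,
    top_fn_terms = report$top_fn_terms,
    top_fp_terms = report$top_fp_terms,
    top_fn_documents = report$top_fn_documents,
    top_fp_documents = report$top_fp_documents,
    per_document = report$per_doc)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
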