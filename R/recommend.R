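# Semi-automatic annotation: manual annotations are propagated to unlabelled
# text that matches them exactly (case-insensitively); a curator removes or
# edits the unwanted suggestions, and whatever remains is implicitly accepted
# into the gold standard.

#' Build a propagation lexicon from manual annotations
#'
#' One entry per distinct case-folded surface form, with the class frequency
#' table, total count and a display form (the most frequent original casing,
#' first seen on ties). The index of the last contributing annotation per
#' class is retained to break class-majority ties by recency.
#'
#' @param set an [annotation_set()] of manual annotations.
#' @return a `lexicon` object (named list of entries keyed by folded form).
#' @export
build_lexicon <- function(set) {
  m <- set$mentions
  entries <- list()
  if (nrow(m)) {
    folded <- fold_case(m$text)
    for (f in unique(folded)) {
      idx <- which(folded == f)
      orig <- m$text[idx]
      t_orig <- table(factor(orig, levels = unique(orig)))
      cls <- ifelse(is.na(m$class[idx]), "(unclassed)", m$class[idx])
      freq <- table(cls)
      last_seen <- vapply(names(freq), function(cc) max(idx[cls == cc]), 0)
      entries[[f]] <- list(
        form = f,
        display = names(t_orig)[which.max(t_orig)],
        total = length(idx),
        class_freq = stats::setNames(as.integer(freq), names(freq)),
        last_seen = last_seen)
    }
  }
  structure(entries, class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d form(s)>\n", length(x)))
  for (e in utils::head(unclass(x), 8))
    cat(sprintf("  %s (n=%d): %s\n", dQuote(e$display), e$total,
                paste(names(e$class_freq), e$class_freq, sep = "=",
                      collapse = " ")))
  invisible(x)
}

# Majority class of a lexicon entry; ties go to the class whose contributing
# annotation appeared most recently in the source set.
entry_class <- function(e) {
  top <- names(e$class_freq)[e$class_freq == max(e$class_freq)]
  if (length(top) > 1L) top <- top[which.max(e$last_seen[top])]
  if (top == "(unclassed)") NA_character_ else top
}

# All occurrences (0-based [start,end)) of `form` in folded `text`,
# including self-overlapping ones.
find_occurrences <- function(text_folded, form) {
  n <- cp_len(text_folded); len <- cp_len(form)
  if (len == 0L || len > n) return(integer())
  starts <- 1:(n - len + 1L)
  which(substring(text_folded, starts, starts + len - 1L) == form) - 1L
}

is_word_cp <- function(cp) {
  (cp >= 0x30 & cp <= 0x39) | (cp >= 0x41 & cp <= 0x5A) |
  (cp >= 0x61 & cp <= 0x7A) | cp == 0x5F | cp >= 0xC0
}

# boundary = "word": the characters immediately outside the span must be
# non-word characters or text edges. Annotations themselves may still cover
# partial words; the boundary rule only gates automatic propagation.
at_word_boundary <- function(text, start, end) {
  cp <- utf8ToInt(enc2utf8(text))
  left_ok <- start == 0L || !is_word_cp(cp[start])
  right_ok <- end >= length(cp) || !is_word_cp(cp[end + 1L])
  left_ok && right_ok
}

#' Suggest annotations by propagating a lexicon over a corpus
#'
#' Scans every document section for unlabelled text that is an exact,
#' case-insensitive match of a lexicon form. Occurrences overlapping an
#' existing annotation are skipped (nesting is not allowed), and competing
#' candidate occurrences are resolved greedily — longest form first, then
#' leftmost. Each suggestion takes the majority class of its lexicon entry.
#'
#' @param corpus a [corpus()].
#' @param set the existing [annotation_set()] (manual annotations).
#' @param lex a [build_lexicon()] result; defaults to the lexicon of `set`.
#' @param boundary `"word"` (default) requires matches to abut non-word
#'   characters or text edges; `"none"` also propagates into substrings of
#'   words.
#' @return a `recommendation_set`: list with `suggestions` (mention frame,
#'   provenance `"automatic"`) and `source_set`.
#' @export
suggest_annotations <- function(corpus, set, lex = build_lexicon(set),
                                boundary = c("word", "none")) {
  boundary <- match.arg(boundary)
  forms <- names(lex)
  # longest-first, then scan order; start offset breaks ties leftmost
  forms <- forms[order(-cp_len(forms), forms)]
  sugg <- list()
  existing <- set$mentions
  for (i in seq_len(nrow(corpus))) {
    id <- corpus$doc_id[i]
    for (sec in c("T", "A")) {
      text <- if (sec == "T") corpus$title[i] else corpus$abstract[i]
      if (!nzchar(text)) next
      folded <- fold_case(text)
      ex <- existing[existing$doc_id == id & existing$section == sec, ,
                     drop = FALSE]
      taken_s <- ex$start; taken_e <- ex$end
      cand <- list()
      for (f in forms) {
        occ <- find_occurrences(folded, f)
        if (!length(occ)) next
        len <- cp_len(f)
        for (s in occ) {
          e <- s + len
          if (boundary == "word" && !at_word_boundary(text, s, e)) next
          cand[[length(cand) + 1L]] <- c(s, e, match(f, names(lex)))
        }
      }
      if (!length(cand)) next
      cm <- do.call(rbind, cand)
      # greedy: longest span first, then leftmost
      cm <- cm[order(-(cm[, 2] - cm[, 1]), cm[, 1]), , drop = FALSE]
      for (r in seq_len(nrow(cm))) {
        s <- cm[r, 1]; e <- cm[r, 2]
        if (any(taken_s < e & s < taken_e)) next
        entry <- lex[[cm[r, 3]]]
        sugg[[length(sugg) + 1L]] <- mention_frame(
          doc_id = id, section = sec, start = s, end = e,
          text = cp_slice(text, s, e), class = entry_class(entry),
          provenance = "automatic")
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
  }
  suggestions <- if (length(sugg)) do.call(rbind, sugg) else mention_frame()
  suggestions <- suggestions[order(suggestions$doc_id, suggestions$section,
                                   suggestions$start), , drop = FALSE]
  rownames(suggestions) <- NULL
  structure(list(suggestions = suggestions, source_set = set),
            class = "recommendation_set")
}

#' @export
print.recommendation_set <- function(x, ...) {
  cat(sprintf("<recommendation_set: %d suggestion(s) in %d document(s)>\n",
              nrow(x$suggestions), length(unique(x$suggestions$doc_id))))
  invisible(x)
}

#' Revise a recommendation set
#'
#' Curator operations on suggestions before acceptance: delete by row index,
#' or edit a suggestion's span or class. Edits are re-validated against the
#' manual annotations and the remaining suggestions; an edit that creates an
#' overlap is rejected.
#'
#' @param recs a [suggest_annotations()] result.
#' @param removals integer row indices of suggestions to drop.
#' @param edits list of edits, each a list with `ref` (row index) and any of
#'   `start`, `end`, `class`; `corpus` must be supplied when spans change.
#' @param corpus the [corpus()], required to re-derive surface text on span
#'   edits.
#' @return the revised `recommendation_set`.
#' @export
revise <- function(recs, removals = integer(), edits = list(), corpus = NULL) {
  s <- recs$suggestions
  if (length(removals)) {
    if (any(removals < 1L | removals > nrow(s)))
      stop("removal reference out of range", call. = FALSE)
    s <- s[-removals, , drop = FALSE]
    rownames(s) <- NULL
  }
  for (ed in edits) {
    i <- ed$ref
    if (is.null(i) || i < 1L || i > nrow(s))
      stop("edit reference does not resolve to a suggestion", call. = FALSE)
    if (!is.null(ed$class)) s$class[i] <- ed$class
    if (!is.null(ed$start) || !is.null(ed$end)) {
      if (is.null(corpus))
        stop("span edits require the corpus", call. = FALSE)
      s$start[i] <- as.integer(ed$start %||% s$start[i])
      s$end[i] <- as.integer(ed$end %||% s$end[i])
      txt <- section_text(corpus, s$doc_id[i], s$section[i])
      if (s$start[i] < 0L || s$end[i] <= s$start[i] || s$end[i] > cp_len(txt))
        stop("edited span out of range", call. = FALSE)
      s$text[i] <- cp_slice(txt, s$start[i], s$end[i])
    }
  }
  all_m <- rbind(recs$source_set$mentions, s)
  ov <- find_overlaps(all_m)
  if (nrow(ov))
    stop("edit rejected: it would create overlapping annotations", call. = FALSE)
  recs$suggestions <- s
  recs
}

#' Accept remaining suggestions into the annotation set
#'
#' Implicit acceptance at the end of a revision round: every remaining
#' suggestion is merged into the set with provenance `"accepted"`. The merged
#' set must satisfy all annotation-set invariants; propagating again with the
#' same lexicon then yields nothing new (the operation is a fixed point).
#'
#' @param set the manual [annotation_set()].
#' @param recs the revised [suggest_annotations()] result over `set`.
#' @return the merged [annotation_set()].
#' @export
finalize_annotations <- function(set, recs) {
  s <- recs$suggestions
  if (nrow(s)) s$provenance <- "accepted"
  merged <- rbind(set$mentions, s)
  merged <- merged[order(merged$doc_id, merged$section, merged$start), ,
                   drop = FALSE]
  classes <- unique(c(set$classes, stats::na.omit(s$class)))
  annotation_set(merged, task = set$task, classes = classes)
}

#' Batch-retype annotations of a term
#'
#' Changes the class of every mention whose case-folded text equals the
#' case-folded term and whose class is `from_class`.
#'
#' @param set an [annotation_set()].
#' @param term surface form (matched case-insensitively).
#' @param from_class,to_class class labels in the set's inventory.
#' @return the updated set, with attribute `n_changed`.
#' @export
batch_retype <- function(set, term, from_class, to_class) {
  if (!(to_class %in% set$classes))
    stop("to_class not in inventory: ", to_class, call. = FALSE)
  m <- set$mentions
  hit <- fold_case(m$text) == fold_case(term) & !is.na(m$class) &
    m$class == from_class
  m$class[hit] <- to_class
  out <- annotation_set(m, task = set$task, classes = set$classes)
  attr(out, "n_changed") <- sum(hit)
  out
}

#' Delete all annotations of a term
#'
#' Removes every mention matching the case-folded term, optionally restricted
#' to one class.
#'
#' @param set an [annotation_set()].
#' @param term surface form (matched case-insensitively).
#' @param cls optional class restriction.
#' @return the updated set, with attribute `n_removed`.
#' @export
delete_term <- function(set, term, cls = NULL) {
  m <- set$mentions
  hit <- fold_case(m$text) == fold_case(term)
  if (!is.null(cls)) hit <- hit & !is.na(m$class) & m$class == cls
  out <- annotation_set(m[!hit, , drop = FALSE], task = set$task,
                        classes = set$classes)
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Review listing of suggestions, indexed by document
#'
#' Plain-text rendering for curators: for each document, the suggested terms
#' to review with their spans and proposed classes.
#'
#' @param recs a [suggest_annotations()] result.
#' @return character vector of lines, invisibly printed.
#' @export
review_listing <- function(recs) {
  s <- recs$suggestions
  if (!nrow(s)) return(invisible("no suggestions"))
  lines <- character()
  for (id in unique(s$doc_id)) {
    lines <- c(lines, sprintf("document %s:", id))
    sub <- s[s$doc_id == id, , drop = FALSE]
    lines <- c(lines, sprintf("  [%s %d:%d] %s%s", sub$section, sub$start,
                              sub$end, dQuote(sub$text),
                              ifelse(is.na(sub$class), "",
                                     paste0(" -> ", sub$class))))
  }
  invisible(lines)
}
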