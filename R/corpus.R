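#' @keywords internal
"_PACKAGE"

# ---- offset arithmetic -------------------------------------------------------
# All offsets are 0-based, half-open [start, end), counted in Unicode code
# points of the raw section text (title and abstract addressed separately).

cp_len <- function(x) nchar(x, type = "chars")

#' Extract a code-point slice from text
#'
#' Offsets are 0-based and half-open, counted in Unicode code points, matching
#' the stand-off annotation convention used throughout the package.
#'
#' @param x character vector.
#' @param start 0-based inclusive start offset(s).
#' @param end exclusive end offset(s).
#' @return character vector of slices.
#' @export
#' @examples
#' cp_slice("We tested aspirin.", 10, 17)
cp_slice <- function(x, start, end) {
  substr(x, start + 1L, end)
}

# Locale-independent, length-preserving lowercase fold over the ASCII,
# Latin-1, Greek and Cyrillic blocks.  base::tolower() consults the C locale
# and is not reproducible across systems; a fixed mapping is, and preserving
# one-code-point-per-code-point keeps offsets valid after folding.
fold_case <- function(x) {
  out <- vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (!nzchar(s)) return(s)
    cp <- utf8ToInt(enc2utf8(s))
    i <- (cp >= 0x41L & cp <= 0x5AL) |
      (cp >= 0xC0L & cp <= 0xDEL & cp != 0xD7L) |
      (cp >= 0x391L & cp <= 0x3A9L & cp != 0x3A2L) |
      (cp >= 0x410L & cp <= 0x42FL)
    cp[i] <- cp[i] + 32L
    intToUtf8(cp)
  }, character(1), USE.NAMES = FALSE)
  Encoding(out) <- "UTF-8"
  out
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# ---- class inventories -------------------------------------------------------

#' Annotation class inventories
#'
#' The chemical-entity task uses eight mention classes and the
#' gene/protein-related-object task uses four; `custom` tasks supply their own.
#'
#' @param task one of `"CEMP"`, `"GPRO"` or `"custom"`.
#' @param classes character vector of class labels, required for `"custom"`.
#' @return character vector of class labels.
#' @export
class_inventory <- function(task = c("CEMP", "GPRO", "custom"), classes = NULL) {
  task <- match.arg(task)
  switch(task,
    CEMP = c("SYSTEMATIC", "TRIVIAL", "FAMILY", "FORMULA", "ABBREVIATIONS",
             "IDENTIFIERS", "MULTIPLE", "NO CLASS"),
    GPRO = c("NESTED MENTIONS", "IDENTIFIER", "FULL NAME", "ABBREVIATION"),
    custom = {
      if (is.null(classes) || !length(classes))
        stop("custom task requires a non-empty class inventory", call. = FALSE)
      as.character(classes)
    })
}

# ---- corpus ------------------------------------------------------------------

#' Construct a document corpus
#'
#' A corpus is a set of identified documents, each a title/abstract text pair.
#' Sections are addressed separately by the single-letter codes `"T"` (title)
#' and `"A"` (abstract).
#'
#' @param doc_id character vector of unique, non-empty document identifiers.
#' @param title,abstract character vectors of section texts; either may be
#'   empty for a given document but not both.
#' @return a `ner_corpus` data frame with columns `doc_id`, `title`,
#'   `abstract`, in input order.
#' @export
corpus <- function(doc_id, title, abstract) {
  doc_id <- as.character(doc_id)
  title <- enc2utf8(as.character(title))
  abstract <- enc2utf8(as.character(abstract))
  stopifnot(length(doc_id) == length(title), length(doc_id) == length(abstract))
  if (any(!nzchar(doc_id) | is.na(doc_id)))
    stop("doc_id must be non-empty", call. = FALSE)
  dup <- duplicated(doc_id)
  if (any(dup))
    stop("duplicate doc_id: ", paste(unique(doc_id[dup]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(title) & !nzchar(abstract)))
    stop("title and abstract must not both be empty", call. = FALSE)
  structure(
    data.frame(doc_id = doc_id, title = title, abstract = abstract,
               stringsAsFactors = FALSE),
    class = c("ner_corpus", "data.frame"))
}

#' @export
print.ner_corpus <- function(x, ...) {
  cat(sprintf("<corpus of %d documents>\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 5), ...)
  if (nrow(x) > 5) cat(sprintf("... and %d more\n", nrow(x) - 5L))
  invisible(x)
}

# Section text lookup, vectorized over (doc_id, section).
section_text <- function(corp, doc_id, section) {
  idx <- match(doc_id, corp$doc_id)
  ifelse(section == "T", corp$title[idx], corp$abstract[idx])
}

# ---- mentions ----------------------------------------------------------------

# Canonical empty mention table; every mention collection in the package is a
# data frame with exactly these columns.
mention_frame <- function(doc_id = character(), section = character(),
                          start = integer(), end = integer(),
                          text = character(), class = character(),
                          provenance = character(),
                          confidence = numeric(), rank = integer()) {
  n <- length(doc_id)
  rep_or <- function(x, default) {
    if (!length(x) && n > 0) rep(default, n) else x
  }
  data.frame(
    doc_id = as.character(doc_id),
    section = as.character(section),
    start = as.integer(start),
    end = as.integer(end),
    text = enc2utf8(as.character(text)),
    class = as.character(rep_or(class, NA_character_)),
    provenance = as.character(rep_or(provenance, "manual")),
    confidence = as.numeric(rep_or(confidence, NA_real_)),
    rank = as.integer(rep_or(rank, NA_integer_)),
    stringsAsFactors = FALSE)
}

span_key <- function(m, with_class = FALSE) {
  k <- paste(m$doc_id, m$section, m$start, m$end, sep = "\r")
  if (with_class) paste(k, m$class, sep = "\r") else k
}

# Overlap detection within one corpus: returns a data frame of offending pairs
# (row indices i < j) with a kind column, "nested" or "partial".
find_overlaps <- function(m) {
  out <- list()
  grp <- split(seq_len(nrow(m)), paste(m$doc_id, m$section))
  for (idx in grp) {
    if (length(idx) < 2) next
    o <- idx[order(m$start[idx], m$end[idx])]
    s <- m$start[o]; e <- m$end[o]
    for (j in 2:length(o)) {
      # any earlier interval still open at s[j] overlaps interval j
      prev <- which(e[1:(j - 1)] > s[j])
      for (p in prev) {
        nested <- (s[p] <= s[j] && e[j] <= e[p]) || (s[j] <= s[p] && e[p] <= e[j])
        out[[length(out) + 1L]] <- data.frame(
          i = o[p], j = o[j], kind = if (nested) "nested" else "partial",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    data.frame(i = integer(), j = integer(), kind = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Construct a validated annotation set
#'
#' An annotation set is a collection of mention spans over a corpus for one
#' task. Mention classes are unique and exclusive, and annotations may not nest
#' or overlap within a document section: the offsets of one annotation cannot
#' fall between the offsets of another.
#'
#' @param mentions a mention data frame (columns `doc_id`, `section`, `start`,
#'   `end`, `text`, `class`, `provenance`, `confidence`, `rank`).
#' @param task task label: `"CEMP"`, `"GPRO"` or `"custom"`.
#' @param classes class inventory; defaults to the task's standard inventory.
#' @param corpus optional `ner_corpus`; when given, every mention is checked
#'   for offset range and slice/text equality against its section text.
#' @param lenient if `TRUE`, partial (non-nested) overlaps are downgraded to
#'   warnings; nesting always errors.
#' @return an `annotation_set` object.
#' @export
annotation_set <- function(mentions, task = "custom", classes = NULL,
                           corpus = NULL, lenient = FALSE) {
  if (is.null(classes)) {
    classes <- if (task %in% c("CEMP", "GPRO")) class_inventory(task)
               else unique(stats::na.omit(mentions$class))
  }
  m <- mention_frame(mentions$doc_id, mentions$section, mentions$start,
                     mentions$end, mentions$text, mentions$class,
                     mentions$provenance, mentions$confidence, mentions$rank)
  if (nrow(m)) {
    if (!all(m$section %in% c("T", "A")))
      stop("section must be T or A", call. = FALSE)
    bad_cls <- !is.na(m$class) & !(m$class %in% classes)
    if (any(bad_cls))
      stop("class not in inventory: ",
           paste(unique(m$class[bad_cls]), collapse = ", "), call. = FALSE)
    if (any(m$start < 0L | m$end <= m$start))
      stop("invalid span: need 0 <= start < end", call. = FALSE)
    if (!is.null(corpus)) {
      txt <- section_text(corpus, m$doc_id, m$section)
      if (anyNA(txt))
        stop("mention refers to unknown doc_id: ",
             paste(unique(m$doc_id[is.na(txt)]), collapse = ", "),
             call. = FALSE)
      over <- m$end > cp_len(txt)
      if (any(over))
        stop("span beyond section end for doc ",
             paste(unique(m$doc_id[over]), collapse = ", "), call. = FALSE)
      slice <- cp_slice(txt, m$start, m$end)
      bad <- slice != m$text
      if (any(bad))
        stop("slice/text mismatch (offset convention error?) at doc ",
             m$doc_id[which(bad)[1]], ": slice ", dQuote(slice[which(bad)[1]]),
             " != text ", dQuote(m$text[which(bad)[1]]), call. = FALSE)
    }
    ov <- find_overlaps(m)
    if (nrow(ov)) {
      nested <- ov[ov$kind == "nested", , drop = FALSE]
      partial <- ov[ov$kind == "partial", , drop = FALSE]
      msg <- function(p) sprintf("(%s,%s,%d,%d) vs (%s,%s,%d,%d)",
        m$doc_id[p$i], m$section[p$i], m$start[p$i], m$end[p$i],
        m$doc_id[p$j], m$section[p$j], m$start[p$j], m$end[p$j])
      if (nrow(nested))
        stop("nested annotations are not allowed: ", msg(nested[1, ]),
             call. = FALSE)
      if (nrow(partial)) {
        if (lenient)
          warning("overlapping annotations: ", msg(partial[1, ]), call. = FALSE)
        else
          stop("overlapping annotations are not allowed: ", msg(partial[1, ]),
               call. = FALSE)
      }
    }
  }
  structure(list(task = task, classes = classes, mentions = m),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set task=%s: %d mentions in %d documents, %d classes>\n",
              x$task, nrow(x$mentions), length(unique(x$mentions$doc_id)),
              length(x$classes)))
  if (nrow(x$mentions)) {
    tab <- sort(table(x$mentions$provenance), decreasing = TRUE)
    cat("provenance:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Construct a prediction run
#'
#' One system submission: a set of predicted mention spans. Predicted spans may
#' overlap each other (systems emit them freely) but exact duplicates — same
#' document, section, start and end — are collapsed. At most five runs per team
#' are accepted per task.
#'
#' @param mentions mention data frame; provenance is forced to `"predicted"`.
#' @param team_id team identifier.
#' @param run_id run number, 1 to 5.
#' @return a `prediction_run` object.
#' @export
prediction_run <- function(mentions, team_id = "team", run_id = 1L) {
  run_id <- as.integer(run_id)
  if (is.na(run_id) || run_id < 1L || run_id > 5L)
    stop("run_id must be in 1..5 (maximum of five runs per task)", call. = FALSE)
  m <- mention_frame(mentions$doc_id, mentions$section, mentions$start,
                     mentions$end, mentions$text, mentions$class,
                     rep("predicted", nrow(mentions)),
                     mentions$confidence, mentions$rank)
  dup <- duplicated(span_key(m))
  if (any(dup)) {
    warning(sum(dup), " duplicate predicted span(s) collapsed", call. = FALSE)
    m <- m[!dup, , drop = FALSE]
    rownames(m) <- NULL
  }
  structure(list(team_id = as.character(team_id), run_id = run_id, mentions = m),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf("<prediction_run %s/run%d: %d predicted mentions in %d documents>\n",
              x$team_id, x$run_id, nrow(x$mentions),
              length(unique(x$mentions$doc_id))))
  invisible(x)
}
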