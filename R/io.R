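# Readers and writers for the headerless UTF-8 TSV dialects:
#   documents:   doc_id \t title \t abstract
#   gold:        doc_id \t section(T|A) \t start \t end \t text \t class
#                (stand-off export appends \t provenance)
#   predictions: doc_id \t section:start:end \t rank \t confidence
#                (extended dialect appends \t text \t class)
# Lines may end \n or \r\n; empty lines are ignored.

read_tsv_lines <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!all(validUTF8(txt)))
    stop("file is not valid UTF-8: ", path, call. = FALSE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a document corpus from TSV
#'
#' Each non-empty line carries three tab-separated fields: document id, title,
#' abstract. Input order is preserved.
#'
#' @param path path to a headerless UTF-8 TSV file.
#' @return a [corpus()] object.
#' @export
read_documents <- function(path) {
  lf <- read_tsv_lines(path)
  if (!length(lf$lines)) return(corpus(character(), character(), character()))
  fields <- split_fields(lf$lines)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1]
    stop(sprintf("line %d: expected 3 tab-separated fields, got %d",
                 lf$lineno[bad], nf[bad]), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- which(duplicated(ids))
  if (length(dup)) {
    first <- match(ids[dup[1]], ids)
    stop(sprintf("duplicate doc_id %s at lines %d and %d",
                 dQuote(ids[dup[1]]), lf$lineno[first], lf$lineno[dup[1]]),
         call. = FALSE)
  }
  corpus(ids, vapply(fields, `[[`, "", 2L), vapply(fields, `[[`, "", 3L))
}

#' Write a document corpus to TSV
#'
#' @param corp a [corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_documents <- function(corp, path) {
  lines <- paste(corp$doc_id, corp$title, corp$abstract, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Read a gold-standard annotation file
#'
#' Lines carry `doc_id, section, start, end, text, class` and optionally a
#' seventh provenance field (as written by [export_standoff()]). Every mention
#' is validated against its document: offsets must lie within the section and
#' the stored surface text must equal the addressed code-point slice, which
#' guards against offset-convention mistakes. Nested or overlapping
#' annotations are rejected.
#'
#' @param path path to the TSV file.
#' @param corpus the [corpus()] the annotations address.
#' @param classes class inventory (see [class_inventory()]); `NULL` accepts the
#'   classes found in the file.
#' @param task task label stored on the returned set.
#' @param lenient downgrade partial-overlap violations to warnings.
#' @return an [annotation_set()] with provenance `"manual"` unless the file
#'   carries a provenance column.
#' @export
read_gold_annotations <- function(path, corpus, classes = NULL,
                                  task = "custom", lenient = FALSE) {
  lf <- read_tsv_lines(path)
  if (!length(lf$lines))
    return(annotation_set(mention_frame(), task = task, classes = classes,
                          corpus = corpus))
  fields <- split_fields(lf$lines)
  nf <- lengths(fields)
  if (any(nf < 6L | nf > 7L)) {
    bad <- which(nf < 6L | nf > 7L)[1]
    stop(sprintf("line %d: expected 6 or 7 fields, got %d",
                 lf$lineno[bad], nf[bad]), call. = FALSE)
  }
  get <- function(k) vapply(fields, function(f) if (length(f) >= k) f[[k]] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(3)))
  end <- suppressWarnings(as.integer(get(4)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("line %d: non-integer offsets", lf$lineno[bad]), call. = FALSE)
  }
  prov <- if (any(nf == 7L)) ifelse(nf == 7L, get(7), "manual") else "manual"
  cls <- get(6)
  cls[!nzchar(cls)] <- NA_character_   # empty class field = unclassed
  m <- mention_frame(get(1), get(2), start, end, get(5), cls, prov)
  tryCatch(
    annotation_set(m, task = task, classes = classes, corpus = corpus,
                   lenient = lenient),
    error = function(e) stop("in ", path, ": ", conditionMessage(e), call. = FALSE))
}

# Parse one prediction line; returns a one-row mention frame or a condition
# string. Shared by read_prediction_run() and validate_submission().
parse_prediction_fields <- function(f) {
  if (length(f) < 4L || length(f) > 6L)
    return(sprintf("expected 4 to 6 fields, got %d", length(f)))
  triple <- strsplit(f[[2]], ":", fixed = TRUE)[[1]]
  if (length(triple) != 3L || !(triple[1] %in% c("T", "A")))
    return(sprintf("malformed span %s (want section:start:end with section T|A)",
                   dQuote(f[[2]])))
  start <- suppressWarnings(as.integer(triple[2]))
  end <- suppressWarnings(as.integer(triple[3]))
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    return(sprintf("invalid span offsets in %s", dQuote(f[[2]])))
  rank <- suppressWarnings(as.integer(f[[3]]))
  if (is.na(rank) || rank < 1L)
    return(sprintf("rank must be a positive integer, got %s", dQuote(f[[3]])))
  conf <- suppressWarnings(as.numeric(f[[4]]))
  if (is.na(conf) || conf < 0 || conf > 1)
    return(sprintf("confidence must be in [0,1], got %s", dQuote(f[[4]])))
  mention_frame(
    doc_id = f[[1]], section = triple[1], start = start, end = end,
    text = if (length(f) >= 5L) f[[5]] else NA_character_,
    class = if (length(f) >= 6L) f[[6]] else NA_character_,
    provenance = "predicted", confidence = conf, rank = rank)
}

#' Read a prediction run
#'
#' Reads the ranked prediction dialect `doc_id <TAB> section:start:end <TAB>
#' rank <TAB> confidence`, optionally extended with trailing text and class
#' fields. Missing surface text is filled from the document slice. Exact
#' duplicate spans are collapsed with a warning.
#'
#' @inheritParams read_gold_annotations
#' @param team_id,run_id identity of the run (run_id in 1..5).
#' @param strict if `TRUE` (default), a prediction addressing a document absent
#'   from the corpus is an error; if `FALSE` it is skipped with a warning.
#' @return a [prediction_run()].
#' @export
read_prediction_run <- function(path, corpus, team_id = "team", run_id = 1L,
                                strict = TRUE) {
  lf <- read_tsv_lines(path)
  rows <- vector("list", length(lf$lines))
  fields <- split_fields(lf$lines)
  for (i in seq_along(fields)) {
    r <- parse_prediction_fields(fields[[i]])
    if (is.character(r))
      stop(sprintf("line %d: %s", lf$lineno[i], r), call. = FALSE)
    rows[[i]] <- r
  }
  m <- if (length(rows)) do.call(rbind, rows) else mention_frame()
  if (nrow(m)) {
    known <- m$doc_id %in% corpus$doc_id
    if (!all(known)) {
      bad <- unique(m$doc_id[!known])
      if (strict)
        stop("prediction for unknown doc_id: ", paste(bad, collapse = ", "),
             call. = FALSE)
      warning("skipping predictions for unknown doc_id: ",
              paste(bad, collapse = ", "), call. = FALSE)
      m <- m[known, , drop = FALSE]
    }
    if (nrow(m)) {
      txt <- section_text(corpus, m$doc_id, m$section)
      if (any(m$end > cp_len(txt)))
        stop("prediction span beyond section end for doc ",
             paste(unique(m$doc_id[m$end > cp_len(txt)]), collapse = ", "),
             call. = FALSE)
      fill <- is.na(m$text)
      m$text[fill] <- cp_slice(txt[fill], m$start[fill], m$end[fill])
    }
  }
  prediction_run(m, team_id = team_id, run_id = run_id)
}

#' Validate a submission of prediction files
#'
#' Runs the structural checks of the prediction dialect over 1 to 5 run files
#' and the per-task run cap, without raising on content problems: every
#' problem is reported as an error or warning entry with its file and line.
#'
#' @param paths character vector of prediction file paths.
#' @param corpus the [corpus()] predictions address.
#' @return a `validation_report` with fields `ok`, `errors`, `warnings`; `ok`
#'   is `TRUE` iff no errors were recorded.
#' @export
validate_submission <- function(paths, corpus) {
  entry <- function(file, line, code, message)
    data.frame(file = file, line = line, code = code, message = message,
               stringsAsFactors = FALSE)
  empty <- entry(character(), integer(), character(), character())
  errors <- list(); warnings <- list()
  if (length(paths) > 5L)
    errors[[length(errors) + 1L]] <-
      entry(NA_character_, NA_integer_, "run_limit",
            sprintf("run limit exceeded: %d files submitted, maximum of five runs per task",
                    length(paths)))
  if (!length(paths))
    errors[[length(errors) + 1L]] <-
      entry(NA_character_, NA_integer_, "no_runs", "no run files supplied")
  for (p in paths) {
    lf <- tryCatch(suppressWarnings(read_tsv_lines(p)),
                   error = function(e) e)
    if (inherits(lf, "error")) {
      errors[[length(errors) + 1L]] <-
        entry(p, NA_integer_, "unreadable", conditionMessage(lf))
      next
    }
    fields <- split_fields(lf$lines)
    seen <- character()
    for (i in seq_along(fields)) {
      r <- parse_prediction_fields(fields[[i]])
      if (is.character(r)) {
        errors[[length(errors) + 1L]] <- entry(p, lf$lineno[i], "malformed", r)
        next
      }
      if (!(r$doc_id %in% corpus$doc_id)) {
        errors[[length(errors) + 1L]] <-
          entry(p, lf$lineno[i], "unknown_doc",
                sprintf("unknown doc_id %s", dQuote(r$doc_id)))
        next
      }
      txt <- section_text(corpus, r$doc_id, r$section)
      if (r$end > cp_len(txt)) {
        errors[[length(errors) + 1L]] <-
          entry(p, lf$lineno[i], "span_range",
                sprintf("span [%d,%d) beyond %s section length %d",
                        r$start, r$end, r$section, cp_len(txt)))
        next
      }
      k <- span_key(r)
      if (k %in% seen)
        warnings[[length(warnings) + 1L]] <-
          entry(p, lf$lineno[i], "duplicate", "duplicate predicted span")
      seen <- c(seen, k)
    }
  }
  errors <- if (length(errors)) do.call(rbind, errors) else empty
  warnings <- if (length(warnings)) do.call(rbind, warnings) else empty
  structure(list(ok = nrow(errors) == 0L, errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %s — %d error(s), %d warning(s)>\n",
              if (x$ok) "OK" else "FAILED", nrow(x$errors), nrow(x$warnings)))
  show <- function(df, label) {
    for (i in seq_len(min(nrow(df), 10L)))
      cat(sprintf("  %s %s:%s [%s] %s\n", label,
                  ifelse(is.na(df$file[i]), "-", df$file[i]),
                  ifelse(is.na(df$line[i]), "-", df$line[i]),
                  df$code[i], df$message[i]))
  }
  show(x$errors, "ERROR"); show(x$warnings, "WARN")
  invisible(x)
}

#' Export an annotation set in the stand-off dialect
#'
#' Writes the gold TSV dialect plus a seventh provenance column. Reading the
#' file back with [read_gold_annotations()] reproduces the mention multiset.
#'
#' @param set an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_standoff <- function(set, path) {
  m <- set$mentions
  lines <- if (nrow(m))
    paste(m$doc_id, m$section, m$start, m$end, m$text,
          ifelse(is.na(m$class), "", m$class), m$provenance, sep = "\t")
  else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_attr_escape <- function(x) gsub('"', "&quot;", html_escape(x), fixed = TRUE)

# Serialize one section's text with its (disjoint, sorted) mentions inlined.
render_section <- function(text, m) {
  if (!nrow(m)) return(html_escape(text))
  m <- m[order(m$start), , drop = FALSE]
  n <- cp_len(text)
  pieces <- character()
  cur <- 0L
  for (i in seq_len(nrow(m))) {
    if (m$start[i] > cur)
      pieces <- c(pieces, html_escape(cp_slice(text, cur, m$start[i])))
    cls_tokens <- c("mention",
                    if (!is.na(m$class[i])) m$class[i],
                    if (m$provenance[i] != "manual") "auto")
    pieces <- c(pieces, sprintf(
      '<span class="%s" data-provenance="%s" data-start="%d" data-end="%d">%s</span>',
      html_attr_escape(paste(cls_tokens, collapse = " ")),
      html_attr_escape(m$provenance[i]), m$start[i], m$end[i],
      html_escape(cp_slice(text, m$start[i], m$end[i]))))
    cur <- m$end[i]
  }
  if (cur < n) pieces <- c(pieces, html_escape(cp_slice(text, cur, n)))
  paste(pieces, collapse = "")
}

#' Export a corpus with inline HTML annotations
#'
#' Writes one UTF-8 HTML file per document with title and abstract in separate
#' container elements carrying the section letter. Each mention is wrapped in
#' a `<span>` whose class attribute carries the annotation class, with data
#' attributes for provenance and offsets; non-manual annotations carry an
#' extra `auto` class token so they are visually distinguishable. Text outside
#' mentions is HTML-escaped, so stripping markup recovers the section text
#' exactly.
#'
#' @param corpus a [corpus()].
#' @param set an [annotation_set()] over that corpus (mentions may not
#'   overlap — inline markup cannot represent overlaps).
#' @param dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
export_inline_html <- function(corpus, set, dir) {
  ov <- find_overlaps(set$mentions)
  if (nrow(ov))
    stop("cannot serialize overlapping mentions inline", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    id <- corpus$doc_id[i]
    sel <- set$mentions$doc_id == id
    body <- sprintf(paste0(
      '<div class="section" data-section="T">%s</div>\n',
      '<div class="section" data-section="A">%s</div>'),
      render_section(corpus$title[i],
                     set$mentions[sel & set$mentions$section == "T", , drop = FALSE]),
      render_section(corpus$abstract[i],
                     set$mentions[sel & set$mentions$section == "A", , drop = FALSE]))
    html <- sprintf(paste0(
      '<!DOCTYPE html>\n<html><head><meta charset="utf-8"/>',
      '<title>%s</title></head>\n<body data-doc-id="%s">\n%s\n</body></html>'),
      html_escape(id), html_attr_escape(id), body)
    files[i] <- file.path(dir, paste0(id, ".html"))
    con <- file(files[i], open = "wb")
    writeLines(enc2utf8(html), con, useBytes = TRUE)
    close(con)
  }
  invisible(files)
}
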