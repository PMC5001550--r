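# Shared in-code fixtures: a tiny hand-built corpus whose offsets are easy to
# verify by eye, plus convenience constructors.

tiny_corpus <- function() {
  corpus(
    doc_id = c("D1", "D2", "D3"),
    title = c("Aspirin salts", "Novel opioid agonists", "Formulae"),
    abstract = c("We tested aspirin and caffeine.",
                 "The opioid morphine binds μ-receptors.",
                 "NaCl dissolved with aspirin."))
}

# gold over tiny_corpus:
#   D1 A [10,17) "aspirin"  TRIVIAL
#   D1 A [22,30) "caffeine" TRIVIAL
#   D2 A [11,19) "morphine" TRIVIAL
#   D2 A [4,10)  "opioid"   FAMILY
#   D3 A [0,4)   "NaCl"     FORMULA
tiny_gold <- function(corp = tiny_corpus()) {
  m <- mentions_df(
    doc_id = c("D1", "D1", "D2", "D2", "D3"),
    section = rep("A", 5),
    start = c(10L, 22L, 11L, 4L, 0L),
    end = c(17L, 30L, 19L, 10L, 4L),
    text = c("aspirin", "caffeine", "morphine", "opioid", "NaCl"),
    class = c("TRIVIAL", "TRIVIAL", "TRIVIAL", "FAMILY", "FORMULA"))
  annotation_set(m, task = "CEMP", corpus = corp)
}

mentions_df <- function(doc_id, section, start, end, text, class = NA,
                        provenance = "manual", confidence = NA_real_,
                        rank = NA_integer_) {
  n <- length(doc_id)
  data.frame(doc_id = doc_id, section = section, start = start, end = end,
             text = text, class = rep_len(class, n),
             provenance = rep_len(provenance, n),
             confidence = rep_len(confidence, n),
             rank = rep_len(rank, n), stringsAsFactors = FALSE)
}

pred_from_gold <- function(gold, team_id = "t", run_id = 1L) {
  prediction_run(gold$mentions, team_id = team_id, run_id = run_id)
}

# Independent micro-score oracle coded straight from the defining equations.
oracle_micro <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) (if (fn == 0) 1 else 0) else tp / (tp + fp)
  r <- if (tp + fn == 0) (if (fp == 0) 1 else 0) else tp / (tp + fn)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, fscore = f)
}

write_lines_utf8 <- function(lines, path = tempfile(fileext = ".tsv")) {
  con <- file(path, open = "wb")
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  close(con)
  path
}
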