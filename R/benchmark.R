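# Benchmarking: ranking prediction runs by micro F-score, estimating the
# sampling variability of each team's F by document-level bootstrap
# resampling, and grouping teams whose scores are not separated by a
# configurable multiple of the bootstrap standard deviation (two SD by
# default, the challenge convention).

#' Select each team's best run
#'
#' Micro-averaged F-score determines the top-scoring run per team; exact ties
#' go to the lower run number.
#'
#' @param gold an [annotation_set()].
#' @param runs list of [prediction_run()]s, possibly several per team.
#' @param class_strict passed to [match_run()].
#' @return named list mapping team_id to its best [prediction_run()].
#' @export
best_run_per_team <- function(gold, runs, class_strict = FALSE) {
  if (!length(runs)) stop("no runs supplied", call. = FALSE)
  teams <- vapply(runs, `[[`, "", "team_id")
  out <- list()
  for (tm in unique(teams)) {
    rs <- runs[teams == tm]
    f <- vapply(rs, function(r)
      micro_scores(match_run(gold, r, class_strict = class_strict))$fscore, 0)
    ids <- vapply(rs, `[[`, 0L, "run_id")
    best <- order(-f, ids)[1]
    out[[tm]] <- rs[[best]]
  }
  out
}

# Per-document (tp, fp, fn) counts for one team, restricted to the frame of
# annotated documents, aligned to `frame_docs`.
frame_counts <- function(gold, run, frame_docs, class_strict = FALSE) {
  m <- match_run(gold, run, class_strict = class_strict)
  idx <- match(frame_docs, m$per_doc$doc_id)
  cbind(tp = ifelse(is.na(idx), 0L, m$per_doc$tp[idx]),
        fp = ifelse(is.na(idx), 0L, m$per_doc$fp[idx]),
        fn = ifelse(is.na(idx), 0L, m$per_doc$fn[idx]))
}

#' Bootstrap the micro F-score of each team
#'
#' The sampling frame is the set of documents with at least one gold
#' annotation. Each bootstrap sample draws that many documents with
#' replacement from the frame — a document drawn twice contributes its counts
#' twice — and the micro F of every team is computed on the same sample, so
#' the resampled scores are directly comparable across teams. The per-team
#' standard deviation of the resampled F-scores (sample SD, n-1 denominator)
#' estimates the variability of the observed score.
#'
#' @param gold an [annotation_set()].
#' @param runs named list mapping team_id to one [prediction_run()] (e.g. from
#'   [best_run_per_team()]).
#' @param n_samples number of bootstrap samples (default 2500).
#' @param seed integer seed; identical seed and inputs give bit-identical
#'   sample lists.
#' @param class_strict passed to [match_run()].
#' @param keep_draws if `TRUE`, attach the `n_samples` x `n_docs` matrix of
#'   drawn frame indices as attribute `draws` (for auditing the shared-sample
#'   contract).
#' @return a `bootstrap_result` data frame, one row per team, ranked by
#'   observed F descending, with columns `team_id`, `run_id`, `observed_f`,
#'   `sd`, `rank`, `group`, and a list-column `samples` of resampled
#'   F-scores. `observed_f` is the micro F over the sampling frame.
#' @export
bootstrap_fscores <- function(gold, runs, n_samples = 2500L, seed = 1L,
                              class_strict = FALSE, keep_draws = FALSE) {
  stopifnot(n_samples >= 2L)
  if (is.null(names(runs)) || any(!nzchar(names(runs))))
    names(runs) <- vapply(runs, `[[`, "", "team_id")
  frame_docs <- unique(gold$mentions$doc_id)
  if (!length(frame_docs))
    stop("no annotated documents to resample", call. = FALSE)
  nd <- length(frame_docs)
  counts <- lapply(runs, frame_counts, gold = gold, frame_docs = frame_docs,
                   class_strict = class_strict)
  draws <- with_seed(seed, matrix(
    sample.int(nd, n_samples * nd, replace = TRUE), nrow = n_samples))
  f_of <- function(ct, w) prf(sum(ct[, "tp"] * w), sum(ct[, "fp"] * w),
                              sum(ct[, "fn"] * w))[["fscore"]]
  w_all <- rep(1L, nd)
  res <- lapply(names(runs), function(tm) {
    ct <- counts[[tm]]
    samples <- vapply(seq_len(n_samples), function(s)
      f_of(ct, tabulate(draws[s, ], nbins = nd)), 0)
    list(team_id = tm, run_id = runs[[tm]]$run_id,
         observed_f = f_of(ct, w_all),
         sd = stats::sd(samples), samples = samples)
  })
  out <- data.frame(
    team_id = vapply(res, `[[`, "", "team_id"),
    run_id = vapply(res, `[[`, 0L, "run_id"),
    observed_f = vapply(res, `[[`, 0, "observed_f"),
    sd = vapply(res, `[[`, 0, "sd"),
    stringsAsFactors = FALSE)
  out$samples <- lapply(res, `[[`, "samples")
  ord <- order(-out$observed_f, out$team_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out <- group_by_significance(out)
  if (keep_draws) attr(out, "draws") <- draws
  attr(out, "n_samples") <- as.integer(n_samples)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("bootstrap_result", "data.frame")
  out
}

#' Group ranked teams by statistical significance
#'
#' Walks the ranking top-down and keeps consecutive teams in the same group
#' while the gap between their observed F-scores is within `k_sd` times the
#' larger of the two bootstrap SDs; a larger gap starts a new group. With the
#' default `k_sd = 2` this clusters systems whose scores are not separated at
#' two standard deviations. `k_sd = 0` separates every distinct score;
#' `k_sd = Inf` merges everything.
#'
#' @param results a data frame ranked by `observed_f` descending, with columns
#'   `observed_f` and `sd` (e.g. a [bootstrap_fscores()] result).
#' @param k_sd the significance multiple.
#' @return `results` with a `group` column of integers starting at 1,
#'   non-decreasing along the ranking.
#' @export
group_by_significance <- function(results, k_sd = 2.0) {
  n <- nrow(results)
  if (!n) { results$group <- integer(); return(results) }
  if (is.unsorted(-results$observed_f))
    stop("results must be ranked by observed_f descending", call. = FALSE)
  if (n == 1L) { results$group <- 1L; return(results) }
  gap <- results$observed_f[-n] - results$observed_f[-1]
  thr <- if (is.infinite(k_sd)) rep(Inf, n - 1L)
         else k_sd * pmax(results$sd[-n], results$sd[-1])
  results$group <- cumsum(c(1L, as.integer(gap > thr)))
  results
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf("<bootstrap_result: %d team(s), %d samples, seed %d>\n",
              nrow(x), attr(x, "n_samples") %||% NA_integer_,
              attr(x, "seed") %||% NA_integer_))
  df <- as.data.frame(x)[, c("rank", "team_id", "run_id", "observed_f", "sd",
                             "group")]
  df$observed_f <- round(df$observed_f, digits)
  df$sd <- signif(df$sd, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# ---- leaderboard -------------------------------------------------------------

#' Fingerprint of a gold standard
#'
#' MD5 over the canonical stand-off export of the set (mentions sorted by
#' document, section, start, end). Leaderboards store this fingerprint so a
#' new run is only ever compared against scores computed on the same gold
#' standard.
#'
#' @param gold an [annotation_set()].
#' @return hex string.
#' @export
gold_fingerprint <- function(gold) {
  m <- gold$mentions
  m <- m[order(m$doc_id, m$section, m$start, m$end), , drop = FALSE]
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  lines <- if (nrow(m))
    paste(m$doc_id, m$section, m$start, m$end, m$text,
          ifelse(is.na(m$class), "", m$class), sep = "\t")
  else character()
  con <- file(tmp, open = "wb")
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Build a leaderboard from bootstrap results
#'
#' @param boot a [bootstrap_fscores()] result over each team's best run.
#' @param gold the [annotation_set()] the scores were computed on.
#' @param runs the named list of runs that produced `boot` (used for
#'   precision/recall of each entry).
#' @param task task label stored in the metadata.
#' @param class_strict passed to [match_run()].
#' @return a `leaderboard` data frame with columns `team_id`, `precision`,
#'   `recall`, `fscore`, `sd`, sorted by `fscore` descending, and metadata
#'   attributes `task`, `fingerprint`, `n_samples`, `seed`.
#' @export
make_leaderboard <- function(boot, gold, runs, task = gold$task,
                             class_strict = FALSE) {
  pr <- lapply(boot$team_id, function(tm) {
    micro_scores(match_run(gold, runs[[tm]], class_strict = class_strict))
  })
  entries <- data.frame(
    team_id = boot$team_id,
    precision = vapply(pr, `[[`, 0, "precision"),
    recall = vapply(pr, `[[`, 0, "recall"),
    fscore = vapply(pr, `[[`, 0, "fscore"),
    sd = boot$sd,
    stringsAsFactors = FALSE)
  entries <- entries[order(-entries$fscore, entries$team_id), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries,
            task = task, fingerprint = gold_fingerprint(gold),
            n_samples = attr(boot, "n_samples"), seed = attr(boot, "seed"),
            class = c("leaderboard", "data.frame"))
}

#' Write or read a leaderboard TSV
#'
#' The file is a TSV of `team_id, precision, recall, fscore, sd` entries,
#' preceded by `#`-prefixed metadata lines recording the task, the gold
#' fingerprint, and the bootstrap settings.
#'
#' @param board a `leaderboard`.
#' @param path file path.
#' @return `path` (write) or a `leaderboard` (read).
#' @export
write_leaderboard <- function(board, path) {
  meta <- sprintf("# %s=%s",
                  c("task", "fingerprint", "n_samples", "seed"),
                  c(attr(board, "task") %||% "custom",
                    attr(board, "fingerprint") %||% "",
                    attr(board, "n_samples") %||% 0L,
                    attr(board, "seed") %||% 0L))
  body <- sprintf("%s\t%.17g\t%.17g\t%.17g\t%.17g", board$team_id,
                  board$precision, board$recall, board$fscore, board$sd)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(meta, body)), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_leaderboard
#' @export
read_leaderboard <- function(path) {
  lf <- read_tsv_lines(path)
  lines <- lf$lines
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = FALSE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  fields <- split_fields(body)
  if (length(fields) && any(lengths(fields) != 5L))
    stop("leaderboard entries need 5 fields", call. = FALSE)
  col <- function(k, f = as.numeric) f(vapply(fields, `[[`, "", k))
  entries <- data.frame(
    team_id = if (length(fields)) col(1, as.character) else character(),
    precision = if (length(fields)) col(2) else numeric(),
    recall = if (length(fields)) col(3) else numeric(),
    fscore = if (length(fields)) col(4) else numeric(),
    sd = if (length(fields)) col(5) else numeric(),
    stringsAsFactors = FALSE)
  structure(entries,
            task = meta$task %||% "custom", fingerprint = meta$fingerprint %||% "",
            n_samples = as.integer(meta$n_samples %||% 0L),
            seed = as.integer(meta$seed %||% 0L),
            class = c("leaderboard", "data.frame"))
}

#' Place a new prediction run into a stored leaderboard
#'
#' Post-workshop mode: scores a new system against the gold standard, runs the
#' bootstrap to estimate its SD, and inserts it into the stored ranking by
#' F-score without recomputing the stored entries (the original submissions
#' are not available). Insertion is stable: a run tying a stored entry's F is
#' placed immediately after it. The two-SD relationship to the adjacent
#' entries is reported as ranking context.
#'
#' @param board a `leaderboard` (its fingerprint must match `gold`).
#' @param gold the [annotation_set()] the board was computed on.
#' @param run the new [prediction_run()].
#' @param n_samples,seed bootstrap settings for the new run's SD.
#' @param k_sd significance multiple for the neighbour context.
#' @param class_strict passed to [match_run()].
#' @return list with `scores` (micro `ner_scores`), `sd`, `rank`, `board`
#'   (the augmented leaderboard) and `context` (data frame of the adjacent
#'   entries with a `separable` flag at `k_sd`).
#' @export
place_new_run <- function(board, gold, run, n_samples = 2500L, seed = 1L,
                          k_sd = 2.0, class_strict = FALSE) {
  fp <- attr(board, "fingerprint")
  if (!is.null(fp) && nzchar(fp) && !identical(fp, gold_fingerprint(gold)))
    stop("corpus fingerprint mismatch: leaderboard was computed on a different gold standard",
         call. = FALSE)
  sc <- micro_scores(match_run(gold, run, class_strict = class_strict))
  boot <- bootstrap_fscores(gold, stats::setNames(list(run), run$team_id),
                            n_samples = n_samples, seed = seed,
                            class_strict = class_strict)
  new_row <- data.frame(team_id = run$team_id, precision = sc$precision,
                        recall = sc$recall, fscore = sc$fscore, sd = boot$sd[1],
                        stringsAsFactors = FALSE)
  rank <- sum(board$fscore >= new_row$fscore) + 1L
  entries <- as.data.frame(board)
  upper <- if (rank > 1L) entries[rank - 1L, , drop = FALSE]
  lower <- if (rank <= nrow(entries)) entries[rank, , drop = FALSE]
  merged <- rbind(
    if (rank > 1L) entries[seq_len(rank - 1L), , drop = FALSE],
    new_row,
    if (rank <= nrow(entries)) entries[rank:nrow(entries), , drop = FALSE])
  rownames(merged) <- NULL
  attributes(merged)[c("task", "fingerprint", "n_samples", "seed")] <-
    attributes(board)[c("task", "fingerprint", "n_samples", "seed")]
  class(merged) <- c("leaderboard", "data.frame")
  ctx <- rbind(upper, lower)
  if (!is.null(ctx) && nrow(ctx)) {
    ctx$separable <- abs(ctx$fscore - new_row$fscore) >
      k_sd * pmax(ctx$sd, new_row$sd)
  }
  list(scores = sc, sd = new_row$sd, rank = rank, board = merged,
       context = ctx)
}

#' @export
print.leaderboard <- function(x, digits = 4, ...) {
  cat(sprintf("<leaderboard: task %s, %d entr%s, fingerprint %s>\n",
              attr(x, "task") %||% "?", nrow(x),
              if (nrow(x) == 1) "y" else "ies",
              substr(attr(x, "fingerprint") %||% "", 1, 8)))
  df <- as.data.frame(x)
  for (cc in c("precision", "recall", "fscore", "sd"))
    df[[cc]] <- round(df[[cc]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
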