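#' Read and write trial tables
#'
#' Trial tables are UTF-8 TSV with a header row and columns
#' `subject_id`, `group`, `condition`, `target`, `response`, and an
#' optional `masker_id`. Targets carry uppercase keywords. TSV (not CSV)
#' avoids quoting commas inside sentences.
#'
#' @param path File path.
#' @return `read_trials` returns the trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  tr <- utils::read.delim(path, header = TRUE, quote = "",
                          colClasses = "character",
                          fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "condition", "target", "response")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("trial file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(tr) == 0L) stop("trial file ", path, " contains no trials")
  tr$response[is.na(tr$response)] <- ""
  tr
}

#' @rdname read_trials
#' @param trials Trial data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a masker sentence inventory
#'
#' Plain text, one sentence per line, one file per condition/talker.
#'
#' @param path File path.
#' @return Character vector of sentences (empty lines dropped).
#' @export
read_maskers <- function(path) {
  if (!file.exists(path)) stop("masker file not found: ", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Content-word inventory of a masker set
#'
#' Tokenizes and tags every masker sentence and collects the unique
#' content words -- as roots (default) or surface norms -- forming the
#' reference set that DNH-Incorrect responses are compared against.
#'
#' @param maskers Character vector of masker sentences.
#' @param lexicon A `spin_lexicon`.
#' @param level `"root"` (default) or `"surface"`.
#' @return Character vector of roots (or norms).
#' @export
masker_root_inventory <- function(maskers, lexicon,
                                  level = c("root", "surface")) {
  level <- match.arg(level)
  words <- unique(unlist(lapply(maskers, tokenize)))
  if (length(words) == 0L) return(character(0))
  hit <- lexicon_lookup(words, lexicon)
  keep <- hit$cls == "content"
  sort(unique(if (level == "root") hit$root[keep] else words[keep]))
}

#' Write per-trial scores as JSON lines
#'
#' One JSON object per trial holding every scored field plus the
#' alignment as `[target_word|null, response_word|null, kind]` triples
#' (absent for DNH trials).
#'
#' @param scores Per-trial score table from [score_trials()] (run with
#'   `keep_alignments = TRUE` to include alignments).
#' @param path Output path.
#' @export
write_trial_json <- function(scores, path) {
  details <- attr(scores, "details")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(scores))) {
    rec <- as.list(scores[i, , drop = FALSE])
    rec <- lapply(rec, function(x) if (is.factor(x)) as.character(x) else x)
    if (!is.null(details)) {
      d <- details[[i]]
      rec$keyword_correct <- d$keyword_correct
      if (!is.null(d$alignment)) {
        p <- alignment_pairs(d$alignment)
        rec$alignment <- lapply(seq_len(nrow(p)), function(k) {
          list(target = p$target[k], response = p$response[k],
               kind = p$kind[k])
        })
        rec$alignment_score <- d$alignment$score
      }
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read per-trial scores back from JSON lines
#'
#' Restores the tabular fields written by [write_trial_json()] (the
#' alignment detail is kept as a list column attribute-free round trip of
#' the summary-relevant fields).
#'
#' @param path JSON-lines file path.
#' @return Per-trial score data frame.
#' @export
read_trial_json <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("score file ", path, " is empty")
  cols <- c("subject_id", "group", "condition", "n_keywords",
            "n_keywords_correct", "dnh_status", "masker_matched",
            "masker_total", "content_sub", "content_add", "content_om",
            "function_sub", "function_add", "function_om",
            "morpheme_errors")
  int_cols <- setdiff(cols, c("subject_id", "group", "condition",
                              "dnh_status"))
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- do.call(rbind, lapply(recs, function(r) {
    vals <- lapply(cols, function(cn) {
      v <- r[[cn]]
      if (is.null(v)) NA else v
    })
    names(vals) <- cols
    as.data.frame(vals, stringsAsFactors = FALSE)
  }))
  for (cn in int_cols) out[[cn]] <- as.integer(out[[cn]])
  out
}

#' Run configuration
#'
#' Bundles the alignment weights and matching options; defaults reproduce
#' the package's reference values (+20/+5/-5/-5, partial distance 2,
#' root-level masker matching).
#'
#' @param weights A [word_weights()] configuration.
#' @param masker_match_level `"root"` (default) or `"surface"`; level at
#'   which DNH-Incorrect content words are compared with the masker
#'   inventory.
#' @param n_perm,seed Permutation-test settings.
#' @return A `run_config` list.
#' @export
run_config <- function(weights = word_weights(),
                       masker_match_level = c("root", "surface"),
                       n_perm = 1000L, seed = 1L) {
  masker_match_level <- match.arg(masker_match_level)
  structure(list(weights = weights,
                 masker_match_level = masker_match_level,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any of the keys `match_reward`,
#'   `partial_reward`, `mismatch_penalty`, `gap_penalty`,
#'   `partial_max_dist`, `masker_match_level`, `n_perm`, `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- word_weights()
  w <- word_weights(
    match_reward = y$match_reward %||% defaults$match_reward,
    partial_reward = y$partial_reward %||% defaults$partial_reward,
    mismatch_penalty = y$mismatch_penalty %||% defaults$mismatch_penalty,
    gap_penalty = y$gap_penalty %||% defaults$gap_penalty,
    partial_max_dist = y$partial_max_dist %||% defaults$partial_max_dist)
  run_config(weights = w,
             masker_match_level = y$masker_match_level %||% "root",
             n_perm = y$n_perm %||% 1000L,
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
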