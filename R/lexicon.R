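#' Forms of the verb "to be"
#'
#' Closed list of be-forms. These words are tagged with their own class
#' (`"be_form"`) because they are excluded from content-word matching when
#' classifying whole-sentence omissions, and are pooled with function words
#' in word-level error counts.
#'
#' @return Character vector of be-forms.
#' @export
be_forms <- function() {
  .be_forms
}

.be_forms <- c("be", "am", "is", "are", "was", "were", "been", "being",
               "'s", "'m", "'re")

#' Load a word-class/root lexicon from TSV
#'
#' The lexicon maps each normalized word to a word class (`content` for
#' nouns, verbs, adjectives and adverbs; `function` for closed-class words;
#' `be_form` for forms of "to be") and a root (lemma) form. An optional
#' fourth column carries a corpus frequency used to rank spell-correction
#' candidates.
#'
#' Every root named in the file must itself be an entry whose root is
#' itself (roots are fixed points), so that root-level matching is well
#' defined.
#'
#' @param path Path to a UTF-8 TSV file with columns
#'   `word<TAB>class<TAB>root[<TAB>frequency]` and no header.
#' @return An object of class `spin_lexicon`: a list with character vectors
#'   `word`, `cls`, `root`, numeric `freq`, and `vocabulary` (= `word`).
#' @examples
#' lex <- load_lexicon(spinerr_lexicon_path())
#' lex
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path)
  }
  if (file.size(path) == 0L) {
    return(new_lexicon(character(), character(), character(), numeric()))
  }
  raw <- utils::read.delim(path, header = FALSE, quote = "",
                           colClasses = "character",
                           fileEncoding = "UTF-8",
                           blank.lines.skip = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    return(new_lexicon(character(), character(), character(), numeric()))
  }
  if (!ncol(raw) %in% c(3L, 4L)) {
    stop("malformed lexicon: expected 3 or 4 tab-separated columns, got ",
         ncol(raw))
  }
  word <- trimws(raw[[1L]])
  cls <- trimws(raw[[2L]])
  root <- trimws(raw[[3L]])
  freq <- if (ncol(raw) == 4L) suppressWarnings(as.numeric(raw[[4L]])) else
    rep(0, nrow(raw))
  bad_cls <- !cls %in% c("content", "function", "be_form")
  if (any(bad_cls)) {
    stop("malformed lexicon row for word '", word[which(bad_cls)[1L]],
         "': unknown class '", cls[which(bad_cls)[1L]], "'")
  }
  if (any(word == "" | root == "")) {
    stop("malformed lexicon: empty word or root field")
  }
  if (anyDuplicated(word)) {
    stop("duplicate lexicon entry: '", word[duplicated(word)][1L], "'")
  }
  if (anyNA(freq)) stop("malformed lexicon: non-numeric frequency field")
  missing_root <- setdiff(root, word)
  if (length(missing_root)) {
    stop("lexicon root '", missing_root[1L],
         "' has no entry of its own (roots must be fixed points)")
  }
  self_root <- root[match(unique(root), word)] == unique(root)
  if (!all(self_root)) {
    stop("lexicon root '", unique(root)[!self_root][1L],
         "' does not map to itself")
  }
  new_lexicon(word, cls, root, freq)
}

new_lexicon <- function(word, cls, root, freq) {
  structure(list(word = word, cls = cls, root = root, freq = freq,
                 vocabulary = word),
            class = "spin_lexicon")
}

#' @export
print.spin_lexicon <- function(x, ...) {
  cat("<spin_lexicon> ", length(x$word), " entries (",
      sum(x$cls == "content"), " content, ",
      sum(x$cls == "function"), " function, ",
      sum(x$cls == "be_form"), " be-form)\n", sep = "")
  invisible(x)
}

#' Path to the packaged fixture lexicon
#'
#' A small (~230 word) lexicon covering the worked examples and the
#' synthetic generator's vocabulary. It is a synthetic stand-in for a full
#' dictionary resource and makes every generated word taggable.
#'
#' @return Path to the installed `lexicon.tsv`.
#' @export
spinerr_lexicon_path <- function() {
  system.file("extdata", "lexicon.tsv", package = "spinerr", mustWork = TRUE)
}

# fast lookup: (cls, root) for a vector of norms; OOV words fall back to
# cls = "content", root = norm; be-forms always win.
lexicon_lookup <- function(norm, lexicon) {
  idx <- match(norm, lexicon$word)
  cls <- lexicon$cls[idx]
  root <- lexicon$root[idx]
  oov <- is.na(idx)
  if (any(oov)) {
    cls[oov] <- "content"
    root[oov] <- norm[oov]
  }
  cls[norm %in% .be_forms] <- "be_form"
  list(cls = cls, root = root)
}
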