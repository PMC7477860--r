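#' Tagged sentence
#'
#' A sentence is a character vector of surface tokens (single characters for
#' Chinese text, but any string token is legal) together with one IOB label
#' per token.
#'
#' @param tokens Character vector of tokens.
#' @param labels Character vector of IOB tags, same length as `tokens`.
#' @param scheme Optional [tag_scheme()]; when supplied, labels are validated
#'   against its closed tag set.
#' @return An object of class `tagged_sentence`.
#' @export
tagged_sentence <- function(tokens, labels = rep("O", length(tokens)),
                            scheme = NULL) {
  tokens <- as.character(tokens)
  labels <- as.character(labels)
  if (length(tokens) != length(labels)) {
    stop_validation("tokens and labels must have equal length")
  }
  if (!is.null(scheme)) tag_indices(labels, scheme)
  structure(list(tokens = tokens, labels = labels), class = "tagged_sentence")
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat(paste(x$tokens, x$labels, sep = "/"), "\n")
  invisible(x)
}

#' Read a two-column CoNLL-style annotated corpus
#'
#' One `token<sep>tag` pair per line, blank lines separating sentences,
#' UTF-8 encoded.  All tags must belong to the scheme's closed tag set.
#'
#' A blank line terminates a sentence; a blank line with no pending token
#' lines records an empty sentence, so [write_conll()] round-trips corpora
#' containing zero-token sentences.
#'
#' @param path File path.
#' @param scheme A [tag_scheme()].
#' @param sep Column separator; TAB by default, `" "` for the single-space
#'   dialect.
#' @return A list of [tagged_sentence()] objects, in file order.
#' @export
read_conll <- function(path, scheme = tag_scheme(), sep = "\t") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  toks <- character()
  labs <- character()
  flush <- function() {
    sentences[[length(sentences) + 1L]] <<- tagged_sentence(toks, labs)
    toks <<- character(); labs <<- character()
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) {
      flush()
      next
    }
    parts <- strsplit(ln, sep, fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[[1]])) {
      stop_validation(
        sprintf("malformed line %d in '%s': expected token%stag", i, path,
                if (sep == "\t") "<TAB>" else sep),
        class = "tcmner_parse_error")
    }
    tag_indices(parts[[2]], scheme)
    toks <- c(toks, parts[[1]])
    labs <- c(labs, parts[[2]])
  }
  if (length(toks)) flush()
  sentences
}

#' Write an annotated corpus in two-column CoNLL format
#'
#' Inverse of [read_conll()]: writing then re-reading is byte-stable for
#' well-formed corpora.
#'
#' @param sentences List of [tagged_sentence()] objects.
#' @param path Output file path.
#' @param sep Column separator (TAB default).
#' @export
write_conll <- function(sentences, path, sep = "\t") {
  blocks <- vapply(sentences, function(s) {
    if (length(s$tokens) == 0) return("\n")
    paste0(paste(s$tokens, s$labels, sep = sep, collapse = "\n"), "\n\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(paste(blocks, collapse = "")), con, sep = "",
             useBytes = TRUE)
}

#' Tokenize raw text at character granularity
#'
#' One token per Unicode code point, whitespace dropped — the granularity at
#' which Chinese clinical text is tagged.
#'
#' @param x Character vector of sentences.
#' @return A list of character vectors (one per input sentence).
#' @export
tokenize_text <- function(x) {
  lapply(strsplit(as.character(x), ""), function(ch) ch[!grepl("^\\s$", ch)])
}

#' Read an unlabeled corpus (one sentence per line)
#'
#' @param path UTF-8 plain-text file, one sentence per line.
#' @return A list of token vectors (character-tokenized, whitespace dropped);
#'   empty lines are skipped.
#' @export
read_unlabeled <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  toks <- tokenize_text(lines)
  toks[vapply(toks, length, 1L) > 0L]
}

#' Convert an IOB label sequence to typed entity spans
#'
#' Each maximal run `B-X (I-X)*` becomes one span of category `X`.  An `I-X`
#' that begins a run (ill-formed model output) is conservatively repaired as
#' if it were `B-X`, so the conversion is total on any sequence drawn from the
#' scheme's tag set.  Spans use 0-based, half-open token intervals.
#'
#' @param labels Character vector of tags.
#' @param scheme A [tag_scheme()].
#' @param tokens Optional token vector; when given, each span carries the
#'   concatenated surface text.
#' @return A data.frame with columns `category`, `start`, `end`, `text`,
#'   sorted by `start`; zero rows for a span-free sentence.
#' @export
tags_to_spans <- function(labels, scheme = tag_scheme(), tokens = NULL) {
  tag_indices(labels, scheme)
  n <- length(labels)
  cat_v <- character(); start_v <- integer(); end_v <- integer()
  open_cat <- NULL
  open_start <- 0L
  close_span <- function(end) {
    cat_v <<- c(cat_v, open_cat)
    start_v <<- c(start_v, open_start)
    end_v <<- c(end_v, end)
    open_cat <<- NULL
  }
  for (i in seq_len(n)) {
    lab <- labels[[i]]
    if (lab == "O") {
      if (!is.null(open_cat)) close_span(i - 1L)
    } else {
      prefix <- substr(lab, 1, 1)
      cat <- substring(lab, 3)
      if (prefix == "B" || is.null(open_cat) || open_cat != cat) {
        # B- opens; orphan I- (run start or category switch) repaired to B-
        if (!is.null(open_cat)) close_span(i - 1L)
        open_cat <- cat
        open_start <- i - 1L
      }
    }
  }
  if (!is.null(open_cat)) close_span(n)
  text_v <- if (is.null(tokens)) rep(NA_character_, length(cat_v)) else {
    vapply(seq_along(cat_v), function(j) {
      paste(tokens[(start_v[j] + 1L):end_v[j]], collapse = "")
    }, character(1))
  }
  data.frame(category = cat_v, start = start_v, end = end_v, text = text_v,
             stringsAsFactors = FALSE)
}

#' Convert non-overlapping entity spans to an IOB label sequence
#'
#' Inverse of [tags_to_spans()] on well-formed input.
#'
#' @param spans data.frame with columns `category`, `start`, `end`
#'   (0-based, half-open).
#' @param length Sentence length in tokens.
#' @param scheme A [tag_scheme()].
#' @return Character vector of `length` tags.
#' @export
spans_to_tags <- function(spans, length, scheme = tag_scheme()) {
  labels <- rep("O", length)
  if (nrow(spans) == 0) return(labels)
  if (!all(spans$category %in% scheme$categories)) {
    bad <- setdiff(spans$category, scheme$categories)[1]
    stop_validation(sprintf("unknown category '%s'", bad),
                    class = "tcmner_tag_error")
  }
  spans <- spans[order(spans$start), , drop = FALSE]
  if (any(spans$start < 0) || any(spans$end > length) ||
      any(spans$start >= spans$end)) {
    stop_validation("span out of bounds or empty")
  }
  if (nrow(spans) > 1 &&
      any(spans$start[-1] < spans$end[-nrow(spans)])) {
    stop_validation("overlapping spans")
  }
  for (j in seq_len(nrow(spans))) {
    s <- spans$start[j] + 1L
    e <- spans$end[j]
    labels[s] <- paste0("B-", spans$category[j])
    if (e > s) labels[(s + 1L):e] <- paste0("I-", spans$category[j])
  }
  labels
}
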