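#' Build a categorized feature-word lexicon from annotated terms
#'
#' For each category, the feature words are the sub-tokens of that category's
#' terms whose occurrence count (raw count inside the category's annotated
#' terms) is strictly greater than the threshold `T`.  Each category also
#' receives one `k`-dimensional standard-Gaussian vector, sampled once from
#' the seed, used by [augment_table()] to fill the appended embedding
#' dimensions.
#'
#' @param terms data.frame with columns `term` and `category` (or a list of
#'   `c(term, category)` pairs).
#' @param threshold Minimum count `T`; comparison is strict (`count > T`).
#' @param k Augmentation dimension.
#' @param seed RNG seed for the per-category Gaussian vectors.
#' @param unit `"char"` (default): feature words are single characters;
#'   `"ngram"`: all substrings up to `ngram_max` characters are counted.
#' @param ngram_max Maximum n-gram length in `"ngram"` mode.
#' @return An object of class `feature_lexicon` with elements `categories`,
#'   `words_by_category`, `gaussian_by_category`, `threshold`, `k`, `seed`,
#'   `unit`, `ngram_max`.  Categories whose feature set is empty after
#'   thresholding are dropped with a warning; if every category is empty,
#'   construction fails with a suggestion to lower `T`.
#' @export
build_lexicon <- function(terms, threshold = 1L, k = 8L, seed = 1L,
                          unit = c("char", "ngram"), ngram_max = 4L) {
  unit <- match.arg(unit)
  if (is.list(terms) && !is.data.frame(terms)) {
    terms <- data.frame(term = vapply(terms, `[`, character(1), 1L),
                        category = vapply(terms, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)
  }
  if (!all(c("term", "category") %in% names(terms)) || nrow(terms) == 0) {
    stop_validation("terms must be a non-empty table with columns term, category")
  }
  if (threshold < 0) stop_validation("threshold T must be >= 0")
  if (k < 1) stop_validation("k must be >= 1")

  subtokens <- function(term) {
    ch <- strsplit(term, "")[[1]]
    if (unit == "char") return(ch)
    n <- length(ch)
    out <- character()
    for (L in seq_len(min(ngram_max, n))) {
      for (s in seq_len(n - L + 1L)) {
        out <- c(out, paste(ch[s:(s + L - 1L)], collapse = ""))
      }
    }
    out
  }

  cats <- sort(unique(terms$category), method = "radix")
  words_by_category <- lapply(cats, function(cat) {
    counts <- table(unlist(lapply(terms$term[terms$category == cat], subtokens)))
    sort(names(counts)[counts > threshold], method = "radix")
  })
  names(words_by_category) <- cats

  keep <- vapply(words_by_category, length, 1L) > 0L
  if (!any(keep)) {
    stop_validation(sprintf(
      "no feature words survive threshold T=%d in any category; try a lower T",
      threshold))
  }
  if (!all(keep)) {
    warning(sprintf("dropping categories with no feature words at T=%d: %s",
                    threshold, paste(cats[!keep], collapse = ", ")))
  }
  cats <- cats[keep]
  words_by_category <- words_by_category[keep]

  gaussian_by_category <- with_seed(seed, {
    g <- lapply(cats, function(cat) rnorm(k))
    names(g) <- cats
    g
  })

  structure(list(categories = cats, words_by_category = words_by_category,
                 gaussian_by_category = gaussian_by_category,
                 threshold = as.integer(threshold), k = as.integer(k),
                 seed = as.integer(seed), unit = unit,
                 ngram_max = as.integer(ngram_max)),
            class = "feature_lexicon")
}

#' @export
print.feature_lexicon <- function(x, ...) {
  cat(sprintf("<feature_lexicon> T=%d k=%d unit=%s; %d categories (%s)\n",
              x$threshold, x$k, x$unit, length(x$categories),
              paste(sprintf("%s:%d", x$categories,
                            vapply(x$words_by_category, length, 1L)),
                    collapse = " ")))
  invisible(x)
}

#' Match feature words against a token sequence
#'
#' In `"char"` mode token `i` carries category `j` iff the token, as a
#' single-character word, is in category `j`'s feature set.  In `"maximal"`
#' mode, forward-maximal matching finds the longest feature word starting at
#' each position and marks every covered token with the matched word's
#' categories.
#'
#' @param tokens Character vector.
#' @param lex A [build_lexicon()] result.
#' @param mode `"char"` or `"maximal"`.
#' @return A list, one element per token, each a character vector of category
#'   names (empty for a non-feature token).
#' @export
match_tokens <- function(tokens, lex, mode = c("char", "maximal")) {
  mode <- match.arg(mode)
  n <- length(tokens)
  out <- rep(list(character(0)), n)
  if (n == 0) return(out)
  cats_of <- function(word) {
    lex$categories[vapply(lex$categories, function(cat) {
      word %in% lex$words_by_category[[cat]]
    }, logical(1))]
  }
  if (mode == "char") {
    for (i in seq_len(n)) out[[i]] <- cats_of(tokens[i])
    return(out)
  }
  maxlen <- max(nchar(unlist(lex$words_by_category)))
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (L in seq(min(maxlen, n - i + 1L), 1L)) {
      w <- paste(tokens[i:(i + L - 1L)], collapse = "")
      cats <- cats_of(w)
      if (length(cats)) {
        for (p in i:(i + L - 1L)) {
          out[[p]] <- sort(union(out[[p]], cats), method = "radix")
        }
        matched <- L
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  out
}

#' Serialize a feature lexicon to a plain-text sidecar file
#'
#' First line is a JSON header carrying `T`, `k`, `seed`, `unit`, `ngram_max`
#' and the per-category Gaussian vectors at full precision; the rest is one
#' `word TAB category` line per membership.  [read_lexicon()] round-trips the
#' lexicon exactly.
#'
#' @param lex A [build_lexicon()] result.
#' @param path Output path.
#' @export
write_lexicon <- function(lex, path) {
  header <- jsonlite::toJSON(
    list(threshold = lex$threshold, k = lex$k, seed = lex$seed,
         unit = lex$unit, ngram_max = lex$ngram_max,
         categories = lex$categories,
         # %.17g round-trips IEEE doubles exactly through text
         gaussian_by_category = lapply(lex$gaussian_by_category, sprintf,
                                       fmt = "%.17g")),
    auto_unbox = TRUE, digits = NA)
  body <- unlist(lapply(lex$categories, function(cat) {
    paste(lex$words_by_category[[cat]], cat, sep = "\t")
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(as.character(header), body)), con, useBytes = TRUE)
}

#' Read a feature lexicon written by [write_lexicon()]
#'
#' @param path File path.
#' @return A `feature_lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  words <- vapply(parts, `[`, character(1), 1L)
  cats <- vapply(parts, `[`, character(1), 2L)
  categories <- as.character(hdr$categories)
  words_by_category <- lapply(categories, function(cat) {
    sort(words[cats == cat], method = "radix")
  })
  names(words_by_category) <- categories
  gaussian <- lapply(categories, function(cat) {
    as.numeric(hdr$gaussian_by_category[[cat]])
  })
  names(gaussian) <- categories
  structure(list(categories = categories,
                 words_by_category = words_by_category,
                 gaussian_by_category = gaussian,
                 threshold = as.integer(hdr$threshold), k = as.integer(hdr$k),
                 seed = as.integer(hdr$seed), unit = hdr$unit,
                 ngram_max = as.integer(hdr$ngram_max)),
            class = "feature_lexicon")
}
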