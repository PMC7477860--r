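#' Embedding table
#'
#' A vocabulary-to-vector map of fixed dimension, stored as a numeric matrix
#' with one row per token.
#'
#' @param vectors Numeric matrix, rownames are the (unique, non-empty) tokens.
#' @param meta Free-text provenance tag (e.g. `"TCM"`, `"mixed lambda=0.5"`).
#' @return An object of class `embedding_table` with elements `dim`,
#'   `vectors`, `meta`.
#' @export
embedding_table <- function(vectors, meta = "") {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) < 1L) stop_validation("embedding dimension must be > 0")
  tok <- rownames(vectors)
  if (is.null(tok) || any(!nzchar(tok))) {
    stop_validation("every vector needs a non-empty token rowname")
  }
  if (anyDuplicated(tok)) stop_validation("vocabulary keys must be unique")
  structure(list(dim = ncol(vectors), vectors = vectors, meta = meta),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens, dim %d%s\n", nrow(x$vectors),
              x$dim, if (nzchar(x$meta)) paste0(" [", x$meta, "]") else ""))
  invisible(x)
}

#' Read an embedding table in word2vec text format
#'
#' Accepts both the headered dialect (first line `"<vocab> <dim>"`) and the
#' header-less dialect (recognized when every line has equal arity).  A
#' duplicated token keeps its last vector, with a warning.
#'
#' @param path UTF-8 text file.
#' @param meta Provenance tag for the resulting table (defaults to the file
#'   name).
#' @return An [embedding_table()].
#' @export
read_word2vec <- function(path, meta = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_validation("empty embedding file")
  fields <- strsplit(lines, "[ \t]+")
  arity <- vapply(fields, length, 1L)
  has_header <- arity[1] == 2L &&
    !is.na(suppressWarnings(as.numeric(fields[[1]][2]))) &&
    (length(arity) == 1L || arity[2] > 2L)
  if (has_header) {
    fields <- fields[-1]
    arity <- arity[-1]
  }
  if (length(fields) == 0) stop_validation("embedding file has no vectors")
  d <- arity[1] - 1L
  bad <- which(arity != d + 1L)
  if (length(bad)) {
    stop_validation(sprintf(
      "inconsistent vector length at line %d of '%s' (expected dim %d)",
      bad[1] + has_header, path, d), class = "tcmner_parse_error")
  }
  tokens <- vapply(fields, `[`, character(1), 1L)
  mat <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(d)))
  if (d == 1L) mat <- matrix(mat, ncol = 1L)
  if (anyDuplicated(tokens)) {
    warning("duplicate tokens in embedding file; keeping the last occurrence")
    keep <- !duplicated(tokens, fromLast = TRUE)
    tokens <- tokens[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  rownames(mat) <- tokens
  embedding_table(mat, meta = meta)
}

#' Write an embedding table in word2vec text format
#'
#' @param table An [embedding_table()].
#' @param path Output path.
#' @param digits Decimal places per coordinate (6, the conventional precision
#'   of word2vec text files).
#' @param header Write the `"<vocab> <dim>"` header line?
#' @export
write_word2vec <- function(table, path, digits = 6, header = TRUE) {
  m <- table$vectors
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i],
          paste(formatC(m[i, ], format = "f", digits = digits),
                collapse = " "))
  }, character(1))
  lines <- c(if (header) sprintf("%d %d", nrow(m), ncol(m)), body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
}

#' Mix two embedding tables with a custom weight
#'
#' For every token in the union vocabulary the mixed vector is
#' `lambda * a[t] + (1 - lambda) * b[t]`; a token missing from one table
#' contributes a zero vector there, so the `lambda = 0` and `lambda = 1`
#' limits reproduce the corresponding input table exactly on its own
#' vocabulary.
#'
#' @param a,b [embedding_table()] objects of equal dimension.
#' @param lambda Mixing weight in `[0, 1]` applied to table `a`.
#' @return An [embedding_table()] over the sorted union vocabulary.
#' @export
mix_tables <- function(a, b, lambda) {
  if (a$dim != b$dim) {
    stop_validation(sprintf("dimension mismatch: %d vs %d", a$dim, b$dim))
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop_validation("lambda must be a single number in [0, 1]")
  }
  vocab <- sort(union(rownames(a$vectors), rownames(b$vectors)), method = "radix")
  pick <- function(tab, tok) {
    m <- matrix(0, length(tok), tab$dim)
    hit <- tok %in% rownames(tab$vectors)
    m[hit, ] <- tab$vectors[tok[hit], , drop = FALSE]
    m
  }
  mixed <- lambda * pick(a, vocab) + (1 - lambda) * pick(b, vocab)
  rownames(mixed) <- vocab
  embedding_table(mixed, meta = sprintf("mixed lambda=%g (%s | %s)",
                                        lambda, a$meta, b$meta))
}

# Appended k-block for one token under a feature lexicon: the mean of the
# Gaussian vectors of the categories whose feature-word set contains the
# token; exactly zero for a non-feature token.
feature_block <- function(token, lex) {
  cats <- lex$categories[vapply(lex$categories, function(cat) {
    token %in% lex$words_by_category[[cat]]
  }, logical(1))]
  if (length(cats) == 0) return(numeric(lex$k))
  blocks <- vapply(cats, function(cat) lex$gaussian_by_category[[cat]],
                   numeric(lex$k))
  rowMeans(matrix(blocks, nrow = lex$k))
}

#' Append feature-word augmentation dimensions to an embedding table
#'
#' Adds `k` coordinates to every vector.  A token that is a feature word
#' receives the mean of the per-category Gaussian vectors of the categories
#' containing it; any other token receives an exactly-zero block.  The
#' original coordinates are unchanged.
#'
#' @param table An [embedding_table()].
#' @param lex A [build_lexicon()] result carrying the per-category Gaussian
#'   vectors.
#' @param k Number of appended dimensions; must equal `lex$k`.
#' @return An [embedding_table()] of dimension `table$dim + k`.
#' @export
augment_table <- function(table, lex, k = lex$k) {
  if (!is.numeric(k) || k < 1) stop_validation("k must be a positive integer")
  if (k != lex$k) {
    stop_validation(sprintf("requested k=%d but the lexicon was built with k=%d",
                            k, lex$k))
  }
  vocab <- rownames(table$vectors)
  blocks <- t(vapply(vocab, feature_block, numeric(lex$k), lex = lex))
  if (lex$k == 1L) blocks <- matrix(blocks, ncol = 1L)
  aug <- cbind(table$vectors, blocks)
  rownames(aug) <- vocab
  embedding_table(aug, meta = sprintf("%s + augmented k=%d", table$meta, lex$k))
}

#' Synthetic random embedding table
#'
#' Draws an independent Gaussian vector per token — a synthetic stand-in for
#' pretrained character vectors, used by the simulation and test pipeline.
#'
#' @param tokens Character vector of vocabulary tokens.
#' @param dim Vector dimension.
#' @param seed RNG seed (generation is deterministic given the seed).
#' @param sd Coordinate standard deviation.
#' @return An [embedding_table()].
#' @export
random_embedding_table <- function(tokens, dim, seed = 1L, sd = 0.5) {
  tokens <- unique(as.character(tokens))
  with_seed(seed, {
    m <- matrix(rnorm(length(tokens) * dim, sd = sd), nrow = length(tokens))
    rownames(m) <- tokens
    embedding_table(m, meta = sprintf("synthetic dim=%d seed=%d", dim, seed))
  })
}

# Embed a token sequence as a T x dim matrix.  Out-of-vocabulary tokens get a
# zero base vector; when a lexicon is supplied (augmented table), their
# appended block still follows the feature-word rule.
embed_tokens <- function(tokens, table, lex = NULL) {
  d <- table$dim
  X <- matrix(0, length(tokens), d)
  if (length(tokens) == 0) return(X)
  hit <- tokens %in% rownames(table$vectors)
  X[hit, ] <- table$vectors[tokens[hit], , drop = FALSE]
  if (!is.null(lex) && any(!hit)) {
    base <- d - lex$k
    if (base < 0) stop_validation("table dimension smaller than lexicon k")
    for (i in which(!hit)) {
      X[i, (base + 1L):d] <- feature_block(tokens[i], lex)
    }
  }
  X
}
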