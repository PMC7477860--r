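# Independent brute-force counter: occurrences of each character within one
# category's terms.
brute_counts <- function(terms, category) {
  chars <- unlist(strsplit(terms$term[terms$category == category], ""))
  table(chars)
}

test_that("feature words are the sub-tokens with count strictly above T", {
  terms <- data.frame(term = rep("头痛", 3), category = "SYM")
  lex <- build_lexicon(terms, threshold = 2L, k = 2L, seed = 1L)
  expect_setequal(lex$words_by_category$SYM, c("头", "痛"))

  # strictness: count 3 is NOT > 3
  expect_error(build_lexicon(terms, threshold = 3L, k = 2L, seed = 1L),
               "lower T", class = "tcmner_validation_error")
})

test_that("per-category counts match a brute-force counter", {
  set.seed(31)
  alphabet <- letters[1:8]
  terms <- data.frame(
    term = replicate(60, paste(sample(alphabet, sample(2:4, 1),
                                      replace = TRUE), collapse = "")),
    category = sample(c("MED", "SYM"), 60, replace = TRUE))
  for (T in 0:3) {
    got <- suppressWarnings(
      tryCatch(build_lexicon(terms, threshold = T, k = 2L, seed = 1L),
               tcmner_validation_error = function(e) NULL))
    for (cat in c("MED", "SYM")) {
      counts <- brute_counts(terms, cat)
      want <- sort(names(counts)[counts > T])
      if (is.null(got)) {
        expect_length(want, 0L)
      } else if (cat %in% got$categories) {
        expect_identical(got$words_by_category[[cat]], want)
      } else {
        expect_length(want, 0L)
      }
    }
  }
})

test_that("raising the threshold never adds a feature word", {
  set.seed(13)
  terms <- data.frame(
    term = replicate(40, paste(sample(letters[1:6], 3, replace = TRUE),
                               collapse = "")),
    category = sample(c("A", "B"), 40, replace = TRUE))
  prev <- build_lexicon(terms, threshold = 0L, k = 2L, seed = 1L)
  for (T in 1:4) {
    cur <- suppressWarnings(
      tryCatch(build_lexicon(terms, threshold = T, k = 2L, seed = 1L),
               tcmner_validation_error = function(e) NULL))
    if (is.null(cur)) break
    for (cat in cur$categories) {
      expect_true(all(cur$words_by_category[[cat]] %in%
                        prev$words_by_category[[cat]]))
    }
    prev <- cur
  }
})

test_that("character-mode matching is per-token set membership", {
  terms <- data.frame(term = c("ab", "ab", "bc", "bc"),
                      category = c("MED", "MED", "SYM", "SYM"))
  lex <- build_lexicon(terms, threshold = 1L, k = 2L, seed = 1L)
  m <- match_tokens(c("x", "a", "b"), lex)
  expect_identical(m[[1]], character(0))
  expect_identical(m[[2]], "MED")
  expect_identical(m[[3]], c("MED", "SYM"))  # hit in two categories
  expect_length(match_tokens(character(0), lex), 0L)
  # category order of the lexicon does not affect matching
  lex2 <- build_lexicon(terms[c(3, 4, 1, 2), ], threshold = 1L, k = 2L,
                        seed = 1L)
  expect_identical(match_tokens(c("x", "a", "b"), lex2), m)
})

test_that("forward-maximal matching agrees with an exhaustive oracle", {
  terms <- data.frame(term = c(rep("abc", 2), rep("ab", 2), rep("cd", 2)),
                      category = c("MED", "MED", "SYM", "SYM", "SYM", "SYM"))
  lex <- build_lexicon(terms, threshold = 1L, k = 2L, seed = 1L,
                       unit = "ngram", ngram_max = 3L)
  tokens <- strsplit("xabcdabq", "")[[1]]
  got <- match_tokens(tokens, lex, mode = "maximal")

  # oracle: scan left to right, take the longest word in the lexicon at each
  # position, mark covered tokens, jump past the match
  words <- unique(unlist(lex$words_by_category))
  cats_of <- function(w) {
    names(Filter(function(ws) w %in% ws, lex$words_by_category))
  }
  want <- rep(list(character(0)), length(tokens))
  i <- 1L
  while (i <= length(tokens)) {
    hit <- 0L
    for (L in rev(seq_len(min(3L, length(tokens) - i + 1L)))) {
      w <- paste(tokens[i:(i + L - 1L)], collapse = "")
      if (w %in% words) {
        for (p in i:(i + L - 1L)) want[[p]] <- sort(union(want[[p]], cats_of(w)))
        hit <- L
        break
      }
    }
    i <- i + max(hit, 1L)
  }
  expect_identical(got, want)
})

test_that("lexicon serialization round-trips exactly", {
  terms <- data.frame(term = c("头痛", "头痛", "桂枝", "桂枝"),
                      category = c("SYM", "SYM", "MED", "MED"))
  lex <- build_lexicon(terms, threshold = 1L, k = 8L, seed = 77L)
  path <- withr::local_tempfile()
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_equal(unclass(back), unclass(lex))
  # Gaussian vectors survive at full precision
  expect_identical(back$gaussian_by_category$MED,
                   lex$gaussian_by_category$MED)
})
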