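toy_table <- function(vecs) {
  embedding_table(do.call(rbind, vecs))
}

test_that("word2vec text reader handles both dialects and bad input", {
  path <- withr::local_tempfile()
  writeLines(c("2 3", "a 1 2 3", "b 4 5 6"), path)
  tab <- read_word2vec(path)
  expect_equal(tab$dim, 3L)
  expect_equal(nrow(tab$vectors), 2L)
  expect_equal(unname(tab$vectors["b", ]), c(4, 5, 6))

  # header-less dialect: every line has equal arity
  writeLines(c("a 1 2 3", "b 4 5 6"), path)
  expect_equal(read_word2vec(path)$vectors, tab$vectors)

  writeLines(c("a 1 2 3", "b 4 5"), path)
  expect_error(read_word2vec(path), "line 2",
               class = "tcmner_validation_error")

  writeLines(c("a 1 2", "a 9 9"), path)
  expect_warning(dup <- read_word2vec(path), "duplicate")
  expect_equal(unname(dup$vectors["a", ]), c(9, 9))
})

test_that("word2vec write -> read preserves vectors to 6 decimals", {
  set.seed(5)
  m <- matrix(rnorm(40), 10, 4)
  rownames(m) <- sprintf("tok%02d", 1:10)
  tab <- embedding_table(m)
  path <- withr::local_tempfile()
  write_word2vec(tab, path)
  back <- read_word2vec(path)
  expect_equal(back$vectors[rownames(m), ], m, tolerance = 5e-7)
  # and header-less write round-trips identically
  write_word2vec(tab, path, header = FALSE)
  expect_equal(read_word2vec(path)$vectors[rownames(m), ], m,
               tolerance = 5e-7)
})

test_that("mix_tables implements the lambda limits and arithmetic exactly", {
  a <- toy_table(list(x = c(1, 0), y = c(2, 2)))
  b <- toy_table(list(x = c(0, 1), z = c(3, 3)))

  lim1 <- mix_tables(a, b, 1)
  expect_equal(lim1$vectors[c("x", "y"), ], a$vectors[c("x", "y"), ])
  expect_equal(unname(lim1$vectors["z", ]), c(0, 0))

  lim0 <- mix_tables(a, b, 0)
  expect_equal(lim0$vectors[c("x", "z"), ], b$vectors[c("x", "z"), ])
  expect_equal(unname(lim0$vectors["y", ]), c(0, 0))

  half <- mix_tables(a, b, 0.5)
  expect_equal(unname(half$vectors["x", ]), c(0.5, 0.5))

  # affine symmetry: swapping arguments and lambda -> 1 - lambda is identical
  expect_equal(mix_tables(a, b, 0.3)$vectors, mix_tables(b, a, 0.7)$vectors)

  expect_error(mix_tables(a, toy_table(list(w = 1:3)), 0.5),
               "dimension", class = "tcmner_validation_error")
  expect_error(mix_tables(a, b, 1.5), class = "tcmner_validation_error")
})

test_that("augmentation fills appended dimensions per the feature-word rule", {
  terms <- data.frame(term = c("ab", "ab", "bc", "bc"),
                      category = c("MED", "MED", "SYM", "SYM"))
  lex <- build_lexicon(terms, threshold = 1L, k = 4L, seed = 9L)
  # a: MED only; b: both; c: SYM only
  tab <- toy_table(list(a = c(1, 2), b = c(3, 4), c = c(5, 6), q = c(7, 8)))
  aug <- augment_table(tab, lex)
  expect_equal(aug$dim, 6L)
  # original coordinates unchanged, elementwise
  expect_equal(aug$vectors[, 1:2], tab$vectors)
  g_med <- lex$gaussian_by_category$MED
  g_sym <- lex$gaussian_by_category$SYM
  # non-feature token: exactly zero block
  expect_identical(unname(aug$vectors["q", 3:6]), rep(0, 4))
  # single membership: that category's Gaussian vector verbatim
  expect_identical(unname(aug$vectors["a", 3:6]), g_med)
  expect_identical(unname(aug$vectors["c", 3:6]), g_sym)
  # double membership: the mean of the two category Gaussians
  expect_equal(unname(aug$vectors["b", 3:6]), (g_med + g_sym) / 2)

  expect_error(augment_table(tab, lex, k = 0), class = "tcmner_validation_error")
})

test_that("augmentation is seed-deterministic", {
  terms <- data.frame(term = rep("ab", 3), category = "MED")
  tab <- toy_table(list(a = c(1, 1)))
  a1 <- augment_table(tab, build_lexicon(terms, 1L, k = 8L, seed = 3L))
  a2 <- augment_table(tab, build_lexicon(terms, 1L, k = 8L, seed = 3L))
  expect_identical(a1$vectors, a2$vectors)
  a3 <- augment_table(tab, build_lexicon(terms, 1L, k = 8L, seed = 4L))
  expect_false(identical(a1$vectors, a3$vectors))
})

test_that("appended Gaussian blocks are standard normal in the aggregate", {
  # many single-term categories -> many independent k-vectors
  n_cat <- 400L
  terms <- data.frame(term = sprintf("x%03da", seq_len(n_cat)),
                      category = sprintf("C%03d", seq_len(n_cat)))
  lex <- build_lexicon(terms, threshold = 0L, k = 8L, seed = 21L)
  draws <- unlist(lex$gaussian_by_category)
  n <- length(draws)
  expect_equal(n, n_cat * 8L)
  expect_lt(abs(mean(draws)), 3 / sqrt(n))
  expect_lt(abs(var(draws) - 1), 4 * sqrt(2 / (n - 1)))
})

test_that("out-of-vocabulary tokens get zero base plus the feature block", {
  terms <- data.frame(term = rep("zz", 2), category = "MED")
  lex <- build_lexicon(terms, threshold = 1L, k = 3L, seed = 2L)
  tab <- augment_table(toy_table(list(a = c(1, 2))), lex)
  X <- tcmner:::embed_tokens(c("a", "z", "w"), tab, lex)
  expect_equal(X[1, ], unname(tab$vectors["a", ]))
  expect_equal(X[2, ], c(0, 0, lex$gaussian_by_category$MED))
  expect_equal(X[3, ], rep(0, 5))
})
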