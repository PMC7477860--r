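test_that("read_conll parses the two-column format and validates tags", {
  path <- withr::local_tempfile()
  writeLines(enc2utf8(c("桂\tB-MED", "枝\tI-MED")), path,
             useBytes = TRUE)
  sents <- read_conll(path)
  expect_length(sents, 1L)
  expect_identical(sents[[1]]$tokens, c("桂", "枝"))
  expect_identical(sents[[1]]$labels, c("B-MED", "I-MED"))

  writeLines(character(0), path)
  expect_length(read_conll(path), 0L)

  writeLines(c("a\tB-XYZ"), path)
  expect_error(read_conll(path), "B-XYZ", class = "tcmner_tag_error")

  writeLines(c("a\tO", "b c d", "e\tO"), path)
  expect_error(read_conll(path), "line 2", class = "tcmner_parse_error")

  writeLines(c("a O", "b I-SYM"), path)
  space <- read_conll(path, sep = " ")
  expect_identical(space[[1]]$labels, c("O", "I-SYM"))
})

test_that("write/read round-trip is byte-stable, including empty sentences", {
  set.seed(101)
  scheme <- tag_scheme()
  corpus <- replicate(100, random_tagged_sentence(scheme), simplify = FALSE)
  corpus <- append(corpus, list(tagged_sentence(character(0))), after = 50)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_conll(corpus, p1)
  back <- read_conll(p1, scheme)
  expect_equal(lapply(back, unclass), lapply(corpus, unclass))
  write_conll(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("tags_to_spans follows the IOB scheme with orphan-I repair", {
  sc <- tag_scheme()
  sp <- tags_to_spans(c("B-MED", "I-MED", "O", "B-SYM"), sc,
                      tokens = c("a", "b", "c", "d"))
  expect_equal(sp$category, c("MED", "SYM"))
  expect_equal(sp$start, c(0L, 3L))
  expect_equal(sp$end, c(2L, 4L))
  expect_equal(sp$text, c("ab", "d"))

  expect_equal(nrow(tags_to_spans(c("O", "O", "O"), sc)), 0L)
  expect_equal(nrow(tags_to_spans(character(0), sc)), 0L)

  # orphan I-DES run start repaired as if it were B-DES
  rep1 <- tags_to_spans(c("I-DES", "I-DES", "O"), sc)
  expect_equal(rep1$category, "DES")
  expect_equal(c(rep1$start, rep1$end), c(0L, 2L))

  # category switch inside an I-run starts a new span
  rep2 <- tags_to_spans(c("B-MED", "I-SYM"), sc)
  expect_equal(rep2$category, c("MED", "SYM"))

  expect_error(tags_to_spans(c("B-MED", "J-MED"), sc),
               class = "tcmner_tag_error")
})

test_that("tags_to_spans agrees with an independent hand-traced oracle", {
  sc <- tag_scheme()
  set.seed(7)
  for (rep in 1:200) {
    n <- sample.int(10, 1)
    labels <- sample(sc$tags, n, replace = TRUE)
    got <- tags_to_spans(labels, sc)
    want <- brute_spans(labels)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$category, vapply(want, `[[`, "", "category"))
      expect_equal(got$start, vapply(want, function(w) w$start, 1L))
      expect_equal(got$end, vapply(want, function(w) w$end, 1L))
    }
    # span count law: one span per B- tag or orphan I- run start
    runs <- sum(grepl("^B-", labels)) +
      sum(vapply(seq_along(labels), function(i) {
        grepl("^I-", labels[i]) &&
          (i == 1 || labels[i - 1] == "O" ||
             sub("^[BI]-", "", labels[i - 1]) != sub("^I-", "", labels[i]))
      }, TRUE))
    expect_equal(nrow(got), runs)
  }
})

test_that("spans_to_tags inverts tags_to_spans and validates input", {
  sc <- tag_scheme()
  expect_equal(
    spans_to_tags(data.frame(category = "MED", start = 0, end = 2), 3, sc),
    c("B-MED", "I-MED", "O"))
  expect_equal(spans_to_tags(data.frame(category = character(0),
                                        start = integer(0),
                                        end = integer(0)), 2, sc),
               c("O", "O"))
  expect_error(
    spans_to_tags(data.frame(category = c("MED", "SYM"), start = c(0, 1),
                             end = c(2, 3)), 4, sc),
    "overlap", class = "tcmner_validation_error")
  expect_error(
    spans_to_tags(data.frame(category = "MED", start = 1, end = 5), 3, sc),
    class = "tcmner_validation_error")

  # round-trip identity over random well-formed sentences, both directions
  set.seed(42)
  for (rep in 1:200) {
    s <- random_tagged_sentence(sc)
    spans <- tags_to_spans(s$labels, sc)
    expect_identical(spans_to_tags(spans, length(s$labels), sc), s$labels)
    back <- tags_to_spans(spans_to_tags(spans, length(s$labels), sc), sc)
    expect_equal(back[c("category", "start", "end")],
                 spans[c("category", "start", "end")])
  }
})

test_that("tokenize_text splits per code point and drops whitespace", {
  toks <- tokenize_text(c("桂 枝", "ab"))
  expect_identical(toks[[1]], c("桂", "枝"))
  expect_identical(toks[[2]], c("a", "b"))
})
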