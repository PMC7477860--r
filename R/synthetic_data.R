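#' Grammar configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure of an annotated
#' Traditional Chinese Medicine corpus: five entity categories with skewed
#' frequencies (medicines and symptoms common, formulas rare), category-
#' specific suffix regularity (a tunable probability that an entity ends in a
#' category-specific marker character — strong for symptoms, absent for
#' formulas), entities embedded in filler text, and an unlabeled pool several
#' times the labeled set.  Sentences are sequences of single-character
#' tokens drawn from disjoint per-category and filler alphabets; the
#' `ambiguity` knob injects entity characters into the filler so the task can
#' be dialed from cleanly separable to realistic.
#'
#' @param categories Entity category codes.
#' @param weights Per-category sampling weights (normalized internally).
#' @param n_entities Distinct entity strings per category lexicon.
#' @param entity_len Range of entity lengths (characters).
#' @param suffix_regularity Per-category probability that an entity ends in
#'   the category's marker character.
#' @param entities_per_sentence Integer range, entities per sentence.
#' @param filler_run Integer range, filler tokens between/around entities.
#' @param ambiguity Probability that a filler token is drawn from the entity
#'   alphabets instead of the filler alphabet.
#' @param filler_alphabet_size Number of distinct filler characters.
#' @param sizes Named token budgets for the four splits (`train`, `dev`,
#'   `test`, `unlabeled`).  The defaults mirror a 20,000-word training set,
#'   3,500-word development set, 5,100-word test set, and a 100,000-word
#'   unlabeled pool (5x the labeled training set).
#' @param entity_lexicon Optional named list of fixed entity string vectors,
#'   overriding the generated lexicons for those categories.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return A list of class `grammar_config`.
#' @export
grammar_config <- function(
    categories = c("MED", "FOL", "SYM", "DES", "PAT"),
    weights = c(MED = 0.30, FOL = 0.10, SYM = 0.30, DES = 0.15, PAT = 0.15),
    n_entities = c(MED = 80, FOL = 20, SYM = 80, DES = 40, PAT = 40),
    entity_len = c(2L, 4L),
    suffix_regularity = c(MED = 0.8, FOL = 0, SYM = 0.9, DES = 0.4, PAT = 0.4),
    entities_per_sentence = c(1L, 3L),
    filler_run = c(2L, 6L),
    ambiguity = 0.15,
    filler_alphabet_size = 256L,
    sizes = c(train = 20000, dev = 3500, test = 5100, unlabeled = 100000),
    entity_lexicon = NULL,
    seed = 1L) {
  weights <- weights[categories]
  n_entities <- n_entities[categories]
  suffix_regularity <- suffix_regularity[categories]
  if (anyNA(weights) || any(weights <= 0)) {
    stop_validation("every category needs a positive frequency weight")
  }
  if (anyNA(sizes[c("train", "dev", "test", "unlabeled")]) || any(sizes <= 0)) {
    stop_validation("all four split sizes must be positive")
  }
  structure(list(categories = categories, weights = weights / sum(weights),
                 n_entities = n_entities, entity_len = as.integer(entity_len),
                 suffix_regularity = suffix_regularity,
                 entities_per_sentence = as.integer(entities_per_sentence),
                 filler_run = as.integer(filler_run), ambiguity = ambiguity,
                 filler_alphabet_size = as.integer(filler_alphabet_size),
                 sizes = sizes, entity_lexicon = entity_lexicon,
                 seed = as.integer(seed)),
            class = "grammar_config")
}

# Disjoint single-character alphabets carved out of the CJK Unified
# Ideographs block: one run per category, one for suffix markers, one for
# filler.  Built at run time so no non-ASCII literals live in source.
grammar_alphabets <- function(cfg) {
  base <- 0x4E00L
  n_cat <- length(cfg$categories)
  per <- 64L
  alpha <- lapply(seq_len(n_cat), function(j) {
    intToUtf8(base + (j - 1L) * per + 0:(per - 1L), multiple = TRUE)
  })
  names(alpha) <- cfg$categories
  markers <- intToUtf8(0x75C5L + seq_len(n_cat) - 1L, multiple = TRUE)
  names(markers) <- cfg$categories
  filler <- intToUtf8(0x5B00L + seq_len(cfg$filler_alphabet_size) - 1L,
                      multiple = TRUE)
  list(entity = alpha, markers = markers, filler = filler)
}

# Entity lexicons: n_entities unique strings per category; with probability
# suffix_regularity an entity ends in the category's marker character.
make_entity_lexicons <- function(cfg, alpha) {
  lex <- list()
  for (cat in cfg$categories) {
    if (!is.null(cfg$entity_lexicon[[cat]])) {
      lex[[cat]] <- cfg$entity_lexicon[[cat]]
      next
    }
    pool <- alpha$entity[[cat]]
    out <- character(0)
    guard <- 0L
    while (length(out) < cfg$n_entities[[cat]] && guard < 10000L) {
      len <- sample(cfg$entity_len[1]:cfg$entity_len[2], 1L)
      ch <- sample(pool, len, replace = TRUE)
      if (runif(1) < cfg$suffix_regularity[[cat]]) {
        ch[len] <- alpha$markers[[cat]]
      }
      out <- unique(c(out, paste(ch, collapse = "")))
      guard <- guard + 1L
    }
    lex[[cat]] <- out
  }
  lex
}

gen_sentence <- function(cfg, alpha, entity_lex, scheme) {
  n_ent <- sample(cfg$entities_per_sentence[1]:cfg$entities_per_sentence[2], 1L)
  filler <- function() {
    n <- sample(cfg$filler_run[1]:cfg$filler_run[2], 1L)
    vapply(seq_len(n), function(i) {
      if (runif(1) < cfg$ambiguity) {
        cat <- sample(cfg$categories, 1L, prob = cfg$weights)
        sample(alpha$entity[[cat]], 1L)
      } else {
        sample(alpha$filler, 1L)
      }
    }, character(1))
  }
  tokens <- filler()
  labels <- rep("O", length(tokens))
  for (e in seq_len(n_ent)) {
    cat <- sample(cfg$categories, 1L, prob = cfg$weights)
    ent <- strsplit(sample(entity_lex[[cat]], 1L), "")[[1]]
    tokens <- c(tokens, ent)
    labels <- c(labels, paste0("B-", cat),
                rep(paste0("I-", cat), length(ent) - 1L))
    fil <- filler()  # guarantees >= 1 filler token between entities
    tokens <- c(tokens, fil)
    labels <- c(labels, rep("O", length(fil)))
  }
  tagged_sentence(tokens, labels)
}

gen_split <- function(cfg, alpha, entity_lex, scheme, budget) {
  sentences <- list()
  total <- 0
  while (total < budget) {
    s <- gen_sentence(cfg, alpha, entity_lex, scheme)
    sentences[[length(sentences) + 1L]] <- s
    total <- total + length(s$tokens)
  }
  sentences
}

#' Generate labeled, development, test and unlabeled corpora
#'
#' Produces four splits with the token budgets in `cfg$sizes`.  The labeled
#' splits are lists of [tagged_sentence()] objects whose labels follow the
#' IOB scheme by construction (entities never overlap and are always
#' separated by at least one filler token); the unlabeled split is text only
#' (a list of token vectors).
#'
#' @param cfg A [grammar_config()].
#' @return A list with elements `train`, `dev`, `test`, `unlabeled`, plus
#'   attribute `"entity_lexicon"` (the sampled per-category entity strings).
#' @export
generate_corpus <- function(cfg = grammar_config()) {
  if (max(cfg$entity_len) > max(cfg$filler_run) * 10 + 100) {
    stop_validation("entity length exceeds any plausible sentence length")
  }
  scheme <- tag_scheme(cfg$categories)
  alpha <- grammar_alphabets(cfg)
  with_seed(cfg$seed, {
    entity_lex <- make_entity_lexicons(cfg, alpha)
    train <- gen_split(cfg, alpha, entity_lex, scheme, cfg$sizes[["train"]])
    dev <- gen_split(cfg, alpha, entity_lex, scheme, cfg$sizes[["dev"]])
    test <- gen_split(cfg, alpha, entity_lex, scheme, cfg$sizes[["test"]])
    unlab <- lapply(
      gen_split(cfg, alpha, entity_lex, scheme, cfg$sizes[["unlabeled"]]),
      function(s) s$tokens)
    structure(list(train = train, dev = dev, test = test, unlabeled = unlab),
              entity_lexicon = entity_lex)
  })
}

#' Entity term list of a grammar
#'
#' Emits the generator's entity lexicons with their categories — the input
#' expected by [build_lexicon()].  Uses the same seed semantics as
#' [generate_corpus()], so the two are consistent.
#'
#' @param cfg A [grammar_config()].
#' @return data.frame with columns `term`, `category`.
#' @export
term_list <- function(cfg = grammar_config()) {
  alpha <- grammar_alphabets(cfg)
  entity_lex <- with_seed(cfg$seed, make_entity_lexicons(cfg, alpha))
  data.frame(
    term = unlist(entity_lex, use.names = FALSE),
    category = rep(names(entity_lex), vapply(entity_lex, length, 1L)),
    stringsAsFactors = FALSE)
}

#' Full character vocabulary of a grammar
#'
#' Every character the generator can emit (entity alphabets, suffix markers
#' and filler), e.g. to build a [random_embedding_table()] covering the
#' corpus.
#'
#' @param cfg A [grammar_config()].
#' @return Character vector.
#' @export
grammar_vocabulary <- function(cfg = grammar_config()) {
  alpha <- grammar_alphabets(cfg)
  extra <- if (is.null(cfg$entity_lexicon)) character(0) else {
    unlist(strsplit(unlist(cfg$entity_lexicon), ""))
  }
  unique(c(unlist(alpha$entity), alpha$markers, alpha$filler, extra))
}
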