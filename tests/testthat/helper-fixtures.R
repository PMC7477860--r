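# Shared fixtures and independent oracles used across the suite.

# Small, cleanly separable grammar: disjoint filler/entity alphabets, no
# ambiguity, few distinct entities -- a model should recover the gold labels
# exactly.
separable_grammar <- function(seed, sizes = c(train = 2000, dev = 400,
                                              test = 400, unlabeled = 400)) {
  grammar_config(ambiguity = 0, filler_alphabet_size = 32L,
                 n_entities = c(MED = 12, FOL = 6, SYM = 12, DES = 8, PAT = 8),
                 sizes = sizes, seed = seed)
}

# Desk-scale "realistic" grammar: moderate ambiguity, suffix-regular
# categories, unlabeled pool 5x the labeled set.
desk_grammar <- function(seed) {
  grammar_config(ambiguity = 0.10, filler_alphabet_size = 48L,
                 sizes = c(train = 2000, dev = 2500, test = 4000,
                           unlabeled = 10000),
                 seed = seed)
}

desk_train_config <- function(seed) {
  train_config(epochs = 60L, batch_size = 8L, learning_rate = 0.015,
               hidden_size = 32L, dropout = 0.2, seed = seed, patience = 15L)
}

# Fast throwaway config for plumbing tests.
tiny_train_config <- function(seed, epochs = 2L) {
  train_config(epochs = epochs, batch_size = 4L, learning_rate = 0.02,
               hidden_size = 8L, dropout = 0, seed = seed, patience = 50L)
}

random_tagged_sentence <- function(scheme, max_len = 12L) {
  n <- sample.int(max_len, 1L)
  labels <- character(n)
  i <- 1L
  while (i <= n) {
    if (runif(1) < 0.5) {
      labels[i] <- "O"
      i <- i + 1L
    } else {
      cat <- sample(scheme$categories, 1L)
      len <- min(sample.int(3L, 1L), n - i + 1L)
      labels[i] <- paste0("B-", cat)
      if (len > 1L) labels[(i + 1L):(i + len - 1L)] <- paste0("I-", cat)
      i <- i + len
    }
  }
  tagged_sentence(sprintf("t%02d", seq_len(n)), labels)
}

# Brute-force CRF oracle: enumerate all K^T paths.
enumerate_paths <- function(n_tok, n_tag) {
  as.matrix(expand.grid(rep(list(seq_len(n_tag)), n_tok)))
}

brute_path_score <- function(E, A, y) {
  K <- ncol(E); s_idx <- K + 1L; p_idx <- K + 2L
  sc <- A[s_idx, y[1]] + E[1, y[1]]
  for (t in seq_along(y)[-1]) sc <- sc + A[y[t - 1], y[t]] + E[t, y[t]]
  sc + A[y[length(y)], p_idx]
}

# Brute-force span oracle: hand-traced IOB reading with conservative orphan-I
# repair, written independently of tags_to_spans.
brute_spans <- function(labels) {
  out <- list()
  cur <- NULL
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    if (lab == "O") {
      if (!is.null(cur)) { out[[length(out) + 1L]] <- cur; cur <- NULL }
    } else {
      cat <- sub("^[BI]-", "", lab)
      starts <- grepl("^B-", lab) || is.null(cur) || cur$category != cat
      if (starts) {
        if (!is.null(cur)) out[[length(out) + 1L]] <- cur
        cur <- list(category = cat, start = i - 1L, end = i)
      } else {
        cur$end <- i
      }
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  out
}
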