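#' Training configuration for the BiLSTM-CRF tagger
#'
#' Conventional BiLSTM-CRF defaults; every stochastic choice (initialization,
#' shuffling, dropout) is fixed by `seed`.
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Sentences per gradient step.
#' @param learning_rate Adam step size.
#' @param hidden_size LSTM hidden units per direction (`H`).
#' @param dropout Dropout probability on the encoder output (training only).
#' @param seed RNG seed controlling all stochastic choices.
#' @param patience Early-stopping patience, in epochs without a development
#'   entity-F1 improvement (ignored when no development set is given).
#' @param finetune_embeddings Update the embedding table during training?
#'   (Frozen by default: vectors are a preprocessing artifact.)
#' @param mask_illegal Mask IOB-illegal transitions at `-Inf`?
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 16L, learning_rate = 1e-3,
                         hidden_size = 100L, dropout = 0.5, seed = 1L,
                         patience = 10L, finetune_embeddings = FALSE,
                         mask_illegal = TRUE) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              hidden_size = as.integer(hidden_size), dropout = dropout,
              seed = as.integer(seed), patience = as.integer(patience),
              finetune_embeddings = isTRUE(finetune_embeddings),
              mask_illegal = isTRUE(mask_illegal))
  if (cfg$epochs < 1 || cfg$batch_size < 1 || cfg$hidden_size < 1 ||
      cfg$learning_rate <= 0 || cfg$dropout < 0 || cfg$dropout >= 1) {
    stop_validation("invalid training configuration")
  }
  structure(cfg, class = "train_config")
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# Parameter initialization; forget-gate biases start at 1 (standard practice
# so early cell states are retained).
init_params <- function(scheme, input_dim, cfg) {
  H <- cfg$hidden_size
  K <- length(scheme$tags)
  bf <- numeric(4 * H); bf[(H + 1):(2 * H)] <- 1
  list(w_fx = glorot(4 * H, input_dim), w_fh = glorot(4 * H, H), b_f = bf,
       w_bx = glorot(4 * H, input_dim), w_bh = glorot(4 * H, H), b_b = bf,
       w_p = glorot(K, 2 * H), b_p = numeric(K),
       trans = make_transitions(scheme, cfg$mask_illegal))
}

zeros_like <- function(params) {
  lapply(params, function(p) { p[] <- 0; p })
}

adam_new <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(opt = opt, params = params)
}

#' Per-tag emission scores for one sentence (eval mode)
#'
#' Embeds the tokens through the model's (augmented) table, encodes them with
#' the bidirectional LSTM and projects to per-tag scores.  Deterministic: no
#' dropout is applied.
#'
#' @param model A [train_tagger()] result.
#' @param tokens Character vector of tokens (may be empty).
#' @return A `length(tokens) x |tags|` matrix.
#' @export
emissions <- function(model, tokens) {
  X <- embed_tokens(tokens, model$table, model$lex)
  p <- model$params
  cpp_bilstm_emissions(X, p$w_fx, p$w_fh, p$b_f, p$w_bx, p$w_bh, p$b_b,
                       p$w_p, p$b_p)
}

sentence_tokens <- function(s) if (inherits(s, "tagged_sentence")) s$tokens else s

# One pass over a corpus computing mean loss and accumulated gradients.
# Returns params updated batch-by-batch with Adam.
run_epoch <- function(state, Xs, ys, cfg, trainable_trans) {
  n <- length(Xs)
  ord <- sample.int(n)
  batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
  epoch_loss <- 0
  H2 <- 2L * cfg$hidden_size
  for (batch in batches) {
    gacc <- NULL
    bloss <- 0
    for (idx in batch) {
      X <- Xs[[idx]]
      dm <- if (cfg$dropout > 0) {
        matrix((runif(nrow(X) * H2) >= cfg$dropout) / (1 - cfg$dropout),
               nrow(X), H2)
      } else {
        matrix(0, 0, 0)
      }
      p <- state$params
      res <- cpp_tagger_grad(X, p$w_fx, p$w_fh, p$b_f, p$w_bx, p$w_bh, p$b_b,
                             p$w_p, p$b_p, p$trans, ys[[idx]] - 1L, dm,
                             cfg$finetune_embeddings)
      if (!is.finite(res$loss)) {
        stop_runtime(sprintf(
          "non-finite training loss on sentence %d (length %d); check that gold labels respect the transition mask",
          idx, nrow(X)))
      }
      bloss <- bloss + res$loss
      g <- res[c("w_fx", "w_fh", "b_f", "w_bx", "w_bh", "b_b", "w_p", "b_p",
                 "trans")]
      if (is.null(gacc)) gacc <- zeros_like(g)
      for (nm in names(g)) gacc[[nm]] <- gacc[[nm]] + g[[nm]] / length(batch)
      if (cfg$finetune_embeddings) state$emb_grad[[idx]] <- res$d_x
    }
    gacc$trans[!trainable_trans] <- 0
    st <- adam_step(state$opt, state$params, gacc, cfg$learning_rate)
    state$opt <- st$opt
    state$params <- st$params
    state$params$trans[!trainable_trans] <-
      state$init_trans[!trainable_trans]
    epoch_loss <- epoch_loss + bloss
  }
  state$loss <- epoch_loss / n
  state
}

#' Train a BiLSTM-CRF tagger
#'
#' Maximizes the mean CRF log-likelihood of the corpus by Adam, tracking
#' entity-level micro-F1 on the development set after every epoch and
#' returning the checkpoint with the best development F1 (early stopping
#' after `cfg$patience` epochs without improvement).  Fully reproducible
#' given `cfg$seed`.
#'
#' @param corpus Non-empty list of [tagged_sentence()] objects.
#' @param dev Development corpus (may be empty: then the final epoch's
#'   parameters are returned and no early stopping is applied).
#' @param table [embedding_table()] used to embed tokens (already augmented
#'   when a lexicon is in play).
#' @param lex Optional [build_lexicon()] result, used to embed
#'   out-of-vocabulary feature tokens.
#' @param cfg A [train_config()].
#' @param scheme A [tag_scheme()].
#' @return An object of class `tagger_model` (scheme, table, lexicon, config,
#'   parameters, and a per-epoch `history` data.frame with columns `epoch`,
#'   `loss`, `dev_f1`).
#' @export
train_tagger <- function(corpus, dev = list(), table, lex = NULL,
                         cfg = train_config(), scheme = tag_scheme()) {
  if (length(corpus) == 0) stop_validation("training corpus is empty")
  corpus <- corpus[vapply(corpus, function(s) length(s$tokens) > 0, TRUE)]
  Xs <- lapply(corpus, function(s) embed_tokens(s$tokens, table, lex))
  ys <- lapply(corpus, function(s) tag_indices(s$labels, scheme))

  with_seed(cfg$seed, {
    params <- init_params(scheme, table$dim, cfg)
    trainable_trans <- is.finite(params$trans)
    state <- list(params = params, opt = adam_new(params),
                  init_trans = params$trans, emb_grad = list())
    best <- list(f1 = -Inf, params = params, epoch = 0L)
    since_best <- 0L
    hist_loss <- numeric(0)
    hist_f1 <- numeric(0)

    for (epoch in seq_len(cfg$epochs)) {
      state <- run_epoch(state, Xs, ys, cfg, trainable_trans)
      if (cfg$finetune_embeddings) {
        # accumulate input gradients back into the shared table rows
        gt <- matrix(0, nrow(table$vectors), table$dim,
                     dimnames = dimnames(table$vectors))
        for (i in seq_along(corpus)) {
          gx <- state$emb_grad[[i]]
          if (is.null(gx)) next
          hit <- corpus[[i]]$tokens %in% rownames(gt)
          for (r in which(hit)) {
            gt[corpus[[i]]$tokens[r], ] <- gt[corpus[[i]]$tokens[r], ] + gx[r, ]
          }
        }
        table$vectors <- table$vectors - cfg$learning_rate * gt / length(corpus)
        Xs <- lapply(corpus, function(s) embed_tokens(s$tokens, table, lex))
      }
      hist_loss <- c(hist_loss, state$loss)
      if (length(dev)) {
        m <- new_tagger_model(scheme, table, lex, cfg, state$params,
                              history = NULL)
        pred <- predict_tags(m, dev)
        f1 <- evaluate_corpus(dev, pred, scheme)$total["f1"]
        hist_f1 <- c(hist_f1, f1)
        if (f1 > best$f1) {
          best <- list(f1 = f1, params = state$params, epoch = epoch)
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= cfg$patience) break
        }
      } else {
        hist_f1 <- c(hist_f1, NA_real_)
        best$params <- state$params
      }
    }
    history <- data.frame(epoch = seq_along(hist_loss), loss = hist_loss,
                          dev_f1 = hist_f1)
    new_tagger_model(scheme, table, lex, cfg, best$params, history)
  })
}

new_tagger_model <- function(scheme, table, lex, cfg, params, history) {
  structure(list(scheme = scheme, table = table, lex = lex, cfg = cfg,
                 params = params, history = history),
            class = "tagger_model")
}

#' @export
print.tagger_model <- function(x, ...) {
  cat(sprintf("<tagger_model> %d tags, H=%d, input dim %d\n",
              length(x$scheme$tags), x$cfg$hidden_size, x$table$dim))
  if (!is.null(x$history) && nrow(x$history)) {
    cat(sprintf("  trained %d epochs; best dev F1 %.4f\n", nrow(x$history),
                suppressWarnings(max(x$history$dev_f1, na.rm = TRUE))))
  }
  invisible(x)
}

#' Predict IOB labels for sentences
#'
#' Decodes each sentence exactly with Viterbi over the model's emissions.
#'
#' @param model A [train_tagger()] result.
#' @param sentences List of token vectors or [tagged_sentence()] objects
#'   (existing labels are ignored).
#' @param confidence Also return each sentence's normalized path probability
#'   `exp(score - logZ)` as attribute `"confidence"`?
#' @return A list of [tagged_sentence()] objects, same length as the input.
#' @export
predict_tags <- function(model, sentences, confidence = FALSE) {
  lapply(sentences, function(s) {
    tokens <- sentence_tokens(s)
    if (length(tokens) == 0) {
      out <- tagged_sentence(character(0), character(0))
      if (confidence) attr(out, "confidence") <- 1
      return(out)
    }
    E <- emissions(model, tokens)
    v <- viterbi_decode(E, model$params$trans)
    out <- tagged_sentence(tokens, model$scheme$tags[v$labels])
    if (confidence) {
      attr(out, "confidence") <-
        exp(v$score - crf_log_partition(E, model$params$trans))
    }
    out
  })
}

#' Save / load a tagger checkpoint
#'
#' The checkpoint is a single archive holding the scheme, configuration,
#' lexicon, embedding table and all parameter tensors; save, load and predict
#' is bit-stable in eval mode.
#'
#' @param model A `tagger_model`.
#' @param path Checkpoint path.
#' @export
save_tagger <- function(model, path) saveRDS(model, path)

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "tagger_model")) stop_validation("not a tagger checkpoint")
  m
}
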