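#' Configuration for two-phase self-training
#'
#' @param phase1,phase2 [train_config()] blocks for the two training phases.
#'   Their seeds are overridden deterministically from `seed` so the whole
#'   procedure is reproducible from one number.
#' @param merge_mode `"concat"` (default; plain concatenation of labeled and
#'   pseudo-labeled sentences) or `"confidence"` (keep only pseudo-labeled
#'   sentences whose normalized Viterbi path probability reaches
#'   `confidence_floor`).
#' @param confidence_floor Path-probability threshold in `(0, 1]`, required
#'   when `merge_mode = "confidence"`.
#' @param seed Master seed.
#' @return A list of class `self_train_config`.
#' @export
self_train_config <- function(phase1 = train_config(),
                              phase2 = train_config(),
                              merge_mode = c("concat", "confidence"),
                              confidence_floor = NULL, seed = 1L) {
  merge_mode <- match.arg(merge_mode)
  if (merge_mode == "confidence") {
    if (is.null(confidence_floor) || confidence_floor <= 0 ||
        confidence_floor > 1) {
      stop_validation("confidence_floor must lie in (0, 1]")
    }
  }
  structure(list(phase1 = phase1, phase2 = phase2, merge_mode = merge_mode,
                 confidence_floor = confidence_floor, seed = as.integer(seed)),
            class = "self_train_config")
}

#' Two-phase self-training
#'
#' Phase 1 trains a tagger on the labeled corpus.  The Phase-1 model then
#' pseudo-labels the unlabeled pool; the pseudo-labeled sentences are merged
#' with the original labeled corpus (plain concatenation by default), and
#' Phase 2 trains a fresh tagger on the union.  The development set tunes
#' both phases (early stopping / checkpoint selection).  Pseudo-labeled
#' sentences carry attribute `"provenance" = "pseudo"` so they can never be
#' silently scored as gold.
#'
#' @param labeled Non-empty list of [tagged_sentence()] objects.
#' @param unlabeled Non-empty list of token vectors (or sentences; labels are
#'   ignored).
#' @param dev Non-empty development corpus.
#' @param test Optional held-out test corpus evaluated for both phases.
#' @param table [embedding_table()].
#' @param lex Optional [build_lexicon()] result.
#' @param cfg A [self_train_config()].
#' @param scheme A [tag_scheme()].
#' @return A list of class `self_train_result`: `phase1`, `phase2` (tagger
#'   models) and `report` (corpus sizes, pseudo-label statistics, per-phase
#'   dev/test metrics, config echo).
#' @export
self_train <- function(labeled, unlabeled, dev, test = NULL, table,
                       lex = NULL, cfg = self_train_config(),
                       scheme = tag_scheme()) {
  if (length(unlabeled) == 0) stop_validation("unlabeled pool is empty")
  if (length(dev) == 0) stop_validation("development set is empty")
  cfg$phase1$seed <- cfg$seed
  cfg$phase2$seed <- cfg$seed + 1L

  phase1 <- train_tagger(labeled, dev, table, lex, cfg$phase1, scheme)
  pseudo <- predict_tags(phase1, unlabeled,
                         confidence = cfg$merge_mode == "confidence")
  pseudo <- lapply(pseudo, function(s) { attr(s, "provenance") <- "pseudo"; s })
  n_pseudo_terms <- sum(vapply(pseudo, function(s) {
    nrow(tags_to_spans(s$labels, scheme))
  }, 1L))

  if (cfg$merge_mode == "confidence") {
    conf <- vapply(pseudo, function(s) attr(s, "confidence"), numeric(1))
    kept <- pseudo[conf >= cfg$confidence_floor]
    if (length(kept) == 0) {
      warning("no pseudo-labeled sentence reaches the confidence floor; ",
              "phase 2 degenerates to a retrain on the labeled corpus")
    }
    merged <- c(labeled, kept)
  } else {
    kept <- pseudo
    merged <- c(labeled, pseudo)
  }

  phase2 <- train_tagger(merged, dev, table, lex, cfg$phase2, scheme)

  metrics <- function(model) {
    out <- list(dev = evaluate_corpus(dev, predict_tags(model, dev), scheme))
    if (!is.null(test)) {
      out$test <- evaluate_corpus(test, predict_tags(model, test), scheme)
    }
    out
  }
  report <- list(
    sizes = c(labeled = length(labeled), unlabeled = length(unlabeled),
              pseudo_kept = length(kept), merged = length(merged),
              dev = length(dev), test = length(test)),
    pseudo_term_count = n_pseudo_terms,
    phase1 = metrics(phase1), phase2 = metrics(phase2),
    config = list(merge_mode = cfg$merge_mode,
                  confidence_floor = cfg$confidence_floor, seed = cfg$seed,
                  phase1 = unclass(cfg$phase1), phase2 = unclass(cfg$phase2)))
  structure(list(phase1 = phase1, phase2 = phase2, report = report),
            class = "self_train_result")
}

#' @export
print.self_train_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<self_train_result> %d labeled + %d pseudo (of %d unlabeled)\n",
              r$sizes[["labeled"]], r$sizes[["pseudo_kept"]],
              r$sizes[["unlabeled"]]))
  line <- function(phase) {
    m <- r[[phase]]
    cat(sprintf("  %s: dev F1 %.4f%s\n", phase, m$dev$total[["f1"]],
                if (!is.null(m$test)) {
                  sprintf(", test F1 %.4f", m$test$total[["f1"]])
                } else ""))
  }
  line("phase1"); line("phase2")
  invisible(x)
}

#' Render a self-training report as JSON
#'
#' @param result A [self_train()] result.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
self_train_report_json <- function(result, path = NULL) {
  r <- result$report
  block <- function(m) {
    out <- list(dev = jsonlite::fromJSON(report_to_json(m$dev)))
    if (!is.null(m$test)) out$test <- jsonlite::fromJSON(report_to_json(m$test))
    out
  }
  obj <- list(sizes = as.list(r$sizes), pseudo_term_count = r$pseudo_term_count,
              phase1 = block(r$phase1), phase2 = block(r$phase2),
              config = r$config)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
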