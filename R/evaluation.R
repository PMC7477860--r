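#' Harmonic mean of precision and recall
#'
#' `2pr/(p+r)`, defined as 0 when `p + r = 0`.
#'
#' @param p,r Precision and recall, both in `[0, 1]`.
#' @return The F1 value.
#' @export
f1_score <- function(p, r) {
  if (!is.numeric(p) || !is.numeric(r) || any(p < 0 | p > 1) ||
      any(r < 0 | r > 1)) {
    stop_validation("precision and recall must lie in [0, 1]")
  }
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1_score(p, r))
}

#' Entity-level evaluation of a predicted corpus against gold
#'
#' A predicted span counts as a true positive iff a gold span with identical
#' category, start and end exists (exact match; no partial credit).  Counts
#' are accumulated over sentences; the `Total` row is micro-averaged (summed
#' TP/FP/FN, not averaged ratios).  Ill-formed predicted IOB runs are
#' repaired by [tags_to_spans()] before matching.
#'
#' @param gold,pred Aligned lists of [tagged_sentence()] objects: same
#'   sentence count and identical token sequences.
#' @param scheme A [tag_scheme()].
#' @return An object of class `eval_report`: `per_category` (data.frame with
#'   one row per category: tp, fp, fn, precision, recall, f1) and `total`
#'   (named numeric with the same fields).
#' @export
evaluate_corpus <- function(gold, pred, scheme = tag_scheme()) {
  if (length(gold) != length(pred)) {
    stop_validation(sprintf("corpus size mismatch: %d gold vs %d predicted",
                            length(gold), length(pred)))
  }
  cats <- scheme$categories
  tp <- fp <- fn <- setNames(numeric(length(cats)), cats)
  for (i in seq_along(gold)) {
    g <- gold[[i]]; p <- pred[[i]]
    if (!identical(g$tokens, p$tokens)) {
      stop_validation(sprintf(
        "gold and predicted corpora diverge at sentence %d (tokens differ)", i))
    }
    gs <- tags_to_spans(g$labels, scheme)
    ps <- tags_to_spans(p$labels, scheme)
    gkey <- paste(gs$category, gs$start, gs$end)
    pkey <- paste(ps$category, ps$start, ps$end)
    hit <- pkey %in% gkey
    for (cat in cats) {
      tp[cat] <- tp[cat] + sum(hit & ps$category == cat)
      fp[cat] <- fp[cat] + sum(!hit & ps$category == cat)
      fn[cat] <- fn[cat] + sum(!(gkey %in% pkey) & gs$category == cat)
    }
  }
  per <- t(vapply(cats, function(cat) prf(tp[[cat]], fp[[cat]], fn[[cat]]),
                  numeric(6)))
  per <- data.frame(category = cats, per, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(per_category = per, total = prf(sum(tp), sum(fp), sum(fn))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  per <- x$per_category[order(x$per_category$category), , drop = FALSE]
  rows <- rbind(per[, -1], Total = x$total)
  labels <- c(per$category, "Total")
  cat(sprintf("%-6s %5s %5s %5s %10s %8s %8s\n", "", "TP", "FP", "FN",
              "Precision", "Recall", "F1"))
  for (i in seq_len(nrow(rows))) {
    cat(sprintf("%-6s %5.0f %5.0f %5.0f %10.4f %8.4f %8.4f\n", labels[i],
                rows$tp[i], rows$fp[i], rows$fn[i],
                round(rows$precision[i], digits), round(rows$recall[i], digits),
                round(rows$f1[i], digits)))
  }
  invisible(x)
}

#' Render an evaluation report as JSON
#'
#' Ratios are rounded half-even to 4 decimals, the precision at which such
#' results are conventionally reported.
#'
#' @param report An [evaluate_corpus()] result.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  rnd <- function(v) {
    v[c("precision", "recall", "f1")] <- round(v[c("precision", "recall", "f1")], 4)
    as.list(v)
  }
  per <- lapply(seq_len(nrow(report$per_category)), function(i) {
    rnd(unlist(report$per_category[i, -1]))
  })
  names(per) <- report$per_category$category
  obj <- list(per_category = per, total = rnd(report$total))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
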