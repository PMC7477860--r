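#' Transition matrix for a linear-chain CRF with virtual START/STOP states
#'
#' Builds the `(|tags|+2) x (|tags|+2)` transition matrix (zeros by default)
#' with the last two rows/columns reserved for the virtual START and STOP
#' states.  With `mask_illegal = TRUE` (default), transitions that are
#' ill-formed under the IOB scheme — `START -> I-X`, `O -> I-X`, and
#' `B-X/I-X -> I-Y` for `X != Y` — are fixed at `-Inf`, so neither decoding
#' nor the partition function can ever use them.
#'
#' @param scheme A [tag_scheme()].
#' @param mask_illegal Mask IOB-illegal bigrams at `-Inf`?
#' @return A numeric matrix with dimnames `c(tags, "START", "STOP")`.
#' @export
make_transitions <- function(scheme, mask_illegal = TRUE) {
  tags <- scheme$tags
  K <- length(tags)
  nm <- c(tags, "START", "STOP")
  A <- matrix(0, K + 2, K + 2, dimnames = list(nm, nm))
  if (mask_illegal) {
    for (cat in scheme$categories) {
      itag <- paste0("I-", cat)
      ok_prev <- c(paste0("B-", cat), itag)
      A[setdiff(nm, c(ok_prev, "STOP")), itag] <- -Inf
    }
  }
  A
}

check_crf_args <- function(emissions, transitions, labels = NULL) {
  K <- ncol(emissions)
  if (nrow(transitions) != K + 2 || ncol(transitions) != K + 2) {
    stop_validation(sprintf(
      "transitions must be (%d+2) x (%d+2) for %d tags", K, K, K))
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(emissions)) {
      stop_validation("labels length must equal the number of emission rows")
    }
    if (length(labels) && (min(labels) < 1 || max(labels) > K)) {
      stop_validation("label indices out of range")
    }
  }
  invisible(TRUE)
}

#' Exact CRF log-likelihood of a label sequence
#'
#' `score(labels) - logZ`, where the path score sums emission and transition
#' terms (including the virtual START/STOP transitions) and `logZ` is the
#' exact log-partition function computed by the forward algorithm in
#' log-space with per-position log-sum-exp stabilization.  Always `<= 0`.
#'
#' @param emissions `T x K` matrix of per-tag scores.
#' @param transitions `(K+2) x (K+2)` matrix from [make_transitions()].
#' @param labels Integer vector of 1-based tag indices, length `T`.
#' @return The log-likelihood (a single non-positive number).
#' @export
crf_log_likelihood <- function(emissions, transitions, labels) {
  check_crf_args(emissions, transitions, labels)
  cpp_crf_score(emissions, transitions, as.integer(labels) - 1L) -
    cpp_crf_logZ(emissions, transitions)
}

#' Exact Viterbi decoding
#'
#' Returns an argmax-scoring label sequence and its unnormalized path score;
#' ties are broken toward the lowest tag index at each backtrack step.
#'
#' @inheritParams crf_log_likelihood
#' @return A list with `labels` (1-based integer vector) and `score`.
#' @export
viterbi_decode <- function(emissions, transitions) {
  check_crf_args(emissions, transitions)
  v <- cpp_crf_viterbi(emissions, transitions)
  list(labels = as.integer(v$path) + 1L, score = v$score)
}

#' CRF log-partition function (forward algorithm)
#'
#' @inheritParams crf_log_likelihood
#' @return `log Z`, the log-sum-exp of all path scores.
#' @export
crf_log_partition <- function(emissions, transitions) {
  check_crf_args(emissions, transitions)
  cpp_crf_logZ(emissions, transitions)
}
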