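# Binary transition-matrix Viterbi repair. A transition gets score 1 if the
# training labels contain it and 0 otherwise; decoding maximises the sum of
# per-token log-probabilities over tag sequences whose every consecutive
# transition (and sentence-initial/final tag) was observed in training.

#' Learn the binary tag-transition matrix from training labels
#'
#' `allowed[i, j]` is `TRUE` iff label `j` immediately follows label `i`
#' somewhere in the training tags; `start_allowed`/`end_allowed` record the
#' observed sentence-initial and sentence-final labels.
#'
#' @param train A [conll_split()] of training sentences.
#' @param labels Ordered label vocabulary.
#' @return An object of class `transition_matrix`.
#' @export
fit_transition_matrix <- function(train, labels) {
  stopifnot(inherits(train, "conll_split"))
  if (length(train) == 0L) stopf("train split is empty")
  L <- length(labels)
  allowed <- matrix(FALSE, L, L, dimnames = list(labels, labels))
  start_allowed <- stats::setNames(logical(L), labels)
  end_allowed <- stats::setNames(logical(L), labels)
  for (s in train$sentences) {
    idx <- match(s$tag, labels)
    if (anyNA(idx)) {
      stopf("tag '%s' not in label vocabulary", s$tag[which(is.na(idx))[1L]])
    }
    start_allowed[idx[1L]] <- TRUE
    end_allowed[idx[length(idx)]] <- TRUE
    if (length(idx) > 1L) {
      allowed[cbind(idx[-length(idx)], idx[-1L])] <- TRUE
    }
  }
  structure(list(labels = labels, allowed = allowed,
                 start_allowed = start_allowed, end_allowed = end_allowed),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix: %d labels, %d/%d transitions allowed>\n",
              length(x$labels), sum(x$allowed), length(x$allowed)))
  invisible(x)
}

#' Constrained Viterbi decoding over a binary transition matrix
#'
#' Returns the tag sequence maximising the sum of per-token log-probabilities
#' subject to every consecutive transition (and the sentence-initial/final
#' tags) being allowed. Probabilities of 0 are floored at `1e-12` before the
#' log; forbidden transitions score `-Inf`. Ties are broken towards the lowest
#' label index at the latest differing position. When no allowed path exists
#' the per-token argmax sequence is returned with a warning.
#'
#' @param distributions Numeric matrix, one row per token, each row a
#'   probability distribution over the labels.
#' @param matrix A `transition_matrix`.
#' @return Character vector of decoded tags.
#' @export
constrained_viterbi_decode <- function(distributions, matrix) {
  stopifnot(inherits(matrix, "transition_matrix"))
  distributions <- as.matrix(distributions)
  n <- nrow(distributions)
  L <- length(matrix$labels)
  if (n < 1L) stopf("need at least one token")
  if (ncol(distributions) != L) {
    stopf("distribution rows have %d columns, vocabulary has %d labels",
          ncol(distributions), L)
  }
  if (any(abs(rowSums(distributions) - 1) > 1e-4)) {
    stopf("distribution rows must sum to 1")
  }
  logp <- log(pmax(distributions, 1e-12))
  logT <- ifelse(matrix$allowed, 0, -Inf)
  delta <- logp[1L, ] + ifelse(matrix$start_allowed, 0, -Inf)
  psi <- base::matrix(NA_integer_, n, L)
  if (n > 1L) {
    for (t in 2:n) {
      M <- delta + logT  # M[i, j] = delta[i] + logT[i, j]
      best_prev <- max.col(t(M), ties.method = "first")
      delta <- M[cbind(best_prev, seq_len(L))] + logp[t, ]
      psi[t, ] <- best_prev
    }
  }
  final <- delta + ifelse(matrix$end_allowed, 0, -Inf)
  if (!any(is.finite(final))) {
    warning("no allowed tag path; falling back to per-token argmax",
            call. = FALSE)
    return(matrix$labels[max.col(logp, ties.method = "first")])
  }
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1L) {
    for (t in n:2) path[t - 1L] <- psi[t, path[t]]
  }
  matrix$labels[path]
}

#' Predict and repair tag sequences for a corpus split
#'
#' Scores every token window with the model (dropout off), then repairs each
#' sentence's predicted tags by [constrained_viterbi_decode()].
#'
#' @param model A `ner_model`.
#' @param split A [conll_split()].
#' @param corpus The `ner_corpus` supplying the label vocabulary.
#' @param table An `embedding_table`.
#' @param trans A `transition_matrix` fitted on the corpus's training labels;
#'   `NULL` decodes by per-token argmax without repair.
#' @param task Task name for multi-output models.
#' @param chunk_size Examples scored per forward call.
#' @return List of character tag vectors, one per sentence.
#' @export
predict_tags <- function(model, split, corpus, table, trans = NULL,
                         task = NULL, chunk_size = 1024L) {
  ds <- window_dataset(split, corpus, model$spec$n, table)
  Eaug <- augmented_matrix(table)
  n_ex <- nrow(ds$idx)
  probs <- base::matrix(0, n_ex, ds$n_labels)
  at <- 1L
  while (at <= n_ex) {
    rows <- at:min(at + chunk_size - 1L, n_ex)
    probs[rows, ] <- model_forward(model, list(X = embed_rows(ds, rows, Eaug)),
                                   table, task = task)
    at <- at + length(rows)
  }
  ends <- cumsum(ds$sentence_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  labs <- corpus$label_vocabulary
  lapply(seq_along(starts), function(i) {
    rows <- starts[i]:ends[i]
    if (is.null(trans)) {
      labs[max.col(probs[rows, , drop = FALSE], ties.method = "first")]
    } else {
      constrained_viterbi_decode(probs[rows, , drop = FALSE], trans)
    }
  })
}
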