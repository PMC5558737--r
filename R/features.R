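# Fixed-width context-window examples: each token is classified from itself
# plus n neighbours on each side (2n+1 surfaces), with sentence-break padding
# beyond the sentence boundary so windows never read across sentences.

#' Build context-window examples for one sentence
#'
#' @param sentence A sentence (list with `surface` and `tag`).
#' @param n Context half-width; the window holds `2n + 1` surfaces.
#' @param corpus The owning `ner_corpus` (supplies the label vocabulary).
#' @param break_token Padding token used beyond sentence boundaries.
#' @return List with `windows` (character matrix, one row per token,
#'   `2n + 1` columns), `labels` (integer indices into
#'   `corpus$label_vocabulary`) and `corpus_name`.
#' @export
build_window_examples <- function(sentence, n, corpus, break_token = "<S>") {
  stopifnot(n >= 0, inherits(corpus, "ner_corpus"))
  m <- length(sentence$surface)
  w <- 2L * n + 1L
  padded <- c(rep(break_token, n), sentence$surface, rep(break_token, n))
  windows <- matrix("", m, w)
  for (p in seq_len(w)) windows[, p] <- padded[(p - 1L) + seq_len(m)]
  labels <- match(sentence$tag, corpus$label_vocabulary)
  if (anyNA(labels)) {
    stopf("tag '%s' not in label vocabulary of corpus '%s'",
          sentence$tag[which(is.na(labels))[1L]], corpus$name)
  }
  list(windows = windows, labels = labels, corpus_name = corpus$name)
}

# Precompute all windows of a split as rows into an embedding table's
# augmented matrix: the per-batch embedding step is then pure indexing.
window_dataset <- function(split, corpus, n, table) {
  stopifnot(inherits(split, "conll_split"))
  exs <- lapply(split$sentences, build_window_examples, n = n, corpus = corpus,
                break_token = table$break_token)
  windows <- do.call(rbind, lapply(exs, `[[`, "windows"))
  labels <- unlist(lapply(exs, `[[`, "labels"))
  sent_len <- vapply(split$sentences, function(s) length(s$surface), integer(1))
  idx <- matrix(surface_rows(table, as.vector(windows)), nrow = nrow(windows))
  list(idx = idx, labels = labels, sentence_lengths = sent_len,
       corpus_name = corpus$name, n = n, width = 2L * n + 1L,
       n_labels = length(corpus$label_vocabulary))
}

# Embed selected dataset rows into a B x (2n+1)d design matrix, column blocks
# ordered by window position.
embed_rows <- function(ds, rows, Eaug) {
  d <- ncol(Eaug)
  w <- ds$width
  X <- matrix(0, length(rows), w * d)
  for (p in seq_len(w)) {
    X[, ((p - 1L) * d + 1L):(p * d)] <- Eaug[ds$idx[rows, p], , drop = FALSE]
  }
  X
}

#' Infinite shuffled mini-batch iterator over a corpus split
#'
#' Training examples (token windows) are shuffled once per epoch with a
#' seed-deterministic order; the final short batch of an epoch is kept, and the
#' stream reshuffles and restarts when exhausted.
#'
#' @param split A [conll_split()] with at least one sentence.
#' @param corpus The owning `ner_corpus`.
#' @param n Context half-width.
#' @param batch_size Examples per mini-batch (>= 1).
#' @param seed Integer seed for the shuffle order.
#' @param table An `embedding_table` (used to pre-index windows).
#' @return A function of no arguments; each call returns a mini-batch as a
#'   list with `rows` (dataset row indices), `labels`, `windows` row selector
#'   and `corpus_name`.
#' @export
batch_iterator <- function(split, corpus, n, batch_size, seed, table) {
  if (length(split) == 0L) stopf("cannot iterate over an empty split")
  if (batch_size < 1L) stopf("`batch_size` must be >= 1")
  ds <- window_dataset(split, corpus, n, table)
  n_ex <- nrow(ds$idx)
  epoch <- 0L
  order_ <- integer()
  pos <- 1L
  nxt <- function() {
    if (pos > length(order_)) {
      epoch <<- epoch + 1L
      order_ <<- with_seed(derive_seed(seed, epoch), sample.int(n_ex))
      pos <<- 1L
    }
    take <- order_[pos:min(pos + batch_size - 1L, length(order_))]
    pos <<- pos + length(take)
    list(rows = take, labels = ds$labels[take], corpus_name = ds$corpus_name,
         epoch = epoch)
  }
  attr(nxt, "dataset") <- ds
  nxt
}
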