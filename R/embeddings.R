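# Frozen word-vector tables. Vectors never change during training; the table
# provides dedicated unknown-word and sentence-break vectors.

new_embedding_table <- function(words, E, unknown_vector, break_vector,
                                unknown_token = "<UNK>", break_token = "<S>") {
  d <- ncol(E)
  stopifnot(length(unknown_vector) == d, length(break_vector) == d)
  rownames(E) <- NULL
  structure(list(dimension = d,
                 words = words,
                 words_lower = tolower(words),
                 E = E,
                 unknown_vector = as.numeric(unknown_vector),
                 break_vector = as.numeric(break_vector),
                 unknown_token = unknown_token,
                 break_token = break_token),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d words, dimension %d>\n",
              length(x$words), x$dimension))
  invisible(x)
}

#' Load word vectors in word2vec text format
#'
#' Expects a header line `V d` followed by `V` lines of `word v1 ... vd`.
#' If the file contains the reserved unknown token its vector is used for
#' out-of-vocabulary words; otherwise the unknown vector is the element-wise
#' mean of all stored vectors. The sentence-break vector is taken from the
#' reserved break token if present, else synthesised deterministically.
#'
#' @param path Path to a word2vec text file.
#' @param unknown_token,break_token Reserved token names (defaults `"<UNK>"`,
#'   `"<S>"`).
#' @return An `embedding_table`.
#' @export
load_embedding_table <- function(path, unknown_token = "<UNK>",
                                 break_token = "<S>") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stopf("empty embedding file: %s", path)
  hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stopf("line 1: expected header 'V d'")
  }
  v <- as.integer(hdr[1L])
  d <- as.integer(hdr[2L])
  if (length(lines) - 1L != v) {
    stopf("header declares %d vectors but file has %d data lines",
          v, length(lines) - 1L)
  }
  words <- character(v)
  E <- matrix(0, v, d)
  for (i in seq_len(v)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(fields) != d + 1L) {
      stopf("line %d: expected %d values after the word, found %d",
            i + 1L, d, length(fields) - 1L)
    }
    words[i] <- fields[1L]
    vec <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vec)) stopf("line %d: non-numeric vector component", i + 1L)
    E[i, ] <- vec
  }
  if (anyDuplicated(words)) {
    dup <- unique(words[duplicated(words)])
    warning(sprintf("duplicate word(s) in embedding file (first occurrence kept): %s",
                    paste(utils::head(dup, 3L), collapse = ", ")), call. = FALSE)
    keep <- !duplicated(words)
    words <- words[keep]
    E <- E[keep, , drop = FALSE]
  }
  take <- function(tok) {
    i <- match(tok, words)
    if (is.na(i)) NULL else E[i, ]
  }
  unk <- take(unknown_token) %||% colMeans(E)
  brk <- take(break_token) %||%
    with_seed(20170815L, stats::runif(d, -0.5 / d, 0.5 / d))
  new_embedding_table(words, E, unk, brk, unknown_token, break_token)
}

#' Build a seeded random embedding table
#'
#' Vectors are i.i.d. uniform on `[-0.5/dimension, 0.5/dimension]`, drawn
#' deterministically from `seed`; distinct unknown and sentence-break vectors
#' are appended. Used as a stand-in for pre-trained vectors in tests and
#' synthetic experiments.
#'
#' @param vocabulary Character vector of word surfaces (non-empty).
#' @param dimension Vector dimension.
#' @param seed Integer seed.
#' @inheritParams load_embedding_table
#' @return An `embedding_table`.
#' @export
make_random_table <- function(vocabulary, dimension, seed,
                              unknown_token = "<UNK>", break_token = "<S>") {
  if (!length(vocabulary)) stopf("`vocabulary` must be non-empty")
  if (!is.numeric(dimension) || dimension < 1) stopf("`dimension` must be positive")
  vocabulary <- unique(as.character(vocabulary))
  d <- as.integer(dimension)
  M <- with_seed(seed, matrix(stats::runif((length(vocabulary) + 2L) * d,
                                           -0.5 / d, 0.5 / d),
                              nrow = length(vocabulary) + 2L, byrow = TRUE))
  n <- length(vocabulary)
  new_embedding_table(vocabulary, M[seq_len(n), , drop = FALSE],
                      M[n + 1L, ], M[n + 2L, ], unknown_token, break_token)
}

# Row indices into the augmented matrix rbind(E, unknown, break).
unk_row <- function(table) length(table$words) + 1L
break_row <- function(table) length(table$words) + 2L

augmented_matrix <- function(table) {
  rbind(table$E, table$unknown_vector, table$break_vector, deparse.level = 0)
}

# Map surfaces to augmented-matrix rows: exact match, then lowercase match,
# then the unknown row; the break token maps to the break row.
surface_rows <- function(table, surfaces) {
  idx <- match(surfaces, table$words)
  miss <- is.na(idx)
  if (any(miss)) {
    low <- match(tolower(surfaces[miss]), table$words_lower)
    idx[miss] <- ifelse(is.na(low), unk_row(table), low)
  }
  idx[surfaces == table$break_token] <- break_row(table)
  idx
}

#' Look up word vectors
#'
#' Resolution order: exact surface match, then lowercased match, then the
#' unknown-word vector; the reserved sentence-break token yields the
#' sentence-break vector. Total and deterministic.
#'
#' @param table An `embedding_table`.
#' @param surfaces Character vector of token surfaces.
#' @return Numeric matrix, one row per surface.
#' @export
embedding_lookup <- function(table, surfaces) {
  stopifnot(inherits(table, "embedding_table"))
  augmented_matrix(table)[surface_rows(table, surfaces), , drop = FALSE]
}
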