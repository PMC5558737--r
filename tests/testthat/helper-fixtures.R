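# Shared fixtures and independent oracles used across the suite.

# Random BIOES-valid tag sequence via a direct grammar walk (independent of
# mentions_to_tags).
random_bioes_tags <- function(len, types = c("G", "C")) {
  tags <- character(0)
  i <- 1L
  while (i <= len) {
    if (stats::runif(1) < 0.5) {
      tags <- c(tags, "O")
      i <- i + 1L
    } else {
      ty <- sample(types, 1L)
      span <- sample.int(min(3L, len - i + 1L), 1L)
      tags <- c(tags, if (span == 1L) paste0("S-", ty) else {
        c(paste0("B-", ty),
          rep(paste0("I-", ty), span - 2L),
          paste0("E-", ty))
      })
      i <- i + span
    }
  }
  tags
}

# Random non-overlapping mention set for a sentence of given length.
random_mentions <- function(len, types = c("G", "C")) {
  men <- data.frame(sentence = integer(), start = integer(), end = integer(),
                    type = character(), stringsAsFactors = FALSE)
  i <- 0L
  while (i < len) {
    if (stats::runif(1) < 0.4) {
      span <- sample.int(min(3L, len - i), 1L)
      men <- rbind(men, data.frame(sentence = 0L, start = i, end = i + span,
                                   type = sample(types, 1L),
                                   stringsAsFactors = FALSE))
      i <- i + span
    } else {
      i <- i + 1L
    }
  }
  men
}

# Exhaustive-search decoder: enumerate every label sequence, keep those whose
# start/end/pair transitions are allowed, maximise summed log-probabilities
# (same accumulation order as the Viterbi recursion), break ties towards the
# lowest label index at the latest differing position.
brute_force_decode <- function(distributions, tm) {
  n <- nrow(distributions)
  L <- length(tm$labels)
  logp <- log(pmax(distributions, 1e-12))
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))[, n:1, drop = FALSE]
  ok <- tm$start_allowed[grid[, 1L]] & tm$end_allowed[grid[, n]]
  if (n > 1L) {
    for (t in 2:n) ok <- ok & tm$allowed[cbind(grid[, t - 1L], grid[, t])]
  }
  if (!any(ok)) return(NULL)
  cand <- grid[ok, , drop = FALSE]
  score <- logp[cbind(rep(1L, nrow(cand)), cand[, 1L])]
  if (n > 1L) {
    for (t in 2:n) score <- score + logp[cbind(rep(t, nrow(cand)), cand[, t])]
  }
  best <- cand[score == max(score), , drop = FALSE]
  # reversed-position lexicographic minimum
  for (t in n:1) {
    best <- best[best[, t] == min(best[, t]), , drop = FALSE]
    if (nrow(best) == 1L) break
  }
  tm$labels[best[1L, ]]
}

# Small deterministic corpus from explicit sentences.
make_corpus <- function(name, train, dev = train, test = train,
                        entity_types = NULL) {
  mk <- function(xs) conll_split(lapply(xs, function(x) {
    list(surface = x$surface, tag = x$tag)
  }))
  corpus(name, mk(train), mk(dev), mk(test), entity_types = entity_types)
}

s_ <- function(surface, tag) list(surface = surface, tag = tag)

# Tiny architecture/schedule used by fast model tests.
tiny_arch <- function(kind = "single_task", d = 10L) {
  architecture_spec(kind, embedding_dimension = d, n = 3L,
                    filter_widths = c(3L, 4L, 5L), filters_per_width = 4L,
                    fully_connected_size = 8L,
                    dropout_keep_probability = 0.75)
}

tiny_collection <- function(n_corpora = 2L, seed = 101L,
                            splits = c(60L, 25L, 30L)) {
  generate_collection(synthetic_config(n_corpora = n_corpora,
                                       sentences_per_split = splits,
                                       seed = seed))
}

table_for <- function(collection, d = 10L, seed = 7L) {
  make_random_table(collection_vocabulary(collection), d, seed = seed)
}

# 12-sentence scoring fixture with hand-counted outcomes: exact matches,
# boundary errors, type errors, multi-mention sentences, spurious and missed
# mentions. Hand count: tp 7, fp 5, fn 5.
fixture_12 <- function() {
  list(
    list(g = c("S-G", "O"),               p = c("S-G", "O")),
    list(g = c("B-G", "E-G", "O"),        p = c("B-G", "E-G", "O")),
    list(g = c("B-G", "E-G", "O"),        p = c("S-G", "O", "O")),
    list(g = c("S-G", "O"),               p = c("S-C", "O")),
    list(g = c("S-G", "O", "S-C"),        p = c("S-G", "O", "S-C")),
    list(g = c("O", "O"),                 p = c("O", "O")),
    list(g = c("O", "S-C"),               p = c("O", "O")),
    list(g = c("O", "O"),                 p = c("O", "S-G")),
    list(g = c("B-C", "I-C", "E-C"),      p = c("B-C", "I-C", "E-C")),
    list(g = c("B-C", "I-C", "E-C", "O"), p = c("O", "B-C", "E-C", "O")),
    list(g = c("S-G", "S-C", "O"),        p = c("S-G", "O", "O")),
    list(g = c("O", "B-G", "E-G"),        p = c("S-C", "B-G", "E-G"))
  )
}

# Random transition structure over L labels.
random_transition_matrix <- function(L) {
  labels <- sprintf("L%d", seq_len(L))
  structure(list(labels = labels,
                 allowed = matrix(stats::runif(L * L) < 0.6, L, L,
                                  dimnames = list(labels, labels)),
                 start_allowed = stats::setNames(stats::runif(L) < 0.7, labels),
                 end_allowed = stats::setNames(stats::runif(L) < 0.7, labels)),
            class = "transition_matrix")
}

# Random probability-distribution matrix (rows sum to 1).
random_dist_rows <- function(n, L) {
  m <- matrix(stats::rexp(n * L), n, L)
  m / rowSums(m)
}
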