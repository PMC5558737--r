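# ---- BIOES tag grammar ------------------------------------------------------

tag_prefix <- function(tags) ifelse(tags == "O", "O", substr(tags, 1L, 1L))

tag_type <- function(tags) ifelse(tags == "O", NA_character_, substring(tags, 3L))

tag_is_wellformed <- function(tags) {
  tags == "O" | grepl("^[BIES]-.+$", tags)
}

#' Check a tag sequence for BIOES validity
#'
#' A sequence is BIOES-valid when every `B-T` is closed by an `E-T` with only
#' `I-T` in between, `I-T`/`E-T` never follow `O` or a different type, and
#' `S-T`/`O` occur only outside open spans.
#'
#' @param tags Character vector of tags (`"O"` or `"P-T"`, `P` in B/I/E/S).
#' @return `TRUE` if valid, otherwise a character string describing the first
#'   violation.
#' @export
bioes_check <- function(tags) {
  if (length(tags) == 0L) return("empty tag sequence")
  bad <- which(!tag_is_wellformed(tags))
  if (length(bad)) {
    return(sprintf("malformed tag '%s' at position %d", tags[bad[1L]], bad[1L]))
  }
  open <- FALSE
  open_type <- NA_character_
  for (i in seq_along(tags)) {
    p <- tag_prefix(tags[i])
    ty <- tag_type(tags[i])
    if (open) {
      if (p == "I" && identical(ty, open_type)) next
      if (p == "E" && identical(ty, open_type)) {
        open <- FALSE
        next
      }
      return(sprintf("tag '%s' at position %d inside an open %s span",
                     tags[i], i, open_type))
    }
    if (p == "B") {
      open <- TRUE
      open_type <- ty
    } else if (p %in% c("I", "E")) {
      return(sprintf("tag '%s' at position %d does not continue a span",
                     tags[i], i))
    }
  }
  if (open) return(sprintf("span of type %s left open at end of sentence", open_type))
  TRUE
}

bioes_valid <- function(tags) isTRUE(bioes_check(tags))

#' Convert IOB/IOB2 tags to BIOES
#'
#' Accepts `O`, `B-T` and `I-T` tags in either IOB1 (chunk-initial `I-T`) or
#' IOB2 dialect and re-tags each maximal chunk with the BIOES scheme
#' (single-token chunks become `S-T`, longer ones `B-T`, `I-T`..., `E-T`).
#'
#' @param tags Character vector of IOB tags.
#' @return Character vector of BIOES tags.
#' @export
iob_to_bioes <- function(tags) {
  if (length(tags) == 0L) return(character())
  ok <- tags == "O" | grepl("^[BIES]-.+$", tags)
  if (any(!ok)) {
    stopf("tag '%s' is neither BIOES nor IOB", tags[which(!ok)[1L]])
  }
  n <- length(tags)
  p <- tag_prefix(tags)
  ty <- tag_type(tags)
  # chunk start: B or S always; I when not continuing a chunk of same type
  prev_ty <- c(NA_character_, ty[-n])
  prev_p <- c("O", p[-n])
  starts <- p %in% c("B", "S") |
    (p == "I" & (prev_p == "O" | prev_p == "E" | prev_p == "S" |
                   is.na(prev_ty) | prev_ty != ty))
  out <- tags
  i <- 1L
  while (i <= n) {
    if (p[i] == "O") {
      i <- i + 1L
      next
    }
    j <- i
    while (j + 1L <= n && !starts[j + 1L] && p[j + 1L] %in% c("I", "E") &&
           identical(ty[j + 1L], ty[i])) {
      j <- j + 1L
    }
    if (i == j) {
      out[i] <- paste0("S-", ty[i])
    } else {
      out[i] <- paste0("B-", ty[i])
      if (j > i + 1L) out[(i + 1L):(j - 1L)] <- paste0("I-", ty[i])
      out[j] <- paste0("E-", ty[i])
    }
    i <- j + 1L
  }
  out
}

# ---- sentences and splits ---------------------------------------------------

new_sentence <- function(surface, tag) {
  list(surface = as.character(surface), tag = as.character(tag))
}

validate_sentence <- function(s, check_tags = TRUE) {
  if (length(s$surface) == 0L) stopf("sentence must be non-empty")
  if (length(s$surface) != length(s$tag)) stopf("surface/tag length mismatch")
  if (any(!nzchar(s$surface)) || any(grepl("[[:space:]]", s$surface))) {
    stopf("token surfaces must be non-empty and contain no whitespace")
  }
  if (check_tags) {
    chk <- bioes_check(s$tag)
    if (!isTRUE(chk)) stopf("invalid BIOES sequence: %s", chk)
  }
  invisible(s)
}

#' Construct a corpus split from sentences
#'
#' @param sentences List of sentences, each a list with character vectors
#'   `surface` and `tag` of equal length.
#' @param validate Check BIOES validity of every sentence (default `TRUE`).
#' @return An object of class `conll_split`.
#' @export
conll_split <- function(sentences = list(), validate = TRUE) {
  if (validate) lapply(sentences, validate_sentence)
  structure(list(sentences = sentences), class = "conll_split")
}

#' @export
length.conll_split <- function(x) length(x$sentences)

#' @export
print.conll_split <- function(x, ...) {
  ntok <- sum(vapply(x$sentences, function(s) length(s$surface), integer(1)))
  cat(sprintf("<conll_split: %d sentences, %d tokens>\n", length(x), ntok))
  invisible(x)
}

split_tags <- function(split) lapply(split$sentences, `[[`, "tag")
split_surfaces <- function(split) lapply(split$sentences, `[[`, "surface")

#' Read a CoNLL-style column file into a corpus split
#'
#' One token per line with whitespace-separated columns; blank lines delimit
#' sentences (consecutive blank lines are collapsed).
#'
#' @param path File to read (UTF-8).
#' @param token_column 1-based index of the surface column (default 1).
#' @param tag_column 1-based index of the tag column; `NULL` (default) means
#'   the last column of each line.
#' @param repair_iob If `TRUE`, IOB/IOB2 tag sequences are converted to BIOES;
#'   by default tags are strictly validated as BIOES.
#' @return A [conll_split()].
#' @export
read_conll_split <- function(path, token_column = 1L, tag_column = NULL,
                             repair_iob = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  sentences <- list()
  cur_s <- character()
  cur_t <- character()
  flush <- function() {
    if (length(cur_s)) {
      tags <- if (repair_iob) iob_to_bioes(cur_t) else cur_t
      sentences[[length(sentences) + 1L]] <<- new_sentence(cur_s, tags)
      cur_s <<- character()
      cur_t <<- character()
    }
  }
  for (i in seq_along(lines)) {
    if (blank[i]) {
      flush()
      next
    }
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    tc <- tag_column %||% length(fields)
    if (length(fields) < max(token_column, tc)) {
      stopf("line %d of %s has %d field(s), need at least %d",
            i, path, length(fields), max(token_column, tc))
    }
    cur_s <- c(cur_s, fields[token_column])
    cur_t <- c(cur_t, fields[tc])
  }
  flush()
  conll_split(sentences)
}

#' Write a corpus split as a two-column CoNLL-style file
#'
#' Inverse of [read_conll_split()]: `token<TAB>tag` lines, one blank line
#' between sentences.
#'
#' @param split A [conll_split()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll_split <- function(split, path) {
  stopifnot(inherits(split, "conll_split"))
  blocks <- vapply(split$sentences, function(s) {
    paste(paste(s$surface, s$tag, sep = "\t"), collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(blocks)) {
    writeLines(enc2utf8(paste(blocks, collapse = "\n\n")), con, useBytes = TRUE)
  }
  invisible(path)
}

# ---- mentions ---------------------------------------------------------------

empty_mentions <- function() {
  data.frame(sentence = integer(), start = integer(), end = integer(),
             type = character(), stringsAsFactors = FALSE)
}

#' Decode BIOES tags into entity mentions
#'
#' @param tags A character vector of BIOES tags, or a sentence (list with a
#'   `tag` element).
#' @param sentence_index 0-based sentence index recorded on each mention.
#' @return A data frame with columns `sentence`, `start` (0-based, inclusive),
#'   `end` (exclusive) and `type`, one row per maximal entity span, ordered by
#'   `start`.
#' @export
tags_to_mentions <- function(tags, sentence_index = 0L) {
  if (is.list(tags)) tags <- tags$tag
  chk <- bioes_check(tags)
  if (!isTRUE(chk)) stopf("invalid BIOES sequence: %s", chk)
  p <- tag_prefix(tags)
  starts <- which(p %in% c("B", "S"))
  if (!length(starts)) return(empty_mentions())
  ends <- integer(length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    ends[k] <- if (p[i] == "S") i else {
      j <- i
      while (p[j] != "E") j <- j + 1L
      j
    }
  }
  data.frame(sentence = as.integer(sentence_index),
             start = starts - 1L, end = ends,
             type = tag_type(tags)[starts],
             stringsAsFactors = FALSE)
}

#' Encode entity mentions as a BIOES tag sequence
#'
#' Inverse of [tags_to_mentions()]; positions outside every mention get `"O"`.
#'
#' @param mentions Data frame with columns `start`, `end`, `type` (0-based,
#'   half-open spans).
#' @param sentence_length Number of tokens in the sentence.
#' @return Character vector of `sentence_length` BIOES tags.
#' @export
mentions_to_tags <- function(mentions, sentence_length) {
  tags <- rep("O", sentence_length)
  if (is.null(mentions) || nrow(mentions) == 0L) return(tags)
  m <- mentions[order(mentions$start), , drop = FALSE]
  if (any(m$start < 0L) || any(m$end > sentence_length) || any(m$start >= m$end)) {
    stopf("mention out of bounds for sentence of length %d", sentence_length)
  }
  if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)])) {
    stopf("overlapping mentions are not supported")
  }
  for (k in seq_len(nrow(m))) {
    a <- m$start[k] + 1L
    b <- m$end[k]
    ty <- m$type[k]
    if (a == b) {
      tags[a] <- paste0("S-", ty)
    } else {
      tags[a] <- paste0("B-", ty)
      if (b > a + 1L) tags[(a + 1L):(b - 1L)] <- paste0("I-", ty)
      tags[b] <- paste0("E-", ty)
    }
  }
  tags
}

#' All mentions of a corpus split
#'
#' @param split A [conll_split()].
#' @return Mentions of every sentence, with 0-based `sentence` indices.
#' @export
split_mentions <- function(split) {
  out <- lapply(seq_along(split$sentences), function(i) {
    tags_to_mentions(split$sentences[[i]]$tag, i - 1L)
  })
  do.call(rbind, c(out, list(empty_mentions())))
}

# ---- corpus -----------------------------------------------------------------

bioes_vocabulary <- function(entity_types) {
  if (!length(entity_types)) return("O")
  c("O", sort_c(as.vector(outer(c("B", "E", "I", "S"), sort_c(entity_types),
                                paste, sep = "-"))))
}

observed_types <- function(corpus_splits) {
  tys <- unlist(lapply(corpus_splits, function(sp) {
    unlist(lapply(sp$sentences, function(s) tag_type(s$tag)))
  }))
  sort_c(unique(tys[!is.na(tys)]))
}

#' Construct an NER corpus with train/dev/test splits
#'
#' The label vocabulary is the full BIOES set over `entity_types`
#' (4 x number of types + 1 labels), sorted with `"O"` first so label indices
#' are reproducible across runs.
#'
#' @param name Corpus identifier.
#' @param train,dev,test [conll_split()] objects.
#' @param entity_types Character vector of entity type names; derived from the
#'   tags observed in the splits when `NULL`.
#' @return An object of class `ner_corpus`.
#' @export
corpus <- function(name, train, dev, test, entity_types = NULL) {
  stopifnot(inherits(train, "conll_split"), inherits(dev, "conll_split"),
            inherits(test, "conll_split"))
  if (is.null(entity_types)) {
    entity_types <- observed_types(list(train, dev, test))
  }
  entity_types <- sort_c(unique(entity_types))
  vocab <- bioes_vocabulary(entity_types)
  for (sp in list(train, dev, test)) {
    tags <- unlist(split_tags(sp))
    unknown <- setdiff(unique(tags), vocab)
    if (length(unknown)) {
      stopf("corpus '%s': tag '%s' not in label vocabulary", name, unknown[1L])
    }
  }
  structure(list(name = name, entity_types = entity_types,
                 train = train, dev = dev, test = test,
                 label_vocabulary = vocab),
            class = "ner_corpus")
}

#' @export
print.ner_corpus <- function(x, ...) {
  cat(sprintf("<ner_corpus '%s': types {%s}; train/dev/test = %d/%d/%d sentences>\n",
              x$name, paste(x$entity_types, collapse = ", "),
              length(x$train), length(x$dev), length(x$test)))
  invisible(x)
}

#' Keep one entity type, relabelling all others to Out
#'
#' Tags of every type other than `focus_type` become `"O"`; the resulting
#' corpus has the 5-label vocabulary of a single-type task. Token surfaces and
#' sentence counts are unchanged.
#'
#' @param corpus An `ner_corpus`.
#' @param focus_type Entity type to keep.
#' @return A new `ner_corpus`.
#' @export
restrict_to_entity_type <- function(corpus, focus_type) {
  stopifnot(inherits(corpus, "ner_corpus"))
  if (!focus_type %in% corpus$entity_types) {
    stopf("corpus '%s' has no entity type '%s'", corpus$name, focus_type)
  }
  relabel <- function(sp) {
    conll_split(lapply(sp$sentences, function(s) {
      keep <- !is.na(tag_type(s$tag)) & tag_type(s$tag) == focus_type
      new_sentence(s$surface, ifelse(keep, s$tag, "O"))
    }), validate = FALSE)
  }
  corpus(corpus$name, relabel(corpus$train), relabel(corpus$dev),
         relabel(corpus$test), entity_types = focus_type)
}

#' Subsample a corpus's training split
#'
#' Replaces the train split with a uniformly random, seed-deterministic subset
#' of `round(fraction * N)` sentences (at least 1), preserving their original
#' order; dev and test are untouched.
#'
#' @param corpus An `ner_corpus`.
#' @param fraction Fraction of training sentences to keep, in (0, 1].
#' @param seed Integer seed.
#' @return A new `ner_corpus`.
#' @export
subsample_training <- function(corpus, fraction, seed) {
  stopifnot(inherits(corpus, "ner_corpus"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stopf("`fraction` must be in (0, 1]")
  }
  n <- length(corpus$train)
  if (n == 0L) stopf("corpus '%s' has an empty train split", corpus$name)
  k <- max(1L, as.integer(round(fraction * n)))
  keep <- with_seed(seed, sort(sample.int(n, k)))
  corpus(corpus$name,
         conll_split(corpus$train$sentences[keep], validate = FALSE),
         corpus$dev, corpus$test, entity_types = corpus$entity_types)
}

#' Fraction of test sentences appearing verbatim in a train split
#'
#' A test sentence counts as overlapping when its whitespace-joined token
#' surfaces equal those of some train sentence.
#'
#' @param train,test [conll_split()] objects.
#' @return Overlap fraction in \[0, 1\] (denominator: test sentences).
#' @export
compute_cross_split_overlap <- function(train, test) {
  stopifnot(inherits(train, "conll_split"), inherits(test, "conll_split"))
  if (length(test) == 0L) stopf("test split is empty")
  if (length(train) == 0L) stopf("train split is empty")
  key <- function(sp) vapply(sp$sentences, function(s) {
    paste(s$surface, collapse = " ")
  }, character(1))
  mean(key(test) %in% key(train))
}
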