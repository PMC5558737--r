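# Seed-deterministic synthetic multi-corpus NER collections. The generator
# emulates the transfer premise of multi-corpus biomedical NER: several
# corpora with (partially) distinct entity-type inventories whose entity
# lexicons partially overlap, arranged so that some surface forms appear in
# one corpus's evaluation data but only in ANOTHER corpus's training data.
#
# Entity surfaces are multi-token composites over dedicated entity-piece
# alphabets, disjoint from the context vocabulary; a type-specific trigger
# token precedes an entity with fixed probability, so entity status is partly
# (but not fully) recoverable from context alone. Memorisable surfaces plus
# imperfect context cues mirror why frozen-embedding window models work on
# real corpora while leaving headroom for cross-corpus transfer.

#' Configure the synthetic corpus generator
#'
#' Defaults describe the reference study conditions: 3 corpora, each
#' annotating a shared GENE type plus one private type, half of each type's
#' entity lexicon drawn from a pool shared across corpora, 500/100/100
#' train/dev/test sentences of 6-12 tokens with 1.5 entities expected per
#' sentence, and no label noise.
#'
#' @param n_corpora Number of corpora.
#' @param entity_types List (length `n_corpora`) of character vectors of type
#'   names per corpus; `NULL` gives each corpus `GENE` plus one private type.
#' @param shared_lexicon_fraction Fraction of each type's lexicon drawn from
#'   the pool shared across corpora annotating that type, in \[0, 1\].
#' @param vocabulary_size Context (non-entity) vocabulary size.
#' @param entity_length_distribution Probabilities of entity lengths 1, 2, 3
#'   tokens (normalised if needed).
#' @param sentence_length_range Integer `c(min, max)` sentence length.
#' @param entity_density Expected entities per sentence.
#' @param sentences_per_split Integer `c(train, dev, test)` counts.
#' @param label_noise_rate Probability that a training mention's tags are
#'   flipped to `"O"` (annotation-miss noise; whole mentions only, so tags
#'   stay BIOES-valid), in \[0, 1).
#' @param lexicon_size Entity surface forms per (corpus, type).
#' @param seed Integer seed; generation is bit-reproducible from
#'   (config, seed).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_corpora = 3L,
                             entity_types = NULL,
                             shared_lexicon_fraction = 0.5,
                             vocabulary_size = 300L,
                             entity_length_distribution = c(0.5, 0.3, 0.2),
                             sentence_length_range = c(6L, 12L),
                             entity_density = 1.5,
                             sentences_per_split = c(train = 500L, dev = 100L,
                                                     test = 100L),
                             label_noise_rate = 0,
                             lexicon_size = 20L,
                             seed = 1L) {
  n_corpora <- as.integer(n_corpora)
  if (n_corpora < 1L) stopf("`n_corpora` must be positive")
  if (is.null(entity_types)) {
    private <- c("CHEM", "DISEASE", "SPECIES", "ANATOMY", "CELL", "ORGAN",
                 "TISSUE", "VARIANT")
    entity_types <- lapply(seq_len(n_corpora), function(i) {
      c("GENE", private[(i - 1L) %% length(private) + 1L])
    })
  }
  if (length(entity_types) != n_corpora) {
    stopf("`entity_types` must have one entry per corpus")
  }
  if (shared_lexicon_fraction < 0 || shared_lexicon_fraction > 1) {
    stopf("`shared_lexicon_fraction` must be in [0, 1]")
  }
  if (label_noise_rate < 0 || label_noise_rate >= 1) {
    stopf("`label_noise_rate` must be in [0, 1)")
  }
  p <- as.numeric(entity_length_distribution)
  if (length(p) != 3L || any(p < 0) || sum(p) <= 0) {
    stopf("`entity_length_distribution` must be 3 non-negative probabilities")
  }
  p <- p / sum(p)
  rng <- as.integer(sentence_length_range)
  if (length(rng) != 2L || rng[1L] < 2L || rng[1L] > rng[2L]) {
    stopf("invalid `sentence_length_range`")
  }
  sps <- as.integer(sentences_per_split)
  if (length(sps) != 3L || any(sps < 1L)) {
    stopf("`sentences_per_split` must be 3 positive counts")
  }
  names(sps) <- c("train", "dev", "test")
  max_len <- max(which(p > 0))
  if (entity_density * max_len > rng[1L]) {
    stopf("infeasible config: entity_density (%g) x max entity length (%d) exceeds minimum sentence length (%d)",
          entity_density, max_len, rng[1L])
  }
  structure(list(n_corpora = n_corpora, entity_types = entity_types,
                 shared_lexicon_fraction = shared_lexicon_fraction,
                 vocabulary_size = as.integer(vocabulary_size),
                 entity_length_distribution = p,
                 sentence_length_range = rng,
                 entity_density = entity_density,
                 sentences_per_split = sps,
                 label_noise_rate = label_noise_rate,
                 lexicon_size = as.integer(lexicon_size),
                 triggers_per_type = 5L,
                 trigger_probability = 0.7,
                 pieces_per_alphabet = 15L,
                 heldout_fraction = 0.25,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Read a synthetic-generator configuration from a YAML file
#'
#' @param path YAML file whose keys are [synthetic_config()] arguments.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(synthetic_config, args)
}

# Split a piece alphabet into positional roles. A piece token encodes both
# its entity type and its position (single / begin / mid / end), a synthetic
# analogue of the positional morphology of real biomedical names (prefixes
# and suffixes such as "-ase"); single-token forms never collide with the
# openings of longer forms, so tags are recoverable from surfaces.
role_alphabet <- function(alphabet) {
  n <- length(alphabet)
  if (n < 4L) stopf("piece alphabet needs at least 4 pieces")
  # few single-role pieces: single-token mentions are the hardest unigram
  # decisions, so each single piece should recur often in training
  n_single <- max(1L, round(n * 0.25))
  n_begin <- max(1L, round(n * 0.3))
  n_mid <- max(1L, round(n * 0.2))
  if (n_single + n_begin + n_mid >= n) {
    n_single <- max(1L, n - 3L)
    n_begin <- n_mid <- 1L
  }
  list(single = alphabet[seq_len(n_single)],
       begin = alphabet[n_single + seq_len(n_begin)],
       mid = alphabet[n_single + n_begin + seq_len(n_mid)],
       end = alphabet[(n_single + n_begin + n_mid + 1L):n])
}

# Sample `n_forms` distinct surface forms over a role-split alphabet.
sample_forms <- function(n_forms, alphabet, len_probs) {
  roles <- role_alphabet(alphabet)
  forms <- list()
  seen <- character()
  guard <- 0L
  while (length(forms) < n_forms) {
    guard <- guard + 1L
    if (guard > 50L * n_forms) stopf("cannot draw enough distinct entity forms")
    len <- sample.int(3L, 1L, prob = len_probs)
    f <- switch(len,
                sample(roles$single, 1L),
                c(sample(roles$begin, 1L), sample(roles$end, 1L)),
                c(sample(roles$begin, 1L), sample(roles$mid, 1L),
                  sample(roles$end, 1L)))
    key <- paste(f, collapse = " ")
    if (!key %in% seen) {
      seen <- c(seen, key)
      forms[[length(forms) + 1L]] <- f
    }
  }
  forms
}

generate_sentence <- function(context_vocab, lexicon, triggers, cfg) {
  m <- sample(cfg$sentence_length_range[1L]:cfg$sentence_length_range[2L], 1L)
  k <- stats::rpois(1L, cfg$entity_density)
  forms <- list()
  repeat {
    if (k == 0L) break
    forms <- lexicon$forms[sample.int(length(lexicon$forms), k, replace = TRUE)]
    # at least one context token between entities, so adjacent mentions (whose
    # shared boundary no tagger could recover from surfaces) never occur
    if (sum(lengths(forms)) + k - 1L <= m) break
    k <- k - 1L
  }
  if (k == 0L) {
    return(new_sentence(sample(context_vocab, m, replace = TRUE), rep("O", m)))
  }
  types <- lexicon$types[match(vapply(forms, paste, character(1), collapse = " "),
                               lexicon$keys)]
  r <- m - sum(lengths(forms))
  ctx <- sample(context_vocab, r, replace = TRUE)
  gaps <- sort(sample.int(r + 1L, k) - 1L)  # context tokens before each entity
  surface <- character(0)
  tags <- character(0)
  prev <- 0L
  for (j in seq_len(k)) {
    g <- gaps[j]
    if (g > prev) {
      surface <- c(surface, ctx[(prev + 1L):g])
      tags <- c(tags, rep("O", g - prev))
    }
    # type-specific trigger cue on the immediately preceding context token
    if (g > 0L && stats::runif(1L) < cfg$trigger_probability) {
      surface[length(surface)] <- sample(triggers[[types[j]]], 1L)
    }
    f <- forms[[j]]
    surface <- c(surface, f)
    tags <- c(tags, mentions_to_tags(
      data.frame(start = 0L, end = length(f), type = types[j],
                 stringsAsFactors = FALSE), length(f)))
    prev <- g
  }
  if (prev < r) {
    surface <- c(surface, ctx[(prev + 1L):r])
    tags <- c(tags, rep("O", r - prev))
  }
  new_sentence(surface, tags)
}

apply_label_noise <- function(sentence, rate) {
  if (rate <= 0) return(sentence)
  men <- tags_to_mentions(sentence$tag)
  if (!nrow(men)) return(sentence)
  drop <- stats::runif(nrow(men)) < rate
  if (!any(drop)) return(sentence)
  sentence$tag <- mentions_to_tags(men[!drop, , drop = FALSE],
                                   length(sentence$surface))
  sentence
}

#' Generate a synthetic multi-corpus NER collection
#'
#' Builds `n_corpora` corpora over a common context vocabulary. For every
#' entity type, a `shared_lexicon_fraction` of its surface forms comes from a
#' pool common to all corpora annotating that type; each corpus additionally
#' withholds half of its shared forms from its own training split (they still
#' occur in its dev/test splits), so those surfaces are trainable only from
#' other corpora. Tags are BIOES-valid by construction; optional label noise
#' flips whole training mentions to `"O"`.
#'
#' @param config A [synthetic_config()].
#' @return Named list of `ner_corpus` objects (`corpus1`, `corpus2`, ...),
#'   with the full generator vocabulary attached as
#'   `attr(, "vocabulary")`.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    context_vocab <- sprintf("w%04d", seq_len(cfg$vocabulary_size))
    all_types <- sort_c(unique(unlist(cfg$entity_types)))
    triggers <- stats::setNames(lapply(all_types, function(ty) {
      sprintf("trg_%s_%d", tolower(ty), seq_len(cfg$triggers_per_type))
    }), all_types)
    context_pool <- c(context_vocab, unlist(triggers))
    # piece alphabets are type-specific (and corpus-specific for private
    # forms), so a piece token deterministically identifies its entity type —
    # the property that makes unseen composite forms classifiable from their
    # pieces, as pre-trained embeddings do for real corpora
    shared_alpha <- stats::setNames(lapply(all_types, function(ty) {
      sprintf("shp_%s_%02d", tolower(ty), seq_len(cfg$pieces_per_alphabet))
    }), all_types)
    n_shared <- as.integer(round(cfg$shared_lexicon_fraction * cfg$lexicon_size))
    shared_pool <- stats::setNames(lapply(all_types, function(ty) {
      sample_forms(n_shared, shared_alpha[[ty]], cfg$entity_length_distribution)
    }), all_types)

    corpora <- vector("list", cfg$n_corpora)
    for (i in seq_len(cfg$n_corpora)) {
      types_i <- cfg$entity_types[[i]]
      forms <- list()
      types_of <- character(0)
      heldout <- logical(0)
      for (ty in types_i) {
        own_alpha <- sprintf("pc%d_%s_%02d", i, tolower(ty),
                             seq_len(cfg$pieces_per_alphabet))
        shared <- shared_pool[[ty]]
        private <- sample_forms(cfg$lexicon_size - n_shared, own_alpha,
                                cfg$entity_length_distribution)
        # a quarter of the shared forms never occur in THIS corpus's train
        # split (they remain in its dev/test and in other corpora's train).
        # Held-out forms are chosen among those whose pieces all occur in
        # retained forms, so they are new combinations of attested pieces —
        # recoverable in principle, and directly trainable from the other
        # corpora.
        ho <- logical(length(shared))
        if (length(shared) >= 2L && cfg$n_corpora > 1L) {
          n_ho <- max(1L, as.integer(floor(cfg$heldout_fraction * length(shared))))
          cand <- sample.int(length(shared))
          for (ci in cand) {
            if (sum(ho) >= n_ho) break
            ho[ci] <- TRUE
            covered <- all(unlist(shared[ho]) %in% unlist(shared[!ho]))
            if (!covered) ho[ci] <- FALSE
          }
        }
        forms <- c(forms, shared, private)
        types_of <- c(types_of, rep(ty, length(shared) + length(private)))
        heldout <- c(heldout, ho, logical(length(private)))
      }
      keys <- vapply(forms, paste, character(1), collapse = " ")
      lex_all <- list(forms = forms, types = types_of, keys = keys)
      lex_train <- list(forms = forms[!heldout], types = types_of[!heldout],
                        keys = keys[!heldout])
      gen_split <- function(n_sentences, lex) {
        conll_split(lapply(seq_len(n_sentences), function(j) {
          generate_sentence(context_pool, lex, triggers, cfg)
        }), validate = FALSE)
      }
      corpora[[i]] <- corpus(
        sprintf("corpus%d", i),
        train = gen_split(cfg$sentences_per_split[["train"]], lex_train),
        dev = gen_split(cfg$sentences_per_split[["dev"]], lex_all),
        test = gen_split(cfg$sentences_per_split[["test"]], lex_all),
        entity_types = types_i)
    }
    # annotation-miss noise is a separate pass after generation, so the same
    # config with and without noise yields identical token streams
    if (cfg$label_noise_rate > 0) {
      for (i in seq_along(corpora)) {
        noisy <- conll_split(lapply(corpora[[i]]$train$sentences,
                                    apply_label_noise,
                                    rate = cfg$label_noise_rate),
                             validate = FALSE)
        corpora[[i]] <- corpus(corpora[[i]]$name, noisy, corpora[[i]]$dev,
                               corpora[[i]]$test,
                               entity_types = corpora[[i]]$entity_types)
      }
    }
    names(corpora) <- vapply(corpora, `[[`, character(1), "name")
    private_alpha <- unlist(lapply(seq_len(cfg$n_corpora), function(i) {
      unlist(lapply(cfg$entity_types[[i]], function(ty) {
        sprintf("pc%d_%s_%02d", i, tolower(ty),
                seq_len(cfg$pieces_per_alphabet))
      }))
    }))
    attr(corpora, "vocabulary") <-
      unique(c(context_pool, unlist(shared_alpha), private_alpha))
    attr(corpora, "config") <- cfg
    corpora
  })
}

#' Measure cross-corpus entity-surface overlap
#'
#' Fraction of corpus A's distinct entity surface forms of `type` (pooled over
#' splits) that also occur as entity surfaces of that type in corpus B.
#'
#' @param corpus_a,corpus_b `ner_corpus` objects.
#' @param type Entity type annotated by both corpora.
#' @return Overlap fraction in \[0, 1\].
#' @export
measure_entity_overlap <- function(corpus_a, corpus_b, type) {
  surfaces <- function(co) {
    out <- character(0)
    for (sp in list(co$train, co$dev, co$test)) {
      for (i in seq_along(sp$sentences)) {
        men <- tags_to_mentions(sp$sentences[[i]]$tag)
        men <- men[men$type == type, , drop = FALSE]
        if (nrow(men)) {
          out <- c(out, vapply(seq_len(nrow(men)), function(k) {
            paste(sp$sentences[[i]]$surface[(men$start[k] + 1L):men$end[k]],
                  collapse = " ")
          }, character(1)))
        }
      }
    }
    unique(out)
  }
  a <- surfaces(corpus_a)
  b <- surfaces(corpus_b)
  if (!length(a)) stopf("corpus '%s' has no %s mentions", corpus_a$name, type)
  mean(a %in% b)
}

#' Generate an auxiliary token-classification corpus
#'
#' Produces a POS-like corpus over the same sentences as `corpus`. With
#' probability `informativeness` a token's auxiliary label deterministically
#' encodes whether it lies inside an entity mention; otherwise the label is
#' uniform over the `n_aux_labels` classes — a dial from a useless to a
#' perfectly informative auxiliary task. Labels are encoded as single-token
#' BIOES tags (`S-P1`, `S-P2`, ...).
#'
#' @param corpus An `ner_corpus`.
#' @param informativeness Real in \[0, 1\].
#' @param n_aux_labels Number of auxiliary classes (>= 2).
#' @param seed Integer seed.
#' @return A token-classification `ner_corpus` named `<corpus>_aux`.
#' @export
generate_auxiliary_tagging <- function(corpus, informativeness, n_aux_labels,
                                       seed) {
  stopifnot(inherits(corpus, "ner_corpus"))
  if (informativeness < 0 || informativeness > 1) {
    stopf("`informativeness` must be in [0, 1]")
  }
  if (n_aux_labels < 2L) stopf("`n_aux_labels` must be >= 2")
  classes <- sprintf("P%d", seq_len(n_aux_labels))
  relabel_split <- function(sp) {
    conll_split(lapply(sp$sentences, function(s) {
      inside <- s$tag != "O"
      informative <- stats::runif(length(s$tag)) < informativeness
      lab <- ifelse(inside, classes[1L], classes[2L])
      rnd <- classes[sample.int(n_aux_labels, length(s$tag), replace = TRUE)]
      new_sentence(s$surface, paste0("S-", ifelse(informative, lab, rnd)))
    }), validate = FALSE)
  }
  with_seed(seed, corpus(paste0(corpus$name, "_aux"),
                         relabel_split(corpus$train),
                         relabel_split(corpus$dev),
                         relabel_split(corpus$test),
                         entity_types = classes))
}

#' Write a collection as CoNLL-style files
#'
#' Creates `<dir>/<corpus>/{train,dev,test}.conll` via [write_conll_split()].
#'
#' @param corpora List of `ner_corpus` objects.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_collection <- function(corpora, dir) {
  for (co in corpora) {
    d <- file.path(dir, co$name)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (sp in c("train", "dev", "test")) {
      write_conll_split(co[[sp]], file.path(d, paste0(sp, ".conll")))
    }
  }
  invisible(dir)
}

#' Full generator vocabulary of a collection
#'
#' All surfaces that can occur in a collection (context words, triggers and
#' entity pieces), suitable for [make_random_table()].
#'
#' @param corpora A collection from [generate_collection()].
#' @return Character vector of surfaces.
#' @export
collection_vocabulary <- function(corpora) {
  vocab <- attr(corpora, "vocabulary")
  if (!is.null(vocab)) return(vocab)
  unique(unlist(lapply(corpora, function(co) {
    unlist(lapply(list(co$train, co$dev, co$test), function(sp) {
      unlist(split_surfaces(sp))
    }))
  })))
}
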