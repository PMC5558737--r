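test_that("generated collections validate and are bit-reproducible", {
  col <- tiny_collection(n_corpora = 2L, seed = 5L)
  expect_length(col, 2L)
  for (co in col) {
    for (sp in list(co$train, co$dev, co$test)) {
      for (s in sp$sentences) {
        expect_true(bioes_valid(s$tag))
        expect_silent(tags_to_mentions(s$tag))
      }
    }
    expect_true(all(unlist(split_tags(co$train)) %in% co$label_vocabulary))
  }
  col2 <- tiny_collection(n_corpora = 2L, seed = 5L)
  expect_identical(col[[1]]$train$sentences, col2[[1]]$train$sentences)
  col3 <- tiny_collection(n_corpora = 2L, seed = 6L)
  expect_false(identical(col[[1]]$train$sentences, col3[[1]]$train$sentences))
})

test_that("shared-lexicon limits behave as configured", {
  base <- synthetic_config(n_corpora = 2L,
                           sentences_per_split = c(120L, 30L, 30L))
  zero <- base
  zero$shared_lexicon_fraction <- 0
  col0 <- generate_collection(zero)
  expect_equal(measure_entity_overlap(col0[[1]], col0[[2]], "GENE"), 0)
  one <- base
  one$shared_lexicon_fraction <- 1
  col1 <- generate_collection(one)
  expect_equal(measure_entity_overlap(col1[[1]], col1[[2]], "GENE"), 1,
               tolerance = 0.06)
})

test_that("measured entity overlap tracks the configured shared fraction", {
  col <- generate_collection(synthetic_config(n_corpora = 2L, seed = 31L))
  ov <- measure_entity_overlap(col[[1]], col[[2]], "GENE")
  expect_equal(ov, 0.5, tolerance = 0.05)
})

test_that("some test entities are unseen in their own train split but present
          in another corpus's train split", {
  col <- tiny_collection(n_corpora = 2L, seed = 17L, splits = c(150L, 40L, 60L))
  forms <- function(co, split, type = "GENE") {
    out <- character(0)
    sp <- co[[split]]
    for (i in seq_along(sp$sentences)) {
      s <- sp$sentences[[i]]
      m <- tags_to_mentions(s$tag)
      m <- m[m$type == type, , drop = FALSE]
      if (nrow(m)) out <- c(out, vapply(seq_len(nrow(m)), function(k) {
        paste(s$surface[(m$start[k] + 1L):m$end[k]], collapse = " ")
      }, character(1)))
    }
    unique(out)
  }
  unseen <- setdiff(forms(col[[1]], "test"), forms(col[[1]], "train"))
  expect_gt(length(unseen), 0L)
  expect_gt(length(intersect(unseen, forms(col[[2]], "train"))), 0L)
})

test_that("label noise flips whole training mentions to Out only", {
  cfg <- synthetic_config(n_corpora = 1L, label_noise_rate = 0.5,
                          sentences_per_split = c(120L, 20L, 20L), seed = 8L)
  noisy <- generate_collection(cfg)[[1L]]
  clean_cfg <- cfg
  clean_cfg$label_noise_rate <- 0
  clean <- generate_collection(clean_cfg)[[1L]]
  # surfaces identical, validity preserved, strictly fewer mentions
  expect_identical(split_surfaces(noisy$train), split_surfaces(clean$train))
  for (s in noisy$train$sentences) expect_true(bioes_valid(s$tag))
  expect_lt(nrow(split_mentions(noisy$train)), nrow(split_mentions(clean$train)))
  # dev/test untouched by noise
  expect_identical(split_tags(noisy$dev), split_tags(clean$dev))
  rate <- 1 - nrow(split_mentions(noisy$train)) / nrow(split_mentions(clean$train))
  expect_equal(rate, 0.5, tolerance = 0.12)
})

test_that("infeasible density/length configurations are rejected", {
  expect_error(synthetic_config(entity_density = 4, sentence_length_range = c(6, 8)),
               "infeasible")
  expect_error(synthetic_config(shared_lexicon_fraction = 1.2), "shared_lexicon")
  expect_error(synthetic_config(label_noise_rate = 1), "noise")
})

test_that("auxiliary tagging corpora span the informativeness dial", {
  col <- tiny_collection(n_corpora = 1L, seed = 13L, splits = c(200L, 30L, 30L))
  co <- col[[1L]]
  # informativeness 1: label perfectly encodes entity membership
  aux1 <- generate_auxiliary_tagging(co, 1, 2L, seed = 3L)
  expect_identical(split_surfaces(aux1$train), split_surfaces(co$train))
  for (i in seq_along(co$train$sentences)) {
    inside <- co$train$sentences[[i]]$tag != "O"
    expect_identical(aux1$train$sentences[[i]]$tag,
                     ifelse(inside, "S-P1", "S-P2"))
  }
  # informativeness 0: independent of entity status (chi-square at alpha 1e-3)
  aux0 <- generate_auxiliary_tagging(co, 0, 4L, seed = 3L)
  inside <- unlist(split_tags(co$train)) != "O"
  lab <- unlist(split_tags(aux0$train))
  p <- suppressWarnings(stats::chisq.test(table(inside, lab)))$p.value
  expect_gt(p, 1e-3)
  # determinism
  expect_identical(generate_auxiliary_tagging(co, 0.5, 3L, seed = 9L),
                   generate_auxiliary_tagging(co, 0.5, 3L, seed = 9L))
  expect_error(generate_auxiliary_tagging(co, 0.5, 1L, seed = 1L), "aux_labels")
})

test_that("the default noiseless task is solvable: a single-task model exceeds
          0.9 test F1", {
  col <- generate_collection(synthetic_config(seed = 1L))
  tab <- make_random_table(collection_vocabulary(col), 50L, seed = 2L)
  arch <- architecture_spec("single_task", embedding_dimension = 50L,
                            filters_per_width = 25L,
                            fully_connected_size = 100L)
  fit <- train_single_task(col[[1]], arch,
                           training_schedule(2500L, 50L, 3e-3, 500L, 1000L,
                                             seed = 3L),
                           tab)
  expect_gt(evaluate_fit(fit, col[[1]], "test")$f1, 0.9)
})

test_that("collections write and re-read as CoNLL files", {
  col <- tiny_collection(n_corpora = 2L, seed = 23L, splits = c(20L, 5L, 5L))
  dir <- withr::local_tempdir()
  write_collection(col, dir)
  back <- corpus("corpus1",
                 read_conll_split(file.path(dir, "corpus1", "train.conll")),
                 read_conll_split(file.path(dir, "corpus1", "dev.conll")),
                 read_conll_split(file.path(dir, "corpus1", "test.conll")))
  expect_identical(back$train$sentences, col[[1]]$train$sentences)
  expect_identical(back$label_vocabulary, col[[1]]$label_vocabulary)
})
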