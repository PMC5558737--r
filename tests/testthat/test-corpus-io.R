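test_that("CoNLL reading parses tokens, collapses blank lines, handles empty files", {
  path <- withr::local_tempfile()
  writeLines(c("IL-2\tS-Protein", "binds\tO", ""), path)
  sp <- read_conll_split(path)
  expect_length(sp, 1L)
  expect_equal(sp$sentences[[1]]$surface, c("IL-2", "binds"))
  expect_equal(sp$sentences[[1]]$tag, c("S-Protein", "O"))

  writeLines(character(), path)
  expect_length(read_conll_split(path), 0L)

  writeLines(c("a\tS-G", "", "", "b\tS-G"), path)
  expect_length(read_conll_split(path), 2L)
})

test_that("CoNLL reading reports malformed lines and invalid tags", {
  path <- withr::local_tempfile()
  writeLines(c("solo"), path)
  expect_error(read_conll_split(path, token_column = 1, tag_column = 2),
               "line 1")
  writeLines(c("a\tX-G"), path)
  expect_error(read_conll_split(path), "malformed tag")
  writeLines(c("a\tI-G"), path)
  expect_error(read_conll_split(path), "continue")
})

test_that("IOB input is repaired to BIOES behind the explicit flag", {
  path <- withr::local_tempfile()
  writeLines(c("a\tB-G", "b\tI-G", "c\tO", "d\tB-G", "", "e\tI-C"), path)
  expect_error(read_conll_split(path), "BIOES")
  sp <- read_conll_split(path, repair_iob = TRUE)
  expect_equal(sp$sentences[[1]]$tag, c("B-G", "E-G", "O", "S-G"))
  expect_equal(sp$sentences[[2]]$tag, "S-C")
})

test_that("write/read round trip is the identity, including unicode surfaces", {
  sents <- list(s_(c("IL-2", "binds"), c("S-Protein", "O")),
                s_(c("α-catenin", "x"), c("S-G", "O")),
                s_(c("one"), c("O")))
  sp <- conll_split(sents)
  path <- withr::local_tempfile()
  write_conll_split(sp, path)
  back <- read_conll_split(path)
  expect_equal(back$sentences, sp$sentences)
  # byte-level preservation of the Greek letter
  expect_identical(charToRaw(back$sentences[[2]]$surface[1]),
                   charToRaw(sp$sentences[[2]]$surface[1]))
  # empty split -> empty file
  write_conll_split(conll_split(), path)
  expect_length(read_conll_split(path), 0L)
})

test_that("tags_to_mentions follows the BIOES span rules", {
  expect_equal(tags_to_mentions(c("S-Chem"), 4L),
               data.frame(sentence = 4L, start = 0L, end = 1L, type = "Chem",
                          stringsAsFactors = FALSE))
  expect_equal(tags_to_mentions(c("B-Chem", "E-Chem"))[, c("start", "end")],
               data.frame(start = 0L, end = 2L))
  m <- tags_to_mentions(c("B-G", "I-G", "E-G", "O", "S-C"), 0L)
  expect_equal(m$start, c(0L, 4L))
  expect_equal(m$end, c(3L, 5L))
  expect_equal(m$type, c("G", "C"))
  expect_error(tags_to_mentions(c("I-G", "O")), "BIOES")
})

test_that("mentions_to_tags inverts tags_to_mentions and rejects overlaps", {
  expect_equal(mentions_to_tags(data.frame(start = 0L, end = 1L, type = "G"), 2L),
               c("S-G", "O"))
  expect_equal(mentions_to_tags(empty_mentions(), 3L), c("O", "O", "O"))
  expect_equal(mentions_to_tags(data.frame(start = 1L, end = 4L, type = "G"), 5L),
               c("O", "B-G", "I-G", "E-G", "O"))
  overlapping <- data.frame(start = c(0L, 1L), end = c(2L, 3L),
                            type = c("G", "G"))
  expect_error(mentions_to_tags(overlapping, 4L), "overlap")
})

test_that("tags<->mentions are mutually inverse on random valid sequences", {
  set.seed(42)
  for (rep in 1:250) {
    tags <- random_bioes_tags(sample(1:12, 1))
    men <- tags_to_mentions(tags, 0L)
    expect_identical(mentions_to_tags(men, length(tags)), tags)
    men2 <- random_mentions(sample(1:12, 1))
    len <- max(c(men2$end, 5L))
    tags2 <- mentions_to_tags(men2, len)
    back <- tags_to_mentions(tags2, 0L)
    expect_equal(back[order(back$start), ]$start, sort(men2$start))
    expect_equal(nrow(back), nrow(men2))
  }
})

test_that("corpus derives a sorted label vocabulary with O first", {
  co <- make_corpus("x", list(s_(c("a", "b", "c"),
                                 c("S-G", "O", "S-C"))))
  expect_equal(co$label_vocabulary[1], "O")
  expect_equal(sort(co$entity_types), c("C", "G"))
  expect_length(co$label_vocabulary, 9L)
  expect_identical(co$label_vocabulary, unique(co$label_vocabulary))
  expect_error(corpus("y", co$train, co$dev, co$test, entity_types = "Z"),
               "not in label vocabulary")
})

test_that("restrict_to_entity_type relabels other types to Out only", {
  co <- make_corpus("x", list(s_(c("a", "b", "c"),
                                 c("B-Chem", "E-Chem", "S-Dis"))),
                    entity_types = c("Chem", "Dis"))
  r <- restrict_to_entity_type(co, "Chem")
  expect_equal(r$train$sentences[[1]]$tag, c("B-Chem", "E-Chem", "O"))
  expect_equal(r$train$sentences[[1]]$surface, co$train$sentences[[1]]$surface)
  expect_length(r$label_vocabulary, 5L)
  r2 <- restrict_to_entity_type(co, "Dis")
  expect_equal(r2$train$sentences[[1]]$tag, c("O", "O", "S-Dis"))
  only <- restrict_to_entity_type(r, "Chem")
  expect_equal(only$train$sentences, r$train$sentences)
  expect_error(restrict_to_entity_type(co, "Nope"), "no entity type")
})

test_that("subsample_training is seed-deterministic and leaves dev/test alone", {
  sents <- lapply(1:10, function(i) s_(c(sprintf("w%d", i)), c("O")))
  co <- make_corpus("x", sents,
                    dev = sents[1:2], test = sents[3:4])
  half <- subsample_training(co, 0.5, seed = 9)
  expect_length(half$train, 5L)
  expect_equal(half$dev$sentences, co$dev$sentences)
  expect_equal(half$test$sentences, co$test$sentences)
  expect_equal(subsample_training(co, 1.0, seed = 1)$train$sentences,
               co$train$sentences)
  again <- subsample_training(co, 0.5, seed = 9)
  expect_identical(half$train$sentences, again$train$sentences)
  other <- subsample_training(co, 0.5, seed = 10)
  expect_false(identical(half$train$sentences, other$train$sentences))
  # order preserved
  idx <- match(vapply(half$train$sentences, function(s) s$surface[1], ""),
               vapply(co$train$sentences, function(s) s$surface[1], ""))
  expect_identical(idx, sort(idx))
  expect_error(subsample_training(co, 0, seed = 1), "fraction")
  expect_error(subsample_training(co, 1.2, seed = 1), "fraction")
})

test_that("cross-split overlap counts verbatim surface matches", {
  mk <- function(words) conll_split(lapply(words, function(w) {
    s_(strsplit(w, " ")[[1]], rep("O", length(strsplit(w, " ")[[1]])))
  }))
  train <- mk(c("a b", "c d"))
  expect_equal(compute_cross_split_overlap(train, mk(c("a b", "c d"))), 1.0)
  expect_equal(compute_cross_split_overlap(train, mk(c("x y"))), 0.0)
  expect_equal(compute_cross_split_overlap(train, mk(c("c d", "e f"))), 0.5)
  expect_error(compute_cross_split_overlap(train, conll_split()), "empty")
})
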