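# Model tests run on a tiny architecture (4 filters per width, fc 8, d 10)
# so each forward/backward is instant; shapes and contracts are identical to
# the full-size configuration.

mdl_corpus <- make_corpus("m1", list(
  s_(c("a", "b", "c", "d"), c("O", "S-G", "B-C", "E-C")),
  s_(c("e", "f"), c("S-C", "O"))))
mdl_corpus2 <- make_corpus("m2", list(s_(c("a", "g"), c("S-G", "O"))),
                           entity_types = c("G", "X"))
mdl_tab <- make_random_table(letters[1:10], 10, seed = 4)

mdl_batch <- function(corpus = mdl_corpus, sent = 1L) {
  ex <- build_window_examples(corpus$train$sentences[[sent]], 3L, corpus)
  minibatch(ex$windows, ex$labels, corpus$name)
}

test_that("initialisation is seed-deterministic with spec-consistent shapes", {
  spec <- tiny_arch("multi_output")
  tasks <- c(m1 = 5L, m2 = 9L)
  m1 <- init_model(spec, tasks, seed = 11)
  m2 <- init_model(spec, tasks, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(spec, tasks, seed = 12)
  expect_false(identical(m1$params, m3$params))
  expect_equal(dim(m1$params$conv_W_3), c(30L, 4L))
  expect_equal(dim(m1$params$fc_W), c((5 + 4 + 3) * 4, 8L))
  expect_equal(dim(m1$params[[head_name("m1", "W")]]), c(8L, 5L))
  expect_equal(dim(m1$params[[head_name("m2", "W")]]), c(8L, 9L))
  expect_error(architecture_spec("single_task", embedding_dimension = 10,
                                 n = 3, filter_widths = 9), "exceeds")
})

test_that("baseline forward is ReLU-affine-softmax over the window concat", {
  spec <- tiny_arch("baseline")
  model <- init_model(spec, c(m1 = 5L), seed = 2)
  probs <- forward_baseline(model, mdl_batch(), mdl_tab)
  expect_equal(dim(probs), c(4L, 5L))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  # all-zero parameters -> uniform distribution
  z <- model
  z$params <- lapply(z$params, function(p) p * 0)
  pz <- forward_baseline(z, mdl_batch(), mdl_tab)
  expect_true(all(abs(pz - 0.2) < 1e-12))
})

test_that("single-task trunk has the documented flat feature length and is
          deterministic with dropout off", {
  spec <- architecture_spec("single_task", embedding_dimension = 10,
                            filters_per_width = 100)
  expect_equal(trunk_feature_length(spec), (5 + 4 + 3) * 100)
  model <- init_model(tiny_arch("single_task"), c(m1 = 5L), seed = 3)
  o1 <- forward_single_task(model, mdl_batch(), mdl_tab)
  o2 <- forward_single_task(model, mdl_batch(), mdl_tab)
  expect_identical(o1$probs, o2$probs)
  expect_true(all(abs(rowSums(o1$probs) - 1) < 1e-6))
  expect_equal(dim(o1$fc), c(4L, 8L))
})

test_that("no pooling: permuting window token order changes trunk output", {
  model <- init_model(tiny_arch("single_task"), c(m1 = 5L), seed = 3)
  b <- mdl_batch()
  perm <- b
  perm$windows <- b$windows[, c(2, 1, 3, 5, 4, 7, 6), drop = FALSE]
  o <- forward_single_task(model, b, mdl_tab)
  op <- forward_single_task(model, perm, mdl_tab)
  expect_false(isTRUE(all.equal(o$probs, op$probs)))
})

test_that("multi-output heads share the trunk and emit per-task label counts", {
  spec <- tiny_arch("multi_output")
  model <- init_model(spec, c(m1 = length(mdl_corpus$label_vocabulary),
                              m2 = length(mdl_corpus2$label_vocabulary)),
                      seed = 5)
  b <- mdl_batch()
  o1 <- forward_multi_output(model, b, mdl_tab, "m1")
  o2 <- forward_multi_output(model, b, mdl_tab, "m2")
  expect_equal(ncol(o1$probs), 9L)
  expect_equal(ncol(o2$probs), 9L)
  expect_identical(o1$fc, o2$fc)  # shared trunk activations
  expect_error(forward_multi_output(model, b, mdl_tab, "nope"), "unknown task")
})

test_that("a single-task multi-output model equals the single-task model", {
  spec_mo <- tiny_arch("multi_output")
  spec_st <- tiny_arch("single_task")
  mo <- init_model(spec_mo, c(m1 = 9L), seed = 6)
  st <- init_model(spec_st, c(m1 = 9L), seed = 6)
  expect_identical(mo$params, st$params)
  b <- mdl_batch()
  expect_identical(forward_multi_output(mo, b, mdl_tab, "m1")$probs,
                   forward_single_task(st, b, mdl_tab)$probs)
})

test_that("dependent models concatenate main and frozen auxiliary fc layers", {
  aux <- init_model(tiny_arch("single_task"), c(aux = 5L), seed = 7)
  main_spec <- tiny_arch("single_task")
  dep <- assemble_dependent(main_spec, aux, main_labels = 9L, seed = 8,
                            task_name = "m1")
  expect_equal(dim(dep$params$out_W), c(16L, 9L))  # 8 main + 8 aux
  b <- mdl_batch()
  o <- forward_dependent(dep, b, mdl_tab)
  expect_true(all(abs(rowSums(o$probs) - 1) < 1e-6))
  o2 <- forward_dependent(dep, b, mdl_tab)
  expect_identical(o$probs, o2$probs)  # aux pass deterministic, dropout off
  bad <- tiny_arch("single_task", d = 12L)
  expect_error(assemble_dependent(bad, aux, 9L, 1), "dimension mismatch")
})

test_that("train_step reduces loss and matches closed-form loss values", {
  model <- init_model(tiny_arch("single_task"), c(m1 = 9L), seed = 9)
  b <- mdl_batch()
  opt <- init_optimizer(model, learning_rate = 1e-2)
  set.seed(1)
  # uniform outputs give ln(L) per example
  z <- model
  z$params <- lapply(z$params, function(p) p * 0)
  zr <- train_step(z, b, mdl_tab, init_optimizer(z))
  expect_equal(zr$loss, log(9), tolerance = 1e-10)
  losses <- numeric(60)
  st <- list(model = model, opt = opt)
  set.seed(2)
  for (i in seq_len(60)) {
    st <- train_step(st$model, b, mdl_tab, st$opt)
    losses[i] <- st$loss
  }
  expect_lt(mean(tail(losses, 5)), mean(head(losses, 5)))
  # near-perfect predictions give near-zero loss
  probs <- forward_single_task(st$model, b, mdl_tab)$probs
  if (all(max.col(probs) == b$labels)) {
    expect_lt(cross_entropy(probs, b$labels), log(9))
  }
  expect_error(train_step(model, minibatch(b$windows, rep(99L, 4), "m1"),
                          mdl_tab, opt), "out of range")
})

test_that("multi-output training isolates gradients to the active head", {
  model <- init_model(tiny_arch("multi_output"), c(m1 = 9L, m2 = 9L), seed = 10)
  ex <- build_window_examples(mdl_corpus$train$sentences[[1]], 3L, mdl_corpus)
  b <- minibatch(ex$windows, ex$labels, "m1")
  set.seed(3)
  res <- train_step(model, b, mdl_tab, init_optimizer(model), task = "m1")
  after <- res$model$params
  expect_identical(after[[head_name("m2", "W")]],
                   model$params[[head_name("m2", "W")]])
  expect_identical(after[[head_name("m2", "b")]],
                   model$params[[head_name("m2", "b")]])
  expect_false(identical(after[[head_name("m1", "W")]],
                         model$params[[head_name("m1", "W")]]))
  expect_false(identical(after$fc_W, model$params$fc_W))
  expect_false(identical(after$conv_W_3, model$params$conv_W_3))
  expect_error(train_step(model, b, mdl_tab, init_optimizer(model),
                          task = "m2"), "cannot train")
})

test_that("dependent training never touches the frozen auxiliary", {
  aux <- init_model(tiny_arch("single_task"), c(aux = 5L), seed = 12)
  dep <- assemble_dependent(tiny_arch("single_task"), aux, 9L, seed = 13,
                            task_name = "m1")
  before <- dep$aux$params
  b <- mdl_batch()
  st <- list(model = dep, opt = init_optimizer(dep))
  set.seed(4)
  for (i in 1:10) st <- train_step(st$model, b, mdl_tab, st$opt)
  expect_identical(st$model$aux$params, before)
  expect_false(identical(st$model$params$out_W, dep$params$out_W))
})

test_that("checkpoints round-trip through the versioned serialisation", {
  model <- init_model(tiny_arch("single_task"), c(m1 = 9L), seed = 14)
  path <- withr::local_tempfile()
  save_ner_model(model, path)
  back <- load_ner_model(path)
  expect_identical(back$params, model$params)
  expect_equal(back$version, 1L)
})
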