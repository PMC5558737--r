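# Training-loop tests run tiny corpora and a narrow architecture; they check
# loop contracts (checkpointing, stopping, logging, determinism, freezing),
# not final task quality, which the longer-running acceptance suite covers.

trn_sched <- function(steps = 60L, seed = 1L, eval_every = 20L,
                      patience = 100L, lr = 3e-3) {
  training_schedule(max_steps = steps, batch_size = 16L, learning_rate = lr,
                    eval_every = eval_every, patience = patience, seed = seed)
}

trn_col <- tiny_collection(n_corpora = 2L, seed = 201L, splits = c(30L, 10L, 10L))
trn_tab <- table_for(trn_col, d = 10L)

test_that("single-task training logs losses, selects the best checkpoint, and
          is seed-reproducible", {
  fit <- train_single_task(trn_col[[1]], tiny_arch(), trn_sched(), trn_tab)
  expect_s3_class(fit, "ner_fit")
  expect_equal(nrow(fit$loss_log), 60L)
  expect_true(all(is.finite(fit$loss_log$loss)))
  mean_rows <- fit$dev_history[fit$dev_history$task == ".mean", ]
  expect_equal(fit$best_score, max(mean_rows$score))
  expect_equal(fit$selected_step,
               mean_rows$step[which.max(mean_rows$score)])  # earliest on ties
  fit2 <- train_single_task(trn_col[[1]], tiny_arch(), trn_sched(), trn_tab)
  expect_identical(fit$dev_history, fit2$dev_history)
  expect_identical(fit$model$params, fit2$model$params)
  fit3 <- train_single_task(trn_col[[1]], tiny_arch(), trn_sched(seed = 2L),
                            trn_tab)
  expect_false(identical(fit$loss_log$loss, fit3$loss_log$loss))
})

test_that("early stopping halts after `patience` non-improving evaluations", {
  # an effectively frozen model (learning rate ~ 0) never improves after the
  # first evaluation, so patience 1 stops after exactly 2 evaluations
  fit <- train_single_task(trn_col[[1]], tiny_arch(),
                           trn_sched(steps = 200L, eval_every = 10L,
                                     patience = 1L, lr = 1e-12),
                           trn_tab)
  mean_rows <- fit$dev_history[fit$dev_history$task == ".mean", ]
  expect_equal(nrow(mean_rows), 2L)
  expect_equal(max(fit$loss_log$step), 20L)
})

test_that("multi-output training with one corpus reduces to single-task", {
  st <- train_single_task(trn_col[[1]], tiny_arch("single_task"), trn_sched(),
                          trn_tab)
  mo <- train_multi_output(trn_col[1], tiny_arch("multi_output"), trn_sched(),
                           trn_tab)
  expect_identical(st$dev_history, mo$dev_history)
  expect_identical(st$loss_log$loss, mo$loss_log$loss)
})

test_that("multi-output training samples tasks randomly and logs them", {
  fit <- train_multi_output(trn_col, tiny_arch("multi_output"),
                            trn_sched(steps = 120L), trn_tab)
  expect_setequal(unique(fit$loss_log$task), c("corpus1", "corpus2"))
  counts <- table(fit$loss_log$task)
  expect_true(all(counts > 30))  # both tasks drawn regularly
  expect_error(train_multi_output(list(trn_col[[1]], trn_col[[1]]),
                                  tiny_arch("multi_output"), trn_sched(),
                                  trn_tab),
               "duplicate")
})

test_that("dependent training freezes the auxiliary through phase 2", {
  aux <- generate_auxiliary_tagging(trn_col[[2]], 1, 2L, seed = 5L)
  fit <- train_dependent(trn_col[[1]], aux, tiny_arch(), tiny_arch(),
                         trn_sched(steps = 40L), trn_sched(steps = 40L),
                         trn_tab)
  expect_equal(fit$aux_fit$metric, "token_accuracy")
  expect_true(all(fit$aux_fit$dev_history$score >= 0 &
                    fit$aux_fit$dev_history$score <= 1))
  expect_identical(fit$model$aux$params, fit$aux_fit$model$params)
  expect_equal(fit$model$kind, "dependent")
})

test_that("the ner_fit interface predicts valid tag sequences and evaluates", {
  fit <- train_single_task(trn_col[[1]], tiny_arch(), trn_sched(), trn_tab)
  pred <- predict(fit, trn_col[[1]]$test)
  expect_length(pred, length(trn_col[[1]]$test))
  for (tags in pred) expect_true(bioes_valid(tags))
  rep <- evaluate_fit(fit, trn_col[[1]], "test")
  expect_s3_class(rep, "evaluation_report")
  expect_true(rep$f1 >= 0 && rep$f1 <= 1)
  expect_output(print(fit), "ner_fit")
  expect_output(summary(fit), "Selected step")
})

test_that("fit_ner dispatches on kind", {
  fit <- fit_ner(trn_col[[1]], kind = "single_task", table = trn_tab,
                 schedule = trn_sched(steps = 20L),
                 filters_per_width = 4L, fully_connected_size = 8L)
  expect_equal(fit$kind, "single_task")
  fitb <- fit_ner(trn_col[[1]], kind = "baseline", table = trn_tab,
                  schedule = trn_sched(steps = 20L))
  expect_equal(fitb$kind, "baseline")
})

test_that("run directories capture config, logs and the best checkpoint", {
  dir <- withr::local_tempdir()
  rd <- file.path(dir, "run1")
  fit <- train_single_task(trn_col[[1]], tiny_arch(), trn_sched(steps = 20L),
                           trn_tab, run_dir = rd)
  expect_true(file.exists(file.path(rd, "config.yaml")))
  expect_true(file.exists(file.path(rd, "loss_log.tsv")))
  expect_true(file.exists(file.path(rd, "dev_history.tsv")))
  model <- load_ner_model(file.path(rd, "best_model.rds"))
  expect_identical(model$params, fit$model$params)
  cfg <- yaml::read_yaml(file.path(rd, "config.yaml"))
  expect_equal(cfg$kind, "single_task")
})
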