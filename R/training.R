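# Training loops. All randomness (task choice, shuffling, dropout, init) is
# driven by the schedule seed, so a run is bit-reproducible single-threaded.
# Models are trained on the train section, checkpoints are selected on the
# development section, and final evaluations are done on the test section.

#' Define a training schedule
#'
#' The full-scale reference configuration is 190,000 steps with mini-batches
#' of 200 examples, Adam at learning rate 1e-4. Early stopping (an evaluation
#' on the development split every `eval_every` steps, stopping after
#' `patience` evaluations without improvement) substitutes for fixed
#' per-dataset step counts.
#'
#' @param max_steps Maximum optimisation steps.
#' @param batch_size Mini-batch size (the baseline model uses 50).
#' @param learning_rate Optimiser step size.
#' @param eval_every Steps between development-split evaluations.
#' @param patience Consecutive non-improving evaluations before stopping.
#' @param seed Integer seed driving every source of randomness in the run.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(max_steps = 190000L, batch_size = 200L,
                              learning_rate = 1e-4, eval_every = 2000L,
                              patience = 10L, seed = 1L) {
  stopifnot(max_steps >= 1, batch_size >= 1, learning_rate > 0,
            eval_every >= 1, patience >= 1)
  structure(list(max_steps = as.integer(max_steps),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "training_schedule")
}

# Dev-set score of one task: mention F1 (with Viterbi repair) for NER tasks,
# token accuracy for auxiliary token-classification tasks.
dev_score <- function(model, corpus, table, trans, task, metric) {
  pred <- predict_tags(model, corpus$dev, corpus, table, trans = trans,
                       task = task)
  if (metric == "token_accuracy") {
    score_token_accuracy(split_tags(corpus$dev), pred)
  } else {
    score_tagged_split(corpus$dev, pred)$f1
  }
}

# Shared training loop over one or more tasks.
train_loop <- function(model, corpora, schedule, table, metric = "f1",
                       run_dir = NULL) {
  task_names <- vapply(corpora, `[[`, character(1), "name")
  names(corpora) <- task_names
  trans <- lapply(corpora, function(co) {
    fit_transition_matrix(co$train, co$label_vocabulary)
  })
  datasets <- lapply(corpora, function(co) {
    window_dataset(co$train, co, model$spec$n, table)
  })
  iterators <- lapply(seq_along(corpora), function(i) {
    batch_iterator(corpora[[i]]$train, corpora[[i]], model$spec$n,
                   schedule$batch_size, derive_seed(schedule$seed, i), table)
  })
  names(iterators) <- task_names
  Eaug <- augmented_matrix(table)
  opt <- init_optimizer(model, learning_rate = schedule$learning_rate)
  multi <- length(task_names) > 1L

  best <- list(model = model, score = -Inf, step = 0L)
  history <- list()
  losses <- list()
  stale <- 0L

  with_seed(derive_seed(schedule$seed, 0L), {
    for (step in seq_len(schedule$max_steps)) {
      task <- if (multi) task_names[sample.int(length(task_names), 1L)] else task_names[1L]
      raw <- iterators[[task]]()
      ds <- datasets[[task]]
      batch <- list(X = embed_rows(ds, raw$rows, Eaug), labels = raw$labels,
                    corpus_name = task)
      res <- train_step(model, batch, table, opt, task = task)
      model <- res$model
      opt <- res$opt
      if (!is.finite(res$loss)) {
        stopf("training diverged: non-finite loss at step %d (task %s)",
              step, task)
      }
      losses[[step]] <- data.frame(step = step, task = task, loss = res$loss,
                                   stringsAsFactors = FALSE)
      if (step %% schedule$eval_every == 0L || step == schedule$max_steps) {
        scores <- vapply(task_names, function(tk) {
          dev_score(model, corpora[[tk]], table, trans[[tk]], tk, metric)
        }, numeric(1))
        mean_score <- mean(scores)
        history[[length(history) + 1L]] <-
          data.frame(step = step, task = c(task_names, ".mean"),
                     score = c(scores, mean_score), stringsAsFactors = FALSE)
        if (mean_score > best$score) {
          best <- list(model = model, score = mean_score, step = step)
          stale <- 0L
        } else {
          stale <- stale + 1L
        }
        if (stale >= schedule$patience) break
      }
    }
  })

  fit <- structure(list(model = best$model,
                        kind = model$kind,
                        corpora = task_names,
                        label_vocabs = lapply(corpora, `[[`, "label_vocabulary"),
                        trans = trans,
                        dev_history = do.call(rbind, history),
                        loss_log = do.call(rbind, losses),
                        selected_step = best$step,
                        best_score = best$score,
                        metric = metric,
                        schedule = schedule,
                        table = table),
                   class = "ner_fit")
  if (!is.null(run_dir)) write_run_dir(fit, run_dir)
  fit
}

#' Train a single-task model
#'
#' Loops [train_step()] over shuffled mini-batches; every `eval_every` steps
#' the development split is scored (mention F1 with Viterbi repair, or token
#' accuracy for auxiliary tasks) and the best checkpoint retained, stopping at
#' `max_steps` or when `patience` consecutive evaluations fail to improve.
#'
#' @param corpus An `ner_corpus` with non-empty splits.
#' @param spec An [architecture_spec()] of kind `"single_task"` or
#'   `"baseline"`.
#' @param schedule A [training_schedule()].
#' @param table An `embedding_table`.
#' @param selection_metric `"f1"` (mention level, default) or
#'   `"token_accuracy"`.
#' @param run_dir Optional directory for config snapshot, loss log, dev
#'   history and best checkpoint.
#' @return An object of class `ner_fit`.
#' @export
train_single_task <- function(corpus, spec, schedule, table,
                              selection_metric = c("f1", "token_accuracy"),
                              run_dir = NULL) {
  stopifnot(inherits(corpus, "ner_corpus"))
  selection_metric <- match.arg(selection_metric)
  if (length(corpus$train) == 0L || length(corpus$dev) == 0L) {
    stopf("corpus '%s' needs non-empty train and dev splits", corpus$name)
  }
  tasks <- stats::setNames(length(corpus$label_vocabulary), corpus$name)
  model <- init_model(spec, tasks, seed = derive_seed(schedule$seed, 101L))
  train_loop(model, list(corpus), schedule, table, metric = selection_metric,
             run_dir = run_dir)
}

#' Train a multi-output multi-task model
#'
#' At each step a dataset is chosen uniformly at random (seed-deterministic),
#' a mini-batch is drawn from its iterator, and one update is applied through
#' that dataset's private softmax head and the shared trunk. The checkpoint is
#' selected by the unweighted mean of per-task development F1.
#'
#' @param corpora List of `ner_corpus` objects with distinct names (a single
#'   corpus reduces to single-task behaviour).
#' @inheritParams train_single_task
#' @return An `ner_fit`; `dev_history` holds per-task and `.mean` rows.
#' @export
train_multi_output <- function(corpora, spec, schedule, table, run_dir = NULL) {
  stopifnot(length(corpora) >= 1L)
  nm <- vapply(corpora, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("duplicate corpus names: %s",
                               paste(nm[duplicated(nm)], collapse = ", "))
  spec$kind <- "multi_output"
  tasks <- stats::setNames(vapply(corpora, function(co) {
    length(co$label_vocabulary)
  }, integer(1)), nm)
  model <- init_model(spec, tasks, seed = derive_seed(schedule$seed, 101L))
  train_loop(model, corpora, schedule, table, metric = "f1", run_dir = run_dir)
}

#' Train a dependent multi-task model
#'
#' Phase 1 trains a single-task network on the auxiliary token-classification
#' corpus (checkpoint selected by development token accuracy). Phase 2
#' assembles the dependent model around the frozen auxiliary network and
#' trains the main task only.
#'
#' @param main,auxiliary `ner_corpus` objects (the auxiliary is typically a
#'   POS-like token-classification corpus over its own sentences).
#' @param main_spec,aux_spec [architecture_spec()]s (embedding dimension and
#'   context half-width must agree).
#' @param main_schedule,aux_schedule [training_schedule()]s for the phases.
#' @inheritParams train_single_task
#' @return An `ner_fit` for the main task; the auxiliary phase's fit is
#'   attached as `$aux_fit`.
#' @export
train_dependent <- function(main, auxiliary, main_spec, aux_spec,
                            main_schedule, aux_schedule, table,
                            run_dir = NULL) {
  aux_spec$kind <- "single_task"
  aux_fit <- train_single_task(auxiliary, aux_spec, aux_schedule, table,
                               selection_metric = "token_accuracy")
  model <- assemble_dependent(main_spec, aux_fit$model,
                              length(main$label_vocabulary),
                              seed = derive_seed(main_schedule$seed, 202L),
                              task_name = main$name)
  fit <- train_loop(model, list(main), main_schedule, table, metric = "f1",
                    run_dir = run_dir)
  fit$aux_fit <- aux_fit
  fit
}

#' Fit an NER tagger
#'
#' Umbrella fitting function dispatching on architecture kind:
#' `"baseline"`/`"single_task"` train on one corpus, `"multi_output"` on a
#' list of corpora with hard parameter sharing, `"dependent"` on a main corpus
#' plus a pre-trainable auxiliary corpus.
#'
#' @param corpora An `ner_corpus` or list of them (main corpus first).
#' @param kind Architecture kind.
#' @param table An `embedding_table`.
#' @param schedule A [training_schedule()].
#' @param auxiliary Auxiliary `ner_corpus` (dependent kind only).
#' @param spec Optional [architecture_spec()]; built from `...` when `NULL`.
#' @param ... Passed to [architecture_spec()] when `spec` is `NULL`.
#' @return An `ner_fit`.
#' @export
fit_ner <- function(corpora, kind = c("single_task", "multi_output",
                                      "dependent", "baseline"),
                    table, schedule = training_schedule(),
                    auxiliary = NULL, spec = NULL, ...) {
  kind <- match.arg(kind)
  if (inherits(corpora, "ner_corpus")) corpora <- list(corpora)
  if (is.null(spec)) {
    spec <- architecture_spec(kind = kind,
                              embedding_dimension = table$dimension, ...)
  }
  spec$kind <- kind
  switch(kind,
         baseline = ,
         single_task = train_single_task(corpora[[1L]], spec, schedule, table),
         multi_output = train_multi_output(corpora, spec, schedule, table),
         dependent = {
           if (is.null(auxiliary)) stopf("dependent kind needs `auxiliary`")
           train_dependent(corpora[[1L]], auxiliary, spec, spec,
                           schedule, schedule, table)
         })
}

# ---- ner_fit methods --------------------------------------------------------

#' @export
print.ner_fit <- function(x, ...) {
  cat(sprintf("<ner_fit '%s' on {%s}: best dev %s %.4f at step %d>\n",
              x$kind, paste(x$corpora, collapse = ", "),
              x$metric, x$best_score, x$selected_step))
  invisible(x)
}

#' @export
summary.ner_fit <- function(object, ...) {
  cat(sprintf("Model kind:      %s\n", object$kind))
  cat(sprintf("Tasks:           %s\n", paste(object$corpora, collapse = ", ")))
  cat(sprintf("Selected step:   %d (dev %s %.4f)\n",
              object$selected_step, object$metric, object$best_score))
  cat(sprintf("Steps run:       %d\n", max(object$loss_log$step)))
  cat(sprintf("Final mean loss: %.4f (last 10 steps)\n",
              mean(utils::tail(object$loss_log$loss, 10L))))
  if (!is.null(object$dev_history)) {
    last <- object$dev_history[object$dev_history$step ==
                                 max(object$dev_history$step), ]
    cat("Last evaluation:\n")
    for (i in seq_len(nrow(last))) {
      cat(sprintf("  %-12s %.4f\n", last$task[i], last$score[i]))
    }
  }
  invisible(object)
}

#' Predict repaired tag sequences for new sentences
#'
#' @param object An `ner_fit`.
#' @param newdata A [conll_split()] (tags may be dummy `"O"` placeholders).
#' @param task Task name (defaults to the first/only task).
#' @param repair Apply binary-transition Viterbi repair (default `TRUE`).
#' @param ... Unused.
#' @return List of predicted tag vectors, one per sentence.
#' @export
predict.ner_fit <- function(object, newdata, task = NULL, repair = TRUE, ...) {
  task <- task %||% object$corpora[[1L]]
  if (!task %in% object$corpora) stopf("unknown task '%s'", task)
  stub <- structure(list(name = task,
                         label_vocabulary = object$label_vocabs[[task]]),
                    class = "ner_corpus")
  # prediction windows need label indices; substitute "O" for unseen tags
  newdata <- conll_split(lapply(newdata$sentences, function(s) {
    tg <- ifelse(s$tag %in% stub$label_vocabulary, s$tag, "O")
    new_sentence(s$surface, tg)
  }), validate = FALSE)
  predict_tags(object$model, newdata, stub, object$table,
               trans = if (repair) object$trans[[task]] else NULL,
               task = task)
}

#' Plot development-score history of a fit
#'
#' @param x An `ner_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ner_fit <- function(x, ...) {
  h <- x$dev_history[x$dev_history$task == ".mean", ]
  if (!nrow(h)) h <- x$dev_history
  graphics::plot(h$step, h$score, type = "b", xlab = "training step",
                 ylab = sprintf("dev %s", x$metric),
                 main = sprintf("%s fit", x$kind), ...)
  graphics::abline(v = x$selected_step, lty = 2)
  invisible(x)
}

#' Evaluate a fit on a corpus split
#'
#' @param fit An `ner_fit`.
#' @param corpus The `ner_corpus` to score.
#' @param split `"test"` (default), `"dev"` or `"train"`.
#' @param task Task name (defaults to the corpus name).
#' @return An `evaluation_report` (or token accuracy for auxiliary-metric
#'   fits).
#' @export
evaluate_fit <- function(fit, corpus, split = c("test", "dev", "train"),
                         task = NULL) {
  split <- match.arg(split)
  task <- task %||% corpus$name
  pred <- predict_tags(fit$model, corpus[[split]], corpus, fit$table,
                       trans = fit$trans[[task]], task = task)
  if (fit$metric == "token_accuracy") {
    score_token_accuracy(split_tags(corpus[[split]]), pred)
  } else {
    score_tagged_split(corpus[[split]], pred)
  }
}

# ---- run directories and checkpoints ---------------------------------------

#' Save a model checkpoint
#'
#' Self-describing, versioned serialisation of spec, parameters and task
#' label counts.
#'
#' @param model A `ner_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_ner_model <- function(model, path) {
  stopifnot(inherits(model, "ner_model"))
  saveRDS(list(format = "nermtl_checkpoint", version = model$version,
               model = model), path)
  invisible(path)
}

#' Load a model checkpoint saved by [save_ner_model()]
#'
#' @param path Checkpoint file.
#' @return A `ner_model`.
#' @export
load_ner_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nermtl_checkpoint")) {
    stopf("%s is not a nermtl checkpoint", path)
  }
  obj$model
}

write_run_dir <- function(fit, run_dir) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(kind = fit$kind, corpora = as.list(fit$corpora),
                        metric = fit$metric,
                        schedule = unclass(fit$schedule),
                        selected_step = fit$selected_step,
                        best_score = fit$best_score),
                   file.path(run_dir, "config.yaml"))
  utils::write.table(fit$loss_log, file.path(run_dir, "loss_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$dev_history, file.path(run_dir, "dev_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  save_ner_model(fit$model, file.path(run_dir, "best_model.rds"))
  invisible(run_dir)
}
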