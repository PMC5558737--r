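# Drivers for the five experiment families: baselines, the pairwise
# (main, auxiliary) effects grid, grouped same-entity training, all-dataset
# multi-task runs with a dependent-model comparison, and the dataset-size
# reduction study. Every table cell is a mean over the configured seeds with
# per-seed scores retained, and re-running with the same config and base seed
# reproduces tables exactly.

#' Scale profiles for experiment suites
#'
#' A profile fixes schedule lengths and network width so a whole synthetic
#' suite is tractable at the chosen scale. `"full"` is the reference
#' configuration (190,000 steps, batch 200, Adam 1e-4, 100 filters per width,
#' fully connected size 300); `"default"` keeps that architecture with shorter
#' schedules; `"tiny"` also narrows the network (25 filters per width, fully
#' connected size 100) and raises the learning rate to 3e-3, a sensible
#' optimisation regime for runs two orders of magnitude shorter than full
#' scale. Tiny multi-task schedules are twice the single-task length so
#' per-task exposure stays balanced under uniform two-task sampling.
#'
#' @param name `"tiny"`, `"default"` or `"full"`.
#' @return List of schedule and architecture settings.
#' @export
scale_profile <- function(name = c("tiny", "default", "full")) {
  name <- match.arg(name)
  switch(name,
         tiny = list(name = "tiny", steps_single = 1000L, steps_multi = 2000L,
                     batch_size = 50L, learning_rate = 3e-3,
                     eval_every = 500L, patience = 1000L,
                     embedding_dimension = 50L, filters_per_width = 25L,
                     fully_connected_size = 100L),
         default = list(name = "default", steps_single = 5000L,
                        steps_multi = 8000L, batch_size = 200L,
                        learning_rate = 1e-4, eval_every = 500L,
                        patience = 5L, embedding_dimension = 50L,
                        filters_per_width = 100L, fully_connected_size = 300L),
         full = list(name = "full", steps_single = 190000L,
                     steps_multi = 190000L, batch_size = 200L,
                     learning_rate = 1e-4, eval_every = 2000L,
                     patience = 10L, embedding_dimension = 50L,
                     filters_per_width = 100L, fully_connected_size = 300L))
}

#' Configure an experiment suite
#'
#' @param profile A profile name or [scale_profile()] list.
#' @param seeds Number of runs per configuration (default 3).
#' @param base_seed Integer seed from which every run seed is derived.
#' @param n Context half-width (default 3, a seven word window).
#' @param dropout_keep_probability Keep probability at the fully connected
#'   layer.
#' @param table Optional `embedding_table`; when `NULL` a seeded random table
#'   over the collection vocabulary is built per suite.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(profile = "tiny", seeds = 3L, base_seed = 1L,
                              n = 3L, dropout_keep_probability = 0.75,
                              table = NULL) {
  if (is.character(profile)) profile <- scale_profile(profile)
  structure(list(profile = profile, seeds = as.integer(seeds),
                 base_seed = as.integer(base_seed), n = as.integer(n),
                 dropout_keep_probability = dropout_keep_probability,
                 table = table),
            class = "experiment_config")
}

exp_arch <- function(cfg, kind) {
  architecture_spec(kind = kind,
                    embedding_dimension = cfg$profile$embedding_dimension,
                    n = cfg$n,
                    filters_per_width = cfg$profile$filters_per_width,
                    fully_connected_size = cfg$profile$fully_connected_size,
                    dropout_keep_probability = cfg$dropout_keep_probability)
}

exp_schedule <- function(cfg, steps, seed) {
  training_schedule(max_steps = steps, batch_size = cfg$profile$batch_size,
                    learning_rate = cfg$profile$learning_rate,
                    eval_every = cfg$profile$eval_every,
                    patience = cfg$profile$patience, seed = seed)
}

exp_table <- function(cfg, corpora) {
  cfg$table %||% make_random_table(collection_vocabulary(corpora),
                                   cfg$profile$embedding_dimension,
                                   seed = derive_seed(cfg$base_seed, 77L))
}

run_seed <- function(cfg, block, s) derive_seed(cfg$base_seed, 1000L * block + s)

test_f1 <- function(fit, corpus) evaluate_fit(fit, corpus, "test")$f1

stm_run <- function(corpus, cfg, table, seed) {
  fit <- train_single_task(corpus, exp_arch(cfg, "single_task"),
                           exp_schedule(cfg, cfg$profile$steps_single, seed),
                           table)
  test_f1(fit, corpus)
}

new_run_row <- function(configuration, corpus, model, seed, f1) {
  data.frame(configuration = configuration, corpus = corpus, model = model,
             seed = seed, f1 = f1, stringsAsFactors = FALSE)
}

# Summarise long per-seed runs into a result table; significance is a Welch
# two-tailed t-test of each model's per-seed scores against the reference
# model on the same (configuration, corpus).
summarize_runs <- function(runs, reference_model = "STM") {
  keys <- unique(runs[, c("configuration", "corpus", "model")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- runs$configuration == k$configuration & runs$corpus == k$corpus &
      runs$model == k$model
    scores <- runs$f1[sel]
    ref <- runs$f1[runs$configuration == k$configuration &
                     runs$corpus == k$corpus & runs$model == reference_model]
    pv <- NA_real_
    sig <- NA
    if (k$model != reference_model && length(ref) >= 2L &&
        length(scores) >= 2L) {
      cmp <- compare_runs(scores, ref)
      pv <- cmp$p_value
      sig <- cmp$significant
    }
    data.frame(configuration = k$configuration, corpus = k$corpus,
               model = k$model, mean_f1 = mean(scores),
               n_seeds = length(scores),
               f1_runs = paste(sprintf("%.4f", scores), collapse = ","),
               p_value = pv, significant = sig, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

new_experiment_table <- function(runs, table, experiment) {
  structure(list(experiment = experiment, runs = runs, table = table),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  cat(sprintf("<experiment_table '%s': %d runs>\n", x$experiment,
              nrow(x$runs)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write an experiment result table (and its per-seed runs) as TSV
#'
#' @param x An `experiment_table`.
#' @param path Output file for the summary table; per-seed runs go to
#'   `<path>.runs.tsv`.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$runs, paste0(path, ".runs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise dataset-effects grid
#'
#' Trains a two-task multi-output model for every ordered (main, auxiliary)
#' corpus pair — `k` corpora give `k x (k-1)` models per seed — plus a
#' single-task reference per corpus, and identifies the auxiliary that best
#' improves each main corpus.
#'
#' @param corpora Named list of >= 2 `ner_corpus` objects.
#' @param config An [experiment_config()].
#' @return An `experiment_table`; `$best` maps each corpus to its best
#'   auxiliary partner by mean test F1.
#' @export
run_pairwise_grid <- function(corpora, config) {
  stopifnot(length(corpora) >= 2L)
  table <- exp_table(config, corpora)
  nm <- vapply(corpora, `[[`, character(1), "name")
  runs <- list()
  for (i in seq_along(corpora)) {
    for (s in seq_len(config$seeds)) {
      runs[[length(runs) + 1L]] <- new_run_row(
        "pairwise", nm[i], "STM", s,
        stm_run(corpora[[i]], config, table, run_seed(config, i, s)))
    }
    for (j in seq_along(corpora)) {
      if (i == j) next
      for (s in seq_len(config$seeds)) {
        fit <- train_multi_output(
          list(corpora[[i]], corpora[[j]]), exp_arch(config, "multi_output"),
          exp_schedule(config, config$profile$steps_multi,
                       run_seed(config, 100L + i * length(corpora) + j, s)),
          table)
        runs[[length(runs) + 1L]] <- new_run_row(
          "pairwise", nm[i], paste0("MO-MTM+", nm[j]), s,
          test_f1(fit, corpora[[i]]))
      }
    }
  }
  runs <- do.call(rbind, runs)
  summ <- summarize_runs(runs)
  mo <- summ[grepl("^MO-MTM", summ$model), ]
  best <- do.call(rbind, lapply(unique(mo$corpus), function(co) {
    rows <- mo[mo$corpus == co, ]
    top <- rows[which.max(rows$mean_f1), ]
    data.frame(corpus = co,
               best_auxiliary = sub("^MO-MTM\\+", "", top$model),
               mean_f1 = top$mean_f1,
               stm_mean_f1 = summ$mean_f1[summ$corpus == co &
                                            summ$model == "STM"],
               stringsAsFactors = FALSE)
  }))
  out <- new_experiment_table(runs, summ, "pairwise_grid")
  out$best <- best
  out
}

#' Grouped same-entity multi-task training
#'
#' Restricts every corpus to `focus_type` (all other annotations relabelled to
#' Out), trains one multi-output model on the whole group and a single-task
#' model per corpus, and reports per-corpus and average F1.
#'
#' @param corpora List of `ner_corpus` objects, each annotating `focus_type`.
#' @param focus_type Entity type defining the group.
#' @param config An [experiment_config()].
#' @return An `experiment_table` with one row per corpus per model plus
#'   average rows.
#' @export
run_grouped <- function(corpora, focus_type, config) {
  restricted <- lapply(corpora, restrict_to_entity_type, focus_type = focus_type)
  table <- exp_table(config, corpora)
  nm <- vapply(restricted, `[[`, character(1), "name")
  runs <- list()
  for (i in seq_along(restricted)) {
    for (s in seq_len(config$seeds)) {
      runs[[length(runs) + 1L]] <- new_run_row(
        paste0("grouped:", focus_type), nm[i], "STM", s,
        stm_run(restricted[[i]], config, table, run_seed(config, 200L + i, s)))
    }
  }
  if (length(restricted) >= 2L) {
    for (s in seq_len(config$seeds)) {
      fit <- train_multi_output(restricted, exp_arch(config, "multi_output"),
                                exp_schedule(config, config$profile$steps_multi,
                                             run_seed(config, 300L, s)),
                                table)
      for (i in seq_along(restricted)) {
        runs[[length(runs) + 1L]] <- new_run_row(
          paste0("grouped:", focus_type), nm[i], "MO-MTM", s,
          test_f1(fit, restricted[[i]]))
      }
    }
  } else {
    # group of one: the multi-output model reduces to the single task
    for (s in seq_len(config$seeds)) {
      fit <- train_multi_output(restricted, exp_arch(config, "multi_output"),
                                exp_schedule(config, config$profile$steps_multi,
                                             run_seed(config, 300L, s)),
                                table)
      runs[[length(runs) + 1L]] <- new_run_row(
        paste0("grouped:", focus_type), nm[1L], "MO-MTM", s,
        test_f1(fit, restricted[[1L]]))
    }
  }
  runs <- do.call(rbind, runs)
  summ <- summarize_runs(runs)
  avg <- do.call(rbind, lapply(unique(summ$model), function(md) {
    data.frame(configuration = unique(summ$configuration), corpus = "AVERAGE",
               model = md, mean_f1 = mean(summ$mean_f1[summ$model == md]),
               n_seeds = config$seeds, f1_runs = "", p_value = NA_real_,
               significant = NA, stringsAsFactors = FALSE)
  }))
  new_experiment_table(runs, rbind(summ, avg), "grouped")
}

#' All-dataset multi-task comparison
#'
#' Trains, per corpus: the feed-forward baseline, a single-task CNN, one
#' multi-output model over all corpora, and a dependent model with the given
#' auxiliary token-classification corpus — the baseline/STM/MO-MTM/D-MTM
#' comparison, with significance flags against STM.
#'
#' @param corpora Named list of `ner_corpus` objects.
#' @param config An [experiment_config()].
#' @param auxiliary Auxiliary `ner_corpus` for the dependent model; when
#'   `NULL`, a perfectly informative tagging corpus over the first corpus's
#'   sentences is generated.
#' @return An `experiment_table` with per-corpus and average rows.
#' @export
run_all_multi <- function(corpora, config, auxiliary = NULL) {
  table <- exp_table(config, corpora)
  nm <- vapply(corpora, `[[`, character(1), "name")
  if (is.null(auxiliary)) {
    auxiliary <- generate_auxiliary_tagging(corpora[[1L]], 1, 2L,
                                            seed = derive_seed(config$base_seed, 55L))
  }
  runs <- list()
  for (i in seq_along(corpora)) {
    for (s in seq_len(config$seeds)) {
      sd <- run_seed(config, 400L + i, s)
      bl <- train_single_task(
        corpora[[i]], exp_arch(config, "baseline"),
        training_schedule(max_steps = config$profile$steps_single,
                          batch_size = 50L, learning_rate = 0.01,
                          eval_every = config$profile$eval_every,
                          patience = config$profile$patience, seed = sd),
        table)
      runs[[length(runs) + 1L]] <- new_run_row("all", nm[i], "baseline", s,
                                               test_f1(bl, corpora[[i]]))
      runs[[length(runs) + 1L]] <- new_run_row(
        "all", nm[i], "STM", s, stm_run(corpora[[i]], config, table, sd))
      dfit <- train_dependent(
        corpora[[i]], auxiliary, exp_arch(config, "single_task"),
        exp_arch(config, "single_task"),
        exp_schedule(config, config$profile$steps_single, sd),
        exp_schedule(config, config$profile$steps_single,
                     derive_seed(sd, 9L)),
        table)
      runs[[length(runs) + 1L]] <- new_run_row(
        "all", nm[i], "D-MTM", s, test_f1(dfit, corpora[[i]]))
    }
  }
  for (s in seq_len(config$seeds)) {
    fit <- train_multi_output(corpora, exp_arch(config, "multi_output"),
                              exp_schedule(config, config$profile$steps_multi,
                                           run_seed(config, 500L, s)),
                              table)
    for (i in seq_along(corpora)) {
      runs[[length(runs) + 1L]] <- new_run_row("all", nm[i], "MO-MTM", s,
                                               test_f1(fit, corpora[[i]]))
    }
  }
  runs <- do.call(rbind, runs)
  summ <- summarize_runs(runs)
  avg <- do.call(rbind, lapply(unique(summ$model), function(md) {
    data.frame(configuration = "all", corpus = "AVERAGE", model = md,
               mean_f1 = mean(summ$mean_f1[summ$model == md]),
               n_seeds = config$seeds, f1_runs = "", p_value = NA_real_,
               significant = NA, stringsAsFactors = FALSE)
  }))
  new_experiment_table(runs, rbind(summ, avg), "all_multi")
}

#' Dataset-size reduction study
#'
#' For each corpus and training fraction, trains a single-task model on the
#' subsampled train split and a two-task multi-output model pairing the
#' reduced corpus with its (full-size) best partner; the full-size single-task
#' result is included as reference.
#'
#' @param corpora Named list of `ner_corpus` objects.
#' @param config An [experiment_config()].
#' @param fractions Training fractions (default 0.5, 0.25, 0.1).
#' @param partners Named character vector mapping each corpus to its partner;
#'   with two corpora they default to each other, otherwise the pairwise
#'   grid's best auxiliaries are computed.
#' @return An `experiment_table` with per-fraction rows and average rows.
#' @export
run_size_reduction <- function(corpora, config, fractions = c(0.5, 0.25, 0.1),
                               partners = NULL) {
  if (any(fractions <= 0 | fractions > 1)) stopf("fractions must be in (0, 1]")
  nm <- vapply(corpora, `[[`, character(1), "name")
  names(corpora) <- nm
  if (is.null(partners)) {
    if (length(corpora) == 2L) {
      partners <- stats::setNames(rev(nm), nm)
    } else {
      grid <- run_pairwise_grid(corpora, config)
      partners <- stats::setNames(grid$best$best_auxiliary, grid$best$corpus)
    }
  }
  table <- exp_table(config, corpora)
  runs <- list()
  for (i in seq_along(corpora)) {
    co <- corpora[[i]]
    for (s in seq_len(config$seeds)) {
      runs[[length(runs) + 1L]] <- new_run_row(
        "fraction:1", nm[i], "STM", s,
        stm_run(co, config, table, run_seed(config, 600L + i, s)))
    }
    for (f in fractions) {
      conf_label <- sprintf("fraction:%g", f)
      for (s in seq_len(config$seeds)) {
        red <- subsample_training(co, f, seed = run_seed(config, 700L + i, s))
        runs[[length(runs) + 1L]] <- new_run_row(
          conf_label, nm[i], "STM", s,
          stm_run(red, config, table,
                  run_seed(config, 800L + i + round(100 * f), s)))
        fit <- train_multi_output(
          list(red, corpora[[partners[[nm[i]]]]]),
          exp_arch(config, "multi_output"),
          exp_schedule(config, config$profile$steps_multi,
                       run_seed(config, 900L + i + round(100 * f), s)),
          table)
        runs[[length(runs) + 1L]] <- new_run_row(
          conf_label, nm[i], "MO-MTM", s, test_f1(fit, red))
      }
    }
  }
  runs <- do.call(rbind, runs)
  summ <- summarize_runs(runs)
  avg <- do.call(rbind, lapply(unique(summ$configuration), function(cf) {
    do.call(rbind, lapply(unique(summ$model[summ$configuration == cf]),
                          function(md) {
      sel <- summ$configuration == cf & summ$model == md
      data.frame(configuration = cf, corpus = "AVERAGE", model = md,
                 mean_f1 = mean(summ$mean_f1[sel]), n_seeds = config$seeds,
                 f1_runs = "", p_value = NA_real_, significant = NA,
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- new_experiment_table(runs, rbind(summ, avg), "size_reduction")
  out$partners <- partners
  out
}
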