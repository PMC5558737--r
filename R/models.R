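# Network architectures. Four kinds share conventions:
#   baseline     - window concat -> affine -> ReLU -> affine -> softmax
#   single_task  - window matrix -> 1-D convolutions (widths 3/4/5, no
#                  pooling) -> ReLU -> flatten -> fully connected -> dropout
#                  -> softmax output
#   multi_output - single_task trunk shared by all tasks, one private softmax
#                  head per task (hard parameter sharing)
#   dependent    - a single_task main network whose output layer consumes the
#                  concatenation of its own fully connected activation and
#                  that of a frozen, separately trained auxiliary network
# Word embeddings are inputs, never parameters. All gradients are computed in
# closed form with base matrix algebra; Adam (CNNs) or plain SGD (baseline)
# performs the update.

#' Describe a network architecture
#'
#' Defaults follow the tuned configuration of the window-CNN tagger: a seven
#' word context window (`n = 3`), 100 convolution filters for each of the
#' widths 3, 4 and 5, dropout keep probability 0.75 applied at the fully
#' connected layer only, and a hidden layer of size 300 for the feed-forward
#' baseline. `dropout_keep_probability` is the probability a unit is KEPT;
#' inverted scaling is used so inference needs no rescaling.
#'
#' @param kind One of `"baseline"`, `"single_task"`, `"multi_output"`,
#'   `"dependent"`.
#' @param embedding_dimension Dimension of the (frozen) word vectors.
#' @param n Context half-width; windows hold `2n + 1` tokens.
#' @param filter_widths Convolution filter widths (tokens); each must be
#'   at most `2n + 1`.
#' @param filters_per_width Number of filters per width.
#' @param fully_connected_size Width of the fully connected layer.
#' @param dropout_keep_probability Keep probability in (0, 1].
#' @param hidden_size_baseline Hidden-layer size of the baseline model.
#' @return An object of class `ner_architecture`.
#' @export
architecture_spec <- function(kind = c("single_task", "multi_output",
                                       "dependent", "baseline"),
                              embedding_dimension,
                              n = 3L,
                              filter_widths = c(3L, 4L, 5L),
                              filters_per_width = 100L,
                              fully_connected_size = 300L,
                              dropout_keep_probability = 0.75,
                              hidden_size_baseline = 300L) {
  kind <- match.arg(kind)
  stopifnot(embedding_dimension >= 1, n >= 0, filters_per_width >= 1,
            fully_connected_size >= 1, hidden_size_baseline >= 1)
  if (dropout_keep_probability <= 0 || dropout_keep_probability > 1) {
    stopf("`dropout_keep_probability` must be in (0, 1]")
  }
  w <- 2L * as.integer(n) + 1L
  if (any(filter_widths > w)) {
    stopf("filter width %d exceeds window length %d",
          max(filter_widths), w)
  }
  structure(list(kind = kind,
                 embedding_dimension = as.integer(embedding_dimension),
                 n = as.integer(n),
                 filter_widths = as.integer(filter_widths),
                 filters_per_width = as.integer(filters_per_width),
                 fully_connected_size = as.integer(fully_connected_size),
                 dropout_keep_probability = dropout_keep_probability,
                 hidden_size_baseline = as.integer(hidden_size_baseline)),
            class = "ner_architecture")
}

#' @export
print.ner_architecture <- function(x, ...) {
  cat(sprintf("<ner_architecture '%s': d=%d, window=%d, filters=%s x %d, fc=%d, keep=%.2f>\n",
              x$kind, x$embedding_dimension, 2L * x$n + 1L,
              paste(x$filter_widths, collapse = "/"), x$filters_per_width,
              x$fully_connected_size, x$dropout_keep_probability))
  invisible(x)
}

window_length <- function(spec) 2L * spec$n + 1L

# Flat conv-feature length: sum over widths k of (2n+1-k+1) positions x F.
trunk_feature_length <- function(spec) {
  sum((window_length(spec) - spec$filter_widths + 1L) * spec$filters_per_width)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_trunk_params <- function(spec) {
  d <- spec$embedding_dimension
  fpw <- spec$filters_per_width
  params <- list()
  for (k in spec$filter_widths) {
    params[[sprintf("conv_W_%d", k)]] <- glorot(k * d, fpw)
    params[[sprintf("conv_b_%d", k)]] <- numeric(fpw)
  }
  params$fc_W <- glorot(trunk_feature_length(spec), spec$fully_connected_size)
  params$fc_b <- numeric(spec$fully_connected_size)
  params
}

#' Initialise a model
#'
#' Parameters are drawn seed-deterministically (uniform Glorot fan scaling,
#' zero biases). `baseline` and `single_task` take exactly one task;
#' `multi_output` takes one private softmax head per task. Dependent models
#' are assembled from a trained auxiliary with [assemble_dependent()].
#'
#' @param spec An [architecture_spec()].
#' @param tasks Named integer vector mapping corpus name to label count.
#' @param seed Integer seed.
#' @return An object of class `ner_model`.
#' @export
init_model <- function(spec, tasks, seed) {
  stopifnot(inherits(spec, "ner_architecture"))
  if (!length(tasks) || is.null(names(tasks)) || any(!nzchar(names(tasks)))) {
    stopf("`tasks` must be a named integer vector of label counts")
  }
  if (anyDuplicated(names(tasks))) stopf("duplicate task names")
  tasks <- vapply(tasks, as.integer, integer(1))
  if (spec$kind %in% c("baseline", "single_task") && length(tasks) != 1L) {
    stopf("kind '%s' takes exactly one task", spec$kind)
  }
  if (spec$kind == "dependent") {
    stopf("dependent models are built with assemble_dependent()")
  }
  d <- spec$embedding_dimension
  w <- window_length(spec)
  params <- with_seed(seed, {
    if (spec$kind == "baseline") {
      list(W1 = glorot(w * d, spec$hidden_size_baseline),
           b1 = numeric(spec$hidden_size_baseline),
           W2 = glorot(spec$hidden_size_baseline, tasks[[1L]]),
           b2 = numeric(tasks[[1L]]))
    } else {
      p <- init_trunk_params(spec)
      for (task in names(tasks)) {
        p[[head_name(task, "W")]] <- glorot(spec$fully_connected_size, tasks[[task]])
        p[[head_name(task, "b")]] <- numeric(tasks[[task]])
      }
      p
    }
  })
  structure(list(spec = spec, kind = spec$kind, tasks = tasks,
                 params = params, aux = NULL, version = 1L),
            class = "ner_model")
}

head_name <- function(task, part) sprintf("head.%s.%s", task, part)

#' @export
print.ner_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<ner_model '%s': tasks {%s}; %d parameters%s>\n",
              x$kind, paste(names(x$tasks), collapse = ", "), np,
              if (!is.null(x$aux)) " + frozen auxiliary" else ""))
  invisible(x)
}

# ---- design matrices --------------------------------------------------------

#' Construct a mini-batch from window surfaces
#'
#' @param windows Character matrix of window surfaces (one row per example).
#' @param labels Optional integer gold-label indices.
#' @param corpus_name Optional owning corpus name.
#' @return A list usable by the `forward_*` functions.
#' @export
minibatch <- function(windows, labels = NULL, corpus_name = NULL) {
  list(windows = windows, labels = labels, corpus_name = corpus_name)
}

# Batch -> B x (2n+1)d design matrix, column blocks ordered by window position.
as_design <- function(batch, table, spec) {
  if (!is.null(batch$X)) {
    X <- batch$X
  } else {
    w <- ncol(batch$windows)
    if (w != window_length(spec)) {
      stopf("window length %d does not match architecture (2n+1 = %d)",
            w, window_length(spec))
    }
    d <- table$dimension
    X <- matrix(0, nrow(batch$windows), w * d)
    Eaug <- augmented_matrix(table)
    rows <- matrix(surface_rows(table, as.vector(batch$windows)),
                   nrow = nrow(batch$windows))
    for (p in seq_len(w)) {
      X[, ((p - 1L) * d + 1L):(p * d)] <- Eaug[rows[, p], , drop = FALSE]
    }
  }
  if (ncol(X) != window_length(spec) * spec$embedding_dimension) {
    stopf("embedding dimension mismatch: design has %d columns, architecture expects %d",
          ncol(X), window_length(spec) * spec$embedding_dimension)
  }
  X
}

# ---- forward passes ---------------------------------------------------------

# Convolution trunk on design matrix X; returns flat feature map, fully
# connected activation and caches for backprop. Flatten order: width-major,
# then position, then filter index (any fixed order is equivalent up to a
# permutation of the learned fc weights).
trunk_forward <- function(params, spec, X) {
  d <- spec$embedding_dimension
  fpw <- spec$filters_per_width
  b <- nrow(X)
  feat <- matrix(0, b, trunk_feature_length(spec))
  zs <- list()
  off <- 0L
  for (k in spec$filter_widths) {
    Wk <- params[[sprintf("conv_W_%d", k)]]
    bk <- params[[sprintf("conv_b_%d", k)]]
    npos <- window_length(spec) - k + 1L
    Zk <- matrix(0, b, npos * fpw)
    for (p in seq_len(npos)) {
      cols <- ((p - 1L) * d + 1L):((p - 1L + k) * d)
      Zk[, ((p - 1L) * fpw + 1L):(p * fpw)] <-
        sweep(X[, cols, drop = FALSE] %*% Wk, 2L, bk, "+")
    }
    zs[[as.character(k)]] <- Zk
    feat[, (off + 1L):(off + npos * fpw)] <- relu(Zk)
    off <- off + npos * fpw
  }
  fc <- sweep(feat %*% params$fc_W, 2L, params$fc_b, "+")
  list(feat = feat, zs = zs, fc = fc)
}

# Inverted dropout mask on the fully connected activation (train time only).
dropout_mask <- function(dim_, keep) {
  if (keep >= 1) return(NULL)
  matrix(stats::rbinom(prod(dim_), 1L, keep) / keep, dim_[1L], dim_[2L])
}

#' Forward pass of the feed-forward baseline
#'
#' Concatenated window vectors pass through one ReLU hidden layer and a
#' softmax output layer.
#'
#' @param model A baseline `ner_model`.
#' @param batch A [minibatch()] (or list with a prebuilt design matrix `X`).
#' @param table An `embedding_table`.
#' @return Matrix of per-example label distributions (rows sum to 1).
#' @export
forward_baseline <- function(model, batch, table) {
  stopifnot(model$kind == "baseline")
  X <- as_design(batch, table, model$spec)
  h <- relu(sweep(X %*% model$params$W1, 2L, model$params$b1, "+"))
  softmax_rows(sweep(h %*% model$params$W2, 2L, model$params$b2, "+"))
}

#' Forward pass of the single-task convolutional model
#'
#' @inheritParams forward_baseline
#' @param training_mode If `TRUE`, dropout is applied at the fully connected
#'   layer (stochastic); otherwise the pass is deterministic.
#' @return List with `probs` (per-example label distributions) and `fc`
#'   (fully connected activations, as consumed by the dependent model).
#' @export
forward_single_task <- function(model, batch, table, training_mode = FALSE) {
  stopifnot(model$kind == "single_task")
  X <- as_design(batch, table, model$spec)
  tr <- trunk_forward(model$params, model$spec, X)
  fcd <- tr$fc
  if (training_mode) {
    mask <- dropout_mask(dim(fcd), model$spec$dropout_keep_probability)
    if (!is.null(mask)) fcd <- fcd * mask
  }
  task <- names(model$tasks)[1L]
  probs <- softmax_rows(sweep(fcd %*% model$params[[head_name(task, "W")]],
                              2L, model$params[[head_name(task, "b")]], "+"))
  list(probs = probs, fc = tr$fc)
}

#' Forward pass of the multi-output multi-task model
#'
#' The convolutional trunk and fully connected layer are shared by all tasks;
#' only the named task's private softmax head is applied.
#'
#' @inheritParams forward_single_task
#' @param task Corpus name selecting the output head.
#' @return List with `probs` and shared-trunk `fc` activations.
#' @export
forward_multi_output <- function(model, batch, table, task,
                                 training_mode = FALSE) {
  stopifnot(model$kind == "multi_output")
  if (!task %in% names(model$tasks)) stopf("unknown task '%s'", task)
  X <- as_design(batch, table, model$spec)
  tr <- trunk_forward(model$params, model$spec, X)
  fcd <- tr$fc
  if (training_mode) {
    mask <- dropout_mask(dim(fcd), model$spec$dropout_keep_probability)
    if (!is.null(mask)) fcd <- fcd * mask
  }
  probs <- softmax_rows(sweep(fcd %*% model$params[[head_name(task, "W")]],
                              2L, model$params[[head_name(task, "b")]], "+"))
  list(probs = probs, fc = tr$fc)
}

#' Assemble a dependent multi-task model
#'
#' Builds a main-task network whose output layer consumes the concatenation of
#' its own fully connected activation and that of an already-trained auxiliary
#' single-task network evaluated on the same window. The auxiliary parameters
#' are frozen: training the main task never changes them, and the auxiliary
#' forward pass always runs with dropout disabled.
#'
#' @param main_spec An [architecture_spec()] for the main network.
#' @param trained_auxiliary A trained single-task `ner_model` (or `ner_fit`).
#' @param main_labels Number of labels of the main task.
#' @param seed Integer seed for the main network's initialisation.
#' @param task_name Name of the main task (default `"main"`).
#' @return A `ner_model` of kind `"dependent"`.
#' @export
assemble_dependent <- function(main_spec, trained_auxiliary, main_labels, seed,
                               task_name = "main") {
  if (inherits(trained_auxiliary, "ner_fit")) {
    trained_auxiliary <- trained_auxiliary$model
  }
  stopifnot(inherits(trained_auxiliary, "ner_model"),
            trained_auxiliary$kind == "single_task",
            inherits(main_spec, "ner_architecture"))
  if (main_spec$embedding_dimension !=
      trained_auxiliary$spec$embedding_dimension) {
    stopf("embedding dimension mismatch between main (%d) and auxiliary (%d)",
          main_spec$embedding_dimension,
          trained_auxiliary$spec$embedding_dimension)
  }
  if (main_spec$n != trained_auxiliary$spec$n) {
    stopf("context half-width mismatch between main and auxiliary networks")
  }
  main_labels <- as.integer(main_labels)
  concat_len <- main_spec$fully_connected_size +
    trained_auxiliary$spec$fully_connected_size
  params <- with_seed(seed, {
    p <- init_trunk_params(main_spec)
    p$out_W <- glorot(concat_len, main_labels)
    p$out_b <- numeric(main_labels)
    p
  })
  spec <- main_spec
  spec$kind <- "dependent"
  tasks <- stats::setNames(main_labels, task_name)
  structure(list(spec = spec, kind = "dependent", tasks = tasks,
                 params = params, aux = trained_auxiliary, version = 1L),
            class = "ner_model")
}

#' Forward pass of the dependent multi-task model
#'
#' @inheritParams forward_single_task
#' @return List with `probs`, main-network `fc` and frozen auxiliary `fc_aux`
#'   activations.
#' @export
forward_dependent <- function(model, batch, table, training_mode = FALSE) {
  stopifnot(model$kind == "dependent")
  X <- as_design(batch, table, model$spec)
  tr <- trunk_forward(model$params, model$spec, X)
  aux_tr <- trunk_forward(model$aux$params, model$aux$spec, X)
  fcd <- tr$fc
  if (training_mode) {
    mask <- dropout_mask(dim(fcd), model$spec$dropout_keep_probability)
    if (!is.null(mask)) fcd <- fcd * mask
  }
  z <- sweep(cbind(fcd, aux_tr$fc) %*% model$params$out_W, 2L,
             model$params$out_b, "+")
  list(probs = softmax_rows(z), fc = tr$fc, fc_aux = aux_tr$fc)
}

# Generic forward used by prediction: deterministic, returns distributions.
model_forward <- function(model, batch, table, task = NULL) {
  switch(model$kind,
         baseline = forward_baseline(model, batch, table),
         single_task = forward_single_task(model, batch, table)$probs,
         multi_output = forward_multi_output(model, batch, table, task)$probs,
         dependent = forward_dependent(model, batch, table)$probs)
}
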