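# Closed-form gradients for all four architectures and the optimiser updates.
# Only parameters on the active task's computation path receive gradients: a
# multi-output step on task A leaves every other head untouched, and dependent
# main-task steps never touch the frozen auxiliary network.

one_hot <- function(labels, n_labels) {
  Y <- matrix(0, length(labels), n_labels)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

cross_entropy <- function(probs, labels) {
  -mean(log(pmax(probs[cbind(seq_along(labels), labels)], 1e-12)))
}

# Backprop through the convolution trunk given d(loss)/d(fc).
trunk_backward <- function(params, spec, X, cache, dfc) {
  d <- spec$embedding_dimension
  fpw <- spec$filters_per_width
  grads <- list(fc_W = crossprod(cache$feat, dfc), fc_b = colSums(dfc))
  dfeat <- dfc %*% t(params$fc_W)
  off <- 0L
  for (k in spec$filter_widths) {
    npos <- window_length(spec) - k + 1L
    Zk <- cache$zs[[as.character(k)]]
    dWk <- matrix(0, k * d, fpw)
    dbk <- numeric(fpw)
    for (p in seq_len(npos)) {
      fcols <- (off + (p - 1L) * fpw + 1L):(off + p * fpw)
      zcols <- ((p - 1L) * fpw + 1L):(p * fpw)
      dZ <- dfeat[, fcols, drop = FALSE] *
        (Zk[, zcols, drop = FALSE] > 0)
      xcols <- ((p - 1L) * d + 1L):((p - 1L + k) * d)
      dWk <- dWk + crossprod(X[, xcols, drop = FALSE], dZ)
      dbk <- dbk + colSums(dZ)
    }
    grads[[sprintf("conv_W_%d", k)]] <- dWk
    grads[[sprintf("conv_b_%d", k)]] <- dbk
    off <- off + npos * fpw
  }
  grads
}

#' Create optimiser state for a model
#'
#' Adam for the convolutional kinds, plain stochastic gradient descent for the
#' baseline.
#'
#' @param model A `ner_model`.
#' @param learning_rate Step size (default `1e-4` for Adam as used with the
#'   CNN models; the baseline default is 0.01 SGD).
#' @return An optimiser-state list consumed and returned by [train_step()].
#' @export
init_optimizer <- function(model,
                           learning_rate = if (model$kind == "baseline") 0.01 else 1e-4) {
  list(type = if (model$kind == "baseline") "sgd" else "adam",
       learning_rate = learning_rate,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
       t = 0L, m = list(), v = list())
}

apply_update <- function(params, grads, opt) {
  if (opt$type == "sgd") {
    for (nm in names(grads)) {
      params[[nm]] <- params[[nm]] - opt$learning_rate * grads[[nm]]
    }
    return(list(params = params, opt = opt))
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- opt$m[[nm]]
    v <- opt$v[[nm]]
    if (is.null(m)) m <- g * 0
    if (is.null(v)) v <- g * 0
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g * g
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] -
      opt$learning_rate * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }
  list(params = params, opt = opt)
}

#' One optimisation step on a mini-batch
#'
#' Computes categorical cross-entropy between the model's predicted label
#' distributions and the one-hot gold labels, backpropagates, and applies one
#' optimiser update to the parameters on the active task's computation path
#' only. The embedding table is input, never updated.
#'
#' @param model A `ner_model`.
#' @param batch A [minibatch()] with `labels`, or an internal indexed batch.
#' @param table An `embedding_table`.
#' @param opt Optimiser state from [init_optimizer()].
#' @param task Task (corpus) name; required for multi-output models.
#' @return List with updated `model`, `opt` and the scalar `loss`.
#' @export
train_step <- function(model, batch, table, opt, task = NULL) {
  y <- batch$labels
  if (is.null(y)) stopf("batch has no gold labels")
  task <- task %||% names(model$tasks)[1L]
  if (!task %in% names(model$tasks)) stopf("unknown task '%s'", task)
  if (!is.null(batch$corpus_name) && !identical(batch$corpus_name, task)) {
    stopf("batch from corpus '%s' cannot train task '%s'",
          batch$corpus_name, task)
  }
  n_labels <- model$tasks[[task]]
  if (any(y < 1L | y > n_labels)) {
    stopf("label index out of range for task '%s' (%d labels)", task, n_labels)
  }
  X <- as_design(batch, table, model$spec)
  b <- nrow(X)
  Y <- one_hot(y, n_labels)

  if (model$kind == "baseline") {
    z1 <- sweep(X %*% model$params$W1, 2L, model$params$b1, "+")
    h <- relu(z1)
    probs <- softmax_rows(sweep(h %*% model$params$W2, 2L, model$params$b2, "+"))
    dz2 <- (probs - Y) / b
    dh <- dz2 %*% t(model$params$W2)
    dz1 <- dh * (z1 > 0)
    grads <- list(W2 = crossprod(h, dz2), b2 = colSums(dz2),
                  W1 = crossprod(X, dz1), b1 = colSums(dz1))
    upd <- apply_update(model$params, grads, opt)
    model$params <- upd$params
    return(list(model = model, opt = upd$opt, loss = cross_entropy(probs, y)))
  }

  tr <- trunk_forward(model$params, model$spec, X)
  mask <- dropout_mask(dim(tr$fc), model$spec$dropout_keep_probability)
  fcd <- if (is.null(mask)) tr$fc else tr$fc * mask

  if (model$kind == "dependent") {
    aux_tr <- trunk_forward(model$aux$params, model$aux$spec, X)
    concat <- cbind(fcd, aux_tr$fc)
    probs <- softmax_rows(sweep(concat %*% model$params$out_W, 2L,
                                model$params$out_b, "+"))
    dz <- (probs - Y) / b
    grads <- list(out_W = crossprod(concat, dz), out_b = colSums(dz))
    dconcat <- dz %*% t(model$params$out_W)
    dfc <- dconcat[, seq_len(model$spec$fully_connected_size), drop = FALSE]
    if (!is.null(mask)) dfc <- dfc * mask
    grads <- c(grads, trunk_backward(model$params, model$spec, X, tr, dfc))
  } else {
    hw <- model$params[[head_name(task, "W")]]
    probs <- softmax_rows(sweep(fcd %*% hw, 2L,
                                model$params[[head_name(task, "b")]], "+"))
    dz <- (probs - Y) / b
    grads <- stats::setNames(list(crossprod(fcd, dz), colSums(dz)),
                             c(head_name(task, "W"), head_name(task, "b")))
    dfc <- dz %*% t(hw)
    if (!is.null(mask)) dfc <- dfc * mask
    grads <- c(grads, trunk_backward(model$params, model$spec, X, tr, dfc))
  }
  upd <- apply_update(model$params, grads, opt)
  model$params <- upd$params
  list(model = model, opt = upd$opt, loss = cross_entropy(probs, y))
}
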