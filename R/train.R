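#' Training configuration for the demo trainer
#'
#' Defaults follow standard Adam practice for compact EEG classifiers:
#' learning rate 0.001, beta1 0.9, beta2 0.999, batch size 50. Per-class loss
#' weights handle imbalanced data (e.g. weighting an over-represented class
#' down in inverse proportion to its frequency).
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size minibatch size.
#' @param epochs maximum number of epochs (<= 50).
#' @param class_weights strictly positive per-class loss weights (recycled to
#'   the number of classes; default all 1).
#' @param validation_fraction held-out fraction used to select the best
#'   epoch by validation loss.
#' @param seed RNG seed controlling shuffling and the validation split.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 50L, epochs = 20L, class_weights = 1,
                         validation_fraction = 0.2, seed = 1L) {
  stopifnot(learning_rate >= 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            batch_size >= 1, epochs >= 1, epochs <= 50,
            all(class_weights > 0),
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 class_weights = as.numeric(class_weights),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

.param_fields <- function(kind) {
  switch(kind,
    conv_time = c("W", "b"), conv_channels = c("W", "b"),
    dense = c("W", "b"), batchnorm = c("gamma", "beta"),
    character(0))
}

#' Train a model with Adam and weighted cross-entropy
#'
#' Demo trainer for the compact reference architectures. The loss is
#' cross-entropy on the softmax of the pre-softmax activations, with
#' per-class weights. Batch-normalization layers use minibatch statistics in
#' the forward pass (treated as constants in the backward pass) and maintain
#' running statistics (momentum 0.1) for inference. The returned model
#' carries the parameters of the epoch with the lowest validation loss and a
#' per-epoch `history` data frame (attribute `"history"`).
#'
#' @param model an `eeg_model`.
#' @param dataset list of [eeg_sample] objects with labels set (or plain
#'   matrices, in which case `labels` must be given).
#' @param config a [train_config()].
#' @param labels optional integer class labels (1-based), overriding the
#'   samples' own.
#' @return the trained `eeg_model`, with attribute `history`.
#' @export
train <- function(model, dataset, config = train_config(), labels = NULL) {
  if (is.null(labels)) {
    labels <- vapply(dataset, function(s) {
      if (is.null(s$label)) NA_integer_ else s$label
    }, integer(1))
  }
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("configuration error: unlabelled samples", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("configuration error: training requires at least two classes",
         call. = FALSE)
  }
  xs <- lapply(dataset, .as_matrix_sample)
  for (x in xs) .check_shape(model, x)
  K <- model$num_classes
  w <- rep_len(config$class_weights, K)

  old <- .seed_push(config$seed)
  on.exit(.seed_pop(old), add = TRUE)

  n <- length(xs)
  perm <- sample.int(n)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)

  # Adam state, flat over layers and fields
  mstate <- list(); vstate <- list(); step <- 0L
  eps_adam <- 1e-8

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  best <- list(loss = Inf, layers = model$layers)

  for (epoch in seq_len(config$epochs)) {
    order_ep <- sample(tr_idx)
    batch_losses <- numeric(0)
    for (b0 in seq(1, length(order_ep), by = config$batch_size)) {
      idx <- order_ep[b0:min(b0 + config$batch_size - 1L, length(order_ep))]
      bx <- xs[idx]; by <- labels[idx]
      stats <- .batch_bn_stats(model, bx)
      # running statistics (momentum 0.1)
      for (i in seq_along(model$layers)) {
        if (!is.null(stats[[i]])) {
          model$layers[[i]]$running_mean <-
            0.9 * model$layers[[i]]$running_mean + 0.1 * stats[[i]]$mean
          model$layers[[i]]$running_var <-
            0.9 * model$layers[[i]]$running_var + 0.1 * stats[[i]]$var
        }
      }
      wsum <- sum(w[by])
      acc_grads <- NULL
      loss <- 0
      for (j in seq_along(idx)) {
        fwd <- .forward1(model, bx[[j]], bn_stats = stats)
        p <- .softmax(fwd$scores)
        loss <- loss - w[by[j]] * log(max(p[by[j]], 1e-12)) / wsum
        gscore <- p
        gscore[by[j]] <- gscore[by[j]] - 1
        gscore <- gscore * (w[by[j]] / wsum)
        bw <- .backward1(model, fwd$caches, gscore, rule = "plain",
                         want_param_grads = TRUE)
        acc_grads <- .accumulate_grads(acc_grads, bw$param_grads)
      }
      batch_losses <- c(batch_losses, loss)
      step <- step + 1L
      upd <- .adam_update(model, acc_grads, mstate, vstate, step, config, eps_adam)
      model <- upd$model; mstate <- upd$m; vstate <- upd$v
    }
    val <- .evaluate_loss(model, xs[val_idx], labels[val_idx], w)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val$loss,
                                         val_accuracy = val$accuracy))
    if (length(val_idx) > 0 && is.finite(val$loss) && val$loss < best$loss) {
      best <- list(loss = val$loss, layers = model$layers)
    }
  }
  if (length(val_idx) > 0 && is.finite(best$loss)) model$layers <- best$layers
  attr(model, "history") <- history
  model
}

.accumulate_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    for (f in names(grads[[i]])) acc[[i]][[f]] <- acc[[i]][[f]] + grads[[i]][[f]]
  }
  acc
}

.adam_update <- function(model, grads, mstate, vstate, step, config, eps) {
  lr <- config$learning_rate; b1 <- config$beta1; b2 <- config$beta2
  for (i in seq_along(model$layers)) {
    if (is.null(grads[[i]])) next
    fields <- .param_fields(model$layers[[i]]$kind)
    key <- as.character(i)
    if (is.null(mstate[[key]])) {
      mstate[[key]] <- lapply(grads[[i]], function(g) g * 0)
      vstate[[key]] <- lapply(grads[[i]], function(g) g * 0)
    }
    for (f in fields) {
      g <- grads[[i]][[f]]
      if (is.null(g)) next
      mstate[[key]][[f]] <- b1 * mstate[[key]][[f]] + (1 - b1) * g
      vstate[[key]][[f]] <- b2 * vstate[[key]][[f]] + (1 - b2) * g^2
      mhat <- mstate[[key]][[f]] / (1 - b1^step)
      vhat <- vstate[[key]][[f]] / (1 - b2^step)
      model$layers[[i]][[f]] <- model$layers[[i]][[f]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(model = model, m = mstate, v = vstate)
}

.evaluate_loss <- function(model, xs, labels, w) {
  if (length(xs) == 0L) return(list(loss = NA_real_, accuracy = NA_real_))
  wsum <- sum(w[labels])
  loss <- 0; correct <- 0
  for (j in seq_along(xs)) {
    p <- .softmax(.forward1(model, xs[[j]])$scores)
    loss <- loss - w[labels[j]] * log(max(p[labels[j]], 1e-12)) / wsum
    if (which.max(p) == labels[j]) correct <- correct + 1
  }
  list(loss = loss, accuracy = correct / length(xs))
}
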