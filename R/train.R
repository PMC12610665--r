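#' Training configuration
#'
#' Hyperparameters for the Adam-based training loop: 100 epochs, initial
#' learning rate 0.001 with staircase exponential decay (rate 0.95 every
#' 10,000 iterations), and cross-entropy loss. Batch size defaults to 16,
#' the value tuned for the balanced five-class setting.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param learning_rate Initial Adam learning rate.
#' @param decay_rate Multiplicative decay factor.
#' @param decay_steps Iterations between staircase decay steps.
#' @param loss `"categorical_cross_entropy"` or `"binary_cross_entropy"`
#'   (the latter is the two-class special case of the same softmax head).
#' @param seed Integer seed controlling shuffling, dropout, and (via
#'   [build_model]) initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, learning_rate = 0.001,
                         decay_rate = 0.95, decay_steps = 10000L,
                         loss = c("categorical_cross_entropy", "binary_cross_entropy"),
                         seed = 1L) {
  stopifnot(batch_size >= 1L, decay_rate > 0, decay_rate <= 1, epochs >= 1L)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps), loss = match.arg(loss),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate after a number of iterations
#'
#' Staircase exponential decay:
#' `lr = learning_rate * decay_rate ^ floor(iteration / decay_steps)`.
#'
#' @param cfg A [train_config].
#' @param iteration Zero-based global iteration count.
#' @return Numeric learning rate.
#' @export
decayed_learning_rate <- function(cfg, iteration) {
  cfg$learning_rate * cfg$decay_rate^(iteration %/% cfg$decay_steps)
}

adam_state <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    st <- list(w = list(m = p$w * 0, v = p$w * 0), b = list(m = p$b * 0, v = p$b * 0))
    if (!is.null(p$gamma)) {
      st$gamma <- list(m = p$gamma * 0, v = p$gamma * 0)
      st$beta <- list(m = p$beta * 0, v = p$beta * 0)
    }
    st
  })
}

adam_update <- function(value, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(value = value - lr * mhat / (sqrt(vhat) + eps), state = st)
}

one_hot <- function(labels, label_set) {
  y <- matrix(0, length(label_set), length(labels))
  rownames(y) <- label_set
  y[cbind(match(labels, label_set), seq_along(labels))] <- 1
  y
}

#' Train a WCNN model
#'
#' Minibatch Adam with staircase learning-rate decay and softmax
#' cross-entropy. Fully deterministic given `cfg$seed`. Per-epoch training
#' loss/accuracy (and test metrics when a held-out set is supplied) are
#' recorded in the returned history.
#'
#' @param model A `wcnn_model` from [build_model].
#' @param features List of feature maps or `(H, W, 1, N)` array.
#' @param labels Character vector of class labels, aligned with `features`.
#' @param cfg A [train_config].
#' @param label_set Ordered class names (defaults to sorted unique labels).
#' @param test_features,test_labels Optional held-out set evaluated each
#'   epoch.
#' @param verbose Print a line per epoch.
#' @return The trained model, with a `history` tibble (class
#'   `wcnn_history`) attached as `model$history`.
#' @export
train_wcnn <- function(model, features, labels, cfg = train_config(),
                       label_set = NULL, test_features = NULL,
                       test_labels = NULL, verbose = FALSE) {
  x <- if (is.list(features)) stack_features(features) else features
  n <- dim(x)[4L]
  stopifnot(length(labels) == n)
  if (is.null(label_set)) label_set <- sort(unique(labels))
  stopifnot(length(label_set) == model$arch$n_classes)
  y <- one_hot(labels, label_set)
  x_test <- if (!is.null(test_features)) {
    if (is.list(test_features)) stack_features(test_features) else test_features
  }

  set.seed(cfg$seed)
  state <- adam_state(model$params)
  iteration <- 0L
  t_adam <- 0L
  history <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    order <- sample.int(n)
    epoch_loss <- 0
    epoch_correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- order[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[, idx, drop = FALSE]
      fwd <- forward_pass(model, xb, train = TRUE, keep_cache = TRUE)
      model <- fwd$model                       # carries updated BN running stats
      probs <- fwd$out
      loss <- -mean(colSums(yb * log(pmax(probs, 1e-12))))
      if (!is.finite(loss)) stop("training diverged: non-finite loss at epoch ", epoch)
      epoch_loss <- epoch_loss + loss * length(idx)
      epoch_correct <- epoch_correct +
        sum(max.col(t(probs)) == max.col(t(yb)))
      d_logits <- (probs - yb) / length(idx)   # softmax + CE gradient
      bwd <- backward_pass(model, fwd, d_logits)
      lr <- decayed_learning_rate(cfg, iteration)
      t_adam <- t_adam + 1L
      for (i in seq_along(model$params)) {
        g <- bwd$grads[[i]]
        if (is.null(g)) next
        for (nm in intersect(names(model$params[[i]]), c("w", "b", "gamma", "beta"))) {
          gnm <- switch(nm, w = "dw", b = "db", gamma = "dgamma", beta = "dbeta")
          if (is.null(g[[gnm]])) next
          attrs <- attributes(model$params[[i]][[nm]])
          upd <- adam_update(model$params[[i]][[nm]], g[[gnm]], state[[i]][[nm]], lr, t_adam)
          attributes(upd$value) <- attrs
          model$params[[i]][[nm]] <- upd$value
          state[[i]][[nm]] <- upd$state
        }
      }
      iteration <- iteration + 1L
    }
    row <- tibble::tibble(epoch = epoch, iteration = iteration,
                          learning_rate = decayed_learning_rate(cfg, iteration - 1L),
                          train_loss = epoch_loss / n,
                          train_accuracy = epoch_correct / n,
                          test_loss = NA_real_, test_accuracy = NA_real_)
    if (!is.null(x_test)) {
      pt <- forward_pass(model, x_test, train = FALSE)$out
      yt <- one_hot(test_labels, label_set)
      row$test_loss <- -mean(colSums(yt * log(pmax(pt, 1e-12))))
      row$test_accuracy <- mean(label_set[max.col(t(pt))] == test_labels)
    }
    history[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.4f%s", epoch, row$train_loss,
                      row$train_accuracy,
                      if (!is.null(x_test)) sprintf("  test acc %.4f", row$test_accuracy) else ""))
  }
  model$label_set <- label_set
  model$history <- structure(do.call(rbind, history),
                             class = c("wcnn_history", class(history[[1L]])))
  model
}

#' Hard class predictions
#'
#' Argmax over [predict_wcnn] probabilities (equivalently, threshold 0.5 in
#' the binary case).
#'
#' @inheritParams predict_wcnn
#' @return Character vector of predicted labels.
#' @export
classify_wcnn <- function(model, features) {
  probs <- predict_wcnn(model, features)
  model$label_set[max.col(probs, ties.method = "first")]
}
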