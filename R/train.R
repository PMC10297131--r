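#' Training configuration
#'
#' @param learning_rate positive step size.
#' @param epochs number of passes (>= 1).
#' @param batch_size minibatch size for tabular/baseline models; graph
#'   models always train full-batch with node masks.
#' @param l2 ridge coefficient (>= 0).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (best-epoch parameters restored); `NULL` disables.
#' @param seed RNG seed for shuffling.
#' @return object of class `ckd_train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 200L, batch_size = 32L,
                         l2 = 0, optimizer = c("adam", "sgd"),
                         early_stop_patience = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (l2 < 0) stop("l2 must be >= 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), l2 = l2,
                 optimizer = optimizer,
                 early_stop_patience = if (is.null(early_stop_patience)) NULL
                                       else as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "ckd_train_config")
}

make_optimizer <- function(kind, n_params, lr) {
  if (kind == "sgd") {
    list(step = function(theta, grad) theta - lr * grad)
  } else {
    m <- numeric(n_params); v <- numeric(n_params); t <- 0L
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    list(step = function(theta, grad) {
      t <<- t + 1L
      m <<- beta1 * m + (1 - beta1) * grad
      v <<- beta2 * v + (1 - beta2) * grad^2
      theta - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
    })
  }
}

#' Train a model
#'
#' Seeded optimization of the BCE + L2 loss on the training rows. Graph
#' models (GCN, fusion) are transductive: the forward pass runs over all
#' nodes every step and supervision is masked to the training nodes.
#' Tabular and baseline models use shuffled minibatches. Each epoch the
#' loss and accuracy on the train and test roles are recorded; with
#' `early_stop_patience` set, training stops when the validation loss has
#' not improved for that many epochs and the best-epoch parameters are
#' restored.
#'
#' @param model a `ckd_model`.
#' @param X feature matrix over all rows/nodes.
#' @param y 0/1 labels.
#' @param roles factor with levels train/val/test (see [split_dataset()]).
#' @param config a [train_config()].
#' @return list with `model` (trained) and `history` (data.frame with one
#'   row per epoch run: epoch, train_loss, train_accuracy, test_loss,
#'   test_accuracy).
#' @export
train_model <- function(model, X, y, roles, config = train_config()) {
  X <- as.matrix(X)
  tr <- which(roles == "train"); va <- which(roles == "val")
  te <- which(roles == "test")
  if (!length(tr)) stop("train role is empty")
  full_batch <- model$family %in% c("gnn", "fusion")
  theta <- params_flatten(model$params)
  opt <- make_optimizer(config$optimizer, length(theta), config$learning_rate)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  hist <- vector("list", config$epochs)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  stale <- 0L
  epochs_run <- 0L
  for (ep in seq_len(config$epochs)) {
    if (full_batch) {
      lg <- model_loss_grad(model, X, y, rows = tr, l2 = config$l2)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", ep,
             "; try a smaller learning_rate")
      theta <- opt$step(theta, params_flatten(lg$grads))
      model$params <- params_unflatten(theta, model$params)
    } else {
      idx <- tr[sample.int(length(tr))]
      starts <- seq(1L, length(idx), by = config$batch_size)
      for (s in starts) {
        batch <- idx[s:min(s + config$batch_size - 1L, length(idx))]
        lg <- model_loss_grad(model, X[batch, , drop = FALSE], y[batch],
                              l2 = config$l2)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", ep,
               "; try a smaller learning_rate")
        theta <- opt$step(theta, params_flatten(lg$grads))
        model$params <- params_unflatten(theta, model$params)
      }
    }
    scores <- model_forward(model, X)$scores
    pred <- predict_labels(scores)
    rec <- data.frame(
      epoch = ep,
      train_loss = bce_loss(scores[tr], y[tr], config$l2, model$params),
      train_accuracy = mean(pred[tr] == y[tr]),
      test_loss = if (length(te)) bce_loss(scores[te], y[te]) else NA_real_,
      test_accuracy = if (length(te)) mean(pred[te] == y[te]) else NA_real_)
    hist[[ep]] <- rec
    epochs_run <- ep
    if (!is.null(config$early_stop_patience) && length(va)) {
      val_loss <- bce_loss(scores[va], y[va])
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, theta = theta, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$early_stop_patience) break
      }
    }
  }
  if (!is.null(config$early_stop_patience) && length(va) && best$epoch > 0L)
    model$params <- params_unflatten(best$theta, model$params)
  list(model = model, history = do.call(rbind, hist[seq_len(epochs_run)]))
}

#' Threshold scores into 0/1 labels
#'
#' Label 1 iff `score >= threshold` (boundary inclusive).
#'
#' @param scores numeric vector of probabilities.
#' @param threshold decision cutoff in (0, 1), default 0.5.
#' @return integer 0/1 vector.
#' @export
predict_labels <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  as.integer(scores >= threshold)
}
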