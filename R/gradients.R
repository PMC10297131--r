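## Loss and analytic gradients. One loss serves all families: mean binary
## cross-entropy over the supervised rows plus l2 * sum of squared
## parameters. Gradients are hand-derived backprop, checked against
## central finite differences in the test suite.

#' Binary cross-entropy loss with L2 penalty
#'
#' Mean BCE over the supplied scores/labels, with scores clamped into
#' `[1e-12, 1 - 1e-12]` for numerical stability, plus `l2 * sum(params^2)`
#' when a parameter list is given.
#'
#' @param scores predicted probabilities in (0, 1).
#' @param labels 0/1 vector of the same length.
#' @param l2 ridge coefficient (>= 0).
#' @param params optional parameter list entering the penalty.
#' @return scalar loss.
#' @export
bce_loss <- function(scores, labels, l2 = 0, params = NULL) {
  if (!length(scores)) stop("empty supervision set")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  loss <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  if (!is.null(params) && l2 > 0)
    loss <- loss + l2 * sum(vapply(params, function(w) sum(w^2), numeric(1)))
  loss
}

# l2 gradient contribution, added in place
add_l2 <- function(grads, params, l2) {
  if (l2 > 0) for (nm in names(params))
    grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]
  grads
}

# backward through a dense layer: returns list(dW, db, dHin)
dense_backward <- function(dH_out, Z, Hin, W, activation) {
  dZ <- dH_out * act_deriv(Z, activation)
  list(dW = t(dZ) %*% Hin, db = colSums(dZ), dHin = dZ %*% W)
}

#' Loss and analytic gradient for a model
#'
#' Runs the forward pass on `X`, computes the supervised BCE + L2 loss over
#' `rows`, and backpropagates to every parameter. For graph models `X` must
#' cover all nodes and `rows` selects the supervised nodes (transductive
#' masking); for tabular/baseline models the same convention applies to
#' matrix rows.
#'
#' @param model a `ckd_model`.
#' @param X feature matrix.
#' @param y full 0/1 label vector (length nrow(X)).
#' @param rows integer indices of supervised rows.
#' @param l2 ridge coefficient.
#' @return list with `loss`, `grads` (named like `model$params`), and
#'   `scores`.
#' @export
model_loss_grad <- function(model, X, y, rows = seq_len(nrow(X)), l2 = 0) {
  if (!length(rows)) stop("empty supervision set")
  fw <- model_forward(model, X)
  scores <- fw$scores
  loss <- bce_loss(scores[rows], y[rows], l2, model$params)
  n <- nrow(X); m <- length(rows)
  # d(mean BCE)/d(logit): (p - y)/m on supervised rows, 0 elsewhere
  dz <- numeric(n)
  dz[rows] <- (scores[rows] - y[rows]) / m
  dz <- matrix(dz, ncol = 1)
  grads <- switch(model$family,
                  baseline = baseline_backward(model, X, dz),
                  tabular = tabular_backward(model, fw$cache, dz),
                  gnn = gcn_backward(model, fw$cache, dz),
                  fusion = fusion_backward(model, fw$cache, dz))
  grads <- add_l2(grads, model$params, l2)
  list(loss = loss, grads = grads[names(model$params)], scores = scores)
}

baseline_backward <- function(model, X, dz) {
  list(out_W = t(dz) %*% as.matrix(X), out_b = sum(dz))
}

tabular_backward <- function(model, cache, dz) {
  p <- model$params
  grads <- list(out_W = t(dz) %*% cache$Hlast, out_b = sum(dz))
  dH <- dz %*% p$out_W
  for (l in rev(seq_along(model$arch$hidden_dims))) {
    st <- cache$hid[[l]]
    bk <- dense_backward(dH, st$Z, st$Hin, p[[paste0("hid", l, "_W")]],
                         model$activation)
    grads[[paste0("hid", l, "_W")]] <- bk$dW
    grads[[paste0("hid", l, "_b")]] <- bk$db
    dH <- bk$dHin
  }
  grads
}

gcn_backward <- function(model, cache, dz) {
  p <- model$params
  A <- model$adjacency$A
  grads <- list(out_W = t(dz) %*% cache$Hlast, out_b = sum(dz))
  dH <- dz %*% p$out_W
  for (l in rev(seq_along(model$arch$head_dims))) {
    st <- cache$head[[l]]
    bk <- dense_backward(dH, st$Z, st$Hin, p[[paste0("head", l, "_W")]],
                         model$activation)
    grads[[paste0("head", l, "_W")]] <- bk$dW
    grads[[paste0("head", l, "_b")]] <- bk$db
    dH <- bk$dHin
  }
  for (l in rev(seq_along(model$arch$conv_dims))) {
    st <- cache$conv[[l]]
    W <- p[[paste0("conv", l, "_W")]]
    dZ <- dH * act_deriv(st$Z, model$activation)
    grads[[paste0("conv", l, "_W")]] <- t(dZ) %*% st$AH
    grads[[paste0("conv", l, "_b")]] <- colSums(dZ)
    dH <- as.matrix(Matrix::t(A) %*% (dZ %*% W))
  }
  grads
}

fusion_backward <- function(model, cache, dz) {
  p <- model$params
  A <- model$adjacency$A
  grads <- list(f_W = t(dz) %*% cache$Favg, f_b = sum(dz))
  dF <- dz %*% p$f_W
  dGt <- dF / 2; dTt <- dF / 2
  dZg <- dGt * act_deriv(cache$Zg, "relu")
  grads$tg_W <- t(dZg) %*% cache$G
  grads$tg_b <- colSums(dZg)
  dG <- dZg %*% p$tg_W
  dZt <- dTt * act_deriv(cache$Zt, "relu")
  grads$tt_W <- t(dZt) %*% cache$Tm
  grads$tt_b <- colSums(dZt)
  dT <- dZt %*% p$tt_W
  for (l in rev(seq_along(model$arch$conv_dims))) {
    st <- cache$g[[l]]
    W <- p[[paste0("g_conv", l, "_W")]]
    dZ <- dG * act_deriv(st$Z, model$activation)
    grads[[paste0("g_conv", l, "_W")]] <- t(dZ) %*% st$AH
    grads[[paste0("g_conv", l, "_b")]] <- colSums(dZ)
    dG <- as.matrix(Matrix::t(A) %*% (dZ %*% W))
  }
  for (l in rev(seq_along(model$arch$hidden_dims))) {
    st <- cache$t[[l]]
    bk <- dense_backward(dT, st$Z, st$Hin, p[[paste0("t_hid", l, "_W")]],
                         model$activation)
    grads[[paste0("t_hid", l, "_W")]] <- bk$dW
    grads[[paste0("t_hid", l, "_b")]] <- bk$db
    dT <- bk$dHin
  }
  grads
}
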