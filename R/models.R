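## Model families: GCN on the patient graph, feed-forward tabular net,
## averaging late-fusion of the two, and a logistic baseline. Parameters
## live in a flat named list of arrays; gradients mirror that structure,
## and optimizers work on the flattened numeric vector.

act_fun <- function(Z, tag) {
  switch(tag,
         relu = pmax(Z, 0),
         leaky_relu = ifelse(Z > 0, Z, 0.01 * Z),
         identity = Z,
         sigmoid = 1 / (1 + exp(-Z)),
         stop("unknown activation: ", tag))
}

# derivative w.r.t. pre-activation, given Z (pre-activation)
act_deriv <- function(Z, tag) {
  switch(tag,
         relu = (Z > 0) + 0,
         leaky_relu = ifelse(Z > 0, 1, 0.01),
         identity = array(1, dim(Z)),
         sigmoid = { s <- 1 / (1 + exp(-Z)); s * (1 - s) },
         stop("unknown activation: ", tag))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Seeded parameter initialization
#'
#' Draws an `n_out x n_in` weight matrix from a uniform distribution with
#' the documented fan-based scaling: `glorot_uniform` uses limit
#' `sqrt(6 / (fan_in + fan_out))`, `he_uniform` uses `sqrt(6 / fan_in)`.
#' The same seed always returns the same matrix.
#'
#' @param n_out,n_in output and input dimensions (positive).
#' @param scheme `"glorot_uniform"` or `"he_uniform"`.
#' @param seed integer seed.
#' @return an `n_out x n_in` numeric matrix.
#' @export
init_params <- function(n_out, n_in, scheme = c("glorot_uniform", "he_uniform"),
                        seed = 1L) {
  scheme <- match.arg(scheme)
  if (n_out < 1L || n_in < 1L) stop("dimensions must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  init_matrix(n_out, n_in, scheme)
}

# draws from the current RNG stream (callers manage seeding)
init_matrix <- function(n_out, n_in, scheme = "glorot_uniform") {
  limit <- switch(scheme,
                  glorot_uniform = sqrt(6 / (n_in + n_out)),
                  he_uniform = sqrt(6 / n_in),
                  stop("unknown scheme: ", scheme))
  matrix(stats::runif(n_out * n_in, -limit, limit), n_out, n_in)
}

## ---- constructors -------------------------------------------------------

#' Construct a GCN model
#'
#' Graph-convolutional layers compute `H_out = act(A H W' + b)` where `A`
#' is the normalized adjacency (self-loops included); the pre-head output
#' of the last conv layer is the node embedding matrix G. A dense head
#' (optional hidden layers, then a single sigmoid unit) maps embeddings to
#' per-node CKD probabilities.
#'
#' @param adjacency a `ckd_adjacency` from [normalize_adjacency()].
#' @param in_dim input feature count.
#' @param conv_dims widths of the graph-conv layers.
#' @param head_dims widths of dense head layers before the scalar output.
#' @param activation hidden activation, `"relu"` or `"leaky_relu"`.
#' @param seed parameter-init seed.
#' @return object of class `ckd_model`, family `"gnn"`.
#' @export
gcn_model <- function(adjacency, in_dim, conv_dims = c(32L, 16L),
                      head_dims = integer(0), activation = "relu", seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  prev <- in_dim
  for (l in seq_along(conv_dims)) {
    params[[paste0("conv", l, "_W")]] <- init_matrix(conv_dims[l], prev)
    params[[paste0("conv", l, "_b")]] <- numeric(conv_dims[l])
    prev <- conv_dims[l]
  }
  for (l in seq_along(head_dims)) {
    params[[paste0("head", l, "_W")]] <- init_matrix(head_dims[l], prev)
    params[[paste0("head", l, "_b")]] <- numeric(head_dims[l])
    prev <- head_dims[l]
  }
  params$out_W <- init_matrix(1L, prev)
  params$out_b <- 0
  structure(list(family = "gnn", params = params,
                 arch = list(in_dim = in_dim, conv_dims = conv_dims,
                             head_dims = head_dims),
                 activation = activation, adjacency = adjacency, seed = seed),
            class = "ckd_model")
}

#' Construct a feed-forward tabular model
#'
#' `L` fully connected hidden layers `H_l = act(H_{l-1} W' + b)` followed
#' by a single sigmoid output unit; the last hidden activation H_L is the
#' tabular embedding T.
#'
#' @param in_dim input feature count.
#' @param hidden_dims hidden-layer widths (may be `integer(0)`, which
#'   reduces the model to plain logistic regression).
#' @param activation hidden activation.
#' @param seed parameter-init seed.
#' @return object of class `ckd_model`, family `"tabular"`.
#' @export
tabular_model <- function(in_dim, hidden_dims = c(64L, 32L),
                          activation = "relu", seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  prev <- in_dim
  for (l in seq_along(hidden_dims)) {
    params[[paste0("hid", l, "_W")]] <- init_matrix(hidden_dims[l], prev)
    params[[paste0("hid", l, "_b")]] <- numeric(hidden_dims[l])
    prev <- hidden_dims[l]
  }
  params$out_W <- init_matrix(1L, prev)
  params$out_b <- 0
  structure(list(family = "tabular", params = params,
                 arch = list(in_dim = in_dim, hidden_dims = hidden_dims),
                 activation = activation, adjacency = NULL, seed = seed),
            class = "ckd_model")
}

#' Construct the averaging late-fusion model
#'
#' A GCN branch (conv layers only) produces node embeddings G (n x p) and a
#' tabular branch produces T (n x q). Both are mapped into a shared p'
#' dimensional space by dense transforms with ReLU, averaged elementwise
#' (`F_avg = (G_t + T_t) / 2`), and passed through a single sigmoid head.
#' Training is end-to-end: one loss backpropagates through both branches.
#'
#' @param adjacency a `ckd_adjacency`.
#' @param in_dim input feature count.
#' @param conv_dims GCN-branch conv widths (last = p).
#' @param hidden_dims tabular-branch hidden widths (last = q).
#' @param p_prime shared transformed dimension.
#' @param activation hidden activation for both branches.
#' @param seed parameter-init seed.
#' @return object of class `ckd_model`, family `"fusion"`.
#' @export
fusion_model <- function(adjacency, in_dim, conv_dims = c(32L, 16L),
                         hidden_dims = c(64L, 32L), p_prime = 16L,
                         activation = "relu", seed = 1L) {
  if (length(conv_dims) < 1L || length(hidden_dims) < 1L)
    stop("both branches need at least one layer to define embeddings")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  prev <- in_dim
  for (l in seq_along(conv_dims)) {
    params[[paste0("g_conv", l, "_W")]] <- init_matrix(conv_dims[l], prev)
    params[[paste0("g_conv", l, "_b")]] <- numeric(conv_dims[l])
    prev <- conv_dims[l]
  }
  prev <- in_dim
  for (l in seq_along(hidden_dims)) {
    params[[paste0("t_hid", l, "_W")]] <- init_matrix(hidden_dims[l], prev)
    params[[paste0("t_hid", l, "_b")]] <- numeric(hidden_dims[l])
    prev <- hidden_dims[l]
  }
  p <- conv_dims[length(conv_dims)]
  q <- hidden_dims[length(hidden_dims)]
  params$tg_W <- init_matrix(p_prime, p); params$tg_b <- numeric(p_prime)
  params$tt_W <- init_matrix(p_prime, q); params$tt_b <- numeric(p_prime)
  params$f_W <- init_matrix(1L, p_prime); params$f_b <- 0
  structure(list(family = "fusion", params = params,
                 arch = list(in_dim = in_dim, conv_dims = conv_dims,
                             hidden_dims = hidden_dims, p = p, q = q,
                             p_prime = p_prime),
                 activation = activation, adjacency = adjacency, seed = seed),
            class = "ckd_model")
}

#' Construct the logistic baseline
#'
#' A single sigmoid unit over the raw features — logistic regression
#' trained by the same loop as the deep models.
#'
#' @param in_dim input feature count.
#' @param seed parameter-init seed.
#' @return object of class `ckd_model`, family `"baseline"`.
#' @export
baseline_model <- function(in_dim, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  structure(list(family = "baseline",
                 params = list(out_W = init_matrix(1L, in_dim), out_b = 0),
                 arch = list(in_dim = in_dim),
                 activation = "relu", adjacency = NULL, seed = seed),
            class = "ckd_model")
}

#' @export
print.ckd_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<ckd_model:%s> %d parameters (seed %d)\n", x$family, np, x$seed))
  invisible(x)
}

## ---- forward passes -----------------------------------------------------

#' Single graph-convolution layer
#'
#' Computes `act(A H W' + b)`: each node aggregates its neighbours' (and,
#' through the self-loop, its own) features with the normalized-adjacency
#' coefficients, then applies the learned linear map and nonlinearity.
#'
#' @param H n x m_in node-feature matrix.
#' @param A a `ckd_adjacency` (or a plain matrix of coefficients).
#' @param W m_out x m_in weight matrix.
#' @param b length-m_out bias.
#' @param activation activation tag (`"identity"` for a linear layer).
#' @return n x m_out matrix.
#' @export
gcn_layer_forward <- function(H, A, W, b, activation = "relu") {
  Amat <- if (inherits(A, "ckd_adjacency")) A$A else A
  if (nrow(H) != nrow(Amat))
    stop("H has ", nrow(H), " rows but adjacency has ", nrow(Amat), " nodes")
  if (ncol(W) != ncol(H))
    stop("W is ", nrow(W), "x", ncol(W), " but H is ", nrow(H), "x", ncol(H))
  AH <- as.matrix(Amat %*% H)
  act_fun(sweep(AH %*% t(W), 2, -b), activation)
}

# dense affine layer: H %*% t(W) + b
dense <- function(H, W, b) sweep(H %*% t(W), 2, -b)

#' GCN forward pass
#'
#' @param model a `ckd_model` of family `"gnn"`.
#' @param X node-feature matrix matching the adjacency node count.
#' @return list with `scores` (per-node probability), `embeddings` (the
#'   pre-head node representations G), and `cache` (intermediates for
#'   backpropagation).
#' @export
gcn_forward <- function(model, X) {
  A <- model$adjacency$A
  if (nrow(X) != nrow(A))
    stop("X has ", nrow(X), " rows but adjacency has ", nrow(A), " nodes")
  p <- model$params
  H <- as.matrix(X)
  cache <- list(H0 = H, conv = list(), head = list())
  for (l in seq_along(model$arch$conv_dims)) {
    AH <- as.matrix(A %*% H)
    Z <- dense(AH, p[[paste0("conv", l, "_W")]], p[[paste0("conv", l, "_b")]])
    cache$conv[[l]] <- list(AH = AH, Z = Z)
    H <- act_fun(Z, model$activation)
  }
  G <- H
  for (l in seq_along(model$arch$head_dims)) {
    Z <- dense(H, p[[paste0("head", l, "_W")]], p[[paste0("head", l, "_b")]])
    cache$head[[l]] <- list(Hin = H, Z = Z)
    H <- act_fun(Z, model$activation)
  }
  z <- drop(dense(H, p$out_W, p$out_b))
  cache$Hlast <- H
  list(scores = sigmoid(z), embeddings = G, cache = cache)
}

#' Tabular forward pass
#'
#' @param model a `ckd_model` of family `"tabular"` or `"baseline"`.
#' @param X feature matrix with `in_dim` columns.
#' @return list with `scores`, `embeddings` (last hidden activation; the
#'   input itself when there are no hidden layers), and `cache`.
#' @export
tabular_forward <- function(model, X) {
  if (ncol(X) != model$arch$in_dim)
    stop("X has ", ncol(X), " columns but model expects ", model$arch$in_dim)
  p <- model$params
  H <- as.matrix(X)
  cache <- list(H0 = H, hid = list())
  for (l in seq_along(model$arch$hidden_dims)) {
    Z <- dense(H, p[[paste0("hid", l, "_W")]], p[[paste0("hid", l, "_b")]])
    cache$hid[[l]] <- list(Hin = H, Z = Z)
    H <- act_fun(Z, model$activation)
  }
  z <- drop(dense(H, p$out_W, p$out_b))
  cache$Hlast <- H
  list(scores = sigmoid(z), embeddings = H, cache = cache)
}

#' Baseline forward pass: `sigmoid(X w + b)`
#' @param model a `ckd_model` of family `"baseline"`.
#' @param X feature matrix.
#' @return vector of scores in (0, 1).
#' @export
baseline_forward <- function(model, X) {
  if (ncol(X) != model$arch$in_dim)
    stop("X has ", ncol(X), " columns but model expects ", model$arch$in_dim)
  sigmoid(drop(dense(as.matrix(X), model$params$out_W, model$params$out_b)))
}

#' Fusion forward pass
#'
#' Runs both branches, transforms their embeddings into the shared p'
#' space with ReLU, averages elementwise, and applies the sigmoid head:
#' `G_t = relu(G W_G' + B_G)`, `T_t = relu(T W_T' + B_T)`,
#' `F_avg = (G_t + T_t) / 2`, `score = sigmoid(F_avg W_f' + B_f)`.
#'
#' @param model a `ckd_model` of family `"fusion"`.
#' @param X node-feature matrix over all graph nodes.
#' @return list with `scores`, `F_avg` (fused representation), `embeddings`
#'   (alias of `F_avg`), and `cache`.
#' @export
fusion_forward <- function(model, X) {
  A <- model$adjacency$A
  if (nrow(X) != nrow(A))
    stop("X has ", nrow(X), " rows but adjacency has ", nrow(A), " nodes")
  p <- model$params
  H <- as.matrix(X)
  cache <- list(H0 = H, g = list(), t = list())
  for (l in seq_along(model$arch$conv_dims)) {
    AH <- as.matrix(A %*% H)
    Z <- dense(AH, p[[paste0("g_conv", l, "_W")]], p[[paste0("g_conv", l, "_b")]])
    cache$g[[l]] <- list(AH = AH, Z = Z)
    H <- act_fun(Z, model$activation)
  }
  G <- H
  H <- as.matrix(X)
  for (l in seq_along(model$arch$hidden_dims)) {
    Z <- dense(H, p[[paste0("t_hid", l, "_W")]], p[[paste0("t_hid", l, "_b")]])
    cache$t[[l]] <- list(Hin = H, Z = Z)
    H <- act_fun(Z, model$activation)
  }
  Tm <- H
  Zg <- dense(G, p$tg_W, p$tg_b); Gt <- act_fun(Zg, "relu")
  Zt <- dense(Tm, p$tt_W, p$tt_b); Tt <- act_fun(Zt, "relu")
  Favg <- (Gt + Tt) / 2
  z <- drop(dense(Favg, p$f_W, p$f_b))
  cache <- c(cache, list(G = G, Tm = Tm, Zg = Zg, Zt = Zt,
                         Gt = Gt, Tt = Tt, Favg = Favg))
  list(scores = sigmoid(z), F_avg = Favg, embeddings = Favg, cache = cache)
}

#' Family-dispatching forward pass
#' @param model a `ckd_model`.
#' @param X feature matrix.
#' @return list with at least `scores` and `embeddings`.
#' @export
model_forward <- function(model, X) {
  switch(model$family,
         gnn = gcn_forward(model, X),
         tabular = tabular_forward(model, X),
         fusion = fusion_forward(model, X),
         baseline = {
           s <- baseline_forward(model, X)
           list(scores = s, embeddings = as.matrix(X))
         },
         stop("unknown model family: ", model$family))
}

## ---- flatten / unflatten for optimizers ---------------------------------

params_flatten <- function(params) unlist(lapply(params, as.numeric), use.names = FALSE)

params_unflatten <- function(v, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    chunk <- v[pos + seq_len(len)]
    if (is.matrix(template[[nm]]))
      out[[nm]] <- matrix(chunk, nrow(template[[nm]]), ncol(template[[nm]]))
    else out[[nm]] <- chunk
    pos <- pos + len
  }
  out
}
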