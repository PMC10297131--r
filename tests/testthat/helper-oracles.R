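# Independent reference implementations ("oracles") used to validate the
# package code paths, plus small fixture builders. Oracles deliberately use
# naive loops / dense algebra, never the functions they check.

# brute-force pairwise distances by double loop
oracle_pairwise <- function(X, metric = "euclidean") {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- switch(metric,
      euclidean = sqrt(sum((X[i, ] - X[j, ])^2)),
      manhattan = sum(abs(X[i, ] - X[j, ])),
      cosine = 1 - sum(X[i, ] * X[j, ]) /
        (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2))))
  }
  diag(D) <- 0
  D
}

# exhaustive k-NN edge enumeration: undirected union of directed k-NN
oracle_knn_edges <- function(X, k, metric = "euclidean") {
  D <- oracle_pairwise(X, metric)
  n <- nrow(X)
  edges <- NULL
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    for (j in order(d)[seq_len(k)])
      edges <- rbind(edges, c(min(i, j), max(i, j)))
  }
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# dense normalized adjacency: D^-1/2 (A + I) D^-1/2 or row normalization
oracle_norm_adj <- function(n, edges, weights, scheme = "sym") {
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    A[edges[e, 1], edges[e, 2]] <- weights[e]
    A[edges[e, 2], edges[e, 1]] <- weights[e]
  }
  diag(A) <- 1
  deg <- rowSums(A)
  if (scheme == "sym") diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
  else diag(1 / deg) %*% A
}

# per-node loop form of the graph convolution equation
oracle_gcn_layer <- function(H, Ahat, W, b, act = function(z) pmax(z, 0)) {
  n <- nrow(H)
  out <- matrix(0, n, nrow(W))
  for (i in seq_len(n)) {
    s <- numeric(ncol(H))
    for (j in seq_len(n)) if (Ahat[i, j] != 0)
      s <- s + Ahat[i, j] * H[j, ]
    out[i, ] <- act(as.numeric(W %*% s) + b)
  }
  out
}

# independent confusion counting loop
oracle_metrics <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    else if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
    else if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / length(y_true),
       precision = prec, recall = rec,
       f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

# central finite-difference gradient of the training loss
numeric_gradient <- function(model, X, y, rows, l2 = 0, h = 1e-5) {
  theta <- ckdfusion:::params_flatten(model$params)
  f <- function(v) {
    m <- model
    m$params <- ckdfusion:::params_unflatten(v, model$params)
    fw <- model_forward(m, X)
    bce_loss(fw$scores[rows], y[rows], l2, m$params)
  }
  vapply(seq_along(theta), function(i) {
    e <- numeric(length(theta)); e[i] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, numeric(1))
}

# perturb parameters off ReLU kinks so finite differences are valid
jitter_params <- function(model, sd = 0.05, seed = 1L) {
  theta <- ckdfusion:::params_flatten(model$params)
  set.seed(seed)
  theta <- theta + rnorm(length(theta), 0, sd)
  model$params <- ckdfusion:::params_unflatten(theta, model$params)
  model
}

# tiny hand-buildable dataset: 3 rows, one masked cell in row 2 (age)
tiny_dataset <- function() {
  schema <- ckd_schema()
  d <- length(schema$names)
  X <- matrix(0, 3, d, dimnames = list(NULL, schema$names))
  set.seed(11)
  for (f in schema$names)
    X[, f] <- if (schema$kinds[f] == "categorical-binary") rbinom(3, 1, 0.5)
              else round(runif(3, 1, 9), 2)
  mask <- matrix(FALSE, 3, d)
  mask[2, 1] <- TRUE
  ckd_dataset(X, mask, c(1L, 0L, 1L), schema, "synthetic")
}

# separable fixture: generator defaults with class mean-shift delta = 3
separable_data <- function(n_per_class = 200L, seed = 1L) {
  prep <- run_preprocess(
    generate_synthetic(synthetic_spec(n_per_class = n_per_class, delta = 3,
                                      seed = seed)),
    preprocess_config(smote_enabled = FALSE, seed = seed))
  prep
}

small_graph_setup <- function(n = 6, d = 4, seed = 9, k = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  g <- build_knn_graph(X, k = k)
  list(X = X, y = rbinom(n, 1, 0.5), g = g, adj = normalize_adjacency(g))
}
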