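#' Build a model of a given family from architecture options
#'
#' @param family `"fusion"`, `"gnn"`, `"tabular"`, or `"baseline"`.
#' @param in_dim input feature count.
#' @param adjacency `ckd_adjacency`, required for graph families.
#' @param arch named list of architecture overrides (`conv_dims`,
#'   `hidden_dims`, `head_dims`, `p_prime`, `activation`).
#' @param seed parameter-init seed.
#' @return a `ckd_model`.
#' @export
build_model <- function(family, in_dim, adjacency = NULL, arch = list(),
                        seed = 1L) {
  g <- function(nm, default) if (!is.null(arch[[nm]])) arch[[nm]] else default
  act <- g("activation", "relu")
  switch(family,
    gnn = gcn_model(adjacency, in_dim, conv_dims = g("conv_dims", c(32L, 16L)),
                    head_dims = g("head_dims", integer(0)),
                    activation = act, seed = seed),
    tabular = tabular_model(in_dim, hidden_dims = g("hidden_dims", c(64L, 32L)),
                            activation = act, seed = seed),
    fusion = fusion_model(adjacency, in_dim,
                          conv_dims = g("conv_dims", c(32L, 16L)),
                          hidden_dims = g("hidden_dims", c(64L, 32L)),
                          p_prime = g("p_prime", 16L),
                          activation = act, seed = seed),
    baseline = baseline_model(in_dim, seed = seed),
    stop("unknown model family: ", family))
}

TRAIN_FIELDS <- c("learning_rate", "epochs", "batch_size", "l2", "optimizer",
                  "early_stop_patience")
ARCH_FIELDS <- c("conv_dims", "hidden_dims", "head_dims", "p_prime", "activation")

#' Grid-search hyperparameter tuning
#'
#' Trains one seeded model per point of the Cartesian product of the
#' candidate lists, scores each on the validation role, and returns the
#' best configuration (ties broken by enumeration order, earlier wins)
#' plus the full leaderboard. Grid names may address training fields
#' (`learning_rate`, `epochs`, `batch_size`, `l2`, `optimizer`),
#' architecture fields (`conv_dims`, `hidden_dims`, `p_prime`,
#' `activation`), or `graph_k` (the k-NN graph is then rebuilt per point).
#' A training failure scores `-Inf` instead of aborting the search.
#'
#' @param family model family tag.
#' @param X,y,roles processed data and split (see [run_preprocess()]).
#' @param adjacency `ckd_adjacency` for graph families (ignored when
#'   `graph_k` is in the grid).
#' @param grid named list of candidate-value vectors/lists.
#' @param base_train a [train_config()] supplying non-searched fields.
#' @param base_arch named list of non-searched architecture fields.
#' @param selection_metric `"accuracy"` or `"f1"` on the validation role.
#' @param graph_opts list of graph options (metric, epsilon, scheme,
#'   use_weights) used when rebuilding for `graph_k`.
#' @return list with `best_config` (merged named list), `best_model`,
#'   `leaderboard` (data.frame sorted by decreasing score with the
#'   enumeration index `point`), and `selection_metric`.
#' @export
grid_search <- function(family, X, y, roles, adjacency = NULL, grid,
                        base_train = train_config(), base_arch = list(),
                        selection_metric = c("accuracy", "f1"),
                        graph_opts = list()) {
  selection_metric <- match.arg(selection_metric)
  if (!length(grid) || any(!vapply(grid, length, integer(1))))
    stop("grid must be a nonempty named list of nonempty candidate lists")
  va <- which(roles == "val")
  if (!length(va)) stop("validation role is empty")
  points <- expand.grid(lapply(grid, seq_along), KEEP.OUT.ATTRS = FALSE)
  n_pts <- nrow(points)
  scores <- numeric(n_pts)
  models <- vector("list", n_pts)
  configs <- vector("list", n_pts)
  for (pt in seq_len(n_pts)) {
    choice <- lapply(seq_along(grid), function(j) grid[[j]][[points[pt, j]]])
    names(choice) <- names(grid)
    configs[[pt]] <- choice
    res <- tryCatch({
      tc <- base_train
      for (nm in intersect(names(choice), TRAIN_FIELDS)) tc[[nm]] <- choice[[nm]]
      arch <- base_arch
      for (nm in intersect(names(choice), ARCH_FIELDS)) arch[[nm]] <- choice[[nm]]
      adj <- adjacency
      if ("graph_k" %in% names(choice)) {
        go <- graph_opts
        gg <- build_knn_graph(X, k = choice$graph_k,
                              metric = if (is.null(go$metric)) "euclidean" else go$metric,
                              epsilon = if (is.null(go$epsilon)) 1e-8 else go$epsilon)
        adj <- normalize_adjacency(gg,
                                   scheme = if (is.null(go$scheme)) "sym" else go$scheme,
                                   use_weights = !isFALSE(go$use_weights))
      }
      model <- build_model(family, ncol(X), adj, arch, seed = tc$seed)
      fit <- train_model(model, X, y, roles, tc)
      pred <- predict_labels(model_forward(fit$model, X)$scores)
      m <- compute_metrics(y[va], pred[va])
      list(score = m[[selection_metric]], model = fit$model)
    }, error = function(e) list(score = -Inf, model = NULL))
    scores[pt] <- res$score
    models[[pt]] <- res$model
  }
  ord <- order(-scores)  # stable: earlier enumeration wins ties
  lb <- data.frame(point = seq_len(n_pts),
                   score = scores,
                   config = vapply(configs, function(cf)
                     paste(names(cf), vapply(cf, function(v)
                       paste(format(v), collapse = "/"), character(1)),
                       sep = "=", collapse = ", "), character(1)),
                   stringsAsFactors = FALSE)[ord, ]
  best <- ord[1]
  list(best_config = configs[[best]], best_model = models[[best]],
       leaderboard = lb, selection_metric = selection_metric)
}

#' Train and compare the four model families
#'
#' Trains fusion, GCN, tabular, and baseline models under the identical
#' split and seeds, and reports test-role metrics, confusion matrices,
#' and per-epoch histories — the published comparison protocol.
#'
#' @param X,y,roles processed data and split.
#' @param adjacency `ckd_adjacency` over all rows.
#' @param train a [train_config()] shared by all families.
#' @param arch named list of per-family architecture overrides, e.g.
#'   `list(fusion = list(p_prime = 8))`.
#' @param families model tags to fit (default all four).
#' @return list with `table` (data.frame: model, accuracy, precision,
#'   recall, f1, plus TP/TN/FP/FN counts), `metrics`, `confusions`,
#'   `histories`, and `models`, each keyed by family.
#' @export
compare_models <- function(X, y, roles, adjacency,
                           train = train_config(), arch = list(),
                           families = c("fusion", "gnn", "tabular", "baseline")) {
  te <- which(roles == "test")
  metrics <- list(); histories <- list(); models <- list(); confusions <- list()
  for (fam in families) {
    model <- build_model(fam, ncol(X), adjacency,
                         if (is.null(arch[[fam]])) list() else arch[[fam]],
                         seed = train$seed)
    fit <- train_model(model, X, y, roles, train)
    pred <- predict_labels(model_forward(fit$model, X)$scores)
    m <- compute_metrics(y[te], pred[te])
    metrics[[fam]] <- m
    confusions[[fam]] <- confusion_matrix(m)
    histories[[fam]] <- fit$history
    models[[fam]] <- fit$model
  }
  table <- do.call(rbind, lapply(families, function(fam) {
    m <- metrics[[fam]]
    data.frame(model = fam, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, tp = m$tp, tn = m$tn,
               fp = m$fp, fn = m$fn, stringsAsFactors = FALSE)
  }))
  list(table = table, metrics = metrics, confusions = confusions,
       histories = histories, models = models)
}

#' Save / load a model checkpoint
#'
#' A single JSON file carrying the family, architecture, activation, seed,
#' and every parameter array at full precision, so a reloaded model
#' reproduces forward outputs bit-identically. The adjacency is not stored
#' (serialize the graph separately with [write_graph()]) and must be
#' re-attached on load for graph families.
#'
#' @param model a `ckd_model`.
#' @param path output path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(family = model$family, arch = model$arch,
              activation = model$activation, seed = model$seed,
              params = lapply(model$params, function(p) {
                # shortest exact decimal strings so reload is bit-identical
                list(dim = if (is.matrix(p)) dim(p),
                     data = vapply(as.numeric(p), num_to_str, character(1)))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' @rdname save_checkpoint
#' @param adjacency `ckd_adjacency` to attach (graph families).
#' @return the restored `ckd_model`.
#' @export
load_checkpoint <- function(path, adjacency = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  params <- lapply(obj$params, function(p) {
    v <- as.numeric(unlist(p$data))
    if (!is.null(p$dim) && length(p$dim)) matrix(v, p$dim[[1]], p$dim[[2]]) else v
  })
  arch <- lapply(obj$arch, function(a) if (is.list(a)) unlist(a) else a)
  structure(list(family = obj$family, params = params, arch = arch,
                 activation = obj$activation, adjacency = adjacency,
                 seed = as.integer(obj$seed)),
            class = "ckd_model")
}
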