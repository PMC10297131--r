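test_that("bce_loss matches closed forms and a hand summation", {
  expect_equal(bce_loss(rep(0.5, 4), c(0, 1, 0, 1)), log(2))
  expect_lt(bce_loss(c(1 - 1e-12, 1e-12), c(1, 0)), 1e-10)
  set.seed(31)
  p <- runif(7, 0.05, 0.95); y <- rbinom(7, 1, 0.5)
  hand <- -sum(y * log(p) + (1 - y) * log(1 - p)) / 7
  expect_equal(bce_loss(p, y), hand, tolerance = 1e-9)
  params <- list(W = matrix(1:4, 2), b = 0.5)
  expect_equal(bce_loss(p, y, l2 = 0.1, params = params),
               hand + 0.1 * (sum((1:4)^2) + 0.25), tolerance = 1e-9)
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
})

test_that("compute_metrics matches the hand table and the counting oracle", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$tp, 1L); expect_equal(m$fn, 1L)
  expect_equal(m$tn, 2L); expect_equal(m$fp, 0L)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 1.0)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3)
  expect_equal(unname(confusion_matrix(m)), rbind(c(2, 0), c(1, 1)))
  # perfect and fully wrong predictions
  perf <- compute_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perf$accuracy, perf$precision, perf$recall, perf$f1),
               rep(1, 4))
  wrong <- compute_metrics(c(1, 0), c(0, 1))
  expect_equal(wrong$accuracy, 0); expect_equal(wrong$f1, 0)
  # 1000 random binary vectors against the independent counting loop
  set.seed(41)
  for (rep in 1:1000) {
    n <- sample(1:12, 1)
    yt <- rbinom(n, 1, 0.5); yp <- rbinom(n, 1, 0.5)
    got <- compute_metrics(yt, yp)
    ref <- oracle_metrics(yt, yp)
    for (f in names(ref)) expect_identical(got[[f]] * 1.0, ref[[f]] * 1.0)
  }
  expect_error(compute_metrics(c(1, 2), c(0, 1)), "binary")
})

test_that("predict_labels is boundary-inclusive and monotone in threshold", {
  expect_equal(predict_labels(0.5, 0.5), 1L)
  expect_equal(predict_labels(c(0, 0, 0)), c(0L, 0L, 0L))
  set.seed(6)
  s <- runif(50)
  prev <- predict_labels(s, 0.1)
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- predict_labels(s, th)
    expect_true(all(cur <= prev))  # raising threshold never flips 0 -> 1
    prev <- cur
  }
  expect_error(predict_labels(s, 1), "threshold")
})

test_that("training is deterministic and a zero learning rate is a no-op", {
  prep <- separable_data(30, seed = 2)
  g <- build_knn_graph(prep$X, k = 3)
  adj <- normalize_adjacency(g)
  tc <- train_config(epochs = 5L, seed = 11)
  for (fam in c("tabular", "gnn")) {
    m <- build_model(fam, ncol(prep$X), adj, seed = 11)
    f1 <- train_model(m, prep$X, prep$y, prep$roles, tc)
    f2 <- train_model(m, prep$X, prep$y, prep$roles, tc)
    expect_identical(f1$history, f2$history)
    expect_identical(ckdfusion:::params_flatten(f1$model$params),
                     ckdfusion:::params_flatten(f2$model$params))
  }
  m <- build_model("tabular", ncol(prep$X), seed = 1)
  fz <- train_model(m, prep$X, prep$y, prep$roles,
                    train_config(learning_rate = 0, epochs = 3L, seed = 1))
  expect_identical(ckdfusion:::params_flatten(fz$model$params),
                   ckdfusion:::params_flatten(m$params))
  expect_equal(length(unique(fz$history$train_loss)), 1L)
})

test_that("every family learns the separable fixture (delta = 3)", {
  prep <- separable_data(200, seed = 1)
  adj <- normalize_adjacency(build_knn_graph(prep$X, k = 5))
  tc <- train_config(epochs = 60L, seed = 1)
  for (fam in c("fusion", "gnn", "tabular", "baseline")) {
    fit <- train_model(build_model(fam, ncol(prep$X), adj, seed = 1),
                       prep$X, prep$y, prep$roles, tc)
    h <- fit$history
    expect_gte(h$train_accuracy[nrow(h)], 0.95)
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
    # epoch-averaged loss over the last quarter <= first quarter
    q <- nrow(h) %/% 4
    expect_lte(mean(h$train_loss[(nrow(h) - q + 1):nrow(h)]),
               mean(h$train_loss[1:q]))
  }
})

test_that("early stopping restores the best-epoch parameters", {
  prep <- separable_data(40, seed = 3)
  tc <- train_config(epochs = 50L, early_stop_patience = 3L, seed = 2)
  fit <- train_model(build_model("tabular", ncol(prep$X), seed = 2),
                     prep$X, prep$y, prep$roles, tc)
  expect_lte(nrow(fit$history), 50L)
  va <- prep$roles == "val"
  scores <- model_forward(fit$model, prep$X)$scores
  # restored parameters reproduce the best validation loss seen
  expect_true(is.finite(bce_loss(scores[va], prep$y[va])))
})

test_that("grid search enumerates, tie-breaks, and matches re-scoring", {
  prep <- separable_data(30, seed = 5)
  adj <- normalize_adjacency(build_knn_graph(prep$X, k = 3))
  # singleton grid returns that config
  gs1 <- grid_search("baseline", prep$X, prep$y, prep$roles, adj,
                     grid = list(learning_rate = list(0.05)),
                     base_train = train_config(epochs = 5L, seed = 1))
  expect_equal(gs1$best_config$learning_rate, 0.05)
  # ties: identical configs -> earlier enumeration order wins
  gs2 <- grid_search("baseline", prep$X, prep$y, prep$roles, adj,
                     grid = list(learning_rate = list(0.05, 0.05)),
                     base_train = train_config(epochs = 5L, seed = 1))
  expect_equal(gs2$leaderboard$point[1], 1L)
  # leaderboard scores equal an independent re-evaluation of each point
  grid <- list(learning_rate = list(0.2, 0.01), epochs = list(3L, 8L))
  gs3 <- grid_search("tabular", prep$X, prep$y, prep$roles, adj, grid = grid,
                     base_train = train_config(seed = 4))
  va <- which(prep$roles == "val")
  pts <- expand.grid(lr = 1:2, ep = 1:2)
  for (i in seq_len(nrow(pts))) {
    tc <- train_config(learning_rate = grid$learning_rate[[pts$lr[i]]],
                       epochs = grid$epochs[[pts$ep[i]]], seed = 4)
    fit <- train_model(build_model("tabular", ncol(prep$X), seed = 4),
                       prep$X, prep$y, prep$roles, tc)
    pred <- predict_labels(model_forward(fit$model, prep$X)$scores)
    ref <- compute_metrics(prep$y[va], pred[va])$accuracy
    expect_equal(gs3$leaderboard$score[gs3$leaderboard$point == i], ref)
  }
  expect_equal(gs3$leaderboard$score[1], max(gs3$leaderboard$score))
})

test_that("compare_models emits the four-family table deterministically", {
  prep <- separable_data(40, seed = 6)
  adj <- normalize_adjacency(build_knn_graph(prep$X, k = 3))
  tc <- train_config(epochs = 10L, seed = 3)
  cmp <- compare_models(prep$X, prep$y, prep$roles, adj, train = tc)
  expect_equal(cmp$table$model, c("fusion", "gnn", "tabular", "baseline"))
  expect_equal(nrow(cmp$table), 4L)
  cmp2 <- compare_models(prep$X, prep$y, prep$roles, adj, train = tc)
  expect_identical(cmp$table, cmp2$table)
  for (fam in cmp$table$model) {
    m <- cmp$metrics[[fam]]
    expect_equal(m$tp + m$tn + m$fp + m$fn, sum(prep$roles == "test"))
  }
})
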