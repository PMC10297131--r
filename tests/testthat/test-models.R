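test_that("parameter init is seeded, bounded, and approximately centred", {
  W1 <- init_params(8, 6, "glorot_uniform", seed = 3)
  W2 <- init_params(8, 6, "glorot_uniform", seed = 3)
  expect_identical(W1, W2)
  expect_false(identical(W1, init_params(8, 6, "glorot_uniform", seed = 4)))
  expect_true(all(abs(W1) <= sqrt(6 / (6 + 8))))
  He <- init_params(5, 10, "he_uniform", seed = 1)
  expect_true(all(abs(He) <= sqrt(6 / 10)))
  # Monte-Carlo mean of a large draw is 0 within 3 standard errors
  big <- init_params(500, 200, "glorot_uniform", seed = 9)
  lim <- sqrt(6 / 700)
  se <- (2 * lim / sqrt(12)) / sqrt(length(big))
  expect_lt(abs(mean(big)), 3 * se)
})

test_that("gcn_layer_forward equals the per-node loop oracle", {
  s <- small_graph_setup(n = 5, d = 3, k = 2)
  Ahat <- as.matrix(s$adj$A)
  set.seed(21)
  W <- matrix(rnorm(6), 2, 3); b <- rnorm(2)
  out <- gcn_layer_forward(s$X, s$adj, W, b, "relu")
  expect_equal(out, oracle_gcn_layer(s$X, Ahat, W, b), tolerance = 1e-6)
  # isolated node with identity weights propagates its own features
  g1 <- structure(list(n_nodes = 1L, edges = matrix(integer(0), 0, 2),
                       weights = numeric(0), knn_k = 0L, metric = "euclidean",
                       epsilon = 1e-8, weight_mode = "unit"),
                  class = "ckd_graph")
  a1 <- normalize_adjacency(g1, "sym")
  H <- matrix(c(2, -3), 1, 2)
  expect_equal(gcn_layer_forward(H, a1, diag(2), c(0, 0), "identity"), H)
  expect_error(gcn_layer_forward(s$X, s$adj, matrix(0, 2, 5), c(0, 0)), "2x5")
})

test_that("gcn_forward stacks layers correctly and is a constant net at zero weights", {
  s <- small_graph_setup(n = 4, d = 3, k = 1)
  m <- gcn_model(s$adj, 3, conv_dims = c(3L, 2L), seed = 2)
  fw <- gcn_forward(m, s$X)
  # independently chain the loop oracle through both layers + head
  Ahat <- as.matrix(s$adj$A)
  H1 <- oracle_gcn_layer(s$X, Ahat, m$params$conv1_W, m$params$conv1_b)
  H2 <- oracle_gcn_layer(H1, Ahat, m$params$conv2_W, m$params$conv2_b)
  z <- as.numeric(H2 %*% t(m$params$out_W)) + m$params$out_b
  expect_equal(fw$embeddings, H2, tolerance = 1e-6)
  expect_equal(fw$scores, 1 / (1 + exp(-z)), tolerance = 1e-6)
  expect_true(all(fw$scores > 0 & fw$scores < 1))
  # zero weights, head bias beta -> every score sigmoid(beta)
  mz <- m
  mz$params <- lapply(mz$params, function(p) p * 0)
  mz$params$out_b <- 0.7
  expect_equal(gcn_forward(mz, s$X)$scores, rep(1 / (1 + exp(-0.7)), 4))
})

test_that("GCN is permutation-equivariant in embeddings and scores", {
  s <- small_graph_setup(n = 6, d = 4, k = 2)
  m <- gcn_model(s$adj, 4, seed = 5)
  fw <- gcn_forward(m, s$X)
  perm <- c(3, 1, 6, 2, 5, 4)
  gp <- build_knn_graph(s$X[perm, ], k = 2)
  mp <- m; mp$adjacency <- normalize_adjacency(gp)
  fp <- gcn_forward(mp, s$X[perm, ])
  expect_equal(fp$embeddings, fw$embeddings[perm, ], tolerance = 1e-9)
  expect_equal(fp$scores, fw$scores[perm], tolerance = 1e-9)
})

test_that("tabular forward matches a hand-computed pass and degenerates to logistic", {
  # 1 hidden layer, 2 features, 2 units, hand-chosen weights
  m <- tabular_model(2, hidden_dims = 2L, seed = 1)
  m$params$hid1_W <- rbind(c(1, -1), c(0.5, 2))
  m$params$hid1_b <- c(0.1, -0.2)
  m$params$out_W <- matrix(c(2, -1), 1, 2)
  m$params$out_b <- 0.3
  X <- rbind(c(1, 2), c(-1, 0.5))
  h11 <- pmax(c(1 * 1 + (-1) * 2 + 0.1, 0.5 * 1 + 2 * 2 + (-0.2)), 0)
  h12 <- pmax(c(1 * (-1) + (-1) * 0.5 + 0.1, 0.5 * (-1) + 2 * 0.5 + (-0.2)), 0)
  z <- c(sum(c(2, -1) * h11), sum(c(2, -1) * h12)) + 0.3
  fw <- tabular_forward(m, X)
  expect_equal(fw$scores, 1 / (1 + exp(-z)), tolerance = 1e-9)
  expect_equal(fw$embeddings, rbind(h11, h12), ignore_attr = TRUE,
               tolerance = 1e-9)
  # zero weights -> constant sigmoid(beta)
  mz <- m; mz$params <- lapply(mz$params, function(p) p * 0)
  mz$params$out_b <- -0.4
  expect_equal(tabular_forward(mz, X)$scores, rep(1 / (1 + exp(0.4)), 2))
  # L = 0 hidden layers reduces to the logistic form == baseline
  m0 <- tabular_model(3, hidden_dims = integer(0), seed = 7)
  bl <- baseline_model(3, seed = 7)
  set.seed(2); X3 <- matrix(rnorm(12), 4, 3)
  expect_equal(tabular_forward(m0, X3)$scores, baseline_forward(bl, X3))
  expect_error(tabular_forward(m, X3), "columns")
})

test_that("baseline forward is sigmoid(Xw + b) by hand computation", {
  m <- baseline_model(2, seed = 1)
  m$params$out_W <- matrix(c(0.5, -2), 1, 2)
  m$params$out_b <- 1
  X <- rbind(c(2, 1), c(0, 3))
  expect_equal(baseline_forward(m, X),
               1 / (1 + exp(-c(0.5 * 2 - 2 * 1 + 1, -2 * 3 + 1))),
               tolerance = 1e-12)
  mz <- baseline_model(2, seed = 1)
  mz$params$out_W[] <- 0; mz$params$out_b <- 0
  expect_equal(baseline_forward(mz, X), c(0.5, 0.5))
})

test_that("fusion forward follows the transform-average-head chain exactly", {
  # scalar instance p = q = p' = 1 with hand-chosen parameters
  X <- matrix(c(1, -1), 2, 1)
  g <- build_knn_graph(X, k = 1)
  adj <- normalize_adjacency(g, "sym")
  m <- fusion_model(adj, 1, conv_dims = 1L, hidden_dims = 1L, p_prime = 1L,
                    seed = 1)
  m$params$g_conv1_W <- matrix(1); m$params$g_conv1_b <- 0.5
  m$params$t_hid1_W <- matrix(2); m$params$t_hid1_b <- 0
  m$params$tg_W <- matrix(1.5); m$params$tg_b <- 0.1
  m$params$tt_W <- matrix(-1); m$params$tt_b <- 1
  m$params$f_W <- matrix(2); m$params$f_b <- -0.3
  Ahat <- as.matrix(adj$A)
  G <- pmax(Ahat %*% X * 1 + 0.5, 0)
  Tm <- pmax(X * 2, 0)
  Gt <- pmax(1.5 * G + 0.1, 0)
  Tt <- pmax(-1 * Tm + 1, 0)
  Favg <- (Gt + Tt) / 2
  z <- 2 * Favg - 0.3
  fw <- fusion_forward(m, X)
  expect_equal(fw$F_avg, Favg, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fw$scores, as.numeric(1 / (1 + exp(-z))), tolerance = 1e-9)
  expect_true(all(fw$scores > 0 & fw$scores < 1))
})

test_that("fusion reduces to the average of equals and to the tabular branch", {
  s <- small_graph_setup(n = 5, d = 3, k = 2)
  m <- fusion_model(s$adj, 3, conv_dims = 2L, hidden_dims = 2L, p_prime = 2L,
                    seed = 4)
  # transforms forced equal => F_avg equals either transform
  m1 <- m
  m1$params$tg_W[] <- 0; m1$params$tg_b <- c(0.3, 0.6)
  m1$params$tt_W[] <- 0; m1$params$tt_b <- c(0.3, 0.6)
  fw <- fusion_forward(m1, s$X)
  expect_equal(fw$F_avg, matrix(c(0.3, 0.6), 5, 2, byrow = TRUE),
               ignore_attr = TRUE)
  # GNN transform zeroed: predictions depend on the tabular branch alone
  m2 <- m
  m2$params$tg_W[] <- 0; m2$params$tg_b[] <- 0
  fw_a <- fusion_forward(m2, s$X)
  m2b <- m2
  m2b$params$g_conv1_W <- m2$params$g_conv1_W + 5  # perturb the dead branch
  fw_b <- fusion_forward(m2b, s$X)
  expect_equal(fw_a$scores, fw_b$scores, tolerance = 1e-12)
})

test_that("checkpoints reload to bit-identical forward outputs", {
  s <- small_graph_setup(n = 6, d = 4, k = 2)
  for (fam in c("gnn", "tabular", "fusion", "baseline")) {
    m <- build_model(fam, 4, s$adj,
                     list(conv_dims = c(3L, 2L), hidden_dims = 2L,
                          p_prime = 2L), seed = 8)
    path <- tempfile(fileext = ".json")
    save_checkpoint(m, path)
    back <- load_checkpoint(path, adjacency = s$adj)
    expect_identical(model_forward(back, s$X)$scores,
                     model_forward(m, s$X)$scores)
  }
})
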