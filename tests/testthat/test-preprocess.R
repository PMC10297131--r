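test_that("complete_cases keeps exactly the unmasked rows, order preserved", {
  ds <- tiny_dataset()  # row 2 has a masked cell
  cc <- complete_cases(ds)
  expect_equal(nrow(cc$X), 2L)
  expect_equal(cc$X[1, ], ds$X[1, ])
  expect_equal(cc$X[2, ], ds$X[3, ])
  full <- impute(ds)
  expect_equal(nrow(complete_cases(full)$X), 3L)
  all_miss <- ckd_dataset(matrix(NA_real_, 2, 24),
                          matrix(TRUE, 2, 24), c(0L, 1L))
  expect_error(complete_cases(all_miss), "median_mode")
})

test_that("median/mode imputation fills missing cells and clears the mask", {
  schema <- ckd_schema()
  ds <- tiny_dataset()
  X <- ds$X; mask <- ds$mask
  X[, "age"] <- c(1, NA, 3); mask[, "age"] <- c(FALSE, TRUE, FALSE)
  X[, "htn"] <- c(1, 1, NA); mask[, "htn"] <- c(FALSE, FALSE, TRUE)
  ds2 <- ckd_dataset(X, mask, ds$y, schema)
  imp <- impute(ds2)
  expect_equal(unname(imp$X[2, "age"]), 2)  # median of {1, 3}
  expect_equal(unname(imp$X[3, "htn"]), 1)  # mode of {1, 1}
  expect_false(any(imp$mask))
  # observed cells untouched
  expect_equal(imp$X[1, "bp"], ds2$X[1, "bp"])
  # no-missing input is the identity
  expect_true(dataset_equal(impute(imp), imp))
  # fully-missing column errors with its name
  mask[, "age"] <- TRUE; X[, "age"] <- NA
  expect_error(impute(ckd_dataset(X, mask, ds$y, schema)), "age")
})

test_that("IQR winsorization clips to hand-computed type-7 bounds", {
  schema <- ckd_schema()
  ds <- impute(tiny_dataset())
  X <- ds$X[rep(1, 5), ]
  X[, "age"] <- c(1, 2, 3, 4, 100)
  ds5 <- ckd_dataset(X, matrix(FALSE, 5, 24), rep(c(0L, 1L), length.out = 5),
                     schema)
  w <- winsorize_outliers(ds5, k = 1.5)
  # type-7 quartiles of (1,2,3,4,100): Q1 = 2, Q3 = 4, IQR = 2
  expect_equal(unname(w$X[, "age"]), c(1, 2, 3, 4, 4 + 1.5 * 2))
  # constant column unchanged; in-bounds column unchanged
  expect_equal(w$X[, "bp"], ds5$X[, "bp"])
  # categorical columns untouched even with extreme codes
  expect_equal(w$X[, "htn"], ds5$X[, "htn"])
})

test_that("minmax maps onto [0,1], constant columns to 0, and state reapplies", {
  ds <- impute(generate_synthetic(synthetic_spec(n_per_class = 20, seed = 6)))
  X <- ds$X; X[, "su"] <- 7  # constant column
  ds <- ckd_dataset(X, ds$mask, ds$y, ds$schema, "synthetic")
  norm <- normalize_features(ds, "minmax")
  expect_true(all(norm$dataset$X >= 0 & norm$dataset$X <= 1))
  expect_true(all(norm$dataset$X[, "su"] == 0))
  again <- apply_normalizer(ds, norm$state)
  expect_identical(again$X, norm$dataset$X)
  # simple column: (0, 5, 10) -> (0, 0.5, 1)
  tri <- impute(tiny_dataset())
  Xt <- tri$X; Xt[, "age"] <- c(0, 5, 10)
  tri <- ckd_dataset(Xt, tri$mask, tri$y, tri$schema, "synthetic")
  expect_equal(unname(normalize_features(tri, "minmax")$dataset$X[, "age"]),
               c(0, 0.5, 1))
  # with a split, statistics come from the training rows only
  prep <- separable_data(30)
  tr <- prep$roles == "train"
  expect_true(all(prep$X[tr, ] >= 0 & prep$X[tr, ] <= 1))
})

test_that("SMOTE synthetic rows are convex combinations of same-class originals", {
  set.seed(20)
  X <- matrix(runif(40 * 3), 40, 3)
  y <- rep(c(0L, 1L), c(30L, 10L))
  out <- smote(X, y, target_total = 80L, k_neighbors = 3L, seed = 5)
  expect_equal(sum(out$y == 0L), 40L)
  expect_equal(sum(out$y == 1L), 40L)
  expect_identical(out$X[1:40, ], X)
  synth <- which(out$synthetic)
  for (s in synth) {
    cls <- out$y[s]
    orig <- X[y == cls, , drop = FALSE]
    found <- FALSE
    for (a in seq_len(nrow(orig))) {
      da <- out$X[s, ] - orig[a, ]
      for (b in seq_len(nrow(orig))) {
        if (b == a) next
        dab <- orig[b, ] - orig[a, ]
        nz <- which(abs(dab) > 1e-12)
        if (!length(nz)) next
        u <- da[nz[1]] / dab[nz[1]]
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(da - u * dab)) < 1e-9) { found <- TRUE; break }
      }
      if (found) break
    }
    expect_true(found, info = paste("row", s, "is not on any same-class segment"))
  }
})

test_that("SMOTE on a 2-point class interpolates the segment exactly", {
  X <- rbind(c(0, 0), c(2, 2), c(10, 0), c(10, 1), c(10, 2), c(11, 0))
  y <- c(1L, 1L, 0L, 0L, 0L, 0L)
  out <- smote(X, y, target_total = 12L, k_neighbors = 5L, seed = 3)
  synth1 <- out$X[out$synthetic & out$y == 1L, , drop = FALSE]
  expect_gt(nrow(synth1), 0)
  u <- synth1[, 1] / 2
  expect_equal(synth1[, 2] / 2, u)   # on the line x = y
  expect_true(all(u >= 0 & u <= 1))  # within the segment
})

test_that("SMOTE determinism, no-op case, and error conditions", {
  set.seed(8)
  X <- matrix(rnorm(20 * 2), 20, 2)
  y <- rep(0:1, 10)
  a <- smote(X, y, 40L, seed = 9)
  b <- smote(X, y, 40L, seed = 9)
  expect_identical(a$X, b$X)
  noop <- smote(X, y, 20L, seed = 1)
  expect_identical(noop$X, X)
  expect_false(any(noop$synthetic))
  expect_error(smote(X, y, 10L), "target_total")
  expect_error(smote(X, y, 41L), "even")
})

test_that("stratified split has exact sizes, disjoint roles, determinism", {
  y <- rep(c(0L, 1L), each = 1000L)
  roles <- split_dataset(y, c(0.7, 0.15, 0.15), seed = 4)
  expect_equal(as.vector(table(roles)), c(1400L, 300L, 300L))
  # stratification: each role is exactly half class-1 here
  for (r in levels(roles))
    expect_equal(mean(y[roles == r]), 0.5)
  expect_identical(roles, split_dataset(y, c(0.7, 0.15, 0.15), seed = 4))
  expect_false(identical(roles, split_dataset(y, c(0.7, 0.15, 0.15), seed = 5)))
  expect_error(split_dataset(rep(0:1, 3)[1:6]), "n >= 10")
  expect_error(split_dataset(c(rep(0L, 99), 1L), c(0.7, 0.15, 0.15)), "class")
})

test_that("default pipeline order reproduces the published protocol", {
  ds <- generate_synthetic(synthetic_spec(n_per_class = 40, missing_rate = 0.02,
                                          seed = 12))
  cfg <- preprocess_config(impute_strategy = "complete_case",
                           smote_target_total = 300L, seed = 2)
  prep <- run_preprocess(ds, cfg)
  expect_equal(nrow(prep$X), 300L)
  expect_equal(sum(prep$y == 0L), 150L)
  expect_equal(sum(prep$y == 1L), 150L)
  expect_equal(length(prep$roles), 300L)
  # leakage-safe order: only training rows are oversampled
  safe <- run_preprocess(ds, preprocess_config(
    impute_strategy = "complete_case", smote_target_total = 300L,
    leakage_safe = TRUE, seed = 2))
  expect_true(all(safe$roles[safe$synthetic] == "train"))
  expect_false(any(safe$synthetic & safe$roles != "train"))
})
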