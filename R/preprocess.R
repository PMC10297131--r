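#' Preprocessing configuration
#'
#' Bundles the cleaning-chain options: imputation strategy, outlier rule,
#' normalization, SMOTE oversampling, and the train/validation/test split.
#' The default order reproduces the published protocol: complete-case
#' filtering, SMOTE to `target_total` records on the whole table, then a
#' stratified split. `leakage_safe = TRUE` switches to the statistically
#' sound order (split first, oversample the training rows only).
#'
#' @param impute_strategy `"median_mode"` (fill numerics with the column
#'   median, categoricals with the modal code) or `"complete_case"` (drop
#'   any row with a missing cell).
#' @param outlier_rule `"none"` or `"iqr_winsorize"`.
#' @param outlier_k IQR multiplier for winsorization.
#' @param normalize `"minmax"`, `"zscore"` or `"none"`.
#' @param smote_enabled logical.
#' @param smote_target_total total record count after oversampling (even).
#' @param smote_k number of same-class neighbours for interpolation.
#' @param split_fractions length-3 positive vector (train, val, test), sums to 1.
#' @param leakage_safe oversample after splitting when `TRUE`.
#' @param seed integer; drives SMOTE and the split shuffle.
#' @return an object of class `ckd_preprocess_config`.
#' @export
preprocess_config <- function(impute_strategy = c("median_mode", "complete_case"),
                              outlier_rule = c("none", "iqr_winsorize"),
                              outlier_k = 1.5,
                              normalize = c("minmax", "zscore", "none"),
                              smote_enabled = TRUE,
                              smote_target_total = 2000L,
                              smote_k = 5L,
                              split_fractions = c(train = 0.7, val = 0.15, test = 0.15),
                              leakage_safe = FALSE,
                              seed = 1L) {
  impute_strategy <- match.arg(impute_strategy)
  outlier_rule <- match.arg(outlier_rule)
  normalize <- match.arg(normalize)
  if (length(split_fractions) != 3L || any(split_fractions <= 0))
    stop("split_fractions must be 3 positive numbers")
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop("split_fractions must sum to 1")
  if (smote_k < 1L) stop("smote_k must be >= 1")
  structure(list(impute_strategy = impute_strategy,
                 outlier_rule = outlier_rule, outlier_k = outlier_k,
                 normalize = normalize, smote_enabled = isTRUE(smote_enabled),
                 smote_target_total = as.integer(smote_target_total),
                 smote_k = as.integer(smote_k),
                 split_fractions = stats::setNames(as.numeric(split_fractions),
                                                  c("train", "val", "test")),
                 leakage_safe = isTRUE(leakage_safe), seed = as.integer(seed)),
            class = "ckd_preprocess_config")
}

#' Keep only complete cases
#'
#' @param ds a [ckd_dataset()].
#' @return the dataset restricted to rows with no missing cell, order kept.
#' @export
complete_cases <- function(ds) {
  keep <- rowSums(ds$mask) == 0L
  if (!any(keep))
    stop("no complete cases remain; use impute_strategy = 'median_mode'")
  dataset_rows(ds, which(keep))
}

#' Impute missing cells
#'
#' Numeric (and ordinal) columns are filled with the column median over
#' observed cells; binary categorical columns with the modal code
#' (ties broken toward the lower code). Observed cells are untouched and
#' the mask is cleared.
#'
#' @param ds a [ckd_dataset()].
#' @param strategy currently `"median_mode"`.
#' @return an imputed [ckd_dataset()] with an all-false mask.
#' @export
impute <- function(ds, strategy = "median_mode") {
  stopifnot(identical(strategy, "median_mode"))
  X <- ds$X
  binary <- schema_binary_features(ds$schema)
  for (f in ds$schema$names) {
    miss <- ds$mask[, f]
    if (!any(miss)) next
    obs <- X[!miss, f]
    if (!length(obs)) stop("column '", f, "' is fully missing; cannot impute")
    fill <- if (f %in% binary) {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])  # which.max takes first = lower code
    } else stats::median(obs)
    X[miss, f] <- fill
  }
  ckd_dataset(X, matrix(FALSE, nrow(X), ncol(X)), ds$y, ds$schema, ds$provenance)
}

#' Winsorize outliers by the IQR rule
#'
#' Per numeric column, observed values outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` are clipped to the nearest bound
#' (quartiles by linear interpolation, quantile type 7). Binary categorical
#' columns and masked cells are untouched.
#'
#' @param ds a [ckd_dataset()].
#' @param k IQR multiplier, default 1.5.
#' @return a winsorized [ckd_dataset()].
#' @export
winsorize_outliers <- function(ds, k = 1.5) {
  X <- ds$X
  binary <- schema_binary_features(ds$schema)
  for (f in setdiff(ds$schema$names, binary)) {
    obs <- which(!ds$mask[, f])
    if (length(obs) < 2L) next
    q <- stats::quantile(X[obs, f], c(0.25, 0.75), type = 7, names = FALSE)
    lo <- q[1] - k * (q[2] - q[1])
    hi <- q[2] + k * (q[2] - q[1])
    X[obs, f] <- pmin(pmax(X[obs, f], lo), hi)
  }
  ckd_dataset(X, ds$mask, ds$y, ds$schema, ds$provenance)
}

#' Normalize features
#'
#' `minmax` maps each column affinely onto \[0, 1\]; `zscore` centres and
#' scales. When a split assignment is supplied the statistics come from the
#' training rows only, and the returned state transforms validation/test
#' rows identically. Constant columns map to 0.
#'
#' @param ds a [ckd_dataset()] with no missing values.
#' @param method `"minmax"`, `"zscore"` or `"none"`.
#' @param split optional [split_dataset()] assignment; statistics then use
#'   the `train` rows.
#' @return list with `dataset` (transformed) and `state` (per-column
#'   statistics, class `ckd_normalizer`).
#' @export
normalize_features <- function(ds, method = c("minmax", "zscore", "none"),
                               split = NULL) {
  method <- match.arg(method)
  if (any(ds$mask)) stop("normalize requires no missing values; impute first")
  fit_rows <- if (is.null(split)) seq_len(nrow(ds$X)) else which(split == "train")
  Xf <- ds$X[fit_rows, , drop = FALSE]
  state <- structure(list(method = method,
                          center = apply(Xf, 2, min),
                          scale = apply(Xf, 2, max) - apply(Xf, 2, min)),
                     class = "ckd_normalizer")
  if (method == "zscore") {
    state$center <- colMeans(Xf)
    state$scale <- apply(Xf, 2, stats::sd)
  }
  if (method == "none") {
    state$center <- rep(0, ncol(Xf)); state$scale <- rep(1, ncol(Xf))
  }
  list(dataset = apply_normalizer(ds, state), state = state)
}

#' Apply a fitted normalizer
#' @param ds a [ckd_dataset()] with no missing values.
#' @param state a `ckd_normalizer` from [normalize_features()].
#' @return the transformed [ckd_dataset()].
#' @export
apply_normalizer <- function(ds, state) {
  sc <- ifelse(state$scale == 0 | !is.finite(state$scale), 1, state$scale)
  X <- sweep(sweep(ds$X, 2, state$center, "-"), 2, sc, "/")
  X[, state$scale == 0] <- 0  # constant fitted column -> 0
  ckd_dataset(X, ds$mask, ds$y, ds$schema, ds$provenance)
}

#' SMOTE oversampling, from scratch
#'
#' Brings both classes up to `target_total / 2` rows. Each synthetic point
#' is built by choosing a random row x of an undersized class, one of its
#' `k_neighbors` nearest same-class neighbours x' (Euclidean distance),
#' and emitting `x + u * (x' - x)` with `u ~ Uniform(0, 1)` — a point on
#' the line segment joining the two. Original rows are retained; synthetic
#' rows copy their class label. When a class has fewer than `k_neighbors + 1`
#' members, k is reduced to class size - 1.
#'
#' @param X numeric matrix (no missing values; normalize first so Euclidean
#'   distance is not dominated by large-scale features).
#' @param y 0/1 label vector.
#' @param target_total even total row count after oversampling, >= nrow(X).
#' @param k_neighbors neighbour count, default 5.
#' @param seed RNG seed.
#' @return list with `X` (original rows first, then synthetic), `y`, and
#'   `synthetic` (logical marker per row).
#' @export
smote <- function(X, y, target_total, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  target_total <- as.integer(target_total)
  if (target_total < n) stop("target_total (", target_total,
                             ") must be >= current n (", n, ")")
  if (target_total %% 2L != 0L) stop("target_total must be even")
  half <- target_total %/% 2L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  newX <- list(); newy <- integer(0)
  for (cl in c(0L, 1L)) {
    rows <- which(y == cl)
    need <- half - length(rows)
    if (need <= 0L) next
    if (length(rows) < 2L)
      stop("class ", cl, " has fewer than 2 members; cannot interpolate")
    k <- min(k_neighbors, length(rows) - 1L)
    Xc <- X[rows, , drop = FALSE]
    D <- as.matrix(stats::dist(Xc))
    diag(D) <- Inf
    nn <- apply(D, 1, function(r) order(r)[seq_len(k)])  # k x nc
    nn <- matrix(nn, nrow = k)
    seeds <- sample.int(length(rows), need, replace = TRUE)
    picks <- nn[cbind(sample.int(k, need, replace = TRUE), seeds)]
    u <- stats::runif(need)
    synth <- Xc[seeds, , drop = FALSE] +
      u * (Xc[picks, , drop = FALSE] - Xc[seeds, , drop = FALSE])
    newX[[length(newX) + 1L]] <- synth
    newy <- c(newy, rep(cl, need))
  }
  Xout <- rbind(X, do.call(rbind, newX))
  rownames(Xout) <- NULL
  list(X = Xout, y = c(y, newy),
       synthetic = c(rep(FALSE, n), rep(TRUE, length(newy))))
}

#' Stratified train/validation/test split
#'
#' Shuffles each class separately (seeded) and allocates by the rounded
#' cumulative fractions, so role sizes are exact whenever the fractions
#' divide the class counts and each role's class ratio is within one sample
#' of the global ratio.
#'
#' @param y 0/1 label vector.
#' @param fractions length-3 positive vector (train, val, test) summing to 1.
#' @param seed RNG seed.
#' @return factor of length n with levels `train`, `val`, `test`.
#' @export
split_dataset <- function(y, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  y <- as.integer(y)
  n <- length(y)
  if (n < 10L) stop("split requires n >= 10")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  roles <- character(n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cl in sort(unique(y))) {
    rows <- which(y == cl)
    rows <- rows[sample.int(length(rows))]
    cuts <- round(cumsum(c(0, fractions)) * length(rows))
    sizes <- diff(cuts)
    if (any(sizes == 0L))
      stop("class ", cl, " would be absent from a role at these fractions")
    roles[rows] <- rep(c("train", "val", "test"), times = sizes)
  }
  factor(roles, levels = c("train", "val", "test"))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: missing-value handling (imputation or complete-case
#' filtering), optional IQR winsorization, normalization, SMOTE, and the
#' stratified split. Default order oversamples before splitting (the
#' published protocol); with `leakage_safe = TRUE` the split happens first,
#' normalization statistics come from the training rows, and only training
#' rows are oversampled (to `target_total * train_fraction`, rounded even).
#'
#' @param ds a raw [ckd_dataset()].
#' @param config a [preprocess_config()].
#' @return list with `X` (processed numeric matrix), `y`, `roles` (factor),
#'   `normalizer`, `synthetic` (logical SMOTE marker), and `config`.
#' @export
run_preprocess <- function(ds, config = preprocess_config()) {
  ds <- if (config$impute_strategy == "complete_case") complete_cases(ds)
        else impute(ds)
  if (config$outlier_rule == "iqr_winsorize")
    ds <- winsorize_outliers(ds, config$outlier_k)

  if (!config$leakage_safe) {
    norm <- normalize_features(ds, config$normalize)
    X <- norm$dataset$X; y <- ds$y
    synth <- rep(FALSE, nrow(X))
    if (config$smote_enabled) {
      sm <- smote(X, y, config$smote_target_total, config$smote_k, config$seed)
      X <- sm$X; y <- sm$y; synth <- sm$synthetic
    }
    roles <- split_dataset(y, config$split_fractions, config$seed)
  } else {
    roles0 <- split_dataset(ds$y, config$split_fractions, config$seed)
    norm <- normalize_features(ds, config$normalize, split = roles0)
    X <- norm$dataset$X; y <- ds$y
    synth <- rep(FALSE, nrow(X))
    roles <- as.character(roles0)
    if (config$smote_enabled) {
      tr <- which(roles0 == "train")
      target_train <- 2L * floor(config$smote_target_total *
                                   config$split_fractions[["train"]] / 2)
      target_train <- max(target_train, 2L * ceiling(length(tr) / 2))
      sm <- smote(X[tr, , drop = FALSE], y[tr], target_train,
                  config$smote_k, config$seed)
      added <- sum(sm$synthetic)
      X <- rbind(X, sm$X[sm$synthetic, , drop = FALSE])
      y <- c(y, sm$y[sm$synthetic])
      synth <- c(synth, rep(TRUE, added))
      roles <- c(roles, rep("train", added))
    }
    roles <- factor(roles, levels = c("train", "val", "test"))
  }
  list(X = X, y = y, roles = roles, normalizer = norm$state,
       synthetic = synth, config = config)
}
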