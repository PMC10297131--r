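#' Pairwise distances between patient feature vectors
#'
#' @param X numeric matrix, one row per patient; no missing values.
#' @param metric `"euclidean"`, `"manhattan"`, or `"cosine"` (cosine
#'   distance, 1 minus the cosine similarity).
#' @return symmetric n x n matrix with a zero diagonal.
#' @export
pairwise_distance <- function(X, metric = c("euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  D <- switch(metric,
    euclidean = as.matrix(stats::dist(X, method = "euclidean")),
    manhattan = as.matrix(stats::dist(X, method = "manhattan")),
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      if (any(nrm == 0))
        stop("cosine distance undefined for zero-norm row ", which(nrm == 0)[1])
      S <- (X %*% t(X)) / outer(nrm, nrm)
      1 - pmin(pmax(S, -1), 1)
    })
  dimnames(D) <- NULL
  diag(D) <- 0
  D
}

#' Build the weighted k-nearest-neighbour patient-similarity graph
#'
#' Each patient is linked to its k nearest neighbours (self excluded) under
#' the chosen distance; the directed relation is symmetrized by union into
#' undirected edges. With `weight_mode = "inverse_distance"` an edge (i, j)
#' carries weight `1 / (d(i, j) + epsilon)`, so duplicate rows (distance 0)
#' get the maximal finite weight `1/epsilon`.
#'
#' @param X numeric feature matrix (n rows, n > k).
#' @param k neighbours per node, `1 <= k < n`.
#' @param metric distance metric, see [pairwise_distance()].
#' @param epsilon small positive stabilizer for inverse-distance weights.
#' @param weight_mode `"inverse_distance"` or `"unit"`.
#' @return an object of class `ckd_graph`: list with `n_nodes`, `edges`
#'   (m x 2 integer matrix, i < j, ordered lexicographically), `weights`
#'   (length m, positive finite), `knn_k`, `metric`, `epsilon`,
#'   `weight_mode`.
#' @export
build_knn_graph <- function(X, k = 5L, metric = "euclidean",
                            epsilon = 1e-8, weight_mode = c("inverse_distance", "unit")) {
  weight_mode <- match.arg(weight_mode)
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("need n > k >= 1 (n = ", n, ", k = ", k, ")")
  if (epsilon <= 0) stop("epsilon must be positive")
  D <- pairwise_distance(X, metric)
  # directed k-NN per row: k smallest distances excluding self,
  # ties broken by node index (order() is stable on the index sequence)
  pairs <- matrix(0L, n * k, 2L)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    pairs[(i - 1L) * k + seq_len(k), ] <- cbind(i, nb)
  }
  und <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  und <- unique(und)
  und <- und[order(und[, 1], und[, 2]), , drop = FALSE]
  w <- if (weight_mode == "unit") rep(1, nrow(und))
       else 1 / (D[und] + epsilon)
  structure(list(n_nodes = n, edges = und, weights = w, knn_k = k,
                 metric = metric, epsilon = epsilon, weight_mode = weight_mode),
            class = "ckd_graph")
}

#' @export
print.ckd_graph <- function(x, ...) {
  cat(sprintf("<ckd_graph> %d nodes, %d undirected edges (k = %d, %s)\n",
              x$n_nodes, nrow(x$edges), x$knn_k, x$metric))
  invisible(x)
}

#' Normalized adjacency operator for graph convolution
#'
#' Adds a self-loop of weight 1 to every node, then normalizes: the `sym`
#' scheme gives coefficients `a_ij / sqrt(d_i d_j)` (the canonical
#' spectral-convolution operator, symmetric and well-conditioned); the
#' `row` scheme gives `a_ij / d_i` (each row sums to 1). Degrees include
#' the self-loop. With `use_weights = FALSE` the edge weights are replaced
#' by unit connectivity.
#'
#' @param g a `ckd_graph` from [build_knn_graph()].
#' @param scheme `"sym"` or `"row"`.
#' @param use_weights use the inverse-distance weights (default) or plain
#'   connectivity.
#' @return an object of class `ckd_adjacency`: list with `n_nodes`, `A`
#'   (a `dgCMatrix` sparse operator), and `scheme`.
#' @export
normalize_adjacency <- function(g, scheme = c("sym", "row"), use_weights = TRUE) {
  scheme <- match.arg(scheme)
  n <- g$n_nodes
  w <- if (use_weights) g$weights else rep(1, nrow(g$edges))
  i <- c(g$edges[, 1], g$edges[, 2], seq_len(n))
  j <- c(g$edges[, 2], g$edges[, 1], seq_len(n))
  x <- c(w, w, rep(1, n))  # self-loop weight 1 regardless of weight mode
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  A <- if (scheme == "sym") {
    s <- 1 / sqrt(deg)
    Matrix::Diagonal(n, s) %*% A %*% Matrix::Diagonal(n, s)
  } else {
    Matrix::Diagonal(n, 1 / deg) %*% A
  }
  structure(list(n_nodes = n, A = methods::as(A, "CsparseMatrix"),
                 scheme = scheme),
            class = "ckd_adjacency")
}

#' Serialize / load a patient graph
#'
#' Writes a weighted edge list `i<TAB>j<TAB>w` (0-based ids, one undirected
#' edge per line, i < j) preceded by a one-line JSON header carrying
#' `n_nodes`, `k`, `metric`, `epsilon`, and `weight_mode`. [read_graph()]
#' restores the object bit-exactly.
#'
#' @param g a `ckd_graph`.
#' @param path output path.
#' @export
write_graph <- function(g, path) {
  header <- jsonlite::toJSON(list(n_nodes = g$n_nodes, k = g$knn_k,
                                  metric = g$metric, epsilon = g$epsilon,
                                  weight_mode = g$weight_mode),
                             auto_unbox = TRUE, digits = NA)
  body <- sprintf("%d\t%d\t%s", g$edges[, 1] - 1L, g$edges[, 2] - 1L,
                  vapply(g$weights, num_to_str, character(1)))
  writeLines(c(paste0("#", header), body), path)
  invisible(NULL)
}

#' @rdname write_graph
#' @param path path written by [write_graph()].
#' @return the restored `ckd_graph`.
#' @export
read_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[[1]]))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  M <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  structure(list(n_nodes = as.integer(hdr$n_nodes),
                 edges = cbind(as.integer(M[, 1]) + 1L, as.integer(M[, 2]) + 1L),
                 weights = as.numeric(M[, 3]),
                 knn_k = as.integer(hdr$k), metric = hdr$metric,
                 epsilon = hdr$epsilon, weight_mode = hdr$weight_mode),
            class = "ckd_graph")
}
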