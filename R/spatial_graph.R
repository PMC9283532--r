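# Spatial neighbor graphs: kNN and the 1-skeleton of the alpha complex.
# Adjacency matrices are binary, symmetric, zero-diagonal dgCMatrix.

euclid_dist <- function(coords) {
  as.matrix(stats::dist(coords))
}

#' Build a k-nearest-neighbour spatial graph
#'
#' Computes the directed Euclidean kNN relation and symmetrizes it by union:
#' an edge is kept when i is among the k nearest neighbours of j or vice
#' versa. Distance ties are broken by point index.
#'
#' @param coords N x d coordinate matrix (d = 2 or 3).
#' @param k number of nearest neighbours, `1 <= k < N`.
#' @return N x N binary symmetric sparse adjacency with zero diagonal.
#' @export
build_knn_graph <- function(coords, k = 15L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points")
  if (k >= n) stop("k (", k, ") must be smaller than the number of points (",
                   n, ")")
  D <- euclid_dist(coords)
  nn <- knn_indices(D, k)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn))
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(n, n), use.last.ij = FALSE)
  A <- methods::as(A > 0, "dMatrix")
  Matrix::diag(A) <- 0
  methods::as(Matrix::drop0(A), "CsparseMatrix")
}

# k nearest neighbour indices per row of a distance matrix, self excluded,
# ties by index
knn_indices <- function(D, k) {
  n <- nrow(D)
  res <- vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Estimate the alpha-complex radius from kNN distances
#'
#' A single global radius: the mean, over all spots, of each spot's mean
#' Euclidean distance to its k nearest neighbours.
#'
#' @inheritParams build_knn_graph
#' @return Positive scalar radius.
#' @export
estimate_delta <- function(coords, k = 15L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= k) stop("need more than k = ", k, " points, got ", n)
  D <- euclid_dist(coords)
  nn <- knn_indices(D, k)
  per_spot <- vapply(seq_len(n), function(i) mean(D[i, nn[i, ]]), numeric(1))
  mean(per_spot)
}

#' Build the alpha-complex spatial graph
#'
#' Two cells are connected when their Voronoi cells, each intersected with the
#' closed ball of radius `delta` around its site, share at least one point —
#' the 1-skeleton of the alpha complex at radius `delta`. The test is solved
#' exactly per candidate pair: points common to both Voronoi cells lie on the
#' pair's perpendicular bisector, where every other site contributes one
#' linear inequality; the feasible parameter interval and the minimal distance
#' to the sites on it are available in closed form.
#'
#' Only 2-D coordinates are supported; degenerate inputs where every point
#' coincides fall back to a kNN graph with a warning. Coincident point pairs
#' are connected for any positive radius (they share a Voronoi cell).
#'
#' @param coords N x 2 coordinate matrix.
#' @param delta positive alpha radius, e.g. from [estimate_delta].
#' @param k_fallback neighbourhood size for the kNN fallback on fully
#'   degenerate input.
#' @return N x N binary symmetric sparse adjacency with zero diagonal.
#' @export
build_alpha_graph <- function(coords, delta, k_fallback = 15L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points")
  if (ncol(coords) != 2L)
    stop("alpha-complex graph requires 2-D coordinates; use the knn method ",
         "for ", ncol(coords), "-D data")
  stopifnot(delta > 0)
  # degenerate: a single distinct location
  if (all(coords[, 1] == coords[1, 1]) && all(coords[, 2] == coords[1, 2])) {
    warning("all points coincide; falling back to kNN graph")
    return(build_knn_graph(coords, min(k_fallback, n - 1L)))
  }
  coords <- sweep(coords, 2, colMeans(coords))  # improve conditioning
  scale2 <- max(1, max(abs(coords))^2)
  eps <- 1e-9 * scale2
  D <- euclid_dist(coords)
  cand <- which(upper.tri(D) & D <= 2 * delta, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  keep <- logical(nrow(cand))
  norms2 <- rowSums(coords^2)
  for (p in seq_len(nrow(cand))) {
    i <- cand[p, 1]; j <- cand[p, 2]
    d <- D[i, j]
    if (d == 0) { keep[p] <- TRUE; next }
    pi_ <- coords[i, ]; pj <- coords[j, ]
    m <- (pi_ + pj) / 2
    dir <- (pj - pi_) / d
    u <- c(-dir[2], dir[1])
    others <- setdiff(seq_len(n), c(i, j))
    K <- coords[others, , drop = FALSE]
    a <- 2 * as.vector(K %*% u - sum(pi_ * u))
    b <- 2 * as.vector(K %*% m) - 2 * sum(pi_ * m) + norms2[i] - norms2[others]
    # feasibility of a*t + b <= 0 for all constraints
    zero_a <- abs(a) < 1e-12 * sqrt(scale2)
    if (any(zero_a & (b > eps))) next
    pos <- a > 0 & !zero_a
    neg <- a < 0 & !zero_a
    hi <- if (any(pos)) min(-b[pos] / a[pos]) else Inf
    lo <- if (any(neg)) max(-b[neg] / a[neg]) else -Inf
    tol_t <- 1e-9 * max(1, sqrt(scale2))
    if (lo > hi + tol_t) next
    if (lo > hi) { lo <- hi <- (lo + hi) / 2 }
    tstar <- min(max(0, lo), hi)
    dist2 <- (d / 2)^2 + tstar^2
    keep[p] <- dist2 <= delta^2 * (1 + 1e-9) + 1e-12
  }
  cand <- cand[keep, , drop = FALSE]
  A <- Matrix::sparseMatrix(i = c(cand[, 1], cand[, 2]),
                            j = c(cand[, 2], cand[, 1]),
                            x = 1, dims = c(n, n))
  A <- methods::as(A > 0, "dMatrix")
  Matrix::diag(A) <- 0
  methods::as(Matrix::drop0(A), "CsparseMatrix")
}

#' Assemble a spatial expression graph
#'
#' Attaches node features to a spatial adjacency built from the coordinates,
#' by default the alpha-complex graph with radius estimated from kNN
#' distances. 3-D coordinates (or degenerate 2-D input) fall back to the kNN
#' builder with a warning.
#'
#' @param features an `sf_features` object from [preprocess_st]/[select_hvg],
#'   or a bare cells x g numeric matrix.
#' @param coords N x d coordinate matrix.
#' @param method `"alpha"` (default) or `"knn"`.
#' @param k neighbourhood size for the kNN method and the radius estimate.
#' @param delta alpha radius; estimated via [estimate_delta] when `NULL`.
#' @return An object of class `seg`: list with `X`, `A`, `coords`, `edges`
#'   (2-column matrix of 1-based unordered pairs), `method`, `delta`, `k`.
#' @export
build_seg <- function(features, coords, method = c("alpha", "knn"), k = 15L,
                      delta = NULL) {
  method <- match.arg(method)
  X <- if (inherits(features, "sf_features")) features$X else as.matrix(features)
  coords <- as.matrix(coords)
  if (nrow(X) != nrow(coords))
    stop("features and coords disagree on the number of cells")
  if (method == "alpha" && ncol(coords) != 2L) {
    warning("alpha-complex graph is 2-D only; falling back to kNN")
    method <- "knn"
  }
  if (method == "alpha") {
    if (is.null(delta)) delta <- estimate_delta(coords, k)
    A <- build_alpha_graph(coords, delta, k_fallback = k)
  } else {
    delta <- NA_real_
    A <- build_knn_graph(coords, k)
  }
  structure(list(X = X, A = A, coords = coords,
                 edges = adjacency_to_edges(A), method = method,
                 delta = delta, k = as.integer(k)),
            class = "seg")
}

#' @export
print.seg <- function(x, ...) {
  cat("spatial expression graph: ", nrow(x$X), " nodes, ", nrow(x$edges),
      " edges (", x$method, if (x$method == "alpha")
        sprintf(", delta = %.4g", x$delta) else sprintf(", k = %d", x$k),
      ")\n", sep = "")
  invisible(x)
}

adjacency_to_edges <- function(A) {
  idx <- Matrix::which(A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Permute node features (corrupted negative sample)
#'
#' Builds the contrastive negative graph: node features are randomly
#' row-permuted while the adjacency stays identical.
#'
#' @param seg a `seg` object from [build_seg].
#' @param seed integer seed for the permutation; when `NULL`, the current RNG
#'   stream is used (and left advanced).
#' @return An object of class `permuted_graph`: list with `X_tilde`, `A`,
#'   `permutation`, `seed`.
#' @export
permute_features <- function(seg, seed = NULL) {
  n <- nrow(seg$X)
  if (!is.null(seed)) {
    perm <- with_seed(seed, sample.int(n))
  } else {
    perm <- sample.int(n)
  }
  structure(list(X_tilde = seg$X[perm, , drop = FALSE], A = seg$A,
                 permutation = perm, seed = seed),
            class = "permuted_graph")
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read an edge list as 2-column TSV of 0-based node indices
#'
#' @param edges 2-column matrix of 1-based indices (as in `seg$edges`).
#' @param path output TSV path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges - 1L, path, sep = "\t", row.names = FALSE,
                     col.names = c("i", "j"), quote = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @param n_nodes number of nodes for the reconstructed adjacency.
#' @return `read_edges` returns the symmetric sparse adjacency.
#' @export
read_edges <- function(path, n_nodes) {
  e <- utils::read.table(path, header = TRUE, sep = "\t") + 1L
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]), x = 1,
                       dims = c(n_nodes, n_nodes))
}
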