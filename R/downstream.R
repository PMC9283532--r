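# Downstream analyses on the learned embedding: Leiden domain segmentation,
# diffusion-pseudotime pseudo-spatiotemporal map, marker genes, ARI.

# union-symmetrized kNN adjacency on rows of a matrix
embedding_knn <- function(H, n_neighbors) {
  D <- euclid_dist(H)
  n <- nrow(D)
  if (n <= n_neighbors)
    stop("need more than n_neighbors = ", n_neighbors, " cells, got ", n)
  nn <- knn_indices(D, n_neighbors)
  ii <- rep(seq_len(n), each = n_neighbors)
  jj <- as.vector(t(nn))
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(n, n))
  A <- methods::as(A > 0, "dMatrix")
  Matrix::diag(A) <- 0
  list(A = methods::as(Matrix::drop0(A), "CsparseMatrix"), D = D, nn = nn)
}

#' Segment spatial domains by Leiden clustering of the embedding
#'
#' Builds a union-symmetrized Euclidean kNN graph on the embedding rows and
#' runs Leiden community detection (modularity objective). When `target_k` is
#' given, the resolution is bisection-searched in `[1e-3, 10]` until the
#' cluster count equals `target_k` (at most 40 iterations), mirroring
#' benchmarking protocols that fix the number of annotated domains.
#'
#' @param H cells x latent embedding matrix (or a fitted model accepted by
#'   [fitted]).
#' @param n_neighbors local neighbourhood size of the cluster graph (a larger
#'   value gives smoother segmentations).
#' @param resolution Leiden resolution when `target_k` is `NULL`.
#' @param target_k optional required number of clusters.
#' @param seed seed for the (stochastic) Leiden refinement.
#' @return Integer vector of domain labels `0 .. K-1`, relabeled by
#'   decreasing cluster size.
#' @export
segment_domains <- function(H, n_neighbors = 50L, resolution = 1.0,
                            target_k = NULL, seed = 0L) {
  H <- as.matrix(H)
  A <- embedding_knn(H, n_neighbors)$A
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  leiden_at <- function(res) {
    memb <- with_seed(seed,
      igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity", resolution = res,
        n_iterations = 5L)))
    as.integer(memb)
  }
  if (is.null(target_k)) {
    memb <- leiden_at(resolution)
  } else {
    lo <- 1e-3; hi <- 10
    m_lo <- leiden_at(lo); m_hi <- leiden_at(hi)
    k_lo <- length(unique(m_lo)); k_hi <- length(unique(m_hi))
    if (k_lo == target_k) memb <- m_lo
    else if (k_hi == target_k) memb <- m_hi
    else if (target_k < k_lo || target_k > k_hi)
      stop("target_k = ", target_k, " unreachable: resolution ", lo,
           " gives ", k_lo, " clusters, resolution ", hi, " gives ", k_hi)
    else {
      memb <- NULL
      for (it in seq_len(40L)) {
        mid <- (lo + hi) / 2
        m_mid <- leiden_at(mid)
        k_mid <- length(unique(m_mid))
        if (k_mid == target_k) { memb <- m_mid; break }
        if (k_mid < target_k) { lo <- mid; k_lo <- k_mid }
        else { hi <- mid; k_hi <- k_mid }
      }
      if (is.null(memb))
        stop("target_k = ", target_k, " unreachable after bisection: ",
             "resolution ", lo, " gives ", k_lo, " clusters, resolution ",
             hi, " gives ", k_hi)
    }
  }
  relabel_by_size(memb)
}

# relabel community ids as 0..K-1 by decreasing size, ties by first occurrence
relabel_by_size <- function(memb) {
  ids <- unique(memb)
  sizes <- vapply(ids, function(id) sum(memb == id), integer(1))
  ord <- ids[order(-sizes, match(ids, memb))]
  as.integer(match(memb, ord) - 1L)
}

#' Choose the pseudotime root cell
#'
#' The cell with the largest summed Euclidean distance to all other cells in
#' embedding space; ties are broken by the lowest index.
#'
#' @param H cells x latent embedding matrix.
#' @return 1-based row index of the root cell.
#' @export
select_root <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) == 1L) return(1L)
  sums <- colSums(euclid_dist(H))
  as.integer(which.max(sums))
}

#' Pseudo-spatiotemporal map via diffusion pseudotime
#'
#' Diffusion pseudotime on the union-symmetrized kNN graph of the embedding:
#' an adaptive Gaussian kernel (per-cell bandwidth = distance to the
#' `ceiling(n_neighbors/2)`-th neighbour), the symmetrized diffusion
#' operator's spectral decomposition, and the diffusion distance to the root
#' over the leading non-trivial components weighted by
#' `lambda / (1 - lambda)`. The result is shifted so the root maps to 0 and
#' scaled to maximum 1 (constant embeddings give all zeros). If the kNN graph
#' is disconnected, pseudotime is computed within the root's component and
#' unreachable cells are assigned 1, with a warning.
#'
#' @param H cells x latent embedding matrix.
#' @param root 1-based root index; defaults to [select_root].
#' @param n_neighbors kNN graph neighbourhood size.
#' @param n_comps number of non-trivial diffusion components used.
#' @return Numeric vector of pseudo-spatiotemporal values in `[0, 1]`.
#' @export
compute_psm <- function(H, root = NULL, n_neighbors = 50L, n_comps = 10L) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (is.null(root)) root <- select_root(H)
  stopifnot(root >= 1L, root <= n)
  kn <- embedding_knn(H, n_neighbors)
  if (max(kn$D) == 0) return(numeric(n))  # constant embeddings

  g <- igraph::graph_from_adjacency_matrix(kn$A, mode = "undirected")
  comp <- igraph::components(g)$membership
  in_comp <- comp == comp[root]
  if (!all(in_comp))
    warning("embedding kNN graph is disconnected; ",
            sum(!in_comp), " unreachable cells assigned psm = 1")

  idx <- which(in_comp)
  Dc <- kn$D[idx, idx, drop = FALSE]
  Ac <- kn$A[idx, idx, drop = FALSE]
  m <- length(idx)
  k_sig <- min(as.integer(ceiling(n_neighbors / 2)), m - 1L)
  sigma <- vapply(seq_len(m), function(i) {
    sort(Dc[i, -i], partial = k_sig)[k_sig]
  }, numeric(1))
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1)
  W <- as.matrix(Ac) * exp(-Dc^2 / outer(sigma, sigma))
  deg <- rowSums(W)
  dis <- 1 / sqrt(deg)
  S <- W * outer(dis, dis)
  eig <- eigen(S, symmetric = TRUE)
  ncomp_use <- min(n_comps, m - 1L)
  lam <- pmin(eig$values[seq_len(ncomp_use) + 1L], 1 - 1e-10)
  psi <- eig$vectors[, seq_len(ncomp_use) + 1L, drop = FALSE] * dis
  wts <- lam / (1 - lam)
  rloc <- match(root, idx)
  diffs <- sweep(psi, 2, psi[rloc, ])
  dpt <- sqrt(rowSums(sweep(diffs, 2, wts, `*`)^2))

  psm <- rep(1, n)
  mx <- max(dpt)
  psm[idx] <- if (mx > 0) dpt / mx else 0
  psm[root] <- 0
  psm
}

#' Rank marker genes per domain
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene and domain (normal
#' approximation with tie correction), with Benjamini-Hochberg adjustment
#' across genes within each domain. Domains with fewer than 2 cells are
#' skipped with a warning.
#'
#' @param expr cells x genes matrix of (log-normalized) expression.
#' @param labels per-cell domain labels.
#' @param alpha adjusted-p significance cutoff for the `significant` flag.
#' @return A data.frame of class `marker_table` with columns `domain`,
#'   `gene`, `direction` (+1 up in domain, -1 down), `mean_diff`, `p`,
#'   `adj_p`, `significant`, sorted by adjusted p within domain.
#' @export
rank_markers <- function(expr, labels, alpha = 0.01) {
  expr <- as.matrix(expr)
  n <- nrow(expr)
  stopifnot(length(labels) == n)
  genes <- colnames(expr) %||% as.character(seq_len(ncol(expr)))
  doms <- sort(unique(labels))
  if (length(doms) < 2L) stop("need at least 2 domains")

  R <- apply(expr, 2, rank)
  tie_term <- apply(expr, 2, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })

  out <- list()
  for (d in doms) {
    members <- labels == d
    nA <- sum(members); nB <- n - nA
    if (nA < 2L) {
      warning("domain ", d, " has fewer than 2 cells; skipped")
      next
    }
    W <- colSums(R[members, , drop = FALSE])
    mu <- nA * (n + 1) / 2
    v <- nA * nB / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- ifelse(v > 0, (W - mu) / sqrt(v), 0)
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    adj <- stats::p.adjust(p, method = "BH")
    mean_in <- colMeans(expr[members, , drop = FALSE])
    mean_out <- colMeans(expr[!members, , drop = FALSE])
    df <- data.frame(domain = d, gene = genes,
                     direction = ifelse(z >= 0, 1L, -1L),
                     mean_diff = mean_in - mean_out, p = p, adj_p = adj,
                     significant = adj < alpha)
    out[[length(out) + 1L]] <- df[order(df$adj_p, df$p), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table: 1 for identical partitions (up to relabeling), expectation 0 under
#' independent labelings.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 2L)
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (maximum - expected)
}
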