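#' Filter genes and cells from a raw count matrix
#'
#' Removes lowly detected genes, then sparsely covered cells, in a single
#' pass: first the genes with a strictly positive count in fewer than
#' `min_cells_per_gene` cells (computed on the input matrix), then the cells
#' that express fewer than `min_genes_per_cell` of the surviving genes. The
#' procedure is not iterated to a fixed point.
#'
#' @param data an [st_dataset].
#' @param min_cells_per_gene keep genes detected in at least this many cells.
#' @param min_genes_per_cell keep cells expressing at least this many of the
#'   kept genes.
#' @return The filtered [st_dataset] (coords and ids subset consistently).
#' @export
filter_counts <- function(data, min_cells_per_gene = 3L,
                          min_genes_per_cell = 100L) {
  counts <- data$counts
  cells_per_gene <- Matrix::colSums(counts > 0)
  keep_genes <- which(cells_per_gene >= min_cells_per_gene)
  if (length(keep_genes) == 0L)
    stop("empty after filtering: all ", ncol(counts), " genes removed (",
         nrow(counts), " cells untouched)")
  genes_per_cell <- Matrix::rowSums(counts[, keep_genes, drop = FALSE] > 0)
  keep_cells <- which(genes_per_cell >= min_genes_per_cell)
  if (length(keep_cells) == 0L)
    stop("empty after filtering: all ", nrow(counts), " cells removed (",
         ncol(counts) - length(keep_genes), " of ", ncol(counts),
         " genes removed first)")
  subset_st(data, keep_cells, keep_genes)
}

#' Total-count normalize and log-transform
#'
#' Scales every cell to the same total count (`scale_factor`, default 10000)
#' and applies `log(1 + x)`. Entry (i,j) of the result is
#' `log(1 + scale_factor * c_ij / sum_j c_ij)`.
#'
#' @param data an [st_dataset] (or bare counts matrix).
#' @param scale_factor common post-normalization total per cell.
#' @return Sparse cells x genes matrix of log-normalized expression, with the
#'   scale factor attached as attribute `scale_factor`.
#' @export
normalize_log <- function(data, scale_factor = 1e4) {
  counts <- if (inherits(data, "st_dataset")) data$counts else as_dgc(data)
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stop("zero-count cell at row ", which(totals == 0)[1])
  norm <- Matrix::Diagonal(x = scale_factor / totals) %*% counts
  out <- norm
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Select highly variable genes by binned dispersion
#'
#' Per gene the mean `mu` and dispersion `variance / mu` (0 when `mu` is 0)
#' are computed on the supplied (log-normalized) matrix. Genes are assigned to
#' `n_bins` equal-frequency bins of their mean, and the normalized dispersion
#' is the absolute deviation of a gene's dispersion from its bin median,
#' divided by the bin's median absolute deviation (falling back to the bin
#' standard deviation when the MAD is 0, and to 0 when both are). The `n_top`
#' genes with the largest normalized dispersion are returned in their original
#' column order; boundary ties are broken by original gene index.
#'
#' @param expr cells x genes matrix of log-normalized expression.
#' @param n_top number of genes to keep (all genes when `n_top >= n_genes`).
#' @param n_bins number of equal-frequency mean-expression bins.
#' @return A list of class `sf_features`: `X` (cells x g matrix restricted to
#'   the selection), `selected_genes` (sorted column indices into `expr`), and
#'   `stats` (per-gene mean, dispersion, bin, normalized dispersion).
#' @export
select_hvg <- function(expr, n_top = 3000L, n_bins = 20L) {
  stopifnot(n_bins >= 1L, ncol(expr) >= 1L)
  n_genes <- ncol(expr)
  mu <- Matrix::colMeans(expr)
  ex2 <- Matrix::colMeans(expr^2)
  v <- (ex2 - mu^2) * nrow(expr) / max(1L, nrow(expr) - 1L)
  disp <- ifelse(mu > 0, v / mu, 0)

  breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(breaks) < 2L) {
    bin <- rep(1L, n_genes)
  } else {
    bin <- cut(mu, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }

  norm_disp <- numeric(n_genes)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    d <- disp[idx]
    med <- stats::median(d)
    scale <- stats::mad(d, center = med, constant = 1)
    if (scale == 0) scale <- stats::sd(d)
    if (is.na(scale) || scale == 0) {
      norm_disp[idx] <- 0
    } else {
      norm_disp[idx] <- abs(d - med) / scale
    }
  }

  n_top <- min(n_top, n_genes)
  sel <- sort(order(-norm_disp, seq_len(n_genes))[seq_len(n_top)])
  structure(list(
    X = as.matrix(expr[, sel, drop = FALSE]),
    selected_genes = sel,
    scale_factor = attr(expr, "scale_factor"),
    stats = data.frame(gene = colnames(expr) %||% as.character(seq_len(n_genes)),
                       mean = mu, dispersion = disp, bin = bin,
                       norm_dispersion = norm_disp)
  ), class = "sf_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full preprocessing: filter, normalize, select features
#'
#' Convenience wrapper running [filter_counts], [normalize_log] and
#' [select_hvg] with the package defaults, producing the node feature matrix
#' used for the spatial expression graph.
#'
#' @inheritParams filter_counts
#' @inheritParams normalize_log
#' @inheritParams select_hvg
#' @return A list of class `sf_features` (see [select_hvg]) with the filtered
#'   dataset attached as `$dataset`.
#' @export
preprocess_st <- function(data, min_cells_per_gene = 3L,
                          min_genes_per_cell = 100L, scale_factor = 1e4,
                          n_top = 3000L, n_bins = 20L) {
  filtered <- filter_counts(data, min_cells_per_gene, min_genes_per_cell)
  logn <- normalize_log(filtered, scale_factor)
  feats <- select_hvg(logn, n_top = n_top, n_bins = n_bins)
  feats$dataset <- filtered
  feats
}
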