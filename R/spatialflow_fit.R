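#' Fit a spatially regularized embedding model
#'
#' The package's main entry point: preprocesses a spatial transcriptomics
#' dataset (gene/cell filtering, total-count log normalization, dispersion
#' HVG selection), builds the spatial expression graph, and trains the
#' spatially regularized deep-graph-infomax encoder. Domain segmentation and
#' the pseudo-spatiotemporal map are then available through
#' [segment_domains], [compute_psm] and the object methods.
#'
#' @param data an [st_dataset] (or a `synthetic_tissue`, whose dataset is
#'   used).
#' @param graph spatial graph construction, `"alpha"` (default) or `"knn"`.
#' @param k neighbourhood size for the kNN graph / alpha-radius estimate.
#' @param n_top number of highly variable genes to keep.
#' @param min_cells_per_gene,min_genes_per_cell filtering thresholds.
#' @param scale_factor per-cell total after normalization.
#' @param gamma spatial regularization strength.
#' @param latent_dim embedding dimension.
#' @param lr,max_epochs,min_epochs,patience Adam training schedule.
#' @param seed integer seed governing all randomness of the fit.
#' @param ... further arguments passed to [train_dgi].
#' @return An object of class `spatialflow` with components `embeddings`
#'   (cells x latent), `fit` (the `dgi_fit`), `seg`, `features`, `dataset`
#'   (post-filter), `call`, `config`.
#' @examples
#' \donttest{
#' tis <- simulate_layered_tissue(cells_per_layer = 60, seed = 1)
#' m <- spatialflow(tis, max_epochs = 50, min_epochs = 10, seed = 1)
#' labels <- segment_domains(m, n_neighbors = 15, target_k = 3)
#' }
#' @export
spatialflow <- function(data, graph = c("alpha", "knn"), k = 15L,
                        n_top = 3000L, min_cells_per_gene = 3L,
                        min_genes_per_cell = 100L, scale_factor = 1e4,
                        gamma = 0.1, latent_dim = 50L, lr = 1e-3,
                        max_epochs = 1000L, min_epochs = 100L,
                        patience = 50L, seed = 0L, ...) {
  graph <- match.arg(graph)
  if (inherits(data, "synthetic_tissue")) data <- data$dataset
  stopifnot(inherits(data, "st_dataset"))
  feats <- preprocess_st(data, min_cells_per_gene, min_genes_per_cell,
                         scale_factor, n_top)
  seg <- build_seg(feats, feats$dataset$coords, method = graph, k = k)
  fit <- train_dgi(seg, gamma = gamma, latent_dim = latent_dim, lr = lr,
                   max_epochs = max_epochs, min_epochs = min_epochs,
                   patience = patience, seed = seed, ...)
  H <- fit$H
  rownames(H) <- feats$dataset$cell_ids
  structure(list(embeddings = H, fit = fit, seg = seg, features = feats,
                 dataset = feats$dataset, call = match.call(),
                 config = c(list(graph = graph, k = k, n_top = n_top,
                                 min_cells_per_gene = min_cells_per_gene,
                                 min_genes_per_cell = min_genes_per_cell,
                                 scale_factor = scale_factor),
                            fit$config)),
            class = "spatialflow")
}

#' @export
print.spatialflow <- function(x, ...) {
  cat("Spatially regularized graph embedding\n")
  cat("  cells: ", nrow(x$embeddings), "  latent dims: ",
      ncol(x$embeddings), "\n", sep = "")
  cat("  graph: ", x$seg$method, " (", nrow(x$seg$edges), " edges)",
      "  gamma: ", x$config$gamma, "\n", sep = "")
  cat("  trained ", x$fit$epochs_run, " epochs; best loss ",
      sprintf("%.5f", x$fit$best_loss), " at epoch ", x$fit$best_epoch,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.spatialflow <- function(object, ...) {
  h <- object$fit$history
  structure(list(n_cells = nrow(object$embeddings),
                 latent_dim = ncol(object$embeddings),
                 n_genes_used = ncol(object$features$X),
                 graph = object$seg$method,
                 n_edges = nrow(object$seg$edges),
                 gamma = object$config$gamma,
                 epochs_run = object$fit$epochs_run,
                 best_epoch = object$fit$best_epoch,
                 initial_loss = h$loss_total[1],
                 best_loss = object$fit$best_loss),
            class = "summary.spatialflow")
}

#' @export
print.summary.spatialflow <- function(x, ...) {
  cat("Spatially regularized graph embedding fit\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %s\n", nm,
                if (is.numeric(x[[nm]])) format(x[[nm]], digits = 5)
                else x[[nm]]))
  invisible(x)
}

#' @export
fitted.spatialflow <- function(object, ...) object$embeddings

#' Extract model parameters
#' @param object a fitted `spatialflow` model.
#' @param ... unused.
#' @return List of encoder/discriminator weights (`W1`, `W2`, PReLU slopes,
#'   `Theta`).
#' @export
coef.spatialflow <- function(object, ...) {
  object$fit$state[c("W1", "W2", "prelu1_slope", "prelu2_slope", "Theta")]
}

#' Re-encode features through the trained encoder
#'
#' @param object a fitted `spatialflow` model.
#' @param newdata optional list with elements `X` and `A` (defaults to the
#'   training graph, returning the training embeddings' forward pass).
#' @param ... unused.
#' @return Embedding matrix.
#' @export
predict.spatialflow <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$embeddings)
  gcn_encode(newdata$X, newdata$A, object$fit$state)
}

#' Plot a fitted spatial embedding
#'
#' Scatter of the spatial coordinates colored by domain label, by the
#' pseudo-spatiotemporal value, or by one embedding dimension.
#'
#' @param x a fitted `spatialflow` model.
#' @param color `"domain"`, `"psm"` or `"embedding"`.
#' @param labels precomputed domain labels (computed on the fly otherwise).
#' @param psm precomputed pseudotime values.
#' @param dim embedding dimension used when `color = "embedding"`.
#' @param ... passed to [graphics::plot].
#' @export
plot.spatialflow <- function(x, color = c("domain", "psm", "embedding"),
                             labels = NULL, psm = NULL, dim = 1L, ...) {
  color <- match.arg(color)
  xy <- x$seg$coords
  val <- switch(color,
    domain = {
      if (is.null(labels))
        labels <- segment_domains(x$embeddings,
                                  n_neighbors = min(50L, nrow(xy) - 1L))
      factor(labels)
    },
    psm = {
      if (is.null(psm))
        psm <- compute_psm(x$embeddings,
                           n_neighbors = min(50L, nrow(xy) - 1L))
      psm
    },
    embedding = x$embeddings[, dim])
  if (is.factor(val)) {
    cols <- grDevices::hcl.colors(nlevels(val), "Dark 3")[as.integer(val)]
  } else {
    pal <- grDevices::hcl.colors(100, "Viridis")
    cols <- pal[cut(val, 100, labels = FALSE)]
  }
  graphics::plot(xy[, 1], xy[, 2], col = cols, pch = 16, asp = 1,
                 xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' @export
fitted.dgi_fit <- function(object, ...) object$H
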