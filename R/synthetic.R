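# Ground-truth synthetic tissues. Counts are negative binomial in the
# (mean, dispersion) parameterization: variance = mu + dispersion * mu^2,
# i.e. rnbinom(mu = mu, size = 1 / dispersion), emulating the overdispersion
# of spatial transcriptomics counts.

rnb <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a layered tissue with planted layer markers
#'
#' Cells sit on a jittered grid partitioned into horizontal layer bands
#' (mirroring cortical-layer organization). Counts are negative binomial with
#' a common baseline mean, except that each layer owns a disjoint set of
#' marker genes whose mean is `fold_change * baseline_mean` inside that
#' layer. If a draw leaves some cell expressing fewer than 100 genes (so it
#' would not survive default preprocessing), the baseline mean is bumped by
#' 20% and the counts redrawn, with a warning.
#'
#' @param n_layers number of horizontal layers.
#' @param cells_per_layer cells per layer.
#' @param n_genes total genes.
#' @param n_markers_per_layer planted marker genes per layer (disjoint across
#'   layers; must satisfy `n_markers_per_layer * n_layers <= n_genes`).
#' @param baseline_mean NB mean of background expression.
#' @param fold_change marker mean multiplier inside the owning layer.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param grid_jitter sd of Gaussian jitter on unit-spaced grid positions.
#' @param seed integer seed; the whole tissue is reproducible from it.
#' @return A list of class `synthetic_tissue`: `dataset` ([st_dataset]),
#'   `layer_labels` (0-based layer per cell), `gradient` (ground-truth
#'   ordering coordinate), `planted_markers` (list layer -> gene indices),
#'   `params`.
#' @export
simulate_layered_tissue <- function(n_layers = 3L, cells_per_layer = 200L,
                                    n_genes = 300L, n_markers_per_layer = 20L,
                                    baseline_mean = 1.0, fold_change = 5.0,
                                    nb_dispersion = 0.5, grid_jitter = 0.1,
                                    seed = 1L) {
  stopifnot(n_layers >= 1L, cells_per_layer >= 1L, n_genes >= 1L,
            baseline_mean > 0, fold_change > 0, nb_dispersion > 0,
            grid_jitter >= 0)
  if (n_markers_per_layer * n_layers > n_genes)
    stop("n_markers_per_layer * n_layers (", n_markers_per_layer * n_layers,
         ") exceeds n_genes (", n_genes, ")")
  n <- n_layers * cells_per_layer
  with_seed(seed, {
    ncols <- ceiling(sqrt(n))
    rows_per_layer <- ceiling(cells_per_layer / ncols)
    coords <- matrix(0, n, 2)
    layer <- integer(n)
    idx <- 1L
    for (l in seq_len(n_layers)) {
      for (c in seq_len(cells_per_layer)) {
        row_in_layer <- (c - 1L) %/% ncols
        col <- (c - 1L) %% ncols
        coords[idx, ] <- c(col, (l - 1L) * rows_per_layer + row_in_layer)
        layer[idx] <- l - 1L
        idx <- idx + 1L
      }
    }
    coords <- coords + matrix(stats::rnorm(2 * n, sd = grid_jitter), n, 2)

    markers <- split(seq_len(n_markers_per_layer * n_layers),
                     rep(seq_len(n_layers), each = n_markers_per_layer))
    names(markers) <- as.character(seq_len(n_layers) - 1L)

    draw_counts <- function(base) {
      mu <- matrix(base, n, n_genes)
      for (l in seq_len(n_layers))
        mu[layer == l - 1L, markers[[l]]] <- fold_change * base
      matrix(rnb(n * n_genes, mu = as.vector(mu), dispersion = nb_dispersion),
             n, n_genes)
    }
    base <- baseline_mean
    counts <- draw_counts(base)
    while (n_genes >= 300L && any(rowSums(counts > 0) < 100L)) {
      base <- base * 1.2
      warning("some cells express < 100 genes; bumping baseline_mean to ",
              base, " and redrawing")
      counts <- draw_counts(base)
    }

    data <- st_dataset(counts, coords)
    structure(list(dataset = data, layer_labels = layer, gradient = layer,
                   planted_markers = markers,
                   params = list(n_layers = n_layers,
                                 cells_per_layer = cells_per_layer,
                                 n_genes = n_genes,
                                 n_markers_per_layer = n_markers_per_layer,
                                 baseline_mean = base,
                                 fold_change = fold_change,
                                 nb_dispersion = nb_dispersion,
                                 grid_jitter = grid_jitter, seed = seed)),
              class = "synthetic_tissue")
  })
}

#' Simulate a tissue with a continuous expression gradient
#'
#' Cells sit on a jittered horizontal strip. The negative-binomial means of
#' the program genes interpolate log-linearly along x between two expression
#' programs: the first half of the program genes decays from
#' `program_contrast * baseline_mean` on the left to `baseline_mean` on the
#' right, the second half mirrors it. The ground-truth pseudo-spatiotemporal
#' coordinate is the normalized x position.
#'
#' @param n_cells number of cells.
#' @param n_genes total genes.
#' @param n_program_genes genes participating in the two gradient programs.
#' @param baseline_mean background NB mean.
#' @param program_contrast fold contrast between the two ends of a program.
#' @param nb_dispersion NB dispersion.
#' @param grid_jitter sd of Gaussian position jitter.
#' @param seed integer seed.
#' @return A `synthetic_tissue` (see [simulate_layered_tissue]) whose
#'   `gradient` field holds the normalized x coordinate.
#' @export
simulate_gradient_tissue <- function(n_cells = 600L, n_genes = 300L,
                                     n_program_genes = 50L,
                                     baseline_mean = 1.0,
                                     program_contrast = 5.0,
                                     nb_dispersion = 0.5, grid_jitter = 0.1,
                                     seed = 1L) {
  stopifnot(n_cells >= 2L, n_genes >= 1L, n_program_genes <= n_genes,
            baseline_mean > 0, program_contrast > 0, nb_dispersion > 0)
  with_seed(seed, {
    n_rows <- 10L
    ncols <- ceiling(n_cells / n_rows)
    i <- seq_len(n_cells) - 1L
    coords <- cbind(i %% ncols, i %/% ncols) +
      matrix(stats::rnorm(2 * n_cells, sd = grid_jitter), n_cells, 2)
    g <- (coords[, 1] - min(coords[, 1]))
    g <- g / max(g)

    half <- n_program_genes %/% 2L
    prog_a <- seq_len(half)                          # high on the left
    prog_b <- seq_len(n_program_genes - half) + half # high on the right
    mu <- matrix(baseline_mean, n_cells, n_genes)
    hi <- program_contrast * baseline_mean
    mu[, prog_a] <- exp(outer((1 - g), rep(1, length(prog_a))) * log(hi) +
                          outer(g, rep(1, length(prog_a))) * log(baseline_mean))
    mu[, prog_b] <- exp(outer(g, rep(1, length(prog_b))) * log(hi) +
                          outer((1 - g), rep(1, length(prog_b))) * log(baseline_mean))
    counts <- matrix(rnb(n_cells * n_genes, mu = as.vector(mu),
                         dispersion = nb_dispersion), n_cells, n_genes)
    data <- st_dataset(counts, coords)
    structure(list(dataset = data, layer_labels = NULL, gradient = g,
                   planted_markers = list(program_left = prog_a,
                                          program_right = prog_b),
                   params = list(n_cells = n_cells, n_genes = n_genes,
                                 n_program_genes = n_program_genes,
                                 baseline_mean = baseline_mean,
                                 program_contrast = program_contrast,
                                 nb_dispersion = nb_dispersion,
                                 grid_jitter = grid_jitter, seed = seed)),
              class = "synthetic_tissue")
  })
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat("synthetic tissue: ", nrow(x$dataset$counts), " cells x ",
      ncol(x$dataset$counts), " genes",
      if (!is.null(x$layer_labels))
        paste0(", ", length(unique(x$layer_labels)), " layers") else
        ", gradient design",
      "\n", sep = "")
  invisible(x)
}
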