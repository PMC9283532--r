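# End-to-end pipeline: configuration handling, artifact writing, and the
# programmatic core behind the command-line interface
# (inst/scripts/spatialflow).

#' Build a run configuration
#'
#' All parameters of the pipeline with their defaults; unnamed fields follow
#' the package defaults of the individual stages. Round-trips through
#' [save_config]/[load_config].
#'
#' @param counts,genes,barcodes,coords input paths. Either `counts` pointing
#'   at an `.mtx` (with `genes`/`barcodes` sidecars) or at a dense CSV/TSV.
#' @param outdir output directory.
#' @param ... overrides of any default parameter (see [spatialflow]).
#' @return A list of class `sf_config`.
#' @export
sf_config <- function(counts = NULL, genes = NULL, barcodes = NULL,
                      coords = NULL, outdir = "spatialflow_out", ...) {
  cfg <- list(counts = counts, genes = genes, barcodes = barcodes,
              coords = coords, outdir = outdir,
              min_cells_per_gene = 3L, min_genes_per_cell = 100L,
              scale_factor = 1e4, n_top = 3000L, n_bins = 20L,
              graph = "alpha", k = 15L,
              gamma = 0.1, latent_dim = 50L, lr = 1e-3,
              max_epochs = 1000L, min_epochs = 100L, patience = 50L,
              pair_subsample_threshold = 10000L, n_pairs = NULL,
              n_neighbors = 50L, resolution = 1.0, target_k = NULL,
              seed = 0L, log_level = "info")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sf_config")
}

#' Save / load a run configuration as JSON
#' @param cfg an `sf_config`.
#' @param path JSON file path.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(sf_config, raw[!vapply(raw, is.null, logical(1))])
  for (f in c("min_cells_per_gene", "min_genes_per_cell", "n_top", "n_bins",
              "k", "latent_dim", "max_epochs", "min_epochs", "patience",
              "pair_subsample_threshold", "n_neighbors", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  cfg
}

# short content hash of the resolved configuration (provenance stamp)
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  substr(unname(tools::md5sum(tmp)), 1, 10)
}

#' Run the full pipeline from files on disk
#'
#' Reads the inputs, validates them, runs preprocess, graph construction,
#' training, segmentation and pseudotime, and writes the artifacts into
#' `cfg$outdir`: `embeddings.csv`, `domains.csv`, `psm.csv`, `losses.tsv`
#' and `config_resolved.json`. Every artifact carries the resolved config's
#' hash in a leading comment line.
#'
#' @param cfg an [sf_config] (or path to a saved one).
#' @return Invisibly, a list with `model`, `labels`, `psm`, `root`,
#'   `paths`, `config_hash`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "sf_config"))
  data <- local({
    if (is.null(cfg$counts)) stop("[input] no counts path configured")
    if (grepl("\\.mtx$", cfg$counts)) {
      read_st_mtx(cfg$counts, cfg$genes, cfg$barcodes, cfg$coords)
    } else {
      read_st_csv(cfg$counts, cfg$coords)
    }
  })
  rep <- validate_inputs(data$counts, data$coords)
  if (any(!rep$ok))
    stop("[validate] input validation failed: ",
         paste(rep$check[!rep$ok], collapse = ", "))

  model <- tryCatch(
    spatialflow(data, graph = cfg$graph, k = cfg$k, n_top = cfg$n_top,
                min_cells_per_gene = cfg$min_cells_per_gene,
                min_genes_per_cell = cfg$min_genes_per_cell,
                scale_factor = cfg$scale_factor, gamma = cfg$gamma,
                latent_dim = cfg$latent_dim, lr = cfg$lr,
                max_epochs = cfg$max_epochs, min_epochs = cfg$min_epochs,
                patience = cfg$patience, seed = cfg$seed,
                pair_subsample_threshold = cfg$pair_subsample_threshold,
                n_pairs = cfg$n_pairs),
    error = function(e) stop("[train] ", conditionMessage(e)))

  nn <- min(cfg$n_neighbors, nrow(model$embeddings) - 1L)
  labels <- tryCatch(
    segment_domains(model$embeddings, n_neighbors = nn,
                    resolution = cfg$resolution, target_k = cfg$target_k,
                    seed = cfg$seed),
    error = function(e) stop("[segment] ", conditionMessage(e)))
  root <- select_root(model$embeddings)
  psm <- tryCatch(compute_psm(model$embeddings, root, n_neighbors = nn),
                  error = function(e) stop("[psm] ", conditionMessage(e)))

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  stamp <- paste0("# config: ", hash)
  ids <- model$dataset$cell_ids
  paths <- list(
    embeddings = file.path(cfg$outdir, "embeddings.csv"),
    domains = file.path(cfg$outdir, "domains.csv"),
    psm = file.path(cfg$outdir, "psm.csv"),
    losses = file.path(cfg$outdir, "losses.tsv"),
    config = file.path(cfg$outdir, "config_resolved.json"))

  write_stamped <- function(df, path, sep = ",") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  }
  emb <- data.frame(cell_id = ids, model$embeddings, check.names = FALSE)
  colnames(emb) <- c("cell_id", paste0("z", seq_len(ncol(model$embeddings))))
  write_stamped(emb, paths$embeddings)
  write_stamped(data.frame(cell_id = ids, domain = labels), paths$domains)
  write_stamped(data.frame(cell_id = ids, psm = psm), paths$psm)
  write_stamped(model$fit$history, paths$losses, sep = "\t")
  save_config(cfg, paths$config)

  invisible(list(model = model, labels = labels, psm = psm, root = root,
                 paths = paths, config_hash = hash))
}

#' Write a synthetic tissue to disk in pipeline input format
#'
#' Writes the MTX + sidecar + coordinate files consumed by [run_pipeline],
#' plus the ground-truth labels/gradient as `truth.csv`.
#'
#' @param tissue a `synthetic_tissue`.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(tissue, dir) {
  paths <- write_st_mtx(tissue$dataset, dir)
  truth <- data.frame(cell_id = tissue$dataset$cell_ids)
  if (!is.null(tissue$layer_labels)) truth$layer <- tissue$layer_labels
  truth$gradient <- tissue$gradient
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(truth, tp, row.names = FALSE, quote = FALSE)
  invisible(c(paths, tp))
}
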