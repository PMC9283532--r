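#' Construct a spatial transcriptomics dataset
#'
#' Bundles a raw count matrix (cells/spots in rows, genes in columns) with the
#' spatial coordinates of each cell or spot. This is the entry object for the
#' whole pipeline; counts are stored sparse.
#'
#' @param counts cells x genes matrix of non-negative integer counts
#'   (dense matrix or any \pkg{Matrix} sparse matrix).
#' @param coords cells x d numeric matrix of spatial coordinates, d = 2 or 3,
#'   in arbitrary length units.
#' @param cell_ids,gene_ids optional unique character identifiers; taken from
#'   dimnames when missing, generated (`cell_1`, `gene_1`, ...) otherwise.
#' @return An object of class `st_dataset`: a list with elements `counts`
#'   (dgCMatrix), `coords`, `cell_ids`, `gene_ids`.
#' @examples
#' d <- st_dataset(matrix(rpois(30, 2), 6, 5), cbind(runif(6), runif(6)))
#' dim(d$counts)
#' @export
st_dataset <- function(counts, coords, cell_ids = NULL, gene_ids = NULL) {
  counts <- as_dgc(counts)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(colnames(coords)) && ncol(coords) %in% c(2L, 3L))
    colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  if (is.null(cell_ids)) {
    cell_ids <- rownames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(counts)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != nrow(coords))
    stop("counts has ", nrow(counts), " rows but coords has ", nrow(coords))
  if (!ncol(coords) %in% c(2L, 3L))
    stop("coords must have 2 or 3 columns, got ", ncol(coords))
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(cell_ids, gene_ids)
  rownames(coords) <- cell_ids
  structure(list(counts = counts, coords = coords,
                 cell_ids = cell_ids, gene_ids = gene_ids),
            class = "st_dataset")
}

# coerce anything matrix-like to a numeric general CsparseMatrix
as_dgc <- function(m) {
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  m <- methods::as(m, "CsparseMatrix")
  m <- methods::as(m, "generalMatrix")
  methods::as(m, "dMatrix")
}

#' @export
print.st_dataset <- function(x, ...) {
  cat("st_dataset: ", nrow(x$counts), " cells/spots x ", ncol(x$counts),
      " genes, ", ncol(x$coords), "-D coordinates\n", sep = "")
  cat("  nonzero counts: ", length(x$counts@x), " (",
      sprintf("%.1f%%", 100 * length(x$counts@x) / prod(dim(x$counts))),
      " dense)\n", sep = "")
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) dim(x$counts)

subset_st <- function(data, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(data$counts))
  if (is.null(genes)) genes <- seq_len(ncol(data$counts))
  st_dataset(data$counts[cells, genes, drop = FALSE],
             data$coords[cells, , drop = FALSE],
             data$cell_ids[cells], data$gene_ids[genes])
}

#' Read a MatrixMarket expression matrix with id sidecars and coordinates
#'
#' Expects the conventional triplet layout: an `.mtx` file plus one-id-per-line
#' gene and barcode text files, and a coordinate CSV with columns
#' `cell_id,x,y[,z]`. An MTX stored genes x cells is auto-transposed when its
#' row count matches the gene file length (and differs from the barcode count).
#'
#' @param mtx,genes,barcodes,coords file paths.
#' @return An [st_dataset].
#' @export
read_st_mtx <- function(mtx, genes, barcodes, coords) {
  for (p in c(mtx, genes, barcodes, coords))
    if (!file.exists(p)) stop("input file not found: ", p)
  m <- Matrix::readMM(mtx)
  gene_ids <- readLines(genes)
  cell_ids <- readLines(barcodes)
  if (nrow(m) == length(gene_ids) && nrow(m) != length(cell_ids))
    m <- Matrix::t(m)
  if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match barcode/gene files (", length(cell_ids), ", ",
         length(gene_ids), ")")
  xy <- read_coords(coords)
  xy <- xy[match(cell_ids, rownames(xy)), , drop = FALSE]
  if (anyNA(xy)) stop("coordinates missing for some barcodes")
  st_dataset(m, xy, cell_ids, gene_ids)
}

#' Read a dense CSV/TSV expression matrix and coordinates
#'
#' Cells in rows (first column = cell id), header row of gene ids.
#'
#' @param counts_file path to the dense matrix; separator inferred from the
#'   file extension (`.tsv` = tab) unless `sep` is given.
#' @param coords_file coordinate CSV with columns `cell_id,x,y[,z]`.
#' @param sep optional field separator override.
#' @return An [st_dataset].
#' @export
read_st_csv <- function(counts_file, coords_file, sep = NULL) {
  if (!file.exists(counts_file)) stop("input file not found: ", counts_file)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", counts_file, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(counts_file, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE,
                           comment.char = "#")
  m <- as.matrix(tab)
  xy <- read_coords(coords_file)
  xy <- xy[match(rownames(tab), rownames(xy)), , drop = FALSE]
  if (anyNA(xy)) stop("coordinates missing for some cells in ", coords_file)
  st_dataset(m, xy, rownames(tab), colnames(tab))
}

#' Read a coordinate table
#'
#' @param path CSV with columns `cell_id,x,y` and optionally `z`.
#' @return Numeric matrix with cell ids as row names.
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop("coordinates file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("coordinates file must have columns cell_id,x,y[,z]")
  cols <- intersect(c("x", "y", "z"), names(tab))
  xy <- as.matrix(tab[, cols, drop = FALSE])
  rownames(xy) <- as.character(tab$cell_id)
  xy
}

#' Write an st_dataset as MTX + sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `coords.csv` into
#' `dir`, the same layout [read_st_mtx] consumes.
#'
#' @param data an [st_dataset].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_st_mtx <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "coords.csv"))
  Matrix::writeMM(data$counts, paths[1])
  writeLines(data$gene_ids, paths[2])
  writeLines(data$cell_ids, paths[3])
  utils::write.csv(data.frame(cell_id = data$cell_ids, data$coords,
                              check.names = FALSE),
                   paths[4], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Validate raw pipeline inputs
#'
#' Checks id alignment between expression matrix and coordinates, duplicate
#' ids, and that counts are non-negative integers. Returns a machine-readable
#' report rather than raising.
#'
#' @param counts cells x genes count matrix (rows named by cell id, or use
#'   `cell_ids`).
#' @param coords coordinate matrix/data frame with cell ids as row names, or a
#'   path readable by [read_coords].
#' @param cell_ids,gene_ids optional explicit ids.
#' @return A data.frame with columns `check`, `ok`, `detail`; zero failing
#'   rows means the inputs are consistent.
#' @export
validate_inputs <- function(counts, coords, cell_ids = NULL, gene_ids = NULL) {
  if (is.character(coords) && length(coords) == 1L) coords <- read_coords(coords)
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  rep <- list()
  add <- function(check, ok, detail = "")
    rep[[length(rep) + 1L]] <<- data.frame(check = check, ok = ok,
                                           detail = detail)
  add("dims", nrow(counts) == nrow(coords),
      sprintf("%d matrix rows vs %d coordinate rows", nrow(counts),
              nrow(coords)))
  if (!is.null(cell_ids) && !is.null(rownames(coords))) {
    missing <- setdiff(cell_ids, rownames(coords))
    add("id_alignment", length(missing) == 0L,
        if (length(missing)) paste("no coordinates for:",
                                   paste(utils::head(missing, 5),
                                         collapse = ", ")) else "")
  }
  add("unique_cell_ids", is.null(cell_ids) || !anyDuplicated(cell_ids),
      "")
  add("unique_gene_ids", is.null(gene_ids) || !anyDuplicated(gene_ids),
      "")
  cm <- as.matrix(counts)
  neg <- which(cm < 0, arr.ind = TRUE)
  add("non_negative", nrow(neg) == 0L,
      if (nrow(neg)) sprintf("negative count at (row %d, col %d)",
                             neg[1, 1], neg[1, 2]) else "")
  nonint <- which(abs(cm - round(cm)) > 1e-8, arr.ind = TRUE)
  add("integer_counts", nrow(nonint) == 0L,
      if (nrow(nonint)) sprintf("non-integer count at (row %d, col %d)",
                                nonint[1, 1], nonint[1, 2]) else "")
  do.call(rbind, rep)
}
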