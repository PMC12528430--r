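#' Single-cell expression dataset container
#'
#' A lightweight container for one single-cell RNA-seq dataset: a sparse
#' cells-by-genes count matrix, any number of derived expression layers of
#' the same shape (e.g. `"lognorm"`, `"imputed"`), and a per-cell metadata
#' tibble. Rows are cells and columns are genes throughout the package.
#'
#' @param counts sparse or dense non-negative integer matrix, cells in rows,
#'   genes in columns. Row names are cell barcodes, column names gene
#'   symbols (or pass `gene_ids` / `cell_meta` explicitly).
#' @param cell_meta tibble with one row per cell; must contain columns
#'   `barcode`, `dataset_id`, `cluster` and `annotation`. Missing columns
#'   other than `barcode` are filled with placeholders.
#' @param gene_ids character vector of unique gene symbols, one per column.
#' @param layers named list of matrices with the same shape as `counts`.
#'
#' @return an object of class `ens_dataset`.
#' @export
ens_dataset <- function(counts, cell_meta = NULL, gene_ids = NULL,
                        layers = list()) {
  if (!inherits(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  assert_that(!is.null(gene_ids), "gene_ids missing and counts has no colnames")
  gene_ids <- as.character(gene_ids)
  assert_that(length(gene_ids) == ncol(counts),
              "length(gene_ids) must equal ncol(counts)")
  assert_that(!anyDuplicated(gene_ids), "duplicate gene symbols")
  if (is.null(cell_meta)) {
    bc <- rownames(counts) %||% sprintf("cell%05d", seq_len(nrow(counts)))
    cell_meta <- tibble(barcode = bc)
  }
  cell_meta <- as_tibble(cell_meta)
  assert_that("barcode" %in% names(cell_meta), "cell_meta needs a barcode column")
  assert_that(nrow(cell_meta) == nrow(counts),
              "cell_meta rows must match counts rows")
  assert_that(!anyDuplicated(cell_meta$barcode), "duplicate cell barcodes")
  for (col in c("dataset_id", "cluster", "annotation")) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- NA_character_
  }
  assert_that(min(counts@x %||% 0, 0) >= 0, "counts must be non-negative")
  dimnames(counts) <- list(cell_meta$barcode, gene_ids)
  x <- structure(
    list(counts = counts, layers = layers, cell_meta = cell_meta,
         gene_ids = gene_ids),
    class = "ens_dataset"
  )
  validate_ens_dataset(x)
}

validate_ens_dataset <- function(x) {
  for (nm in names(x$layers)) {
    assert_that(all(dim(x$layers[[nm]]) == dim(x$counts)),
                paste0("layer '", nm, "' shape differs from counts"))
  }
  x
}

#' @export
print.ens_dataset <- function(x, ...) {
  cat(sprintf("<ens_dataset> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  layers:", if (length(x$layers)) paste(names(x$layers), collapse = ", ")
      else "(none)", "\n")
  k <- unique(x$cell_meta$cluster)
  cat(sprintf("  clusters: %d  dataset_id: %s\n", length(k[!is.na(k)]),
              paste(unique(x$cell_meta$dataset_id), collapse = ",")))
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param x an `ens_dataset`
#' @return integer count
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x$counts)

#' Fetch an expression layer as a dense matrix
#'
#' @param x an `ens_dataset`
#' @param layer layer name, or `"counts"` for the raw counts
#' @return dense numeric matrix, cells by genes
#' @export
get_layer <- function(x, layer) {
  if (identical(layer, "counts")) return(as_dense(x$counts))
  if (!layer %in% names(x$layers)) {
    abort(paste0("unknown layer '", layer, "'; available: ",
                 paste(c("counts", names(x$layers)), collapse = ", ")))
  }
  as_dense(x$layers[[layer]])
}

#' Write a dataset to a directory of plain-text files
#'
#' Serializes the counts as Matrix Market (`matrix.mtx`, genes are columns),
#' gene symbols as `genes.tsv`, cell metadata as `cells.tsv`, and each layer
#' as `layer_<name>.mtx`.
#'
#' @param x an `ens_dataset`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_ens_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene = x$gene_ids), file.path(dir, "genes.tsv"))
  readr::write_tsv(x$cell_meta, file.path(dir, "cells.tsv"))
  for (nm in names(x$layers)) {
    Matrix::writeMM(Matrix::Matrix(x$layers[[nm]], sparse = TRUE),
                    file.path(dir, paste0("layer_", nm, ".mtx")))
  }
  invisible(dir)
}

#' Read a dataset written by [write_ens_dataset()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`
#'   and optional `layer_*.mtx` files
#' @return an `ens_dataset`
#' @export
read_ens_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  for (col in c("cluster", "annotation", "dataset_id")) {
    if (col %in% names(cells)) cells[[col]] <- as.character(cells[[col]])
  }
  if (!"cluster" %in% names(cells)) {
    abort("cells.tsv is missing required column 'cluster'")
  }
  x <- ens_dataset(counts, cell_meta = cells, gene_ids = genes$gene)
  layer_files <- list.files(dir, pattern = "^layer_.*\\.mtx$")
  for (f in layer_files) {
    nm <- sub("^layer_", "", sub("\\.mtx$", "", f))
    m <- as.matrix(Matrix::readMM(file.path(dir, f)))
    dimnames(m) <- dimnames(x$counts)
    x$layers[[nm]] <- m
  }
  validate_ens_dataset(x)
}

#' Subset a dataset to selected cells
#'
#' @param x an `ens_dataset`
#' @param idx integer or logical index over cells
#' @return an `ens_dataset` with the selected cells, layers included
#' @export
subset_cells <- function(x, idx) {
  y <- ens_dataset(x$counts[idx, , drop = FALSE],
                   cell_meta = x$cell_meta[idx, , drop = FALSE],
                   gene_ids = x$gene_ids)
  y$layers <- lapply(x$layers, function(m) m[idx, , drop = FALSE])
  y
}
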