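#' Construct a gene-by-cell count matrix
#'
#' The central expression container: a sparse genes x cells matrix carrying
#' either raw UMI counts (`layer = "raw"`) or library-size log-normalized
#' values (`layer = "lognorm"`, i.e. `log(1 + c * target / colsum)` of raw).
#'
#' @param counts matrix or sparse Matrix, genes in rows, cells in columns.
#' @param genes character vector of gene symbols (defaults to rownames).
#' @param cells character vector of cell barcodes (defaults to colnames).
#' @param layer `"raw"` (non-negative integers) or `"lognorm"`.
#' @param size_factor_target library-size target used for normalization
#'   (default 10,000 counts per cell).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, genes = rownames(counts), cells = colnames(counts),
                         layer = c("raw", "lognorm"), size_factor_target = 1e4) {
  layer <- match.arg(layer)
  if (is.null(genes) || is.null(cells)) {
    abort_format("count_matrix requires gene and cell names")
  }
  genes <- as.character(genes)
  cells <- as.character(cells)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "dMatrix"),
                        "CsparseMatrix")
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
    abort_format(sprintf(
      "matrix is %d x %d but %d genes and %d cells were supplied",
      nrow(counts), ncol(counts), length(genes), length(cells)))
  }
  if (anyDuplicated(genes)) abort_format("duplicate gene symbols")
  if (anyDuplicated(cells)) abort_format("duplicate cell barcodes")
  x <- counts@x
  if (length(x) && min(x) < 0) abort_format("negative entries in count matrix")
  if (layer == "raw" && length(x) && any(abs(x - round(x)) > 1e-8)) {
    abort_format("raw layer must be integer-valued")
  }
  dimnames(counts) <- list(genes, cells)
  structure(
    list(genes = genes, cells = cells, counts = counts, layer = layer,
         size_factor_target = size_factor_target),
    class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells, layer = %s\n",
              nrow(x$counts), ncol(x$counts), x$layer))
  invisible(x)
}

#' Subset a count matrix by genes and/or cells
#'
#' @param m a `count_matrix`.
#' @param genes,cells character vectors (or indices) to keep; `NULL` keeps all.
#' @return A `count_matrix` on the selected rows/columns, same layer.
#' @export
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  g <- genes %||% m$genes
  ce <- cells %||% m$cells
  cm <- m$counts[g, ce, drop = FALSE]
  count_matrix(cm, rownames(cm), colnames(cm), layer = m$layer,
               size_factor_target = m$size_factor_target)
}

#' Read a CellRanger-style sparse count matrix
#'
#' Reads a MatrixMarket triplet file together with its feature and barcode
#' lists (the `matrix.mtx` / `features.tsv` / `barcodes.tsv` layout). When
#' the features file has two or more columns the second column (gene symbol)
#' is used; duplicated symbols are made unique with `make.unique`.
#'
#' @param mtx_path path to the MatrixMarket file.
#' @param features_path path to the features/genes TSV (no header).
#' @param barcodes_path path to the barcode list (no header).
#' @return A raw-layer `count_matrix`.
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path)) {
    if (!file.exists(p)) abort_format(paste("file not found:", p))
  }
  mm <- tryCatch(Matrix::readMM(mtx_path),
                 error = function(e) abort_format(paste("invalid MatrixMarket file:", conditionMessage(e))))
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
  bcs <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  genes <- make.unique(as.character(genes))
  if (nrow(mm) != length(genes)) {
    abort_format(sprintf("matrix has %d rows but %d features listed", nrow(mm), length(genes)))
  }
  if (ncol(mm) != length(bcs)) {
    abort_format(sprintf("matrix has %d columns but %d barcodes listed", ncol(mm), length(bcs)))
  }
  count_matrix(mm, genes, as.character(bcs), layer = "raw")
}

#' Write a count matrix in the CellRanger triplet layout
#'
#' @param m a `count_matrix`.
#' @param dir output directory (created if missing); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m$counts, mtx)
  writeLines(paste(m$genes, m$genes, "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  writeLines(m$cells, file.path(dir, "barcodes.tsv"))
  invisible(file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv")))
}
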