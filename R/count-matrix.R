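#' Construct a cell-by-gene count matrix
#'
#' The basic data container of the package: a dense non-negative integer
#' matrix with cells in rows and genes in columns, plus unique cell and gene
#' identifiers.
#'
#' @param counts numeric matrix of non-negative integers, cells x genes.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#'   Defaults to the rownames of `counts`.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column. Defaults to the colnames of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with dimnames), `cell_ids` and `gene_ids`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  validate_counts(counts, cell_ids, gene_ids)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "count_matrix")
}

validate_counts <- function(counts, cell_ids, gene_ids) {
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("count matrix must have at least 2 cells and 2 genes", call. = FALSE)
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("identifier length does not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts contain missing or non-finite entries", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at cell '%s', gene '%s'",
                 cell_ids[bad[1L]], gene_ids[bad[2L]]), call. = FALSE)
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at cell '%s', gene '%s'",
                 cell_ids[bad[1L]], gene_ids[bad[2L]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%.1f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts > 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Reads either a dense CSV/TSV (first column = cell ids, header = gene ids)
#' or a Matrix Market `.mtx` file with plain-text gene and barcode sidecar
#' files. MTX files written as genes x cells (the common CellRanger layout)
#' are detected by comparing the matrix dimensions against the sidecar
#' lengths and transposed to cells x genes; a square matrix is ambiguous and
#' requires `orientation`.
#'
#' @param path path to the CSV/TSV file or to the `.mtx` file.
#' @param format `"csv"` or `"mtx"`. Guessed from the file extension when
#'   missing.
#' @param genes_file,barcodes_file sidecar paths for MTX input; default to
#'   `genes.txt` / `barcodes.txt` (falling back to `features.txt`) next to
#'   the matrix file. One identifier per line, no header.
#' @param orientation for MTX input: `"auto"` (default, resolve by sidecar
#'   lengths), `"cells_x_genes"` or `"genes_x_cells"`.
#' @param sep field separator for CSV input; default `,` (use `"\t"` for
#'   TSV).
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path, format = c("auto", "csv", "mtx"),
                              genes_file = NULL, barcodes_file = NULL,
                              orientation = c("auto", "cells_x_genes",
                                              "genes_x_cells"),
                              sep = ",") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "csv") {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("malformed count table in ", path,
           ": non-numeric entries present", call. = FALSE)
    return(count_matrix(m, cell_ids = rownames(df), gene_ids = colnames(df)))
  }

  ## MTX + sidecars
  dir <- dirname(path)
  if (is.null(genes_file)) {
    for (cand in file.path(dir, c("genes.txt", "features.txt", "genes.tsv",
                                  "features.tsv"))) {
      if (file.exists(cand)) { genes_file <- cand; break }
    }
  }
  if (is.null(barcodes_file)) {
    for (cand in file.path(dir, c("barcodes.txt", "barcodes.tsv"))) {
      if (file.exists(cand)) { barcodes_file <- cand; break }
    }
  }
  if (is.null(genes_file) || !file.exists(genes_file))
    stop("gene sidecar file not found for ", path, call. = FALSE)
  if (is.null(barcodes_file) || !file.exists(barcodes_file))
    stop("barcode sidecar file not found for ", path, call. = FALSE)
  genes <- readLines(genes_file)
  ## features files may carry extra tab-separated columns; keep the first
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1L), 1L)
  barcodes <- readLines(barcodes_file)

  m <- as.matrix(Matrix::readMM(path))
  nr <- nrow(m); nc <- ncol(m)
  if (orientation == "auto") {
    if (nr == nc && length(genes) == length(barcodes))
      stop("square MTX with equally long sidecars is ambiguous; ",
           "pass orientation explicitly", call. = FALSE)
    orientation <-
      if (nr == length(barcodes) && nc == length(genes)) "cells_x_genes"
      else if (nr == length(genes) && nc == length(barcodes)) "genes_x_cells"
      else stop(sprintf(
        "MTX dimensions (%d x %d) match neither sidecar layout (%d genes, %d barcodes)",
        nr, nc, length(genes), length(barcodes)), call. = FALSE)
  }
  if (orientation == "genes_x_cells") m <- t(m)
  count_matrix(m, cell_ids = barcodes, gene_ids = genes)
}

#' Write a count matrix to disk
#'
#' @param x a [count_matrix].
#' @param path output path (`.csv` or `.mtx`).
#' @param format `"csv"` or `"mtx"`; guessed from the extension by default.
#'   MTX output is written cells x genes with `genes.txt` and `barcodes.txt`
#'   sidecars in the same directory.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("auto", "csv", "mtx")) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  if (format == "csv") {
    utils::write.csv(as.data.frame(x$counts), path)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(x$gene_ids, file.path(dirname(path), "genes.txt"))
    writeLines(x$cell_ids, file.path(dirname(path), "barcodes.txt"))
  }
  invisible(path)
}

#' Drop genes detected in too few cells
#'
#' Minimal quality filter applied before per-gene GLM fitting: genes
#' expressed (count > 0) in fewer than `min_cells` cells are removed to
#' avoid degenerate fits.
#'
#' @param x a [count_matrix].
#' @param min_cells minimum number of cells with non-zero count (default 3).
#' @return A filtered [count_matrix].
#' @export
filter_genes <- function(x, min_cells = 3L) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- colSums(x$counts > 0) >= min_cells
  if (sum(keep) < 2L)
    stop("fewer than 2 genes pass the detection filter", call. = FALSE)
  count_matrix(x$counts[, keep, drop = FALSE])
}
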