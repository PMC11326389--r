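#' Construct a cell-level covariate table
#'
#' One row per cell, aligned to a [count_matrix]. Columns are either
#' categorical (stored as factors; e.g. sample, protocol, sex, cell type) or
#' numeric (e.g. library size).
#'
#' @param data data.frame of covariates, one row per cell.
#' @param cell_ids character vector of cell identifiers matching the count
#'   matrix order.
#' @return An object of class `covariate_table`: a data.frame with
#'   rownames = cell ids; character columns are converted to factors.
#' @export
covariate_table <- function(data, cell_ids) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  cell_ids <- as.character(cell_ids)
  if (nrow(data) != length(cell_ids))
    stop("covariate rows (", nrow(data), ") do not match number of cells (",
         length(cell_ids), ")", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers in covariate table", call. = FALSE)
  for (nm in names(data)) {
    col <- data[[nm]]
    if (is.character(col) || is.logical(col)) col <- factor(col)
    if (is.numeric(col) && any(!is.finite(col)))
      stop("numeric covariate '", nm, "' contains non-finite values",
           call. = FALSE)
    data[[nm]] <- col
  }
  for (nm in names(data)) {
    col <- data[[nm]]
    if (is.factor(col) && !any(table(col) >= 2L))
      stop("categorical covariate '", nm,
           "' has no level with at least 2 cells", call. = FALSE)
  }
  rownames(data) <- cell_ids
  class(data) <- c("covariate_table", "data.frame")
  data
}

#' Read covariates and align them to a count matrix
#'
#' The file must contain a cell-identifier column (named `cell_id`,
#' `barcode`, `cell`, or the first column as fallback) whose values match
#' the count matrix ids as a set; rows are reordered to the count matrix
#' order. Column types are inferred: a column is numeric iff all its values
#' parse as numbers. If no `library_size` column is present one is computed
#' as the per-cell total count.
#'
#' @param path CSV/TSV file, one row per cell.
#' @param cell_matrix the [count_matrix] to align against.
#' @param sep field separator (default `,`).
#' @param add_library_size compute `library_size` from the counts when the
#'   file lacks that column (default TRUE).
#' @return A [covariate_table] in count-matrix cell order.
#' @export
read_covariates <- function(path, cell_matrix, sep = ",",
                            add_library_size = TRUE) {
  stopifnot(inherits(cell_matrix, "count_matrix"))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  id_col <- intersect(c("cell_id", "barcode", "cell"), names(df))
  id_col <- if (length(id_col)) id_col[1L] else names(df)[1L]
  ids <- df[[id_col]]
  missing_cells <- setdiff(cell_matrix$cell_ids, ids)
  if (length(missing_cells))
    stop("covariate table is missing cells: ",
         paste(utils::head(missing_cells, 5L), collapse = ", "),
         if (length(missing_cells) > 5L) ", ...", call. = FALSE)
  extra <- setdiff(ids, cell_matrix$cell_ids)
  if (length(extra))
    stop("covariate table has cells absent from the count matrix: ",
         paste(utils::head(extra, 5L), collapse = ", "),
         if (length(extra) > 5L) ", ...", call. = FALSE)
  df <- df[match(cell_matrix$cell_ids, ids), , drop = FALSE]
  df[[id_col]] <- NULL
  ## numeric iff every value parses as a number
  for (nm in names(df)) {
    parsed <- suppressWarnings(as.numeric(df[[nm]]))
    if (!anyNA(parsed)) df[[nm]] <- parsed
  }
  if (add_library_size && !"library_size" %in% names(df))
    df$library_size <- unname(rowSums(cell_matrix$counts))
  covariate_table(df, cell_matrix$cell_ids)
}

#' Write a covariate table to CSV
#'
#' @param x a [covariate_table].
#' @param path output CSV path; the cell id is written as a `cell_id`
#'   column.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(x, path) {
  out <- cbind(cell_id = rownames(x), as.data.frame(x))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

categorical_covariates <- function(covariates) {
  names(covariates)[vapply(covariates, is.factor, logical(1L))]
}

numeric_covariates <- function(covariates) {
  names(covariates)[vapply(covariates, is.numeric, logical(1L))]
}
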