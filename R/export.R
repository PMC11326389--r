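#' Rank genes by their contribution to a factor
#'
#' Orders the loading column of one factor from most to least contributing
#' gene under the chosen direction: `positive` sorts by signed loading
#' descending, `negative` ascending, `absolute` by magnitude descending.
#' Ties are broken by gene id so the ordering is stable.
#'
#' @param model a `factor_model`.
#' @param factor_id factor name (e.g. `"F3"`) or column index.
#' @param direction `"positive"` (default), `"negative"` or `"absolute"`.
#' @return A `ranked_loadings` data.frame with columns `gene`, `loading`
#'   and attributes `factor_id`, `direction`.
#' @export
ranked_loadings <- function(model, factor_id,
                            direction = c("positive", "negative",
                                          "absolute")) {
  stopifnot(inherits(model, "factor_model"))
  direction <- match.arg(direction)
  l <- model$loadings[, factor_id]
  genes <- rownames(model$loadings)
  key <- switch(direction, positive = -l, negative = l, absolute = -abs(l))
  ord <- order(key, genes)
  out <- data.frame(gene = genes[ord], loading = unname(l[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "factor_id") <- factor_id
  attr(out, "direction") <- direction
  class(out) <- c("ranked_loadings", "data.frame")
  out
}

#' Top contributing genes of a factor
#'
#' The first `n` genes of [ranked_loadings]; n = 200 is the conventional
#' input size for downstream enrichment tools.
#'
#' @inheritParams ranked_loadings
#' @param n number of genes (default 200, truncated at the gene count).
#' @return character vector of gene ids.
#' @export
top_genes <- function(model, factor_id, n = 200L,
                      direction = c("positive", "negative", "absolute")) {
  rl <- ranked_loadings(model, factor_id, direction)
  utils::head(rl$gene, n)
}

#' Correlate factor scores with numeric covariates
#'
#' Pearson correlation of every factor with every numeric covariate
#' (library size, detected genes, mitochondrial fraction, ...). Factors
#' whose absolute correlation with any technical covariate exceeds the
#' threshold are flagged as technically driven.
#'
#' @param model a `factor_model`.
#' @param covariates a [covariate_table] (numeric columns used) or a
#'   numeric data.frame/matrix.
#' @param flag_threshold absolute-correlation flag level (default 0.45).
#' @return list with `correlation` (factor x covariate matrix) and
#'   `flagged` (character vector of factor names with any
#'   `|r| > flag_threshold`).
#' @export
factor_covariate_correlation <- function(model, covariates,
                                         flag_threshold = 0.45) {
  stopifnot(inherits(model, "factor_model"))
  if (inherits(covariates, "covariate_table")) {
    num <- numeric_covariates(covariates)
    if (!length(num)) stop("no numeric covariates present", call. = FALSE)
    X <- as.matrix(as.data.frame(covariates)[num])
  } else {
    X <- as.matrix(covariates)
  }
  if (nrow(X) != nrow(model$scores))
    stop("covariates and scores have different numbers of cells",
         call. = FALSE)
  cc <- stats::cor(model$scores, X)
  list(correlation = cc,
       flagged = rownames(cc)[apply(abs(cc) > flag_threshold, 1L, any)])
}

#' Export a ranked gene list as TSV
#'
#' Two-column, rank-preserving `gene<TAB>loading` file with a header, the
#' format consumed by ranked-mode enrichment tools.
#'
#' @param ranked a [ranked_loadings] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_loadings"))
  utils::write.table(ranked[, c("gene", "loading")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
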