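#' Run the full factor discovery pipeline
#'
#' Counts -> gene filter -> per-gene Poisson GLM on the selected technical
#' covariates -> Pearson residuals -> rotated PCA -> ensemble
#' factor-covariate association -> Otsu binarization -> interpretability
#' table.
#'
#' @param counts a [count_matrix].
#' @param covariates a [covariate_table] aligned to the counts.
#' @param regress covariate names to regress out in the GLM (default
#'   `"library_size"` if present, otherwise intercept-only).
#' @param k number of factors (default 30, capped at min(n, g) - 1).
#' @param rotation `"varimax"` (default), `"promax"` or `"none"`.
#' @param residual_type `"pearson"` (default), `"response"` or
#'   `"deviance"`.
#' @param association_covariates categorical covariates to score against
#'   (default: all).
#' @param min_cells gene-detection filter passed to [filter_genes].
#' @param seed RNG seed for the stochastic ensemble members and k-means.
#' @param fis_all_metrics passed to [build_fis_table].
#' @return list with `counts` (filtered), `design`, `residuals`, `model`,
#'   `fca`, `calls`, `fis`.
#' @export
factor_discovery <- function(counts, covariates,
                             regress = intersect("library_size",
                                                 names(covariates)),
                             k = 30L,
                             rotation = c("varimax", "promax", "none"),
                             residual_type = c("pearson", "response",
                                               "deviance"),
                             association_covariates = NULL,
                             min_cells = 3L, seed = 1L,
                             fis_all_metrics = FALSE) {
  rotation <- match.arg(rotation)
  residual_type <- match.arg(residual_type)
  counts <- filter_genes(counts, min_cells = min_cells)
  design <- build_design_matrix(covariates, regress)
  resid <- compute_residual_matrix(counts, design,
                                   residual_type = residual_type)
  k <- min(k, dim(counts)[1L] - 1L, dim(counts)[2L] - 1L)
  model <- factorize_residuals(resid, k = k, rotation = rotation)
  fca <- ensemble_fca(model, covariates,
                      covariate_names = association_covariates,
                      seed = seed)
  calls <- call_associations(fca)
  fis <- build_fis_table(model, fca, covariates, seed = seed,
                         all_metrics = fis_all_metrics)
  list(counts = counts, design = design, residuals = resid, model = model,
       fca = fca, calls = calls, fis = fis)
}

#' Match factors between two factor models
#'
#' Factor order and sign are arbitrary across independent factorizations,
#' so models can only be compared after aligning their factors. Greedy
#' matching on absolute score correlations: the highest |r| pair is
#' matched first, its row/column removed, and so on.
#'
#' @param model_a,model_b `factor_model`s over the same cells.
#' @return integer vector `m` of length k: factor j of `model_a`
#'   corresponds to factor `m[j]` of `model_b`; attribute `correlation`
#'   carries the matched |r| values.
#' @export
match_factors <- function(model_a, model_b) {
  cc <- abs(stats::cor(model_a$scores, model_b$scores))
  k <- ncol(cc)
  m <- integer(k); r <- numeric(k)
  remaining_a <- seq_len(k); remaining_b <- seq_len(k)
  for (step in seq_len(k)) {
    sub <- cc[remaining_a, remaining_b, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    a <- remaining_a[ij[1L]]; b <- remaining_b[ij[2L]]
    m[a] <- b; r[a] <- sub[ij[1L], ij[2L]]
    remaining_a <- setdiff(remaining_a, a)
    remaining_b <- setdiff(remaining_b, b)
  }
  attr(m, "correlation") <- r
  m
}
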