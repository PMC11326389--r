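#' Build a design matrix from selected covariates
#'
#' Encodes the chosen covariates for per-gene Poisson regression: an
#' intercept column, treatment-coded (first level = reference) dummy columns
#' for each categorical covariate, and numeric covariates standardized to
#' zero mean / unit variance. `library_size` is encoded on the log scale
#' (matching the Poisson log link) before standardization. Collinear
#' columns are dropped with a warning.
#'
#' @param covariates a [covariate_table].
#' @param selected character vector of covariate names to include; an empty
#'   selection yields the intercept-only design.
#' @param log_library_size log-transform a numeric covariate named
#'   `library_size` before standardizing (default TRUE).
#' @return A `design_matrix` object: list with `matrix` (n x p, first column
#'   all ones, full column rank), `column_names`, `source_covariates`.
#' @export
build_design_matrix <- function(covariates, selected = character(),
                                log_library_size = TRUE) {
  stopifnot(inherits(covariates, "covariate_table"))
  missing_cov <- setdiff(selected, names(covariates))
  if (length(missing_cov))
    stop("unknown covariates: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  n <- nrow(covariates)
  mat <- matrix(1, n, 1L, dimnames = list(rownames(covariates),
                                          "(Intercept)"))
  for (nm in selected) {
    col <- covariates[[nm]]
    if (is.factor(col)) {
      col <- droplevels(col)
      if (nlevels(col) < 2L) next  # constant: nothing to encode
      dummies <- stats::model.matrix(~col)[, -1L, drop = FALSE]
      colnames(dummies) <- paste0(nm, ":", levels(col)[-1L])
      mat <- cbind(mat, dummies)
    } else {
      x <- col
      if (nm == "library_size" && log_library_size) x <- log(pmax(x, 1))
      s <- stats::sd(x)
      x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
      mat <- cbind(mat, matrix(x, ncol = 1L, dimnames = list(NULL, nm)))
    }
  }
  ## drop collinear columns (keep the intercept, keep earliest columns)
  qr_d <- qr(mat)
  if (qr_d$rank < ncol(mat)) {
    keep <- sort(qr_d$pivot[seq_len(qr_d$rank)])
    dropped <- colnames(mat)[-keep]
    warning("dropping collinear design columns: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    mat <- mat[, keep, drop = FALSE]
  }
  structure(list(matrix = mat, column_names = colnames(mat),
                 source_covariates = selected),
            class = "design_matrix")
}

#' Fit a Poisson GLM to one gene
#'
#' Maximum-likelihood Poisson regression with log link, fitted by
#' iteratively reweighted least squares (`stats::glm.fit`, deviance
#' tolerance 1e-8, at most 50 iterations). Fitted means are floored at
#' `mu_floor` so Pearson residuals stay finite for all-zero genes.
#'
#' @param gene_counts non-negative integer vector, one entry per cell.
#' @param design a `design_matrix` from [build_design_matrix].
#' @param mu_floor lower bound on fitted means (default 1e-10).
#' @return list with `coefficients`, `fitted_means` (> 0), `converged`.
#' @export
fit_poisson_glm <- function(gene_counts, design, mu_floor = 1e-10) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$matrix
  if (length(gene_counts) != nrow(X))
    stop("gene_counts length does not match design rows", call. = FALSE)
  if (any(gene_counts < 0) || any(gene_counts != round(gene_counts)))
    stop("gene_counts must be non-negative integers", call. = FALSE)
  if (all(gene_counts == 0)) {
    return(list(coefficients = stats::setNames(rep(NA_real_, ncol(X)),
                                               colnames(X)),
                fitted_means = rep(mu_floor, nrow(X)),
                converged = FALSE))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, gene_counts, family = stats::poisson(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 50L)))
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       fitted_means = pmax(fit$fitted.values, mu_floor),
       converged = isTRUE(fit$converged))
}

#' Residuals of a Poisson fit
#'
#' Three residual definitions for observed counts `y` and fitted means
#' `mu`: Pearson `(y - mu)/sqrt(mu)` (the Poisson variance equals the
#' mean), response `y - mu`, and deviance
#' `sign(y - mu) * sqrt(2 * (y*log(y/mu) - (y - mu)))` with the convention
#' `0*log(0) = 0`.
#'
#' @param y non-negative counts.
#' @param mu fitted means, strictly positive.
#' @return numeric vector of residuals.
#' @export
pearson_residuals <- function(y, mu) {
  if (any(mu <= 0)) stop("fitted means must be positive", call. = FALSE)
  (y - mu) / sqrt(mu)
}

#' @rdname pearson_residuals
#' @export
response_residuals <- function(y, mu) y - mu

#' @rdname pearson_residuals
#' @export
deviance_residuals <- function(y, mu) {
  if (any(mu <= 0)) stop("fitted means must be positive", call. = FALSE)
  ylogy <- ifelse(y > 0, y * log(y / mu), 0)
  rad <- 2 * (ylogy - (y - mu))
  rad[rad < 0] <- 0  # tiny negatives from rounding when y ~= mu
  sign(y - mu) * sqrt(rad)
}

#' Regress out technical covariates and return the residual matrix
#'
#' Fits the Poisson GLM gene by gene against the supplied design and
#' assembles the chosen residuals into a cells x genes matrix. Pearson
#' residuals are the default and are what the downstream factorization
#' consumes; response and deviance residuals are available for robustness
#' checks.
#'
#' @param counts a [count_matrix].
#' @param design a `design_matrix` aligned to the same cells.
#' @param residual_type `"pearson"` (default), `"response"` or
#'   `"deviance"`.
#' @param fits optional precomputed list of per-gene fits (as returned in
#'   the `fits` attribute) to reuse across residual types.
#' @return A `residual_matrix` object: list with `residuals` (n x g,
#'   dimnames as the counts), `residual_type`, `design_provenance`,
#'   `converged` (per gene) and `fits` (per-gene fitted means, kept so
#'   other residual types can be derived without refitting).
#' @export
compute_residual_matrix <- function(counts, design,
                                    residual_type = c("pearson", "response",
                                                      "deviance"),
                                    fits = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(design, "design_matrix"))
  residual_type <- match.arg(residual_type)
  Y <- counts$counts
  if (nrow(Y) != nrow(design$matrix))
    stop("counts and design have different numbers of cells", call. = FALSE)
  if (is.null(fits)) {
    fits <- apply(Y, 2L, function(y) {
      f <- fit_poisson_glm(y, design)
      list(mu = f$fitted_means, converged = f$converged)
    })
  }
  resfun <- switch(residual_type,
                   pearson = pearson_residuals,
                   response = response_residuals,
                   deviance = deviance_residuals)
  R <- vapply(seq_len(ncol(Y)),
              function(j) resfun(Y[, j], fits[[j]]$mu),
              numeric(nrow(Y)))
  dimnames(R) <- dimnames(Y)
  structure(list(residuals = R, residual_type = residual_type,
                 design_provenance = design$source_covariates,
                 converged = vapply(fits, `[[`, logical(1L), "converged"),
                 fits = fits),
            class = "residual_matrix")
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("residual_matrix: %d cells x %d genes (%s residuals; %d/%d fits converged)\n",
              nrow(x$residuals), ncol(x$residuals), x$residual_type,
              sum(x$converged), length(x$converged)))
  invisible(x)
}
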