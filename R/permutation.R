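#' Shuffle the level assignments of one covariate
#'
#' Uniform random permutation of the cells' labels; level frequencies are
#' preserved exactly.
#'
#' @param covariates a [covariate_table].
#' @param covariate_name the categorical covariate to shuffle.
#' @param seed RNG seed.
#' @return the shuffled label vector (same class as the column).
#' @export
permute_labels <- function(covariates, covariate_name, seed = 1L) {
  col <- covariates[[covariate_name]]
  if (is.null(col)) stop("unknown covariate: ", covariate_name,
                         call. = FALSE)
  with_seed(seed, sample(col))
}

#' Empirical p-values of observed association scores
#'
#' For each (covariate level, factor) cell, the fraction of permuted
#' scores at least as large as the observed one:
#' `p = #(permuted >= observed) / n_perm` (no smoothing by default, so the
#' minimum attainable p is 0, reported as "< 1/n_perm" in printed output;
#' `smoothed = TRUE` uses `(r + 1) / (n_perm + 1)` instead). Each cell is
#' compared against its own permutation null; `pooled = TRUE` pools the
#' null across the factors of a level.
#'
#' @param observed_fca the observed `fca_table`.
#' @param permuted_fcas list of `fca_table`s (or plain matrices of the
#'   same shape) from label permutations.
#' @param smoothed add-one smoothing (default FALSE).
#' @param pooled pool the null across factors within each level (default
#'   FALSE).
#' @return matrix of p-values, covariate levels x factors.
#' @export
empirical_pvalues <- function(observed_fca, permuted_fcas,
                              smoothed = FALSE, pooled = FALSE) {
  obs <- if (inherits(observed_fca, "fca_table")) observed_fca$values
         else as.matrix(observed_fca)
  perms <- lapply(permuted_fcas, function(p)
    if (inherits(p, "fca_table")) p$values else as.matrix(p))
  if (!length(perms)) stop("need at least one permutation", call. = FALSE)
  if (!all(vapply(perms, function(p) all(dim(p) == dim(obs)), logical(1L))))
    stop("permuted tables must match the observed table's shape",
         call. = FALSE)
  n_perm <- length(perms)
  arr <- array(unlist(perms), dim = c(dim(obs), n_perm))
  pv <- obs
  for (i in seq_len(nrow(obs))) {
    if (pooled) {
      null_i <- as.vector(arr[i, , ])
      for (j in seq_len(ncol(obs)))
        pv[i, j] <- sum(null_i >= obs[i, j]) /
          (n_perm * ncol(obs))
    } else {
      for (j in seq_len(ncol(obs)))
        pv[i, j] <- sum(arr[i, j, ] >= obs[i, j]) / n_perm
    }
  }
  if (smoothed) pv <- (pv * n_perm + 1) / (n_perm + 1)
  pv
}

#' Count significant associations per covariate level
#'
#' @param pvalues matrix from [empirical_pvalues].
#' @param alpha significance level (default 0.05).
#' @return list with `per_level` (integer counts of p < alpha) and
#'   `mean` across levels. One significant factor per level is the ideal;
#'   larger counts suggest false positives, zero suggests a false
#'   negative.
#' @export
count_significant <- function(pvalues, alpha = 0.05) {
  counts <- rowSums(pvalues < alpha)
  list(per_level = counts, mean = mean(counts))
}

#' Gini coefficient of one covariate level's association scores
#'
#' The mean-absolute-difference form
#' `G = (1 / (2 n^2 xbar)) * sum_i sum_j |x_i - x_j|`, computed via the
#' equivalent sorted-order expression in O(n log n). Scores must be
#' non-negative with positive mean; `shift = TRUE` (default) translates
#' the vector by its minimum when negative values are present (the
#' standardized association scales can be negative, the inequality measure
#' cannot).
#'
#' @param values numeric vector (one covariate level's scores across
#'   factors).
#' @param shift shift to non-negativity when needed (default TRUE).
#' @return scalar in [0, 1).
#' @export
gini_level <- function(values, shift = TRUE) {
  x <- values
  if (any(x < 0)) {
    if (!shift) stop("Gini requires non-negative values", call. = FALSE)
    x <- x - min(x)
  }
  n <- length(x)
  xb <- mean(x)
  if (xb <= 0) stop("Gini requires a positive mean", call. = FALSE)
  xs <- sort(x)
  ## sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * xb)
}

#' Global Gini summary of an FCA table
#'
#' Per-level Gini coefficients and their unweighted mean. When the table
#' contains negative (e.g. standardized) scores the whole matrix is
#' shifted by its global minimum first, so all levels share one scale.
#'
#' @param fca an `fca_table` or plain levels x factors matrix.
#' @return list with `per_level` (named vector of G_k) and `global`
#'   (their mean).
#' @export
global_gini <- function(fca) {
  v <- if (inherits(fca, "fca_table")) fca$values else as.matrix(fca)
  if (any(v < 0)) v <- v - min(v)
  per <- apply(v, 1L, gini_level, shift = FALSE)
  list(per_level = per, global = mean(per))
}

#' Permutation benchmark of factor-covariate associations
#'
#' Shuffles the labels of each selected covariate `n_perm` times,
#' recomputes the full ensemble association score for the shuffled labels
#' each time, and summarizes: empirical p-values per (level, factor),
#' counts of significant factors per level, and observed vs mean permuted
#' global Gini.
#'
#' @param model a `factor_model`.
#' @param covariates a [covariate_table].
#' @param covariate_names categorical covariates to benchmark (default:
#'   all).
#' @param n_perm number of permutations (default 500).
#' @param alpha significance level (default 0.05).
#' @param seed base RNG seed; permutation b uses `seed + b`.
#' @param ... passed to [ensemble_fca] (classifiers, scaling, mean_type).
#' @return A `permutation_result`: list with `observed` (`fca_table`),
#'   `pvalues`, `n_significant` (list from [count_significant]),
#'   `gini_observed`, `gini_permuted` (per-permutation global Gini),
#'   `n_perm`, `alpha`, `seed`.
#' @export
permutation_benchmark <- function(model, covariates, covariate_names = NULL,
                                  n_perm = 500L, alpha = 0.05, seed = 1L,
                                  ...) {
  stopifnot(inherits(covariates, "covariate_table"))
  if (is.null(covariate_names))
    covariate_names <- categorical_covariates(covariates)
  observed <- ensemble_fca(model, covariates,
                           covariate_names = covariate_names, seed = seed,
                           ...)
  perms <- vector("list", n_perm)
  gini_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    shuffled <- covariates
    for (cov in covariate_names)
      shuffled[[cov]] <- permute_labels(covariates, cov,
                                        seed = seed + b)
    shuffled <- covariate_table(as.data.frame(shuffled),
                                rownames(covariates))
    fca_b <- ensemble_fca(model, shuffled,
                          covariate_names = covariate_names, seed = seed,
                          ...)
    ## align rows in case level order differs
    fca_b$values <- fca_b$values[rownames(observed$values), , drop = FALSE]
    perms[[b]] <- fca_b$values
    gini_perm[b] <- global_gini(fca_b$values)$global
  }
  pv <- empirical_pvalues(observed, perms)
  structure(list(observed = observed, pvalues = pv,
                 n_significant = count_significant(pv, alpha),
                 gini_observed = global_gini(observed)$global,
                 gini_permuted = gini_perm,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d permutations, alpha = %.3g\n",
              x$n_perm, x$alpha))
  cat(sprintf("  mean significant factors per level: %.2f\n",
              x$n_significant$mean))
  cat(sprintf("  global Gini: observed %.3f vs permuted mean %.3f\n",
              x$gini_observed, mean(x$gini_permuted)))
  cat(sprintf("  minimum attainable p-value: < %.3g\n", 1 / x$n_perm))
  invisible(x)
}
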