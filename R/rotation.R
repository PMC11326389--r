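#' Rotation settings
#'
#' @param kaiser_normalize row-normalize loadings by their communalities
#'   before rotation and un-normalize afterwards (default TRUE).
#' @param tol relative convergence tolerance on the rotation criterion
#'   (default 1e-5).
#' @param max_iter iteration cap (default 1000).
#' @param promax_power exponent of the promax pattern matrix (default 3,
#'   must be >= 2).
#' @return A `rotation_settings` list.
#' @export
rotation_settings <- function(kaiser_normalize = TRUE, tol = 1e-5,
                              max_iter = 1000L, promax_power = 3L) {
  stopifnot(tol > 0, promax_power >= 2)
  structure(list(kaiser_normalize = kaiser_normalize, tol = tol,
                 max_iter = as.integer(max_iter),
                 promax_power = as.integer(promax_power)),
            class = "rotation_settings")
}

#' PCA of a residual matrix by singular value decomposition
#'
#' Centers each gene (column), takes the thin SVD `X = U D V'` and keeps
#' the top `k` components. Scores are `U D` (cells x factors), loadings are
#' `V` (genes x factors). Each factor's sign is fixed so that its
#' largest-magnitude gene loading is positive, making the decomposition
#' deterministic.
#'
#' @param residuals a `residual_matrix` (or a plain numeric matrix,
#'   cells x genes).
#' @param k number of factors; must be <= min(n cells, n genes). Default 30.
#' @return A `factor_model`: list with `scores` (n x k), `loadings`
#'   (g x k), `rotation` (k x k, identity here), `explained_variance`
#'   (variance of each score column), `var_ratio` (fraction of total
#'   variance), `rotation_kind = "none"`.
#' @export
pca_svd <- function(residuals, k = 30L) {
  X <- if (inherits(residuals, "residual_matrix")) residuals$residuals
       else as.matrix(residuals)
  n <- nrow(X); g <- ncol(X)
  if (k > min(n, g))
    stop(sprintf("k = %d exceeds min(n cells, n genes) = %d", k, min(n, g)),
         call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  ## deterministic sign: largest-|loading| gene positive per factor
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  fnames <- paste0("F", seq_len(k))
  dimnames(scores) <- list(rownames(X), fnames)
  dimnames(loadings) <- list(colnames(X), fnames)
  structure(list(scores = scores, loadings = loadings,
                 rotation = diag(k),
                 explained_variance = stats::setNames(
                   sv$d[seq_len(k)]^2 / (n - 1), fnames),
                 var_ratio = stats::setNames(
                   sv$d[seq_len(k)]^2 / sum(sv$d^2), fnames),
                 rotation_kind = "none"),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d cells x %d factors (%d genes; rotation: %s)\n",
              nrow(x$scores), ncol(x$scores), nrow(x$loadings),
              x$rotation_kind))
  invisible(x)
}

#' Kaiser criterion of a loading matrix
#'
#' The varimax objective: the summed per-factor variance of
#' communality-scaled squared loadings,
#' `v = sum_j [ g * sum_i (l_ij^2/h_i^2)^2 - (sum_i l_ij^2/h_i^2)^2 ] / g^2`
#' where the communality `h_i^2 = sum_j l_ij^2`. Rows with zero communality
#' carry no information and are dropped with a warning.
#'
#' @param loadings numeric matrix, genes x factors.
#' @return scalar criterion value.
#' @export
kaiser_criterion <- function(loadings) {
  L <- as.matrix(loadings)
  h2 <- rowSums(L^2)
  if (any(h2 == 0)) {
    warning("dropping ", sum(h2 == 0), " zero-communality rows",
            call. = FALSE)
    L <- L[h2 > 0, , drop = FALSE]
    h2 <- h2[h2 > 0]
  }
  g <- nrow(L)
  W <- L^2 / h2  # h_i^2-scaled squared loadings
  sum((g * colSums(W^2) - colSums(W)^2) / g^2)
}

#' Varimax rotation by iterative SVD
#'
#' Finds the orthogonal rotation maximizing the Kaiser criterion of the
#' rotated loadings. With Kaiser normalization on, rows are scaled to unit
#' communality first and rescaled after. Each iteration updates
#' `B = L R`, `M = L'(B^3 - B diag(colSums(B^2))/g)`, and sets `R` to
#' `U V'` from the SVD of `M`; the trace criterion `sum(d)` is monotone
#' non-decreasing and iteration stops when its relative improvement falls
#' below `tol`.
#'
#' @param loadings numeric matrix, genes x factors (k >= 2; k = 1 returns
#'   the input with R = 1).
#' @param settings a [rotation_settings].
#' @return list with `loadings` (rotated), `rotmat` (orthogonal k x k) and
#'   `converged`.
#' @export
varimax_rotate <- function(loadings, settings = rotation_settings()) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 2L)
    return(list(loadings = L, rotmat = matrix(1, 1, 1), converged = TRUE))
  sc <- NULL
  if (settings$kaiser_normalize) {
    sc <- sqrt(rowSums(L^2))
    sc[sc == 0] <- 1
    L <- L / sc
  }
  g <- nrow(L)
  R <- diag(k)
  d <- 0
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    B <- L %*% R
    M <- crossprod(L, B^3 - B %*% diag(colSums(B^2) / g, k, k))
    sv <- svd(M)
    R <- sv$u %*% t(sv$v)
    d_new <- sum(sv$d)
    if (d_new < d * (1 + settings$tol)) { converged <- TRUE; break }
    d <- d_new
  }
  if (!converged)
    message("varimax: criterion still improving after ", settings$max_iter,
            " iterations; returning current iterate")
  Z <- L %*% R
  if (!is.null(sc)) Z <- Z * sc
  dimnames(Z) <- dimnames(loadings)
  list(loadings = Z, rotmat = R, converged = converged)
}

#' Promax oblique rotation
#'
#' Runs varimax first, then builds the ideal pattern matrix
#' `p_ij = |w_ij^(m+1)| / w_ij` (i.e. `sign(w) |w|^m`, default power m = 3)
#' from the row- and column-normalized varimax loadings, and solves the
#' least-squares problem `R = (L'L)^{-1} L' P` for the oblique rotation,
#' normalizing the columns of `R` to unit sum of squares. The returned
#' `rotmat` maps the *input* loadings to the promax solution (varimax and
#' promax steps composed).
#'
#' @inheritParams varimax_rotate
#' @return list with `loadings` (promax-rotated), `rotmat` (composed,
#'   generally non-orthogonal), `rotmat_promax` (the oblique step alone),
#'   `factor_correlation` (informational oblique factor correlation
#'   matrix) and `converged` (from the varimax step).
#' @export
promax_rotate <- function(loadings, settings = rotation_settings()) {
  L0 <- as.matrix(loadings)
  if (ncol(L0) < 2L)
    return(list(loadings = L0, rotmat = matrix(1, 1, 1),
                rotmat_promax = matrix(1, 1, 1),
                factor_correlation = matrix(1, 1, 1), converged = TRUE))
  vr <- varimax_rotate(L0, settings)
  L <- vr$loadings
  ## row/column normalization for the pattern target
  rn <- sqrt(rowSums(L^2)); rn[rn == 0] <- 1
  W <- L / rn
  cn <- sqrt(colSums(W^2)); cn[cn == 0] <- 1
  W <- sweep(W, 2L, cn, "/")
  m <- settings$promax_power
  P <- sign(W) * abs(W)^m
  XtX <- crossprod(L)
  if (rcond(XtX) < .Machine$double.eps * 100)
    stop("varimax loadings are collinear; promax rotation is singular",
         call. = FALSE)
  R <- solve(XtX, crossprod(L, P))
  R <- sweep(R, 2L, sqrt(colSums(R^2)), "/")
  Z <- L %*% R
  dimnames(Z) <- dimnames(loadings)
  Rinv <- solve(R)
  phi <- tcrossprod(Rinv)  # oblique factor correlation, informational
  list(loadings = Z, rotmat = vr$rotmat %*% R, rotmat_promax = R,
       factor_correlation = stats::cov2cor(phi), converged = vr$converged)
}

#' Apply a rotation matrix to a factor model
#'
#' Multiplies both the score and the loading matrix by `R`, following the
#' convention that rotated loadings are `L R` and rotated scores are
#' `S R`. For orthogonal `R` the reconstruction `S L'` is unchanged and
#' per-cell score norms are preserved; for oblique rotations the rotated
#' matrices are taken at face value by all downstream modules. Explained
#' variance is recomputed as the variance of each rotated score column, and
#' the deterministic sign convention is re-applied.
#'
#' @param model a `factor_model`.
#' @param R k x k rotation matrix.
#' @param rotation_kind label stored on the result.
#' @return The rotated `factor_model`.
#' @export
apply_rotation <- function(model, R, rotation_kind = "varimax") {
  stopifnot(inherits(model, "factor_model"))
  k <- ncol(model$scores)
  stopifnot(nrow(R) == k, ncol(R) == k)
  scores <- model$scores %*% R
  loadings <- model$loadings %*% R
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  fnames <- colnames(model$scores)
  dimnames(scores) <- list(rownames(model$scores), fnames)
  dimnames(loadings) <- list(rownames(model$loadings), fnames)
  ev <- apply(scores, 2L, stats::var)
  structure(list(scores = scores, loadings = loadings,
                 rotation = model$rotation %*% R,
                 explained_variance = ev,
                 var_ratio = ev / sum(model$explained_variance) *
                   sum(model$var_ratio),
                 rotation_kind = rotation_kind),
            class = "factor_model")
}

#' Factorize a residual matrix with rotated PCA
#'
#' Convenience wrapper: [pca_svd] followed by the chosen rotation of the
#' top-k loadings ([varimax_rotate] by default, [promax_rotate] or none).
#'
#' @param residuals a `residual_matrix` or numeric matrix (cells x genes).
#' @param k number of factors (default 30).
#' @param rotation `"varimax"` (default), `"promax"` or `"none"`.
#' @param settings a [rotation_settings].
#' @return A `factor_model`.
#' @export
factorize_residuals <- function(residuals, k = 30L,
                                rotation = c("varimax", "promax", "none"),
                                settings = rotation_settings()) {
  rotation <- match.arg(rotation)
  model <- pca_svd(residuals, k = k)
  if (rotation == "none") return(model)
  rot <- switch(rotation,
                varimax = varimax_rotate(model$loadings, settings),
                promax = promax_rotate(model$loadings, settings))
  apply_rotation(model, rot$rotmat, rotation_kind = rotation)
}

#' Write a factor model to a directory of CSV files
#'
#' Writes `scores.csv` (cells x factors), `loadings.csv` (genes x factors),
#' `rotation.csv` and `varexp.csv`.
#'
#' @param model a `factor_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_factor_model <- function(model, dir) {
  stopifnot(inherits(model, "factor_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$scores, file.path(dir, "scores.csv"))
  utils::write.csv(model$loadings, file.path(dir, "loadings.csv"))
  utils::write.csv(model$rotation, file.path(dir, "rotation.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(factor = names(model$explained_variance) %||%
                 paste0("F", seq_along(model$explained_variance)),
               explained_variance = unname(model$explained_variance),
               var_ratio = unname(model$var_ratio)),
    file.path(dir, "varexp.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a factor model written by [write_factor_model]
#'
#' @param dir directory containing `scores.csv`, `loadings.csv`,
#'   `rotation.csv`, `varexp.csv`.
#' @param rotation_kind label to store (not recorded in the CSVs).
#' @return A `factor_model`.
#' @export
read_factor_model <- function(dir, rotation_kind = "varimax") {
  rd <- function(f) as.matrix(utils::read.csv(file.path(dir, f),
                                              row.names = 1L,
                                              check.names = FALSE))
  ve <- utils::read.csv(file.path(dir, "varexp.csv"))
  structure(list(scores = rd("scores.csv"), loadings = rd("loadings.csv"),
                 rotation = as.matrix(utils::read.csv(
                   file.path(dir, "rotation.csv"), check.names = FALSE)),
                 explained_variance = stats::setNames(ve$explained_variance,
                                                      ve$factor),
                 var_ratio = stats::setNames(ve$var_ratio, ve$factor),
                 rotation_kind = rotation_kind),
            class = "factor_model")
}
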