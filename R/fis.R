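#' Two-cluster partition of one factor's scores
#'
#' 1-D k-means with k = 2, best of `nstart` restarts, deterministic given
#' the seed. Used by the cluster-based separability metrics.
#'
#' @param factor_scores numeric vector of one factor's scores across cells.
#' @param seed RNG seed (default 1).
#' @param nstart random restarts (default 10).
#' @return integer vector of cluster labels (1/2).
#' @export
kmeans2_partition <- function(factor_scores, seed = 1L, nstart = 10L) {
  if (stats::sd(factor_scores) == 0)
    stop("cannot partition constant scores", call. = FALSE)
  with_seed(seed,
            stats::kmeans(factor_scores, centers = 2L,
                          nstart = nstart)$cluster)
}

#' Variance ratio score (between- over within-cluster sum of squares)
#'
#' The raw BSS/WSS ratio of a two-group partition (the Calinski-Harabasz
#' statistic without its degrees-of-freedom factor). `chi = TRUE` applies
#' the (n-k)/(k-1) normalization.
#'
#' @param scores numeric vector.
#' @param labels cluster labels (2 groups).
#' @param chi apply the Calinski-Harabasz degrees-of-freedom factor
#'   (default FALSE).
#' @return scalar; larger = better separated clusters.
#' @export
vrs <- function(scores, labels, chi = FALSE) {
  labels <- as.integer(factor(labels))
  n <- length(scores)
  k <- length(unique(labels))
  gm <- mean(scores)
  bss <- sum(tapply(scores, labels, function(g) length(g) * (mean(g) - gm)^2))
  wss <- sum(tapply(scores, labels, function(g) sum((g - mean(g))^2)))
  r <- bss / wss
  if (chi) r <- r * (n - k) / (k - 1)
  r
}

#' Weighted variance ratio score (cluster-size independent)
#'
#' Separation measure insensitive to cluster sizes: the squared gap
#' between cluster means divided by the unweighted mean of the per-cluster
#' variances. `alternative = TRUE` averages per-cluster sums of squares
#' instead of variances.
#'
#' @inheritParams vrs
#' @param alternative use mean per-cluster SS in the denominator.
#' @return scalar; larger = better separated.
#' @export
wvrs <- function(scores, labels, alternative = FALSE) {
  labels <- as.integer(factor(labels))
  mu <- tapply(scores, labels, mean)
  if (length(mu) != 2L) stop("wvrs expects exactly 2 clusters", call. = FALSE)
  denom <- if (alternative)
    mean(tapply(scores, labels, function(g) sum((g - mean(g))^2)))
  else
    mean(tapply(scores, labels, stats::var))
  (mu[[1L]] - mu[[2L]])^2 / denom
}

#' Mean silhouette width of a two-cluster partition
#'
#' Per cell, `(NCD - ICD) / max(ICD, NCD)` where ICD is the mean distance
#' to the cell's own cluster and NCD the mean distance to the nearest other
#' cluster; averaged over cells. Computed with `cluster::silhouette` on the
#' 1-D Euclidean distances.
#'
#' @inheritParams vrs
#' @return scalar in [-1, 1].
#' @export
silhouette_sep <- function(scores, labels) {
  labels <- as.integer(factor(labels))
  sil <- cluster::silhouette(labels, stats::dist(scores))
  mean(sil[, "sil_width"])
}

#' Scaled inverse Davies-Bouldin index
#'
#' The Davies-Bouldin index (mean over clusters of the worst-case
#' `(S_i + S_j) / |c_i - c_j|`, with `S` the mean within-cluster distance
#' to the centroid) is >= 0 with 0 for perfectly separated clusters; it is
#' returned mapped through `1 / (1 + DBI)` so that higher means better,
#' bounded in (0, 1].
#'
#' @inheritParams vrs
#' @param raw return the unscaled DBI instead (default FALSE).
#' @return scalar in (0, 1] (or raw DBI >= 0).
#' @export
davies_bouldin_scaled <- function(scores, labels, raw = FALSE) {
  labels <- as.integer(factor(labels))
  cl <- sort(unique(labels))
  cent <- vapply(cl, function(c) mean(scores[labels == c]), numeric(1L))
  S <- vapply(cl, function(c) mean(abs(scores[labels == c] - cent[c])),
              numeric(1L))
  k <- length(cl)
  ratios <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (S[i] + S[j]) / abs(cent[i] - cent[j]), numeric(1L)))
  }, numeric(1L))
  dbi <- mean(ratios)
  if (raw) dbi else 1 / (1 + dbi)
}

#' Bimodality index from an equal-variance two-component Gaussian mixture
#'
#' Fits a two-component Gaussian mixture with tied variance to the factor
#' scores, computes the standardized gap `delta = |mu1 - mu2| / sigma` and
#' the bimodality index `BI = pi (1 - pi) delta` (with
#' `variant = "sqrt"` the classical `sqrt(pi (1 - pi)) delta`).
#'
#' @param scores numeric vector (n >= 10).
#' @param variant `"product"` (default) or `"sqrt"`.
#' @param seed unused placeholder kept for interface stability; the
#'   mixture fit (mclust, model "E") is deterministic.
#' @return list with `bi` and `fit` (mu1, mu2, sigma, pi, delta,
#'   degenerate flag).
#' @importFrom mclust Mclust mclustBIC
#' @export
bimodality_index <- function(scores, variant = c("product", "sqrt"),
                             seed = NULL) {
  variant <- match.arg(variant)
  if (length(scores) < 10L)
    stop("bimodality index needs at least 10 observations", call. = FALSE)
  fit <- mclust::Mclust(scores, G = 2L, modelNames = "E", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  mu <- fit$parameters$mean
  sigma <- sqrt(fit$parameters$variance$sigmasq[1L])
  p <- fit$parameters$pro[1L]
  degenerate <- FALSE
  floor_sigma <- 1e-6 * diff(range(scores))
  if (!is.finite(sigma) || sigma < floor_sigma) {
    sigma <- max(floor_sigma, .Machine$double.eps)
    degenerate <- TRUE
  }
  delta <- abs(mu[1L] - mu[2L]) / sigma
  bi <- if (variant == "product") p * (1 - p) * delta
        else sqrt(p * (1 - p)) * delta
  list(bi = unname(bi),
       fit = list(mu1 = unname(mu[1L]), mu2 = unname(mu[2L]),
                  sigma = unname(sigma), pi = unname(p),
                  delta = unname(delta), degenerate = degenerate))
}

#' Hartigan's dip statistic
#'
#' The maximum distance between the empirical distribution function and the
#' closest unimodal distribution function, computed with the iterative
#' greatest-convex-minorant / least-concave-majorant algorithm. Only the
#' statistic is returned (no p-value). Exact reference values: a uniform
#' grid of n distinct points has dip `1/(2n)`; two equal point masses have
#' dip `1/4` (the maximum).
#'
#' @param scores numeric vector.
#' @return scalar dip >= 0 (0 for fewer than 2 distinct values).
#' @export
dip_statistic <- function(scores) {
  x <- sort(scores[is.finite(scores)])
  n <- length(x)
  ux <- unique(x)
  if (length(ux) < 2L) return(0)
  w <- tabulate(match(x, ux)) / n
  Fx <- cumsum(w)      # ECDF at each unique value
  Fm <- Fx - w         # left limit F(x-)
  lo <- 1L; hi <- length(ux)
  D <- 0
  repeat {
    idx <- lo:hi
    if (length(idx) < 2L) break
    xs <- ux[idx]; fup <- Fx[idx]; fdn <- Fm[idx]
    gt <- chull_touch(xs, fdn, lower = TRUE)    # GCM fitted to F(x-)
    lt <- chull_touch(xs, fup, lower = FALSE)   # LCM fitted to F(x)
    gcurve <- stats::approx(xs[gt], fdn[gt], xout = xs)$y
    lcurve <- stats::approx(xs[lt], fup[lt], xout = xs)$y
    gap <- lcurve - gcurve
    d_g <- max(gap[gt]); d_l <- max(gap[lt])
    if (d_l > d_g) {
      xr <- max(lt[gap[lt] == d_l])
      xl <- max(gt[gt <= xr])
      d <- d_l
    } else {
      xl <- min(gt[gap[gt] == d_g])
      xr <- min(lt[lt >= xl])
      d <- d_g
    }
    if (d <= D) break
    left_dev <- if (xl >= 1L) max(abs(gcurve[1:xl] - fup[1:xl])) else 0
    right_dev <- if (xr <= length(idx))
      max(abs(lcurve[xr:length(idx)] - fdn[xr:length(idx)])) else 0
    D <- max(D, left_dev, right_dev)
    new_lo <- lo + xl - 1L; new_hi <- lo + xr - 1L
    if (new_lo == lo && new_hi == hi) break
    lo <- new_lo; hi <- new_hi
  }
  D / 2
}

## Touchpoint indices of the lower (convex minorant) or upper (concave
## majorant) hull of the points (x, y), x strictly increasing.
chull_touch <- function(x, y, lower = TRUE) {
  if (!lower) y <- -y
  m <- length(x)
  t <- integer(m); t[1L] <- 1L; nt <- 1L
  for (i in 2:m) {
    while (nt >= 2L) {
      a <- t[nt - 1L]; b <- t[nt]
      ## drop b if it lies on or above the segment a--i
      if ((y[b] - y[a]) * (x[i] - x[a]) >= (y[i] - y[a]) * (x[b] - x[a]))
        nt <- nt - 1L
      else break
    }
    nt <- nt + 1L; t[nt] <- i
  }
  t[seq_len(nt)]
}

#' Variance of factor scores as an effect size
#'
#' @param scores numeric vector.
#' @return sample variance.
#' @export
effect_size_variance <- function(scores) stats::var(scores)

## Rectify an association-score vector at zero and normalize it to a
## probability vector over covariate levels.
fca_probabilities <- function(fca_column) {
  p <- pmax(fca_column, 0)
  s <- sum(p)
  if (s == 0) return(rep(1 / length(p), length(p)))
  p / s
}

#' Simpson diversity index of a factor's association profile
#'
#' `D = sum(p_i^2)` on the factor's association scores across covariate
#' levels, rectified at zero and normalized to probabilities. 1 = the
#' factor is specific to a single level, 1/N = evenly spread.
#'
#' @param fca_column numeric vector: one factor's association scores
#'   across covariate levels.
#' @return scalar in (0, 1].
#' @export
simpson_index <- function(fca_column) {
  p <- fca_probabilities(fca_column)
  sum(p^2)
}

#' Shannon entropy of a factor's association profile
#'
#' `H = -sum(p_i log p_i)` with `0 log 0 = 0`, on the rectified and
#' normalized association scores; ranges from 0 (specific) to `log(N)`
#' (spread over all N levels). With `as_specificity = TRUE` (used in the
#' interpretability table) it is returned as `(log N - H) / log N` so that
#' higher = more specific, aligned with the Simpson index.
#'
#' @inheritParams simpson_index
#' @param as_specificity rescale so higher = more specific (default
#'   FALSE: return the raw entropy).
#' @return scalar entropy (or specificity in [0, 1]).
#' @export
shannon_specificity <- function(fca_column, as_specificity = FALSE) {
  p <- fca_probabilities(fca_column)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  if (!as_specificity) return(h)
  n <- length(p)
  if (n < 2L) return(1)
  (log(n) - h) / log(n)
}

#' Scaled variance of a factor within one covariate level
#'
#' `SV = Var(x_L) / Var(x)`: the variance of the factor's scores among the
#' cells of level L relative to the variance over all cells. Values near 1
#' mean the level is as variable as the whole population (homogeneous
#' factor); values near 0 mean the level pins the factor down.
#'
#' @param scores numeric vector over all cells.
#' @param level_mask logical vector selecting the level's cells (>= 2).
#' @return scalar >= 0.
#' @export
scaled_variance <- function(scores, level_mask) {
  if (sum(level_mask) < 2L)
    stop("covariate level needs at least 2 cells", call. = FALSE)
  v <- stats::var(scores)
  if (v == 0) stop("factor scores have zero variance", call. = FALSE)
  stats::var(scores[level_mask]) / v
}

#' Average scaled variance across the levels of one covariate
#'
#' Homogeneity measure: the arithmetic (default) or geometric mean of the
#' per-level scaled variances of a factor.
#'
#' @param scores numeric vector over all cells.
#' @param levels factor/character vector of covariate levels per cell.
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return scalar >= 0; near 1 when the factor ignores the covariate.
#' @export
asv_homogeneity <- function(scores, levels,
                            mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  levels <- droplevels(factor(levels))
  keep <- names(table(levels))[table(levels) >= 2L]
  sv <- vapply(keep, function(lv) scaled_variance(scores, levels == lv),
               numeric(1L))
  if (mean_type == "arithmetic") mean(sv)
  else exp(mean(log(pmax(sv, .Machine$double.eps))))
}

#' Build the factor interpretability score table
#'
#' Computes, per factor: separability (mean silhouette and bimodality
#' index, both on the factor's own two-cluster partition / mixture fit),
#' effect size (score variance), specificity (Simpson index of the
#' factor's association profile) and homogeneity (arithmetic-mean ASV per
#' categorical covariate). `all_metrics = TRUE` adds VRS, WVRS, the scaled
#' inverse Davies-Bouldin index, the dip statistic, Shannon specificity
#' and geometric-mean ASV.
#'
#' @param model a `factor_model`.
#' @param fca an `fca_table` for the same model (needed for specificity;
#'   may be NULL to skip those rows).
#' @param covariates a [covariate_table] (needed for homogeneity; may be
#'   NULL).
#' @param seed seed for the k-means partitions (default 1).
#' @param all_metrics include the full metric panel (default FALSE).
#' @return A `fis_table`: list with `values` (metric x factor, raw),
#'   `scaled` (the same matrix min-max scaled within each row) and
#'   `metric_names`.
#' @export
build_fis_table <- function(model, fca = NULL, covariates = NULL, seed = 1L,
                            all_metrics = FALSE) {
  stopifnot(inherits(model, "factor_model"))
  scores <- model$scores
  k <- ncol(scores)
  parts <- lapply(seq_len(k), function(j)
    kmeans2_partition(scores[, j], seed = seed))
  rows <- list()
  rows$silhouette <- vapply(seq_len(k), function(j)
    silhouette_sep(scores[, j], parts[[j]]), numeric(1L))
  rows$bimodality_index <- vapply(seq_len(k), function(j)
    bimodality_index(scores[, j])$bi, numeric(1L))
  rows$variance <- apply(scores, 2L, effect_size_variance)
  if (all_metrics) {
    rows$vrs <- vapply(seq_len(k), function(j)
      vrs(scores[, j], parts[[j]]), numeric(1L))
    rows$wvrs <- vapply(seq_len(k), function(j)
      wvrs(scores[, j], parts[[j]]), numeric(1L))
    rows$davies_bouldin_scaled <- vapply(seq_len(k), function(j)
      davies_bouldin_scaled(scores[, j], parts[[j]]), numeric(1L))
    rows$dip <- apply(scores, 2L, dip_statistic)
  }
  if (!is.null(fca)) {
    rows$simpson <- apply(fca$values, 2L, simpson_index)
    if (all_metrics)
      rows$shannon_specificity <- apply(fca$values, 2L,
                                        shannon_specificity,
                                        as_specificity = TRUE)
  }
  if (!is.null(covariates)) {
    for (cov in categorical_covariates(covariates)) {
      rows[[paste0("asv_", cov)]] <- apply(scores, 2L, asv_homogeneity,
                                           levels = covariates[[cov]])
      if (all_metrics)
        rows[[paste0("asv_geom_", cov)]] <-
          apply(scores, 2L, asv_homogeneity, levels = covariates[[cov]],
                mean_type = "geometric")
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- colnames(scores)
  scaled <- t(apply(values, 1L, minmax01))
  dimnames(scaled) <- dimnames(values)
  structure(list(values = values, scaled = scaled,
                 metric_names = rownames(values)),
            class = "fis_table")
}

#' @export
print.fis_table <- function(x, ...) {
  cat(sprintf("fis_table: %d metrics x %d factors\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a FIS table
#'
#' @param fis a `fis_table`.
#' @param path CSV output path for the raw values; a `*_scaled.csv`
#'   sibling carries the row-scaled presentation copy.
#' @return `path`, invisibly.
#' @export
write_fis <- function(fis, path) {
  stopifnot(inherits(fis, "fis_table"))
  utils::write.csv(fis$values, path)
  utils::write.csv(fis$scaled, sub("\\.csv$", "_scaled.csv", path))
  invisible(path)
}
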