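#' Parameters of the two-component Gaussian-mixture factor simulator
#'
#' Each simulated factor draws its component means from
#' `U(mu_min, mu_max)` and standard deviations from `U(sigma_min,
#' sigma_max)`, then assigns each cell to component 1 with probability
#' `p1` and samples its score from that component's normal distribution.
#'
#' @param n_cells cells per factor (default 10000).
#' @param n_factors factors per round (default 10).
#' @param n_rounds simulation rounds (default 100).
#' @param p1 proportion of component 1 (default 0.5).
#' @param mu_min,mu_max range of component means (defaults 0 and 4).
#' @param sigma_min,sigma_max range of component standard deviations
#'   (defaults 0.5 and 1).
#' @param seed RNG seed.
#' @return A `mixture_params` list.
#' @export
mixture_params <- function(n_cells = 10000L, n_factors = 10L,
                           n_rounds = 100L, p1 = 0.5,
                           mu_min = 0, mu_max = 4,
                           sigma_min = 0.5, sigma_max = 1, seed = 1L) {
  stopifnot(p1 > 0, p1 < 1, sigma_min > 0, sigma_max >= sigma_min,
            mu_max >= mu_min)
  structure(list(n_cells = as.integer(n_cells),
                 n_factors = as.integer(n_factors),
                 n_rounds = as.integer(n_rounds), p1 = p1,
                 mu_min = mu_min, mu_max = mu_max,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 seed = as.integer(seed)),
            class = "mixture_params")
}

#' Simulate factors from two-component Gaussian mixtures
#'
#' One round of the simulator: `n_factors` independent factors over
#' `n_cells` cells, each a two-component normal mixture with parameters
#' drawn per factor from the configured uniform ranges. The true component
#' labels, realized parameters and analytic between-component overlap are
#' returned alongside the scores.
#'
#' @param params a [mixture_params].
#' @return A `simulated_factors` list: `scores` (cells x factors),
#'   `component_labels` (same shape, values 1/2), `true_params`
#'   (data.frame: mu1, mu2, sigma1, sigma2, p1 per factor),
#'   `true_overlap` (per factor).
#' @export
simulate_mixture_factors <- function(params = mixture_params()) {
  stopifnot(inherits(params, "mixture_params"))
  with_seed(params$seed, {
    n <- params$n_cells; k <- params$n_factors
    scores <- matrix(NA_real_, n, k)
    labels <- matrix(NA_integer_, n, k)
    tp <- data.frame(mu1 = numeric(k), mu2 = numeric(k),
                     sigma1 = numeric(k), sigma2 = numeric(k),
                     p1 = rep(params$p1, k))
    ov <- numeric(k)
    for (j in seq_len(k)) {
      mu <- stats::runif(2L, params$mu_min, params$mu_max)
      sg <- stats::runif(2L, params$sigma_min, params$sigma_max)
      comp <- 1L + stats::rbinom(n, 1L, 1 - params$p1)
      scores[, j] <- stats::rnorm(n, mu[comp], sg[comp])
      labels[, j] <- comp
      tp[j, c("mu1", "mu2", "sigma1", "sigma2")] <- c(mu, sg)
      ov[j] <- gaussian_overlap(mu[1L], sg[1L], mu[2L], sg[2L])
    }
    colnames(scores) <- colnames(labels) <- paste0("F", seq_len(k))
    structure(list(scores = scores, component_labels = labels,
                   true_params = tp, true_overlap = ov,
                   params = params),
              class = "simulated_factors")
  })
}

#' Intersection point of two normal densities
#'
#' Solves `pdf1(c) = pdf2(c)`. With equal standard deviations the
#' intersection is the midpoint of the means; otherwise the quadratic is
#' solved and the root lying between the two means is returned (the other
#' root sits in a tail and is irrelevant for the overlap mass between the
#' components).
#'
#' @param mu1,sigma1,mu2,sigma2 component means and standard deviations.
#' @return scalar intersection point.
#' @export
gaussian_intersection <- function(mu1, sigma1, mu2, sigma2) {
  if (mu1 == mu2 && sigma1 == sigma2)
    stop("densities are identical; no unique intersection", call. = FALSE)
  if (mu1 == mu2)
    stop("equal means: intersection points are symmetric tail crossings, ",
         "overlap is not defined by a single cut point", call. = FALSE)
  if (sigma1 == sigma2) return((mu1 + mu2) / 2)
  a <- 1 / sigma1^2 - 1 / sigma2^2
  b <- -2 * (mu1 / sigma1^2 - mu2 / sigma2^2)
  cc <- mu1^2 / sigma1^2 - mu2^2 / sigma2^2 - 2 * log(sigma2 / sigma1)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real intersection found", call. = FALSE)
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  lo <- min(mu1, mu2); hi <- max(mu1, mu2)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside)) inside[1L] else roots[which.min(abs(roots - (lo + hi) / 2))]
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Overlap of two normal distributions
#'
#' The shared probability mass of two Gaussian components, evaluated at
#' their density intersection point `c` as
#' `O = 1 - (1/2) (erf((c - mu1)/(sqrt(2) sigma1)) - erf((c - mu2)/(sqrt(2) sigma2)))`
#' with components ordered so that `mu1 <= mu2` (the expression is
#' sign-sensitive). Exact when the densities cross once between the means
#' (always the case for equal standard deviations).
#'
#' @inheritParams gaussian_intersection
#' @return overlap in [0, 1].
#' @export
gaussian_overlap <- function(mu1, sigma1, mu2, sigma2) {
  if (mu1 > mu2) {  # order components so the erf expression applies
    tmp <- c(mu1, sigma1); mu1 <- mu2; sigma1 <- sigma2
    mu2 <- tmp[1L]; sigma2 <- tmp[2L]
  }
  cpt <- gaussian_intersection(mu1, sigma1, mu2, sigma2)
  o <- 1 - 0.5 * (erf((cpt - mu1) / (sqrt(2) * sigma1)) -
                    erf((cpt - mu2) / (sqrt(2) * sigma2)))
  min(max(o, 0), 1)
}

#' Correlation of interpretability metrics with true component overlap
#'
#' Runs the mixture simulator for `n_rounds` rounds; in each round computes
#' the requested metrics for every factor and the Pearson correlation of
#' each metric with the factors' true overlaps, then aggregates the
#' correlations (mean and sd) across rounds. Separability and effect-size
#' metrics are label-free; homogeneity (ASV) uses the true component
#' labels as a two-level covariate. Metrics that separate well should
#' correlate negatively with overlap; homogeneity should correlate
#' positively.
#'
#' @param params a [mixture_params]; round r is simulated with seed
#'   `params$seed + r`.
#' @param metrics subset of `c("silhouette", "bimodality_index", "dip",
#'   "variance", "vrs", "wvrs", "davies_bouldin_scaled", "asv_arithmetic",
#'   "asv_geometric")`.
#' @return A `metric_overlap_report`: data.frame with one row per metric
#'   (mean_correlation, sd_correlation, expected_sign) plus the raw
#'   per-round correlation matrix as attribute `rounds`.
#' @export
metric_overlap_correlation <- function(params = mixture_params(),
                                       metrics = c("silhouette",
                                                   "bimodality_index",
                                                   "variance",
                                                   "asv_arithmetic",
                                                   "asv_geometric")) {
  known <- c(silhouette = -1, bimodality_index = -1, dip = -1,
             variance = NA, vrs = -1, wvrs = -1,
             davies_bouldin_scaled = -1,
             asv_arithmetic = 1, asv_geometric = 1)
  metrics <- match.arg(metrics, names(known), several.ok = TRUE)
  cors <- matrix(NA_real_, params$n_rounds, length(metrics),
                 dimnames = list(NULL, metrics))
  for (r in seq_len(params$n_rounds)) {
    p_r <- params; p_r$seed <- params$seed + r
    sim <- simulate_mixture_factors(p_r)
    k <- ncol(sim$scores)
    vals <- matrix(NA_real_, k, length(metrics),
                   dimnames = list(NULL, metrics))
    for (j in seq_len(k)) {
      x <- sim$scores[, j]
      part <- kmeans2_partition(x, seed = p_r$seed + j)
      truth <- sim$component_labels[, j]
      for (m in metrics) {
        vals[j, m] <- switch(
          m,
          silhouette = silhouette_sep(x, part),
          bimodality_index = bimodality_index(x)$bi,
          dip = dip_statistic(x),
          variance = effect_size_variance(x),
          vrs = vrs(x, part),
          wvrs = wvrs(x, part),
          davies_bouldin_scaled = davies_bouldin_scaled(x, part),
          asv_arithmetic = asv_homogeneity(x, truth, "arithmetic"),
          asv_geometric = asv_homogeneity(x, truth, "geometric"))
      }
    }
    cors[r, ] <- apply(vals, 2L, stats::cor, y = sim$true_overlap)
  }
  report <- data.frame(metric = metrics,
                       mean_correlation = colMeans(cors),
                       sd_correlation = apply(cors, 2L, stats::sd),
                       expected_sign = known[metrics],
                       row.names = NULL)
  attr(report, "rounds") <- cors
  class(report) <- c("metric_overlap_report", "data.frame")
  report
}
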