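two_clumps <- function(n = 60, gap = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n / 2, 0, sd), rnorm(n / 2, gap, sd))
  list(x = x, labels = rep(1:2, each = n / 2))
}

test_that("k-means splits two clumps and rejects constant input", {
  tc <- two_clumps()
  part <- kmeans2_partition(tc$x, seed = 1)
  expect_equal(length(unique(part[1:30])), 1L)
  expect_equal(length(unique(part[31:60])), 1L)
  expect_error(kmeans2_partition(rep(1, 10)), "constant")
})

test_that("VRS matches the sum-of-squares decomposition oracle", {
  set.seed(2)
  for (i in 1:50) {
    x <- rnorm(40)
    lab <- sample(1:2, 40, replace = TRUE)
    if (length(unique(lab)) < 2) next
    tss <- sum((x - mean(x))^2)
    wss <- sum(unlist(tapply(x, lab, function(g) (g - mean(g))^2)))
    expect_equal(vrs(x, lab), (tss - wss) / wss, tolerance = 1e-10)
  }
  tc <- two_clumps()
  expect_gt(vrs(tc$x, tc$labels), 50)
  expect_equal(vrs(tc$x + 100, tc$labels), vrs(tc$x, tc$labels),
               tolerance = 1e-8)
})

test_that("WVRS is stable under class imbalance while VRS is not", {
  set.seed(3)
  balanced <- list(x = c(rnorm(100, 0, 1), rnorm(100, 6, 1)),
                   lab = rep(1:2, each = 100))
  skewed <- list(x = c(rnorm(190, 0, 1), rnorm(10, 6, 1)),
                 lab = rep(1:2, c(190, 10)))
  w_b <- wvrs(balanced$x, balanced$lab)
  w_s <- wvrs(skewed$x, skewed$lab)
  v_b <- vrs(balanced$x, balanced$lab)
  v_s <- vrs(skewed$x, skewed$lab)
  expect_lt(abs(w_b - w_s) / w_b, 0.35)
  expect_gt(abs(v_b - v_s) / v_b, 0.5)
  expect_equal(wvrs(balanced$x + 5, balanced$lab), w_b, tolerance = 1e-8)
  ## balanced equal-variance case: wvrs ~ 4 * vrs up to df effects
  expect_equal(w_b / v_b, 4, tolerance = 0.2)
})

test_that("silhouette matches the brute-force pairwise formula", {
  set.seed(4)
  x <- rnorm(50)
  lab <- rep(1:2, 25)
  expect_equal(silhouette_sep(x, lab), silhouette_bruteforce(x, lab),
               tolerance = 1e-10)
  tc <- two_clumps(gap = 20, sd = 0.1)
  expect_gt(silhouette_sep(tc$x, tc$labels), 0.95)
  ## label swap changes nothing
  expect_equal(silhouette_sep(tc$x, 3 - tc$labels),
               silhouette_sep(tc$x, tc$labels))
})

test_that("scaled Davies-Bouldin maps separation into (0, 1]", {
  tc <- two_clumps(gap = 50, sd = 0.01)
  expect_gt(davies_bouldin_scaled(tc$x, tc$labels), 0.99)
  set.seed(5)
  x <- rnorm(80)
  lab <- rep(1:2, 40)
  raw <- davies_bouldin_scaled(x, lab, raw = TRUE)
  expect_gte(raw, 0)
  expect_equal(davies_bouldin_scaled(x, lab), 1 / (1 + raw))
  ## definition-level oracle
  cent <- tapply(x, lab, mean)
  S <- tapply(seq_along(x), lab,
              function(i) mean(abs(x[i] - mean(x[i]))))
  expect_equal(raw, (S[[1]] + S[[2]]) / abs(cent[[1]] - cent[[2]]),
               tolerance = 1e-10)
})

test_that("bimodality index follows the printed formula on its own fit", {
  tc <- two_clumps(n = 400, gap = 4, sd = 1, seed = 6)
  out <- bimodality_index(tc$x)
  with(out$fit, {
    expect_equal(out$bi, pi * (1 - pi) * delta, tolerance = 1e-12)
    expect_equal(delta, abs(mu1 - mu2) / sigma, tolerance = 1e-12)
  })
  ## pi = 0.5, delta = 4 gives BI near 0.5 * 0.5 * 4 = 1
  expect_equal(out$bi, 1, tolerance = 0.15)
  sq <- bimodality_index(tc$x, variant = "sqrt")
  expect_equal(sq$bi,
               sqrt(sq$fit$pi * (1 - sq$fit$pi)) * sq$fit$delta,
               tolerance = 1e-12)
  ## unimodal data: tiny index
  set.seed(7)
  expect_lt(bimodality_index(rnorm(500))$bi, 0.6)
})

test_that("mixture parameters are recovered across replicates", {
  set.seed(8)
  mu <- c(0, 4); sigma <- 1; p <- 0.5; n <- 500
  est <- t(replicate(60, {
    comp <- rbinom(n, 1, p) + 1
    x <- rnorm(n, mu[comp], sigma)
    f <- bimodality_index(x)$fit
    c(mu1 = min(f$mu1, f$mu2), mu2 = max(f$mu1, f$mu2),
      sigma = f$sigma, pi = f$pi)
  }))
  means <- colMeans(est)
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(means["mu1"] - 0), 3 * se["mu1"] + 0.02)
  expect_lt(abs(means["mu2"] - 4), 3 * se["mu2"] + 0.02)
  expect_lt(abs(means["sigma"] - 1), 3 * se["sigma"] + 0.02)
  expect_lt(abs(means["pi"] - 0.5), 3 * se["pi"] + 0.02)
})

test_that("dip statistic reproduces exact analytic values", {
  expect_equal(dip_statistic(1:10), 1 / 20)           # uniform grid
  expect_equal(dip_statistic(rep(c(0, 1), each = 40)), 0.25)  # two masses
  expect_equal(dip_statistic(rep(3, 5)), 0)           # degenerate
  set.seed(9)
  expect_lt(dip_statistic(runif(1000)), 0.03)         # unimodal null
  expect_gt(dip_statistic(c(rnorm(300, 0, .05), rnorm(300, 5, .05))), 0.2)
  x <- rnorm(200)
  d <- dip_statistic(x)
  expect_gte(d, 1 / (2 * 200))
  expect_lte(d, 0.25)
  ## affine invariance
  expect_equal(dip_statistic(3 * x + 2), d, tolerance = 1e-12)
})

test_that("variance effect size behaves quadratically", {
  x <- rnorm(100)
  expect_equal(effect_size_variance(rep(2, 10)), 0)
  expect_equal(effect_size_variance(2 * x), 4 * effect_size_variance(x))
})

test_that("Simpson and Shannon agree with their closed forms", {
  onehot <- c(1, rep(0, 7))
  expect_equal(simpson_index(onehot), 1)
  expect_equal(simpson_index(rep(1, 5)), 1 / 5)
  expect_equal(shannon_specificity(onehot), 0)
  expect_equal(shannon_specificity(rep(1, 6)), log(6))
  expect_equal(shannon_specificity(onehot, as_specificity = TRUE), 1)
  ## entropy never exceeds log(N), also for rectified negative entries
  set.seed(10)
  for (i in 1:20) {
    v <- rnorm(8)
    expect_lte(shannon_specificity(v), log(8) + 1e-12)
    if (any(v > 0)) {
      p <- pmax(v, 0) / sum(pmax(v, 0))  # rectified probabilities
      expect_equal(simpson_index(v), sum(p^2), tolerance = 1e-12)
    } else {
      ## no positive mass: uniform fallback
      expect_equal(simpson_index(v), 1 / 8)
    }
  }
})

test_that("scaled variance and ASV capture homogeneity", {
  set.seed(11)
  x <- rnorm(400)
  grp <- sample(c("a", "b", "c", "d"), 400, replace = TRUE)
  ## random subsets are as variable as the whole
  expect_equal(scaled_variance(x, grp == "a"), 1, tolerance = 0.35)
  expect_equal(asv_homogeneity(x, grp), 1, tolerance = 0.25)
  ## a level with constant scores has SV = 0
  x2 <- x; x2[grp == "a"] <- 5
  expect_equal(scaled_variance(x2, grp == "a"), 0)
  ## two point masses split by a 2-level covariate: low ASV
  x3 <- rep(c(0, 1), each = 200)
  g3 <- rep(c("u", "v"), each = 200)
  expect_lt(asv_homogeneity(x3, g3), 0.5)
  ## AM >= GM always
  for (i in 1:10) {
    xr <- rnorm(200); gr <- sample(c("p", "q", "r"), 200, TRUE)
    expect_gte(asv_homogeneity(xr, gr) + 1e-12,
               asv_homogeneity(xr, gr, "geometric"))
  }
  expect_error(scaled_variance(rep(1, 10), c(TRUE, TRUE, rep(FALSE, 8))),
               "zero variance")
})

test_that("separability metrics are invariant to positive affine maps", {
  tc <- two_clumps(n = 80, gap = 3, sd = 1, seed = 12)
  x <- tc$x; lab <- tc$labels
  y <- 2.5 * x + 7
  expect_equal(silhouette_sep(y, lab), silhouette_sep(x, lab),
               tolerance = 1e-10)
  expect_equal(vrs(y, lab), vrs(x, lab), tolerance = 1e-10)
  expect_equal(wvrs(y, lab), wvrs(x, lab), tolerance = 1e-10)
  expect_equal(davies_bouldin_scaled(y, lab),
               davies_bouldin_scaled(x, lab), tolerance = 1e-10)
  expect_equal(dip_statistic(y), dip_statistic(x), tolerance = 1e-12)
  expect_equal(bimodality_index(y)$bi, bimodality_index(x)$bi,
               tolerance = 1e-6)
  ## variance is the exception: it scales with the square
  expect_equal(effect_size_variance(y), 2.5^2 * effect_size_variance(x))
})

test_that("the FIS table flags a planted bimodal factor and row-scales", {
  set.seed(13)
  n <- 300
  scores <- cbind(F1 = c(rnorm(n / 2, 0), rnorm(n / 2, 5)),
                  F2 = rnorm(n),
                  F3 = rnorm(n))
  model <- structure(list(scores = scores,
                          loadings = matrix(rnorm(30), 10, 3,
                                            dimnames = list(paste0("g", 1:10),
                                                            colnames(scores)))),
                     class = "factor_model")
  cov <- covariate_table(data.frame(grp = rep(c("a", "b"), each = n / 2)),
                         paste0("c", 1:n))
  fca <- ensemble_fca(model, cov, seed = 1)
  fis <- build_fis_table(model, fca, cov, seed = 1, all_metrics = TRUE)
  expect_gt(fis$values["silhouette", "F1"],
            max(fis$values["silhouette", c("F2", "F3")]))
  expect_gt(fis$values["bimodality_index", "F1"],
            max(fis$values["bimodality_index", c("F2", "F3")]))
  expect_gt(fis$values["variance", "F1"],
            max(fis$values["variance", c("F2", "F3")]))
  expect_lt(fis$values["asv_grp", "F1"],
            min(fis$values["asv_grp", c("F2", "F3")]))
  ## row scaling maps each row onto [0, 1]
  expect_equal(unname(apply(fis$scaled, 1, min)),
               rep(0, nrow(fis$scaled)))
  expect_equal(unname(apply(fis$scaled, 1, max)),
               rep(1, nrow(fis$scaled)))
  ## duplicated factor column gives identical FIS columns
  m2 <- model; m2$scores <- cbind(scores, F4 = scores[, "F1"])
  m2$loadings <- cbind(model$loadings, F4 = model$loadings[, 1])
  fis2 <- build_fis_table(m2, NULL, cov, seed = 1)
  expect_equal(fis2$values[, "F4"], fis2$values[, "F1"],
               tolerance = 1e-6)
})
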