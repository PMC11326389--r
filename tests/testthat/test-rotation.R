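## planar rotation by angle theta (radians)
rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

test_that("rank-2 residuals are recovered exactly by a k=2 PCA", {
  set.seed(1)
  S <- matrix(rnorm(80 * 2), 80, 2)
  L <- matrix(rnorm(30 * 2), 30, 2)
  X <- S %*% t(L)
  m <- pca_svd(X, k = 2)
  recon <- m$scores %*% t(m$loadings)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_lt(norm(Xc - recon, "F") / norm(Xc, "F"), 1e-8)
})

test_that("PCA is equivariant under gene permutation and bounds k", {
  set.seed(2)
  X <- matrix(rnorm(40 * 12), 40, 12)
  colnames(X) <- paste0("g", 1:12)
  m1 <- pca_svd(X, k = 4)
  perm <- sample(12)
  m2 <- pca_svd(X[, perm], k = 4)
  expect_equal(m2$scores, m1$scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m2$loadings, m1$loadings[perm, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pca_svd(X, k = 13), "exceeds")
})

test_that("isotropic noise spreads variance evenly across components", {
  set.seed(3)
  X <- matrix(rnorm(400 * 60), 400, 60)
  m <- pca_svd(X, k = 1)
  ## leading share of variance stays near 1/min(n, g) for pure noise
  expect_lt(m$var_ratio[1L], 3 / 60)
  expect_gt(m$var_ratio[1L], 1 / 60)
})

test_that("Kaiser criterion handles degenerate and permuted input", {
  set.seed(4)
  L <- matrix(rnorm(60), 20, 3)
  expect_equal(kaiser_criterion(L[, 1L, drop = FALSE]), 0)
  expect_equal(kaiser_criterion(L[sample(20), ]), kaiser_criterion(L))
})

test_that("varimax returns an orthogonal matrix and never lowers the criterion", {
  set.seed(5)
  for (rep in 1:5) {
    L <- matrix(rnorm(50 * 4), 50, 4)
    out <- varimax_rotate(L)
    expect_lt(max(abs(crossprod(out$rotmat) - diag(4))), 1e-8)
    expect_gte(kaiser_criterion(out$loadings),
               kaiser_criterion(L) - 1e-9)
  }
})

test_that("perfectly sparse loadings are a varimax fixed point", {
  L <- rbind(diag(3) * 2, diag(3) * -1, diag(3))
  out <- varimax_rotate(L)
  ## rotation is identity up to column permutation and sign
  R <- abs(out$rotmat)
  expect_equal(sort(round(R, 6))[(9 - 2):9], rep(1, 3), tolerance = 1e-6)
  expect_equal(kaiser_criterion(out$loadings), kaiser_criterion(L),
               tolerance = 1e-9)
})

test_that("k=2 varimax matches a brute-force scan over planar angles", {
  set.seed(6)
  L <- matrix(rnorm(40 * 2), 40, 2)
  out <- varimax_rotate(L, rotation_settings(tol = 1e-10))
  v_mine <- kaiser_criterion(out$loadings)
  thetas <- seq(0, pi / 2, by = 0.01 * pi / 180)
  v_grid <- vapply(thetas, function(th) kaiser_criterion(L %*% rot2(th)),
                   numeric(1L))
  expect_lt(abs(v_mine - max(v_grid)), 1e-6)
})

test_that("varimax agrees with the reference implementation in stats", {
  set.seed(7)
  L <- matrix(rnorm(80 * 5), 80, 5)
  mine <- varimax_rotate(L)
  ref <- stats::varimax(L, normalize = TRUE, eps = 1e-5)
  expect_equal(kaiser_criterion(mine$loadings),
               kaiser_criterion(unclass(ref$loadings)), tolerance = 1e-7)
})

test_that("varimax is idempotent up to permutation and sign", {
  set.seed(8)
  L <- matrix(rnorm(60 * 4), 60, 4)
  once <- varimax_rotate(L, rotation_settings(tol = 1e-9))
  twice <- varimax_rotate(once$loadings, rotation_settings(tol = 1e-9))
  ## the second rotation must be a signed permutation
  R <- abs(twice$rotmat)
  expect_equal(unname(colSums(R > 1 - 1e-4)), rep(1L, 4))
  expect_equal(kaiser_criterion(twice$loadings),
               kaiser_criterion(once$loadings), tolerance = 1e-6)
})

test_that("promax columns are unit norm and sparse input is a fixed point", {
  set.seed(9)
  L <- matrix(rnorm(70 * 4), 70, 4)
  out <- promax_rotate(L)
  expect_equal(unname(colSums(out$rotmat_promax^2)), rep(1, 4),
               tolerance = 1e-8)
  ## exactly sparse +-1 loadings: promax stays at the varimax solution
  Ls <- rbind(diag(4), -diag(4), diag(4))
  outs <- promax_rotate(Ls)
  vs <- varimax_rotate(Ls)
  expect_equal(abs(outs$loadings), abs(vs$loadings), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("promax tracks the reference oblique solution", {
  set.seed(10)
  ## loadings with a genuine simple structure for a meaningful rotation
  B <- matrix(0, 60, 3)
  B[1:20, 1] <- runif(20, .5, 1); B[21:40, 2] <- runif(20, .5, 1)
  B[41:60, 3] <- runif(20, .5, 1)
  L <- B + matrix(rnorm(180, sd = 0.05), 60, 3)
  mine <- promax_rotate(L)
  ref <- stats::promax(L, m = 4)
  ## same simple structure: matched columns correlate strongly
  cc <- abs(cor(mine$loadings, unclass(ref$loadings)))
  expect_true(all(apply(cc, 1L, max) > 0.95))
})

test_that("orthogonal rotation preserves reconstruction and norms", {
  set.seed(11)
  X <- matrix(rnorm(50 * 20), 50, 20)
  m <- pca_svd(X, k = 4)
  out <- varimax_rotate(m$loadings)
  rotated <- apply_rotation(m, out$rotmat, "varimax")
  expect_equal(rotated$scores %*% t(rotated$loadings),
               m$scores %*% t(m$loadings), tolerance = 1e-6)
  expect_equal(rowSums(rotated$scores^2), rowSums(m$scores^2),
               tolerance = 1e-8)
  ident <- apply_rotation(m, diag(4), "none")
  expect_equal(ident$scores, m$scores)
})

test_that("rotated factors on the fixture match lines one-to-one, unlike raw log-count PCA", {
  fx <- default_fixture()
  pl <- default_pipeline()
  sig_line <- pl$calls$significant[paste0("line:line", 1:3), ]
  expect_equal(unname(rowSums(sig_line)), rep(1, 3))
  tops <- apply(pl$fca$values[paste0("line:line", 1:3), ], 1L, which.max)
  expect_equal(length(unique(tops)), 3L)
  ## log-count PCA without covariate removal: leading factor tracks depth
  raw <- pca_svd(log1p(fx$counts$counts), k = 10)
  corr <- factor_covariate_correlation(raw, fx$covariates)
  expect_true("F1" %in% corr$flagged)
})
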