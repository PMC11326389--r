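## scores with one factor that separates the classes cleanly
planted_scores <- function(n = 200, k = 6, j = 3, gap = 3, seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * k), n, k,
                   dimnames = list(NULL, paste0("F", 1:k)))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  scores[labels, j] <- scores[labels, j] + gap
  list(scores = scores, labels = labels, j = j)
}

test_that("each importance backend singles out a planted factor", {
  p <- planted_scores()
  for (imp in list(importance_logistic(p$scores, p$labels),
                   importance_auc(p$scores, p$labels),
                   importance_tree(p$scores, p$labels, "decision_tree"),
                   importance_tree(p$scores, p$labels,
                                   "gradient_boosted_trees"))) {
    expect_equal(unname(which.max(imp)), p$j)
  }
})

test_that("tree importances are a probability-like vector", {
  p <- planted_scores()
  for (mod in c("decision_tree", "gradient_boosted_trees")) {
    imp <- importance_tree(p$scores, p$labels, mod)
    expect_true(all(imp >= 0))
    expect_lte(sum(imp), 1 + 1e-9)
  }
})

test_that("single-class labels are rejected", {
  p <- planted_scores()
  expect_error(importance_logistic(p$scores, rep(TRUE, 200)),
               "single class")
  expect_error(importance_auc(p$scores, rep(FALSE, 200)), "single class")
})

test_that("AUC follows the Mann-Whitney U relation", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "F1"))
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(unname(importance_auc(x, labels)), 1)  # U = 4, n0 n1 = 4
  ## identical distributions give ~0.5 before rectification
  set.seed(2)
  y <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "F1"))
  expect_lt(importance_auc(y, rep(c(TRUE, FALSE), 1000))[1L], 0.55)
})

test_that("U-statistic AUC equals explicit ROC integration", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    x <- rnorm(n)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    a_u <- importance_auc(matrix(x, dimnames = list(NULL, "F1")), labels)
    ## trapezoid integration of the empirical ROC curve
    thr <- c(Inf, sort(unique(x), decreasing = TRUE), -Inf)
    tpr <- vapply(thr, function(t) mean(x[labels] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(x[!labels] >= t), numeric(1))
    auc_roc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(unname(a_u), max(auc_roc, 1 - auc_roc),
                 tolerance = 1e-10)
  }
})

test_that("collinear duplicated factors share the signal", {
  p <- planted_scores()
  dup <- cbind(p$scores, dup = p$scores[, p$j])
  imp <- importance_auc(dup, p$labels)
  expect_equal(unname(imp[p$j]), unname(imp["dup"]))
  expect_true(which.max(imp) %in% c(p$j, ncol(dup)))
})

test_that("importance scaling matches the printed transforms", {
  expect_equal(scale_importances(c(1, 2, 3), "minmax"), c(0, 0.5, 1))
  expect_equal(scale_importances(c(10, 30, 20), "rank"),
               c(1 / 3, 1, 2 / 3))
  z <- scale_importances(rnorm(10) * 4 + 2, "standardize")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(scale_importances(rep(2, 5), "standardize"), rep(0, 5))
})

test_that("Otsu threshold separates well-separated clumps", {
  t1 <- otsu_threshold(c(0, 0, 0, 10, 10))
  expect_gt(t1, 0); expect_lt(t1, 10)
  set.seed(4)
  x <- c(rnorm(300, 0), rnorm(300, 8))
  t2 <- otsu_threshold(x)
  expect_gt(t2, 2); expect_lt(t2, 6)
  expect_error(otsu_threshold(rep(1, 10)), "constant")
})

test_that("Otsu equals a brute-force scan over all candidate thresholds", {
  set.seed(5)
  for (i in 1:50) {
    x <- c(rnorm(30, 0), rnorm(sample(5:30, 1), sample(2:8, 1)))
    thr <- otsu_threshold(x)
    cand <- (sort(x)[-1] + sort(x)[-length(x)]) / 2
    best <- max(vapply(cand, function(t) between_class_variance(x, t),
                       numeric(1)))
    expect_equal(between_class_variance(x, thr), best, tolerance = 1e-12)
  }
})

test_that("association calls binarize consistently with the threshold", {
  vals <- rbind("a:x" = c(5, 0, 0), "a:y" = c(0, 5, 0), "a:z" = c(0, 0, 5))
  colnames(vals) <- paste0("F", 1:3)
  fca <- structure(list(values = vals, scaling_method = "minmax",
                        mean_type = "arithmetic", classifier_set = "auc",
                        covariate = rep("a", 3)), class = "fca_table")
  calls <- call_associations(fca)
  expect_equal(unname(rowSums(calls$significant)), rep(1, 3))
  expect_equal(calls$significant == 1, vals > calls$threshold)
  high <- call_associations(fca, threshold = 10)
  expect_equal(high$unannotated_factors, paste0("F", 1:3))
})

test_that("complementary one-vs-rest levels pick the same top factor", {
  p <- planted_scores(n = 150, seed = 6)
  model <- structure(list(scores = p$scores), class = "factor_model")
  cov <- covariate_table(data.frame(grp = ifelse(p$labels, "in", "out")),
                         paste0("c", 1:150))
  fca <- ensemble_fca(model, cov, seed = 1)
  tops <- apply(fca$values, 1L, which.max)
  expect_equal(unname(tops[1L]), unname(tops[2L]))
  expect_equal(unname(tops[1L]), p$j)
})

test_that("shuffling labels lowers the top association score", {
  p <- planted_scores(n = 120, seed = 7)
  model <- structure(list(scores = p$scores), class = "factor_model")
  cov <- covariate_table(data.frame(grp = ifelse(p$labels, "in", "out")),
                         paste0("c", 1:120))
  observed <- max(ensemble_fca(model, cov, seed = 1)$values)
  wins <- 0L
  for (s in 1:20) {
    shuf <- covariate_table(
      data.frame(grp = permute_labels(cov, "grp", seed = s)),
      rownames(cov))
    if (max(ensemble_fca(model, shuf, seed = 1)$values) < observed)
      wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("the FCA table is invariant to factor column order", {
  p <- planted_scores(n = 100, k = 4, j = 2, seed = 8)
  cov <- covariate_table(data.frame(grp = ifelse(p$labels, "in", "out")),
                         paste0("c", 1:100))
  m1 <- structure(list(scores = p$scores), class = "factor_model")
  perm <- c(3, 1, 4, 2)
  m2 <- structure(list(scores = p$scores[, perm]), class = "factor_model")
  f1 <- ensemble_fca(m1, cov, seed = 1)
  f2 <- ensemble_fca(m2, cov, seed = 1)
  expect_equal(f2$values, f1$values[, perm], tolerance = 1e-8)
})

test_that("geometric mean is refused with standardized scaling", {
  p <- planted_scores(n = 60, seed = 9)
  model <- structure(list(scores = p$scores), class = "factor_model")
  cov <- covariate_table(data.frame(grp = ifelse(p$labels, "in", "out")),
                         paste0("c", 1:60))
  expect_error(ensemble_fca(model, cov, mean_type = "geometric"),
               "minmax or rank")
  f <- ensemble_fca(model, cov, scaling = "rank",
                    mean_type = "geometric", seed = 1)
  expect_true(all(is.finite(f$values)))
})

test_that("the ensemble matches the best member on the fixture", {
  pl <- default_pipeline()
  fx <- default_fixture()
  members <- c("logistic", "auc", "decision_tree",
               "gradient_boosted_trees")
  dev_from_one <- function(cls) {
    fca <- ensemble_fca(pl$model, fx$covariates, classifiers = cls,
                        covariate_names = "line", seed = 1)
    counts <- rowSums(call_associations(fca)$significant)
    mean(abs(counts - 1))
  }
  ens <- dev_from_one(members)
  singles <- vapply(members, dev_from_one, numeric(1))
  expect_lte(ens, max(singles))
})
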