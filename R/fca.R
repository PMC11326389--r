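#' Per-factor importances from a joint logistic regression
#'
#' Fits one logistic model of the binary label on all factor scores jointly
#' and returns the absolute coefficient of each factor (the change in
#' log-odds of the covariate level per unit of factor score).
#'
#' @param scores numeric matrix, cells x factors.
#' @param labels logical or 0/1 vector, one per cell; both classes must be
#'   present.
#' @return numeric k-vector of importances.
#' @export
importance_logistic <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class", call. = FALSE)
  df <- data.frame(.y = labels, scores, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = 50L)))
  co <- fit$coefficients[-1L]
  co[is.na(co)] <- 0  # aliased (collinear) factors carry no extra signal
  stats::setNames(abs(co), colnames(scores))
}

#' Per-factor importances from tree models
#'
#' Impurity-decrease importances from either a single decision tree
#' (`rpart`, Gini impurity) or gradient-boosted trees (`xgboost`, gain).
#' Importances are non-negative and normalized to sum to one (all zero when
#' the model makes no split).
#'
#' @inheritParams importance_logistic
#' @param model `"decision_tree"` or `"gradient_boosted_trees"`.
#' @param seed RNG seed for the boosted model (default 1).
#' @param nrounds boosting rounds for `xgboost` (default 50).
#' @return numeric k-vector of importances summing to 1 (or all 0).
#' @export
importance_tree <- function(scores, labels,
                            model = c("decision_tree",
                                      "gradient_boosted_trees"),
                            seed = 1L, nrounds = 50L) {
  model <- match.arg(model)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class", call. = FALSE)
  k <- ncol(scores)
  fnames <- colnames(scores) %||% paste0("F", seq_len(k))
  out <- stats::setNames(rep(0, k), fnames)
  if (model == "decision_tree") {
    df <- data.frame(.y = factor(labels), scores, check.names = FALSE)
    fit <- rpart::rpart(.y ~ ., data = df, method = "class")
    vi <- fit$variable.importance
    if (!is.null(vi) && length(vi)) out[names(vi)] <- vi
  } else {
    with_seed(seed, {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(scores), label = labels)
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 6L,
                      eta = 0.3, nthread = 1L),
        data = dtrain, nrounds = nrounds, verbose = 0)
      imp <- xgboost::xgb.importance(model = bst)
      if (!is.null(imp) && nrow(imp))
        out[imp$Feature] <- imp$Gain
    })
  }
  s <- sum(out)
  if (s > 0) out <- out / s
  out
}

#' Per-factor AUC importances via the Mann-Whitney U relation
#'
#' For each factor independently, the area under the ROC curve of
#' thresholding that factor for the target class, computed as
#' `AUC = U / (n0 * n1)` from the Mann-Whitney U statistic, then rectified
#' as `max(AUC, 1 - AUC)` since factor signs are arbitrary.
#'
#' @inheritParams importance_logistic
#' @return numeric k-vector of rectified AUCs in [0.5, 1].
#' @export
importance_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  auc <- apply(scores, 2L, function(x) {
    r <- rank(x)
    u <- sum(r[labels]) - n1 * (n1 + 1) / 2
    u / (n0 * n1)
  })
  pmax(auc, 1 - auc)
}

#' Scale a vector of raw importances
#'
#' `standardize`: zero mean, unit variance (all zeros if the input is
#' constant); `minmax`: linear map to [0, 1]; `rank`: average ranks divided
#' by the vector length.
#'
#' @param raw numeric vector.
#' @param method `"standardize"`, `"minmax"` or `"rank"`.
#' @return scaled numeric vector.
#' @export
scale_importances <- function(raw, method = c("standardize", "minmax",
                                              "rank")) {
  method <- match.arg(method)
  switch(method,
         standardize = {
           s <- stats::sd(raw)
           if (s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
         },
         minmax = minmax01(raw),
         rank = rank(raw, ties.method = "average") / length(raw))
}

#' Ensemble factor-covariate association scores
#'
#' For every level of every categorical covariate, trains the classifier
#' ensemble (logistic regression, per-factor AUC, decision tree, gradient
#' boosting) on one-vs-rest labels, scales each classifier's k-vector of
#' importances across factors, and averages them into one association score
#' per factor. Rows of the result are labelled `covariate:level`.
#'
#' @param model a `factor_model`.
#' @param covariates a [covariate_table] aligned to the model's cells; only
#'   categorical columns are used. Levels with fewer than 2 cells are
#'   dropped with a message.
#' @param classifiers subset of
#'   `c("logistic", "auc", "decision_tree", "gradient_boosted_trees")`.
#' @param scaling per-row scaling method (default `"standardize"`).
#' @param mean_type `"arithmetic"` (default) or `"geometric"`; the
#'   geometric mean requires non-negative scaled values and is therefore
#'   only allowed with `"minmax"` or `"rank"` scaling.
#' @param covariate_names covariates to use (default: all categorical).
#' @param seed seed for the boosted-tree member (default 1).
#' @return An `fca_table`: list with `values` (levels x factors matrix),
#'   `scaling_method`, `mean_type`, `classifier_set`, `covariate` (source
#'   covariate of each row).
#' @export
ensemble_fca <- function(model, covariates,
                         classifiers = c("logistic", "auc", "decision_tree",
                                         "gradient_boosted_trees"),
                         scaling = c("standardize", "minmax", "rank"),
                         mean_type = c("arithmetic", "geometric"),
                         covariate_names = NULL, seed = 1L) {
  stopifnot(inherits(model, "factor_model"))
  scaling <- match.arg(scaling)
  mean_type <- match.arg(mean_type)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (mean_type == "geometric" && scaling == "standardize")
    stop("geometric mean requires non-negative scaled values; ",
         "use minmax or rank scaling", call. = FALSE)
  if (!inherits(covariates, "covariate_table"))
    covariates <- covariate_table(covariates, rownames(model$scores))
  if (nrow(covariates) != nrow(model$scores))
    stop("covariates and scores have different numbers of cells",
         call. = FALSE)
  cats <- categorical_covariates(covariates)
  if (!is.null(covariate_names)) cats <- intersect(covariate_names, cats)
  if (!length(cats))
    stop("no categorical covariates available for association scoring",
         call. = FALSE)
  scores <- model$scores
  rows <- list(); row_cov <- character()
  for (cov in cats) {
    f <- droplevels(covariates[[cov]])
    tab <- table(f)
    lev <- names(tab)[tab >= 2L]
    if (length(lev) < length(tab))
      message("dropping levels with < 2 cells in '", cov, "': ",
              paste(setdiff(names(tab), lev), collapse = ", "))
    for (lv in lev) {
      labels <- f == lv
      imp <- lapply(classifiers, function(cl) {
        raw <- switch(cl,
                      logistic = importance_logistic(scores, labels),
                      auc = importance_auc(scores, labels),
                      decision_tree = importance_tree(scores, labels,
                                                      "decision_tree"),
                      gradient_boosted_trees = importance_tree(
                        scores, labels, "gradient_boosted_trees",
                        seed = seed))
        scale_importances(raw, scaling)
      })
      imp <- do.call(rbind, imp)
      combined <- if (mean_type == "arithmetic") colMeans(imp)
                  else exp(colMeans(log(pmax(imp, .Machine$double.eps))))
      rows[[paste0(cov, ":", lv)]] <- combined
      row_cov <- c(row_cov, cov)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- colnames(scores)
  structure(list(values = values, scaling_method = scaling,
                 mean_type = mean_type, classifier_set = classifiers,
                 covariate = stats::setNames(row_cov, rownames(values))),
            class = "fca_table")
}

#' @export
print.fca_table <- function(x, ...) {
  cat(sprintf("fca_table: %d covariate levels x %d factors (%s scaling, %s mean; %s)\n",
              nrow(x$values), ncol(x$values), x$scaling_method, x$mean_type,
              paste(x$classifier_set, collapse = "+")))
  invisible(x)
}

#' Otsu threshold of a score distribution
#'
#' Exhaustive scan over all candidate cut points for the threshold
#' maximizing the between-class variance of the induced two-group
#' partition, as used to binarize pooled association scores. By default
#' every midpoint between consecutive distinct values is a candidate
#' (exact scan via prefix sums); `n_bins` switches to a histogram scan
#' over equally spaced bin edges.
#'
#' @param values numeric vector (all pooled association scores).
#' @param n_bins optional number of histogram bins; NULL (default) scans
#'   the exact data resolution.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = NULL) {
  x <- values[is.finite(values)]
  if (length(unique(x)) < 2L)
    stop("cannot threshold a constant score distribution", call. = FALSE)
  if (is.null(n_bins)) {
    u <- sort(unique(x))
    cnt <- tabulate(match(x, u))
    cand <- (u[-1L] + u[-length(u)]) / 2  # midpoints between distinct values
    w0 <- cumsum(cnt)[-length(u)] / length(x)
    m0 <- cumsum(cnt * u)[-length(u)] / length(x)
    mt <- mean(x)
  } else {
    edges <- seq(min(x), max(x), length.out = n_bins + 1L)
    h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
    mids <- (edges[-1L] + edges[-length(edges)]) / 2
    cand <- edges[-c(1L, length(edges))]
    w0 <- cumsum(h)[-n_bins] / sum(h)
    m0 <- cumsum(h * mids)[-n_bins] / sum(h)
    mt <- sum(h * mids) / sum(h)
  }
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, length(cand))
  sigma_b[valid] <- (mt * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  cand[which.max(sigma_b)]
}

#' Binarize an FCA table into significant associations
#'
#' Thresholds the pooled association scores with [otsu_threshold] and
#' derives, per covariate level, the set of significantly associated
#' factors, plus the factors not significant for any level.
#'
#' @param fca an `fca_table`.
#' @param threshold optional fixed threshold overriding the Otsu scan.
#' @return An `association_calls` object: list with `threshold`,
#'   `significant` (binary matrix), `matched_factors` (list per level) and
#'   `unannotated_factors` (character vector).
#' @export
call_associations <- function(fca, threshold = NULL) {
  stopifnot(inherits(fca, "fca_table"))
  if (is.null(threshold)) threshold <- otsu_threshold(fca$values)
  sig <- (fca$values > threshold) * 1L
  matched <- apply(sig, 1L, function(r) colnames(sig)[r == 1L],
                   simplify = FALSE)
  structure(list(threshold = threshold, significant = sig,
                 matched_factors = matched,
                 unannotated_factors = colnames(sig)[colSums(sig) == 0]),
            class = "association_calls")
}

#' @export
print.association_calls <- function(x, ...) {
  cat(sprintf("association_calls: threshold %.4g; %d significant pairs; %d unannotated factors\n",
              x$threshold, sum(x$significant),
              length(x$unannotated_factors)))
  invisible(x)
}

#' Write an FCA table (wide, binary, and long formats)
#'
#' @param fca an `fca_table`.
#' @param path output CSV path for the score matrix; `*_binary.csv` and
#'   `*_long.tsv` siblings are written next to it.
#' @param calls optional [call_associations] result; computed if missing.
#' @return `path`, invisibly.
#' @export
write_fca <- function(fca, path, calls = NULL) {
  stopifnot(inherits(fca, "fca_table"))
  utils::write.csv(fca$values, path)
  if (is.null(calls)) calls <- call_associations(fca)
  utils::write.csv(calls$significant,
                   sub("\\.csv$", "_binary.csv", path))
  long <- data.frame(
    level = rep(rownames(fca$values), ncol(fca$values)),
    factor = rep(colnames(fca$values), each = nrow(fca$values)),
    score = as.vector(fca$values),
    significant = as.vector(calls$significant))
  utils::write.table(long, sub("\\.csv$", "_long.tsv", path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
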