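## Shared test fixtures, built once per test run and memoized.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

## The default synthetic mixture-of-lines dataset.
default_fixture <- function() memo("fixture", make_fixture_dataset(fixture_config()))

## Full pipeline on the default fixture (protocol + library size regressed,
## k = 10 varimax factors), reused across modules.
default_pipeline <- function(residual_type = "pearson") {
  memo(paste0("pipeline_", residual_type), {
    fx <- default_fixture()
    factor_discovery(fx$counts, fx$covariates,
                     regress = c("protocol", "library_size"),
                     k = 10, residual_type = residual_type, seed = 1)
  })
}

## A small deterministic count matrix for IO tests.
tiny_counts <- function() {
  m <- matrix(c(0L, 1L, 2L,
                3L, 0L, 4L,
                5L, 6L, 0L,
                1L, 1L, 1L), nrow = 4L, byrow = TRUE)
  count_matrix(m, cell_ids = paste0("c", 1:4), gene_ids = paste0("g", 1:3))
}

## O(n^2) Gini oracle: the double-sum formula evaluated literally.
gini_bruteforce <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

## Brute-force mean silhouette for a 1-D partition.
silhouette_bruteforce <- function(x, labels) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    other <- which(labels != labels[i])
    if (!length(own)) { s[i] <- 0; next }
    icd <- mean(abs(x[i] - x[own]))
    ncd <- mean(abs(x[i] - x[other]))
    s[i] <- (ncd - icd) / max(icd, ncd)
  }
  mean(s)
}

## Partition-level between-class variance used by the Otsu oracle.
between_class_variance <- function(x, thr) {
  lo <- x[x <= thr]; hi <- x[x > thr]
  if (!length(lo) || !length(hi)) return(-Inf)
  w0 <- length(lo) / length(x)
  w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}
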