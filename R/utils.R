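#' @importFrom methods new is validObject slot
#' @importFrom stats cor rnbinom runif rnorm sd setNames quantile lm coef var
#' @importFrom utils head tail read.delim write.table packageVersion
#' @importFrom utils modifyList
NULL

## Run an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic sign convention: flip each column so its largest-magnitude
## entry is positive. Ties resolved by the first index (which.max).
fixColumnSigns <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

#' Truncated-SVD Moore-Penrose pseudoinverse
#'
#' Singular values below `rtol * max(singular values)` are discarded before
#' inversion, guarding the cell-state estimator against ill-conditioned
#' observability matrices.
#'
#' @param A Real matrix.
#' @param rtol Relative truncation tolerance on singular values.
#' @return The pseudoinverse of `A` (matrix `ncol(A) x nrow(A)`).
#' @export
pseudoInverse <- function(A, rtol = 1e-10) {
  A <- as.matrix(A)
  if (any(!is.finite(A))) stop("pseudoInverse: non-finite entries")
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

## Coefficient of determination pooled over all entries, with per-gene
## (per-row) means as the reference. Shared by model scoring and cell-state
## reconstruction scoring.
pooledR2 <- function(predicted, actual) {
  predicted <- as.matrix(predicted)
  actual <- as.matrix(actual)
  stopifnot(all(dim(predicted) == dim(actual)))
  rowm <- rowMeans(actual)
  sstot <- sum((actual - rowm)^2)
  if (sstot == 0)
    stop("r-squared undefined: zero total deviation from gene means")
  1 - sum((actual - predicted)^2) / sstot
}

## AUC of a score for separating labels (TRUE above FALSE), rank/Wilcoxon form.
rankAUC <- function(score, label) {
  label <- as.logical(label)
  stopifnot(any(label), any(!label))
  r <- rank(score)
  n1 <- sum(label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * sum(!label))
}
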