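## Cell-state reconstruction from a gene subset: simulated outputs,
## observability matrix, pseudoinverse estimator, and the Monte Carlo
## reconstruction experiments.

#' Mask sampling weights to the q largest-magnitude entries
#'
#' All but the q largest-|.| entries are set to zero, simulating the
#' measurement of only the selected genes; ties break by gene order.
#'
#' @param w Weight vector.
#' @param q Number of entries to keep.
#' @return Vector of the same length with exactly `min(q, length(w))`
#'   nonzero entries (fewer if `w` has zeros among the kept positions).
#' @export
maskWeights <- function(w, q) {
  if (q >= length(w)) return(w)
  ord <- order(-abs(w), seq_along(w))
  out <- numeric(length(w))
  keep <- ord[seq_len(q)]
  out[keep] <- w[keep]
  names(out) <- names(w)
  out
}

#' Simulate scalar output measurements from masked weights
#'
#' `y_t = w' K^t z0` for t = 0..T.
#'
#' @param K State-transition matrix.
#' @param w_masked (Masked) sampling-weight vector.
#' @param z0 Initial condition.
#' @param T_steps Last time index T.
#' @return Numeric vector of length T + 1.
#' @export
simulateOutputs <- function(K, w_masked, z0, T_steps) {
  x <- as.numeric(z0)
  y <- numeric(T_steps + 1)
  for (t in 0:T_steps) {
    y[t + 1] <- sum(w_masked * x)
    if (t < T_steps) x <- as.numeric(K %*% x)
  }
  y
}

#' Observability matrix of a sensor placement
#'
#' Stacks the rows `w' K^t`, t = 0..T. Its column rank determines which
#' initial conditions the output sequence can distinguish.
#'
#' @param K State-transition matrix.
#' @param w_masked Sampling-weight vector.
#' @param T_steps Last time index T.
#' @return (T + 1) x genes matrix.
#' @export
observabilityMatrix <- function(K, w_masked, T_steps) {
  n <- length(w_masked)
  O <- matrix(0, T_steps + 1, n)
  row <- as.numeric(w_masked)
  for (t in 0:T_steps) {
    O[t + 1, ] <- row
    if (t < T_steps) row <- as.numeric(row %*% K)
  }
  O
}

#' Estimate the initial cell state from output measurements
#'
#' Minimum-norm least-squares solution `z0hat = pinv(O_T) y` via the
#' truncated-SVD Moore-Penrose pseudoinverse (singular values below
#' `rtol * sigma_max` are discarded, guarding against the redundancy-driven
#' ill conditioning of deep observability matrices).
#'
#' @param O_T Observability matrix from [observabilityMatrix()].
#' @param y Output measurement vector (length nrow(O_T)).
#' @param rtol Relative singular-value truncation tolerance.
#' @return Estimated initial state (length ncol(O_T)).
#' @export
estimateInitialState <- function(O_T, y, rtol = 1e-10) {
  stopifnot(length(y) == nrow(O_T))
  as.numeric(pseudoInverse(O_T, rtol = rtol) %*% y)
}

## Reconstruction R^2 for a single state vector, per the pooled convention
## (reference = mean of the true vector's entries).
vectorR2 <- function(estimated, true) {
  ss <- sum((true - mean(true))^2)
  if (ss == 0) stop("r-squared undefined for a constant true state")
  1 - sum((true - estimated)^2) / ss
}

#' Reconstruct and score the initial state for one gene subset
#'
#' @param K State-transition matrix.
#' @param w Full sampling-weight vector.
#' @param support Indices (or logical mask) of the measured genes.
#' @param z0 True initial state.
#' @param T_steps Last output time index.
#' @param gene_ids Optional gene identifiers.
#' @return List: `estimated_z0`, `true_z0`, `r2`, `T`, `support_q`,
#'   `support_ids`.
#' @export
reconstructFromSupport <- function(K, w, support, z0, T_steps,
                                   gene_ids = NULL) {
  wm <- numeric(length(w))
  wm[support] <- w[support]
  O <- observabilityMatrix(K, wm, T_steps)
  y <- simulateOutputs(K, wm, z0, T_steps)
  est <- estimateInitialState(O, y)
  idx <- which(wm != 0)
  list(estimated_z0 = est, true_z0 = as.numeric(z0),
       r2 = vectorR2(est, z0), T = T_steps, support_q = length(idx),
       support_ids = if (is.null(gene_ids)) idx else gene_ids[idx])
}

#' Monte Carlo reconstruction by weight category
#'
#' Genes are partitioned into equal thirds (low/mid/high) by sampling-weight
#' magnitude. Per repetition, `genes_per_draw` genes are drawn uniformly from
#' one category, the weights are masked to the draw, outputs are simulated
#' for the requested horizon, the initial state is estimated by
#' pseudoinverse, and the reconstruction R-squared against the true state is
#' recorded.
#'
#' @param weights A [GeneWeights-class] (or a numeric weight vector).
#' @param K State-transition matrix.
#' @param z0 True initial state.
#' @param T_steps Last output time index.
#' @param genes_per_draw Genes sampled per repetition (default 50).
#' @param reps Repetitions per category (default 100).
#' @param seed Master seed; per-repetition draws derive from it.
#' @param normalized Partition by sigma-normalized weight magnitude instead
#'   of raw.
#' @return data.frame: `category`, `rep`, `r2`.
#' @export
categoryMonteCarlo <- function(weights, K, z0, T_steps, genes_per_draw = 50,
                               reps = 100, seed = 0, normalized = FALSE) {
  w <- if (is(weights, "GeneWeights")) weights@primaryW else
    as.numeric(weights)
  score <- if (normalized && is(weights, "GeneWeights"))
    abs(weights@normalizedW) else abs(w)
  n <- length(w)
  ord <- order(-score, seq_len(n))
  third <- floor(n / 3)
  category <- rep(NA_character_, n)
  category[ord[seq_len(third)]] <- "high"
  category[ord[(third + 1):(2 * third)]] <- "mid"
  category[ord[(2 * third + 1):n]] <- "low"
  out <- withSeed(seed, {
    rows <- list()
    for (cat in c("low", "mid", "high")) {
      pool <- which(category == cat)
      for (i in seq_len(reps)) {
        draw <- sample(pool, min(genes_per_draw, length(pool)))
        rec <- reconstructFromSupport(K, w, draw, z0, T_steps)
        rows[[length(rows) + 1]] <-
          data.frame(category = cat, rep = i, r2 = rec$r2)
      }
    }
    do.call(rbind, rows)
  })
  out
}

#' Reconstruction accuracy over nested gene sets and time horizons
#'
#' For each horizon T, genes are added in ranked blocks of `gene_step`
#' (top 5, top 10, ...), the state is reconstructed from each nested set and
#' scored, tracing how few well-chosen genes measured long enough outperform
#' many genes measured briefly.
#'
#' @param ranking Gene ranking: a [GeneWeights-class], a permutation of gene
#'   indices (best first), or a numeric weight vector (ranked by |.|).
#' @param K State-transition matrix.
#' @param z0 True initial state.
#' @param T_values Horizons to evaluate.
#' @param gene_step Block size for the nested sets (default 5).
#' @param w Weight vector used for the outputs (defaults to the ranking's
#'   weights when available, else unit weights on the support).
#' @return data.frame: `T`, `n_genes`, `r2`.
#' @export
genesByTimeSweep <- function(ranking, K, z0, T_values, gene_step = 5,
                             w = NULL) {
  if (is(ranking, "GeneWeights")) {
    if (is.null(w)) w <- ranking@primaryW
    ord <- order(-abs(ranking@primaryW), seq_along(ranking@primaryW))
  } else if (is.numeric(ranking) &&
             all(sort(ranking) == seq_along(ranking))) {
    ord <- as.integer(ranking)
    if (is.null(w)) w <- rep(1, length(ord))
  } else {
    if (is.null(w)) w <- as.numeric(ranking)
    ord <- order(-abs(w), seq_along(w))
  }
  sizes <- seq(gene_step, length(ord), by = gene_step)
  if (tail(sizes, 1) < length(ord)) sizes <- c(sizes, length(ord))
  rows <- list()
  for (T_steps in T_values) {
    for (k in sizes) {
      rec <- reconstructFromSupport(K, w, ord[seq_len(k)], z0, T_steps)
      rows[[length(rows) + 1]] <-
        data.frame(T = T_steps, n_genes = k, r2 = rec$r2)
    }
  }
  do.call(rbind, rows)
}
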