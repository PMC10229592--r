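## Biomarker gene-set selection: correlation metric C and the three
## strategies (top rank, correlation threshold, random search).

#' Gene-set correlation metric C
#'
#' `C = || 1_{kxk} - R_abs ||_F` where `R_abs` is the elementwise absolute
#' Pearson correlation matrix of the k gene trajectories. C = 0 iff all pairs
#' are perfectly correlated in absolute value; for k mutually uncorrelated
#' genes C = sqrt(k^2 - k). Larger C means a less internally correlated
#' (more informative) set.
#'
#' @param trajectories k x timepoints matrix (rows = genes).
#' @return Nonnegative scalar.
#' @examples
#' correlationMetric(matrix(c(1, 2, 3, 2, 4, 6), 2, byrow = TRUE)) # 0
#' @export
correlationMetric <- function(trajectories) {
  trajectories <- as.matrix(trajectories)
  if (nrow(trajectories) < 2) stop("need at least 2 genes")
  if (any(apply(trajectories, 1, sd) == 0))
    stop("constant trajectory row: Pearson correlation undefined")
  R <- abs(cor(t(trajectories)))
  norm(1 - R, type = "F")
}

evaluateGeneSet <- function(idx, ranking_df, trajectories, model = NULL,
                            state = NULL, T_steps = 8, strategy) {
  gene_ids <- ranking_df$gene_id[idx]
  traj <- trajectories[idx, , drop = FALSE]
  C <- if (length(idx) >= 2) correlationMetric(traj) else NA_real_
  r2 <- NA_real_
  if (!is.null(model) && !is.null(state)) {
    rec <- reconstructFromSupport(fullOperator(model), ranking_df$w, idx,
                                  model@z0, T_steps)
    r2 <- rec$r2
  }
  ranks <- rank(-abs(ranking_df$w), ties.method = "first")
  list(gene_ids = gene_ids, C_metric = C, recon_r2 = r2,
       strategy = strategy,
       rank_percentiles = 100 * (1 - (ranks[idx] - 1) / nrow(ranking_df)))
}

## Internal: normalize a ranking input to a data.frame with gene order
## preserved (order_in_matrix = row index in the trajectory matrix).
rankingFrame <- function(ranking, n = NULL) {
  if (is(ranking, "GeneWeights")) {
    df <- data.frame(gene_id = ranking@geneIds, w = ranking@primaryW,
                     order_in_matrix = seq_along(ranking@primaryW))
  } else if (is.numeric(ranking)) {
    ids <- if (!is.null(names(ranking))) names(ranking) else
      paste0("gene_", seq_along(ranking))
    df <- data.frame(gene_id = ids, w = as.numeric(ranking),
                     order_in_matrix = seq_along(ranking))
  } else stop("unsupported ranking input")
  df
}

#' Select the top-k ranked genes
#'
#' @param ranking A [GeneWeights-class] or named weight vector (genes in
#'   trajectory-matrix order).
#' @param trajectories genes x timepoints matrix aligned with the ranking.
#' @param k Set size (default 15).
#' @param model,state Optional [DMDModel-class]/[FoldChangeState-class] to
#'   also score cell-state reconstruction at `T_steps`.
#' @param T_steps Reconstruction horizon (default 8).
#' @return List: `gene_ids`, `C_metric`, `recon_r2`, `strategy`,
#'   `rank_percentiles`.
#' @export
selectTopK <- function(ranking, trajectories, k = 15, model = NULL,
                       state = NULL, T_steps = 8) {
  df <- rankingFrame(ranking)
  ord <- order(-abs(df$w), seq_len(nrow(df)))
  idx <- ord[seq_len(min(k, nrow(df)))]
  evaluateGeneSet(idx, df, trajectories, model, state, T_steps, "top_rank")
}

#' Greedy correlation-thresholded selection
#'
#' Walks down the ranking starting from the top gene and admits a gene only
#' if its maximum absolute Pearson correlation with all previously admitted
#' genes is below `threshold`, stopping at k genes or the end of the list.
#' With `threshold = 1` this reduces to [selectTopK()].
#'
#' @inheritParams selectTopK
#' @param threshold Absolute-correlation admission threshold in (0, 1].
#' @return As [selectTopK()] (strategy `"correlation_threshold"`); shorter
#'   than k with a warning if too few genes are admissible.
#' @export
selectCorrelationThreshold <- function(ranking, trajectories,
                                       threshold = 0.5, k = 15,
                                       model = NULL, state = NULL,
                                       T_steps = 8) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  df <- rankingFrame(ranking)
  ord <- order(-abs(df$w), seq_len(nrow(df)))
  chosen <- integer()
  for (i in ord) {
    if (length(chosen) == 0) {
      chosen <- i
    } else {
      cc <- abs(cor(trajectories[i, ],
                    t(trajectories[chosen, , drop = FALSE])))
      if (max(cc) < threshold) chosen <- c(chosen, i)
    }
    if (length(chosen) == k) break
  }
  if (length(chosen) < k)
    warning(sprintf("only %d genes admissible below threshold %.2f",
                    length(chosen), threshold))
  evaluateGeneSet(chosen, df, trajectories, model, state, T_steps,
                  "correlation_threshold")
}

#' Randomized search over gene sets from the top of the ranking
#'
#' Draws `trials` uniform k-subsets of the top fraction of the ranking,
#' scores each by the correlation metric C and by cell-state reconstruction
#' R-squared at `T_steps`, and annotates each trial with its percentile on
#' both axes so Pareto-preferred sets (high R-squared, high C) can be read
#' off.
#'
#' @inheritParams selectTopK
#' @param model,state Model and state used for reconstruction scoring
#'   (required here).
#' @param pool_fraction Fraction of the ranking (by |w|, best first) forming
#'   the sampling pool (default 0.5, the top half).
#' @param trials Number of random sets (default 10000).
#' @param seed RNG seed.
#' @return List: `trials` (data.frame set_id, C, r2, and percentiles),
#'   `sets` (list of gene-id vectors), `best_by_r2` (index of the best
#'   trial).
#' @export
randomSetSearch <- function(ranking, trajectories, model, state, k = 15,
                            pool_fraction = 0.5, trials = 10000, T_steps = 8,
                            seed = 0) {
  df <- rankingFrame(ranking)
  ord <- order(-abs(df$w), seq_len(nrow(df)))
  pool <- ord[seq_len(ceiling(pool_fraction * length(ord)))]
  if (length(pool) < k) stop("pool smaller than k")
  K <- fullOperator(model)
  w <- df$w
  z0 <- model@z0
  res <- withSeed(seed, {
    sets <- vector("list", trials)
    C <- numeric(trials); r2 <- numeric(trials)
    for (i in seq_len(trials)) {
      idx <- sample(pool, k)
      sets[[i]] <- idx
      C[i] <- correlationMetric(trajectories[idx, , drop = FALSE])
      rec <- reconstructFromSupport(K, w, idx, z0, T_steps)
      r2[i] <- rec$r2
    }
    list(sets = sets, C = C, r2 = r2)
  })
  pct <- function(v) 100 * (rank(v) - 1) / max(1, (length(v) - 1))
  trials_df <- data.frame(set_id = seq_len(trials), C = res$C, r2 = res$r2,
                          C_percentile = pct(res$C),
                          r2_percentile = pct(res$r2))
  list(trials = trials_df,
       sets = lapply(res$sets, function(i) df$gene_id[i]),
       best_by_r2 = which.max(res$r2))
}
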