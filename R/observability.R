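## Observability analysis: signal energy, finite-horizon Gram matrices, and
## the relaxed sensor-placement solution giving the gene sampling weights.

#' Enrich initial conditions with synthetic samples
#'
#' Time-series experiments carry few replicates, hence few initial
#' conditions. Per gene g, N synthetic initial conditions are sampled i.i.d.
#' Uniform(min_j z0^(j)(g), max_j z0^(j)(g)) over the replicate initial
#' conditions, giving the Gram matrix a full-rank set of directions. N
#' defaults to the gene count.
#'
#' @param replicate_z0s genes x replicates matrix of initial conditions (or
#'   a [DMDModel-class], whose stored per-replicate initial conditions are
#'   used).
#' @param N Number of synthetic initial conditions (default: gene count).
#' @param seed RNG seed (the sampling is bitwise reproducible given the
#'   seed).
#' @return genes x N matrix.
#' @export
enrichInitialConditions <- function(replicate_z0s, N = NULL, seed = 0) {
  if (is(replicate_z0s, "DMDModel")) replicate_z0s <- replicate_z0s@z0Reps
  Z <- as.matrix(replicate_z0s)
  if (is.null(N)) N <- nrow(Z)
  if (N < 1) stop("N must be >= 1")
  lo <- apply(Z, 1, min)
  hi <- apply(Z, 1, max)
  out <- withSeed(seed, {
    matrix(runif(nrow(Z) * N, rep(lo, N), rep(hi, N)), nrow = nrow(Z))
  })
  rownames(out) <- rownames(Z)
  out
}

#' Finite-horizon observability Gram matrix
#'
#' `G = sum_{i=0}^{m} K^i Z0 Z0' (K^i)'` over the initial-condition matrix
#' `Z0`. The finite horizon keeps the sum convergent even when some
#' eigenvalues of K sit outside the unit circle.
#'
#' @param K Square state-transition matrix (genes x genes).
#' @param Z0 genes x N matrix of (enriched) initial conditions; a vector is
#'   treated as one column.
#' @param horizon_m Horizon m >= 0 (the sum has m + 1 terms).
#' @return A [GramMatrix-class] (full coordinates).
#' @export
gramMatrix <- function(K, Z0, horizon_m) {
  K <- as.matrix(K)
  Z0 <- as.matrix(Z0)
  if (nrow(K) != ncol(K) || nrow(Z0) != nrow(K))
    stop("K must be square with as many rows as Z0")
  if (horizon_m < 0) stop("horizon must be >= 0")
  M <- Z0
  G <- tcrossprod(M)
  for (i in seq_len(horizon_m)) {
    M <- K %*% M
    G <- G + tcrossprod(M)
  }
  G <- (G + t(G)) / 2
  new("GramMatrix", G = G, horizon = as.integer(horizon_m), reduced = FALSE)
}

#' Reduced-order Gram matrix in mode coordinates
#'
#' `Gtilde = sum_{i=0}^{m} Khat^i (U' Z0) (U' Z0)' (Khat^i)'`; its leading
#' eigenpairs approximate those of the full Gram matrix after lifting the
#' eigenvectors through U. This is the feasible route when the gene count
#' makes the full genes x genes matrix too large.
#'
#' @param model A [DMDModel-class].
#' @param Z0 genes x N initial-condition matrix.
#' @param horizon_m Horizon m >= 0.
#' @return A [GramMatrix-class] with `reduced = TRUE` (r x r).
#' @export
reducedGramMatrix <- function(model, Z0, horizon_m) {
  Z0 <- as.matrix(Z0)
  B <- crossprod(model@basisU, Z0)
  M <- B
  G <- tcrossprod(M)
  for (i in seq_len(horizon_m)) {
    M <- model@reducedK %*% M
    G <- G + tcrossprod(M)
  }
  G <- (G + t(G)) / 2
  new("GramMatrix", G = G, horizon = as.integer(horizon_m), reduced = TRUE)
}

#' Finite-horizon output signal energy
#'
#' `E = sum_{t=0}^{m} (w' K^t z0)^2`, the energy of the scalar output
#' sequence read through sampling weights w; equals the quadratic form
#' `z0' G_w z0` for the Gram matrix built from the rank-one output `w w'`.
#'
#' @param K Square state-transition matrix.
#' @param w Sampling-weight vector.
#' @param z0 Initial condition (vector or matrix of columns; energies are
#'   summed over columns).
#' @param horizon_m Horizon m >= 0.
#' @return Nonnegative scalar.
#' @export
signalEnergy <- function(K, w, z0, horizon_m) {
  K <- as.matrix(K)
  Z <- as.matrix(z0)
  w <- as.numeric(w)
  total <- 0
  M <- Z
  for (i in 0:horizon_m) {
    if (i > 0) M <- K %*% M
    y <- crossprod(M, w)
    total <- total + sum(y^2)
  }
  total
}

#' Solve the relaxed sensor-placement problem
#'
#' The weights maximizing the total output signal energy over the initial
#' conditions, subject to orthonormal rows `W W' = I_p`, are the top-p
#' eigenvectors of the Gram matrix. The leading eigenvector q1 is the primary
#' gene sampling-weight vector w; its entries rank genes by contribution to
#' observability, with the sign separating up- from downregulated genes under
#' the deterministic convention (largest-magnitude entry positive).
#'
#' @param G A [GramMatrix-class] (full or reduced) or a symmetric PSD matrix.
#' @param p Number of orthonormal weight vectors (default 1).
#' @param gene_sigma Optional per-gene fold-change standard deviations for
#'   the sigma-normalized display variant (defaults to 1).
#' @param basis Required when `G` is reduced: the model basis U used to lift
#'   eigenvectors back to gene coordinates.
#' @param gene_ids Optional gene identifiers.
#' @param n_ics,seed Provenance fields recorded in the result.
#' @return A [GeneWeights-class].
#' @export
samplingWeights <- function(G, p = 1, gene_sigma = NULL, basis = NULL,
                            gene_ids = NULL, n_ics = NA_integer_,
                            seed = NA_integer_) {
  reduced <- FALSE
  horizon <- NA_integer_
  if (is(G, "GramMatrix")) {
    reduced <- G@reduced
    horizon <- G@horizon
    G <- gramValues(G)
  }
  if (reduced && is.null(basis))
    stop("a reduced Gram matrix needs the projection basis to lift weights")
  if (p < 1 || p > nrow(G)) stop("p must be in 1..nrow(G)")
  eg <- eigen(G, symmetric = TRUE)
  vals <- eg$values
  if (p < length(vals)) {
    gap <- abs(vals[p] - vals[p + 1])
    if (gap <= 1e-10 * max(abs(vals[1]), 1))
      warning("tied leading eigenvalues: weight vectors not unique")
  }
  Q <- eg$vectors[, seq_len(p), drop = FALSE]
  if (reduced) Q <- basis %*% Q
  Q <- fixColumnSigns(Q)
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(rownames(Q))) rownames(Q) else
      paste0("gene_", seq_len(nrow(Q)))
  if (is.null(gene_sigma)) gene_sigma <- rep(1, nrow(Q))
  new("GeneWeights", weightsW = t(Q), primaryW = as.numeric(Q[, 1]),
      normalizedW = as.numeric(Q[, 1]) / gene_sigma,
      gramEigenvalues = vals, horizon = as.integer(horizon),
      nSyntheticICs = as.integer(n_ics), seed = as.integer(seed),
      geneIds = as.character(gene_ids))
}

#' End-to-end gene sampling weights from a fitted model
#'
#' Enriches the replicate initial conditions, builds the finite-horizon Gram
#' matrix (full gene coordinates when the gene count permits, reduced-order
#' otherwise), and solves for the sampling weights.
#'
#' @param model A [DMDModel-class].
#' @param state Optional [FoldChangeState-class] supplying per-gene sigma for
#'   the normalized weight variant and the default horizon (number of
#'   modeled time points).
#' @param p Number of weight vectors.
#' @param horizon_m Gram horizon; defaults to the number of modeled time
#'   points.
#' @param n_ics Number of synthetic initial conditions (default: gene
#'   count).
#' @param seed Seed for the enrichment sampling.
#' @param method `"auto"` (full coordinates up to `full_max_genes` genes,
#'   reduced beyond), `"full"`, or `"reduced"`.
#' @param full_max_genes Gene-count cutoff for the full route.
#' @return A [GeneWeights-class].
#' @export
computeGeneWeights <- function(model, state = NULL, p = 1, horizon_m = NULL,
                               n_ics = NULL, seed = 0,
                               method = c("auto", "full", "reduced"),
                               full_max_genes = 5000) {
  method <- match.arg(method)
  n <- length(model@z0)
  if (is.null(horizon_m)) {
    horizon_m <- if (!is.null(state))
      ncol(stateMatrix(state)) / length(unique(state@replicate)) else
        ncol(model@z0Reps) + nrow(model@reducedK)
    horizon_m <- as.integer(round(horizon_m))
  }
  if (is.null(n_ics)) n_ics <- n
  Z0 <- enrichInitialConditions(model, N = n_ics, seed = seed)
  use_full <- switch(method, full = TRUE, reduced = FALSE,
                     auto = n <= full_max_genes)
  G <- if (use_full) gramMatrix(fullOperator(model), Z0, horizon_m) else
    reducedGramMatrix(model, Z0, horizon_m)
  sigma <- if (!is.null(state)) stateSigma(state) else NULL
  samplingWeights(G, p = p, gene_sigma = sigma,
                  basis = if (use_full) NULL else model@basisU,
                  gene_ids = model@geneIds, n_ics = n_ics, seed = seed)
}

#' Rank genes by sampling weight
#'
#' @param weights A [GeneWeights-class].
#' @param normalized Rank by the sigma-normalized weights instead of the raw
#'   optimization weights (default FALSE).
#' @return data.frame: `gene_id`, `w`, `w_normalized`, `rank_raw`,
#'   `rank_normalized`, sorted by the chosen ranking (best first).
#' @export
rankGenes <- function(weights, normalized = FALSE) {
  w <- weights@primaryW
  wn <- weights@normalizedW
  df <- data.frame(gene_id = weights@geneIds, w = w, w_normalized = wn,
                   rank_raw = rank(-abs(w), ties.method = "first"),
                   rank_normalized = rank(-abs(wn), ties.method = "first"))
  df[order(if (normalized) df$rank_normalized else df$rank_raw), ,
     drop = FALSE]
}
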