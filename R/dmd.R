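## Exact dynamic mode decomposition of the standardized fold-change state.

#' Build time-shifted snapshot matrices
#'
#' Per replicate, the past matrix takes columns 0..m-2 and the future matrix
#' columns 1..m-1; replicate blocks are concatenated so no (past, future)
#' column pair straddles a replicate boundary.
#'
#' @param state A [FoldChangeState-class] (or a plain matrix with a single
#'   replicate).
#' @return List with `Zp`, `Zf`, and `z0Reps` (genes x replicates initial
#'   conditions).
#' @export
buildShiftMatrices <- function(state) {
  if (is(state, "FoldChangeState")) {
    z <- stateMatrix(state)
    reps <- state@replicate
  } else {
    z <- as.matrix(state)
    reps <- rep("rep1", ncol(z))
  }
  ur <- unique(reps)
  Zp <- NULL; Zf <- NULL
  z0 <- matrix(NA_real_, nrow(z), length(ur),
               dimnames = list(rownames(z), ur))
  for (j in seq_along(ur)) {
    block <- z[, reps == ur[j], drop = FALSE]
    if (ncol(block) < 2)
      stop("replicate '", ur[j], "' has fewer than 2 time points")
    Zp <- cbind(Zp, block[, -ncol(block), drop = FALSE])
    Zf <- cbind(Zf, block[, -1, drop = FALSE])
    z0[, j] <- block[, 1]
  }
  list(Zp = Zp, Zf = Zf, z0Reps = z0)
}

orderEigen <- function(values) {
  ## descending modulus; conjugate pairs kept adjacent with the positive
  ## imaginary part first
  order(-Mod(values), round(Re(values), 12), -sign(Im(values)))
}

pinvComplex <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, 0)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * Conj(t(s$u[, keep, drop = FALSE])))
}

#' Fit exact DMD to time-shifted snapshot matrices
#'
#' Takes the rank-r singular value decomposition `Zp = U Sigma T'`, forms the
#' reduced operator `Khat = U' Zf T Sigma^-1`, whose eigenvalues equal the r
#' leading eigenvalues of the full best-fit operator `K = U Khat U'`; the
#' dynamic modes are `v = U s` for eigenvectors `s` of `Khat`, and the
#' amplitudes are `b = pinv(V) z0`. Left singular vectors carry a
#' deterministic sign convention (largest-magnitude entry positive) so fitted
#' models are bit-reproducible.
#'
#' @param Zp,Zf Past/future snapshot matrices from [buildShiftMatrices()], or
#'   a [FoldChangeState-class] as `Zp` (then `Zf` is ignored).
#' @param rank_r Truncation rank r; must not exceed the numerical rank of
#'   `Zp`.
#' @param z0 Reference initial condition for the amplitudes; defaults to the
#'   average of the per-replicate initial conditions.
#' @return A [DMDModel-class].
#' @export
fitExactDMD <- function(Zp, Zf = NULL, rank_r = 10, z0 = NULL) {
  z0Reps <- NULL
  if (is(Zp, "FoldChangeState")) {
    sm <- buildShiftMatrices(Zp)
    Zf <- sm$Zf; z0Reps <- sm$z0Reps; Zp <- sm$Zp
  }
  Zp <- as.matrix(Zp); Zf <- as.matrix(Zf)
  stopifnot(all(dim(Zp) == dim(Zf)))
  if (is.null(z0Reps)) z0Reps <- Zp[, 1, drop = FALSE]
  if (is.null(z0)) z0 <- rowMeans(z0Reps)
  rank_r <- as.integer(rank_r)
  if (rank_r < 1 || rank_r > min(dim(Zp)))
    stop("rank_r must be between 1 and min(dim(Zp))")
  sv <- svd(Zp)
  numrank <- sum(sv$d > max(dim(Zp)) * .Machine$double.eps * sv$d[1])
  if (rank_r > numrank)
    stop(sprintf("requested rank %d exceeds numerical rank %d",
                 rank_r, numrank))
  U <- sv$u[, seq_len(rank_r), drop = FALSE]
  Tm <- sv$v[, seq_len(rank_r), drop = FALSE]
  d <- sv$d[seq_len(rank_r)]
  ## sign convention on U, mirrored on T so U Sigma T' is unchanged
  for (j in seq_len(rank_r)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; Tm[, j] <- -Tm[, j] }
  }
  Khat <- crossprod(U, Zf) %*% Tm %*% diag(1 / d, rank_r)
  eg <- eigen(Khat)
  ord <- orderEigen(eg$values)
  lambda <- eg$values[ord]
  S <- eg$vectors[, ord, drop = FALSE]
  V <- U %*% S
  b <- as.vector(pinvComplex(V) %*% z0)
  gene_ids <- rownames(Zp)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(Zp)))
  rownames(V) <- gene_ids
  new("DMDModel", rank = rank_r, basisU = U, reducedK = Khat,
      modes = V, eigenvalues = as.complex(lambda),
      amplitudes = as.complex(b), singularValues = d,
      z0 = as.numeric(z0), z0Reps = as.matrix(z0Reps), geneIds = gene_ids)
}

#' Reconstruct the full-state evolution operator
#'
#' `K = U Khat U'`, the rank-r best-fit linear operator in gene coordinates.
#'
#' @param model A [DMDModel-class].
#' @return genes x genes real matrix.
#' @export
fullOperator <- function(model) {
  K <- model@basisU %*% model@reducedK %*% t(model@basisU)
  dimnames(K) <- list(model@geneIds, model@geneIds)
  K
}

#' Predict the state trajectory from an initial condition
#'
#' Spectral form `zhat_t = V Lambda^t pinv(V) z0` for t = 0..steps: the full
#' horizon is predicted from the initial condition only, not by chaining
#' one-step predictions through the data. Imaginary residue below `imag_tol`
#' is discarded; larger residue raises a warning.
#'
#' @param model A [DMDModel-class].
#' @param z0 Initial condition (defaults to the model's reference initial
#'   condition).
#' @param steps Number of forward steps.
#' @param imag_tol Tolerance on the discarded imaginary part.
#' @return Real matrix genes x (steps + 1); column t+1 is the prediction at
#'   time t.
#' @export
predictStates <- function(model, z0 = model@z0, steps, imag_tol = 1e-8) {
  stopifnot(length(z0) == nrow(model@modes))
  V <- model@modes
  b <- as.vector(pinvComplex(V) %*% z0)
  lam <- model@eigenvalues
  out <- matrix(0, nrow(V), steps + 1)
  amp <- b
  for (t in 0:steps) {
    zt <- V %*% amp
    if (max(abs(Im(zt))) > imag_tol * max(1, max(abs(Re(zt)))))
      warning("non-negligible imaginary part in prediction at step ", t)
    out[, t + 1] <- Re(zt)
    amp <- amp * lam
  }
  rownames(out) <- model@geneIds
  colnames(out) <- paste0("t", 0:steps)
  out
}

#' Coefficient of determination pooled over genes and time points
#'
#' `R^2 = 1 - sum((actual - predicted)^2) / sum((actual - gene mean)^2)`,
#' with each gene's own temporal mean as the reference.
#'
#' @param predicted,actual Matrices of matching shape (genes x time points).
#' @return Scalar R-squared (<= 1; can be negative).
#' @export
rSquared <- function(predicted, actual) pooledR2(predicted, actual)

#' Full-horizon predictive accuracy of a DMD model
#'
#' Runs one (m-1)-step prediction per replicate from that replicate's initial
#' condition and scores against the observed trajectories, either pooled over
#' replicates (default, one R-squared) or per replicate.
#'
#' @param model A [DMDModel-class].
#' @param state The [FoldChangeState-class] the model was fitted on.
#' @param per_replicate Return one value per replicate instead of pooling.
#' @return Scalar R-squared, or a named vector if `per_replicate`.
#' @export
modelR2 <- function(model, state, per_replicate = FALSE) {
  z <- stateMatrix(state)
  reps <- state@replicate
  ur <- unique(reps)
  preds <- list(); acts <- list()
  for (j in ur) {
    block <- z[, reps == j, drop = FALSE]
    preds[[j]] <- predictStates(model, z0 = block[, 1],
                                steps = ncol(block) - 1)
    acts[[j]] <- block
  }
  if (per_replicate)
    return(vapply(ur, function(j) pooledR2(preds[[j]], acts[[j]]),
                  numeric(1)))
  pooledR2(do.call(cbind, preds), do.call(cbind, acts))
}

#' Scan model rank against accuracy and instability
#'
#' Fits one model per requested rank and reports the full-horizon pooled
#' R-squared and the number of unstable eigenvalues (|lambda| > 1).
#'
#' @param state A [FoldChangeState-class].
#' @param r_values Integer ranks to scan.
#' @param tol Instability tolerance on |lambda| - 1.
#' @return data.frame with columns `r`, `r2`, `n_unstable`.
#' @export
rankScan <- function(state, r_values, tol = 1e-9) {
  rows <- lapply(r_values, function(r) {
    model <- fitExactDMD(state, rank_r = r)
    data.frame(r = r, r2 = modelR2(model, state),
               n_unstable = sum(Mod(model@eigenvalues) > 1 + tol))
  })
  do.call(rbind, rows)
}

#' Classify dynamic modes by eigenvalue location
#'
#' Eigenvalues inside the unit circle are decaying (stable), outside growing
#' (unstable), on it (within `tol`) marginal; a nonzero imaginary part marks
#' an oscillatory mode. Oscillatory modes come in conjugate pairs for real
#' data.
#'
#' @param model A [DMDModel-class].
#' @param tol Tolerance on |lambda| - 1 (and on |Im lambda| for
#'   oscillation).
#' @return data.frame: `index`, `stability`, `oscillatory`, `magnitude`,
#'   `frequency` (arg lambda, radians/step).
#' @export
classifyModes <- function(model, tol = 1e-9) {
  lam <- model@eigenvalues
  mag <- Mod(lam)
  stability <- ifelse(mag < 1 - tol, "stable",
                      ifelse(mag > 1 + tol, "unstable", "marginal"))
  data.frame(index = seq_along(lam), stability = stability,
             oscillatory = abs(Im(lam)) > tol, magnitude = mag,
             frequency = Arg(lam))
}

#' Genes most influenced by a dynamic mode
#'
#' Ranks genes by the modulus of their loading on the requested mode,
#' `|V[gene, mode]|`, descending; ties break by gene order. This clusters
#' genes by the temporal pattern the mode carries.
#'
#' @param model A [DMDModel-class].
#' @param mode_index Mode column (1-based, <= rank).
#' @param top_k How many genes to return.
#' @return Character vector of gene ids.
#' @export
clusterByMode <- function(model, mode_index, top_k = 10) {
  if (mode_index < 1 || mode_index > model@rank)
    stop("mode_index out of range")
  loading <- Mod(model@modes[, mode_index])
  ord <- order(-loading, seq_along(loading))
  model@geneIds[head(ord, top_k)]
}
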