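# Shared fixtures, built in code.

# Random rank-r linear system on n genes: K = B D B' with B orthonormal and
# a real, distinct, stable spectrum; z0 lies in the system's column space so
# trajectories are exactly rank r.
randomLowRankSystem <- function(n, r, seed = 1, eig = NULL) {
  set.seed(seed)
  B <- qr.Q(qr(matrix(rnorm(n * r), n, r)))
  if (is.null(eig)) eig <- seq(0.9, 0.3, length.out = r)
  K <- B %*% (eig * t(B))
  z0 <- as.numeric(B %*% rnorm(r, sd = 2))
  list(K = K, B = B, eig = eig, z0 = z0)
}

# Trajectory matrix z_t = K^t z0, t = 0..m-1, one replicate.
trajectoryMatrix <- function(K, z0, m) {
  out <- matrix(0, length(z0), m)
  x <- z0
  for (t in seq_len(m)) {
    out[, t] <- x
    x <- as.numeric(K %*% x)
  }
  out
}

# Wrap a raw trajectory matrix into a FoldChangeState without standardizing
# (mu = 0, sigma = 1), for exactness tests on known linear systems.
rawState <- function(z, n_reps = 1) {
  z <- as.matrix(z)
  m <- ncol(z) / n_reps
  rownames(z) <- paste0("gene_", seq_len(nrow(z)))
  methods::new("FoldChangeState", zbar = z, mu = rep(0, nrow(z)),
               sigma = rep(1, nrow(z)), rawZ = exp(z) + 0,
               timeMin = rep(seq_len(m), n_reps),
               replicate = rep(paste0("rep", seq_len(n_reps)), each = m),
               dropped = character(0))
}

# Small paired ExpressionTimeSeries in TPM from given matrices.
pairedTPM <- function(pert, ctrl, m = ncol(pert), reps = 1) {
  tm <- rep(seq(0, by = 10, length.out = m / reps), reps)
  rp <- rep(paste0("r", seq_len(reps)), each = m / reps)
  list(perturbed = ExpressionTimeSeries(pert, tm, rp, "perturbed", "TPM"),
       control = ExpressionTimeSeries(ctrl, tm, rp, "control", "TPM"))
}
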