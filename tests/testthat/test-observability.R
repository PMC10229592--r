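test_that("initial-condition enrichment samples inside per-gene bounds", {
  z0s <- cbind(c(1, -2, 0.5), c(1, -1, 1.5))
  Z0 <- enrichInitialConditions(z0s, N = 200, seed = 42)
  expect_equal(dim(Z0), c(3, 200))
  lo <- apply(z0s, 1, min); hi <- apply(z0s, 1, max)
  expect_true(all(Z0 >= lo & Z0 <= hi))
  # identical replicates collapse to that vector
  same <- cbind(c(1, 2), c(1, 2))
  expect_equal(enrichInitialConditions(same, N = 5, seed = 0),
               matrix(c(1, 2), 2, 5), ignore_attr = TRUE)
  # bitwise reproducibility, and N defaults to the gene count
  expect_identical(enrichInitialConditions(z0s, seed = 7),
                   enrichInitialConditions(z0s, seed = 7))
  expect_equal(ncol(enrichInitialConditions(z0s, seed = 7)), 3)
})

test_that("Gram matrix collapses correctly for identity and zero dynamics", {
  z0 <- c(1, 2, -1)
  G_id <- gramValues(gramMatrix(diag(3), z0, horizon_m = 4))
  expect_equal(G_id, 5 * tcrossprod(z0), tolerance = 1e-12)
  Z0 <- matrix(rnorm(12), 3)
  G_zero <- gramValues(gramMatrix(matrix(0, 3, 3), Z0, horizon_m = 7))
  expect_equal(G_zero, tcrossprod(Z0), tolerance = 1e-12)
  expect_error(gramMatrix(diag(3), z0, horizon_m = -1), ">= 0")
})

test_that("Gram matrix equals the explicit term-by-term oracle", {
  set.seed(15)
  K <- matrix(rnorm(36, sd = 0.4), 6)
  Z0 <- matrix(rnorm(24), 6)
  G <- gramValues(gramMatrix(K, Z0, horizon_m = 5))
  oracle <- matrix(0, 6, 6)
  for (i in 0:5) {
    Ki <- diag(6)
    for (j in seq_len(i)) Ki <- K %*% Ki
    oracle <- oracle + Ki %*% Z0 %*% t(Z0) %*% t(Ki)
  }
  expect_equal(G, oracle, tolerance = 1e-10)
  # PSD within tolerance
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("signal energy equals the quadratic form through the Gram matrix", {
  set.seed(16)
  K <- matrix(rnorm(36, sd = 0.4), 6)
  z0 <- rnorm(6)
  w <- rnorm(6); w <- w / sqrt(sum(w^2))
  E <- signalEnergy(K, w, z0, horizon_m = 5)
  # two-route consistency: E = z0' G_w z0 with the rank-one output Gramian
  Gw <- matrix(0, 6, 6)
  M <- diag(6)
  for (i in 0:5) {
    if (i > 0) M <- K %*% M
    Gw <- Gw + t(M) %*% tcrossprod(w) %*% M
  }
  expect_equal(E, as.numeric(t(z0) %*% Gw %*% z0), tolerance = 1e-10)
  # K = 0 leaves only the t = 0 term
  expect_equal(signalEnergy(matrix(0, 6, 6), w, z0, 3),
               sum(w * z0)^2, tolerance = 1e-12)
  # unobservable direction gives zero energy
  K2 <- diag(c(0.9, 0))
  expect_equal(signalEnergy(K2, c(0, 1), c(1, 0), 5), 0, tolerance = 1e-14)
})

test_that("sampling weights are the top Gram eigenvectors", {
  gw <- samplingWeights(diag(c(3, 2, 1)), p = 2)
  expect_equal(abs(primaryWeights(gw)), c(1, 0, 0), ignore_attr = TRUE)
  W <- gw@weightsW
  expect_equal(tcrossprod(W), diag(2), tolerance = 1e-10)
  expect_equal(gramSpectrum(gw), c(3, 2, 1))
})

test_that("analytic weights beat a dense grid search over unit sensors", {
  set.seed(17)
  K <- matrix(rnorm(4, sd = 0.5), 2)
  Z0 <- matrix(rnorm(20), 2)
  G <- gramMatrix(K, Z0, horizon_m = 6)
  q1 <- primaryWeights(samplingWeights(G))
  e_opt <- signalEnergy(K, q1, Z0, 6)
  th <- seq(0, pi, length.out = 1800)
  e_grid <- vapply(th, function(a)
    signalEnergy(K, c(cos(a), sin(a)), Z0, 6), numeric(1))
  expect_gte(e_opt, max(e_grid) - 1e-3 * max(e_grid))
  # and matches the best grid direction to coarse angular resolution
  best <- th[which.max(e_grid)]
  ang <- abs(atan2(q1[2], q1[1])) %% pi
  expect_lt(min(abs(ang - best), pi - abs(ang - best)), 1e-2)
})

test_that("weights are scale-equivariant and supported on signal genes", {
  set.seed(18)
  K <- matrix(0, 6, 6)
  K[1:3, 1:3] <- matrix(rnorm(9, sd = 0.4), 3)
  Z0 <- rbind(matrix(rnorm(18), 3), matrix(0, 3, 6))
  G1 <- gramMatrix(K, Z0, 5)
  G2 <- gramMatrix(K, 3 * Z0, 5)
  w1 <- samplingWeights(G1); w2 <- samplingWeights(G2)
  expect_equal(gramSpectrum(w2), 9 * gramSpectrum(w1), tolerance = 1e-8)
  expect_equal(primaryWeights(w2), primaryWeights(w1), tolerance = 1e-8)
  # support contained in the signal-carrying set
  expect_lt(max(abs(primaryWeights(w1)[4:6])), 1e-8)
})

test_that("optimality of q1 over random unit vectors", {
  set.seed(19)
  K <- matrix(rnorm(25, sd = 0.3), 5)
  Z0 <- matrix(rnorm(40), 5)
  G <- gramMatrix(K, Z0, 6)
  q1 <- primaryWeights(samplingWeights(G))
  e_opt <- signalEnergy(K, q1, Z0, 6)
  for (i in 1:200) {
    u <- rnorm(5); u <- u / sqrt(sum(u^2))
    expect_gte(e_opt + 1e-10, signalEnergy(K, u, Z0, 6))
  }
})

test_that("reduced-order Gram matrix agrees with the full computation", {
  # full-rank basis: reduced route must coincide exactly
  sys <- randomLowRankSystem(5, 5, seed = 23, eig = seq(0.9, 0.1, -0.2))
  z <- trajectoryMatrix(sys$K, rnorm(5), 12)
  model <- fitExactDMD(rawState(z), rank_r = 5)
  Z0 <- matrix(rnorm(25), 5)
  Gf <- gramMatrix(fullOperator(model), Z0, 6)
  Gr <- reducedGramMatrix(model, Z0, 6)
  lift <- model@basisU %*% gramValues(Gr) %*% t(model@basisU)
  expect_equal(gramValues(Gf), lift, tolerance = 1e-8, ignore_attr = TRUE)
  wf <- samplingWeights(Gf)
  wr <- samplingWeights(Gr, basis = model@basisU)
  expect_equal(primaryWeights(wr), primaryWeights(wf), tolerance = 1e-6)
})

test_that("reduced route approximates the leading eigenpair on low-rank systems", {
  sys <- randomLowRankSystem(10, 3, seed = 29, eig = c(0.9, 0.7, 0.5))
  z1 <- trajectoryMatrix(sys$K, sys$z0, 9)
  z2 <- trajectoryMatrix(sys$K, sys$z0 + sys$B %*% rnorm(3, sd = 0.1), 9)
  st <- rawState(cbind(z1, z2), n_reps = 2)
  model <- fitExactDMD(st, rank_r = 3)
  # initial conditions inside the mode subspace: the reduced route is exact
  set.seed(30)
  Z0 <- model@basisU %*% matrix(rnorm(3 * 10), 3)
  Gf <- gramMatrix(fullOperator(model), Z0, 9)
  Gr <- reducedGramMatrix(model, Z0, 9)
  # projection cannot inflate the leading eigenvalue
  expect_lte(gramSpectrum(samplingWeights(Gr, basis = model@basisU))[1],
             gramSpectrum(samplingWeights(Gf))[1] + 1e-6)
  q_full <- primaryWeights(samplingWeights(Gf))
  q_red <- primaryWeights(samplingWeights(Gr, basis = model@basisU))
  angle <- acos(min(1, abs(sum(q_full * q_red))))
  expect_lt(angle, 1e-3)
  # enriched box-sampled initial conditions leave the subspace slightly;
  # the lifted leading eigenvector still tracks the full one closely
  Z0e <- enrichInitialConditions(model, N = 10, seed = 1)
  qf <- primaryWeights(samplingWeights(gramMatrix(fullOperator(model),
                                                  Z0e, 9)))
  qr_ <- primaryWeights(samplingWeights(reducedGramMatrix(model, Z0e, 9),
                                        basis = model@basisU))
  expect_gt(abs(sum(qf * qr_)), 0.99)
})

test_that("end-to-end weights are deterministic given the seed", {
  sys <- randomLowRankSystem(8, 3, seed = 31)
  z1 <- trajectoryMatrix(sys$K, sys$z0, 8)
  z2 <- trajectoryMatrix(sys$K, sys$z0 * 0.9, 8)
  st <- rawState(cbind(z1, z2), n_reps = 2)
  model <- fitExactDMD(st, rank_r = 3)
  w1 <- computeGeneWeights(model, st, seed = 5)
  w2 <- computeGeneWeights(model, st, seed = 5)
  expect_identical(primaryWeights(w1), primaryWeights(w2))
  df <- rankGenes(w1)
  expect_identical(df$gene_id[1],
                   names(which.max(abs(primaryWeights(w1)))))
})
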