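test_that("shift matrices pair consecutive columns within replicates only", {
  z <- matrix(1:6, 2)            # columns a, b, c
  sm <- buildShiftMatrices(rawState(z))
  expect_equal(sm$Zp, z[, 1:2], ignore_attr = TRUE)
  expect_equal(sm$Zf, z[, 2:3], ignore_attr = TRUE)
  # two replicates of m = 3: 4 pairs, none across the boundary
  z2 <- cbind(z, 10 * z)
  sm2 <- buildShiftMatrices(rawState(z2, n_reps = 2))
  expect_equal(ncol(sm2$Zp), 4)
  expect_equal(sm2$Zp[, 3], 10 * z[, 1], ignore_attr = TRUE)  # rep2 starts over
  expect_equal(sm2$z0Reps[, 2], 10 * z[, 1], ignore_attr = TRUE)
  expect_error(buildShiftMatrices(rawState(z[, 1, drop = FALSE])),
               "fewer than 2")
})

test_that("shift matrices satisfy Zf = K Zp on data from a linear system", {
  sys <- randomLowRankSystem(6, 6, seed = 4, eig = seq(0.9, 0.2, -0.14))
  z <- trajectoryMatrix(sys$K, rnorm(6), 8)
  sm <- buildShiftMatrices(rawState(z))
  expect_equal(sm$Zf, sys$K %*% sm$Zp, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("exact DMD recovers a single decaying mode", {
  v <- c(1, 2, -1)
  z <- sapply(0:9, function(t) v * 0.5^t)
  model <- fitExactDMD(rawState(z), rank_r = 1)
  expect_equal(Re(dmdEigenvalues(model)), 0.5, tolerance = 1e-10)
  expect_equal(Im(dmdEigenvalues(model)), 0, tolerance = 1e-10)
})

test_that("exact DMD matches a dense eigendecomposition oracle", {
  # random diagonalizable stable 5-dim dynamics embedded in 12 genes
  sys <- randomLowRankSystem(12, 5, seed = 7)
  z <- trajectoryMatrix(sys$K, sys$z0, 20)
  model <- fitExactDMD(rawState(z), rank_r = 5)
  oracle <- eigen(sys$K)$values
  oracle <- oracle[order(-Mod(oracle))][1:5]
  got <- dmdEigenvalues(model)[order(-Mod(dmdEigenvalues(model)))]
  expect_equal(sort(Re(got)), sort(Re(oracle)), tolerance = 1e-8)
  expect_lt(max(abs(Im(got))), 1e-8)
})

test_that("exact DMD recovers the analytic spectrum of a planar rotation", {
  th <- 0.7
  K <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  z <- trajectoryMatrix(K, c(1, 0.3), 12)
  model <- fitExactDMD(rawState(z), rank_r = 2)
  lam <- dmdEigenvalues(model)
  expect_equal(sort(Arg(lam)), sort(c(-th, th)), tolerance = 1e-8)
  expect_equal(Mod(lam), c(1, 1), tolerance = 1e-8)
})

test_that("requested rank beyond the numerical rank is rejected", {
  sys <- randomLowRankSystem(8, 2, seed = 5)
  z <- trajectoryMatrix(sys$K, sys$z0, 10)
  expect_error(fitExactDMD(rawState(z), rank_r = 5), "numerical rank")
})

test_that("prediction reproduces a noiseless linear trajectory", {
  sys <- randomLowRankSystem(10, 4, seed = 11)
  z <- trajectoryMatrix(sys$K, sys$z0, 15)
  model <- fitExactDMD(rawState(z), rank_r = 4)
  pred <- predictStates(model, z0 = z[, 1], steps = 14)
  expect_equal(pred, z, tolerance = 1e-8, ignore_attr = TRUE)
  # steps = 0 returns the rank-r projection of z0 (exact here)
  p0 <- predictStates(model, z0 = z[, 1], steps = 0)
  expect_equal(p0[, 1], z[, 1], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("an excited unstable mode produces geometric growth", {
  K <- diag(c(1.2, 0.5))
  z <- trajectoryMatrix(K, c(1, 1), 8)
  model <- fitExactDMD(rawState(z), rank_r = 2)
  pred <- predictStates(model, z0 = c(1, 1), steps = 10)
  norms <- sqrt(colSums(pred^2))
  expect_true(all(diff(norms[5:11]) > 0))
})

test_that("coefficient of determination uses per-gene means as reference", {
  set.seed(8)
  actual <- matrix(rnorm(40), 4)
  expect_equal(rSquared(actual, actual), 1)
  permean <- matrix(rowMeans(actual), 4, 10)
  expect_equal(rSquared(permean, actual), 0)
  expect_error(rSquared(permean, permean), "undefined")
})

test_that("rank scan reports accuracy and instability per rank", {
  sys <- randomLowRankSystem(9, 3, seed = 13, eig = c(0.9, 0.6, 0.4))
  z <- trajectoryMatrix(sys$K, sys$z0, 12)
  scan <- rankScan(rawState(z), 1:3)
  expect_equal(scan$r, 1:3)
  expect_lt(scan$r2[1], 1)
  expect_equal(scan$r2[3], 1, tolerance = 1e-8)
  expect_equal(scan$n_unstable, c(0, 0, 0))
  # training R^2 is non-decreasing in rank on noisy data too
  set.seed(14)
  zn <- z + matrix(rnorm(length(z), 0, 0.05), nrow(z))
  scan_n <- rankScan(rawState(zn), 1:6)
  expect_true(all(diff(scan_n$r2) > -1e-10))
})

test_that("modes classify by eigenvalue location and pair conjugates", {
  rot <- 0.5 * matrix(c(cos(pi / 4), sin(pi / 4),
                        -sin(pi / 4), cos(pi / 4)), 2) * sqrt(2)
  K <- as.matrix(Matrix::bdiag(0.9, rot, 1.01))
  z <- trajectoryMatrix(K, c(1, 1, 0.5, 1), 14)
  model <- fitExactDMD(rawState(z), rank_r = 4)
  cls <- classifyModes(model)
  expect_setequal(cls$stability[!cls$oscillatory], c("stable", "unstable"))
  expect_equal(sum(cls$oscillatory), 2)
  osc <- dmdEigenvalues(model)[cls$oscillatory]
  expect_equal(osc[1], Conj(osc[2]), tolerance = 1e-8)
  expect_equal(sort(cls$magnitude), sort(c(0.9, 0.707107, 0.707107, 1.01)),
               tolerance = 1e-6)
})

test_that("mode loadings cluster genes from the generating block", {
  K <- diag(c(0.9, 0.85, 0.8, 0.5, 0.45, 0.4))
  z <- trajectoryMatrix(K, rep(1, 6), 10)
  model <- fitExactDMD(rawState(z), rank_r = 6)
  # modes ordered by |lambda|: slow block first
  expect_identical(clusterByMode(model, 1, 1), "gene_1")
  expect_true(all(clusterByMode(model, 4, 3) %in%
                  c("gene_4", "gene_5", "gene_6")))
  expect_setequal(clusterByMode(model, 2, 6), paste0("gene_", 1:6))
})

test_that("replicate-averaged amplitudes and pooled scoring work together", {
  sys <- randomLowRankSystem(8, 3, seed = 21)
  z1 <- trajectoryMatrix(sys$K, sys$z0, 9)
  z2 <- trajectoryMatrix(sys$K, sys$z0 * 1.05, 9)
  st <- rawState(cbind(z1, z2), n_reps = 2)
  model <- fitExactDMD(st, rank_r = 3)
  expect_equal(model@z0, rowMeans(cbind(z1[, 1], z2[, 1])), tolerance = 1e-12)
  expect_equal(modelR2(model, st), 1, tolerance = 1e-8)
  pr <- modelR2(model, st, per_replicate = TRUE)
  expect_length(pr, 2)
  expect_equal(unname(pr), c(1, 1), tolerance = 1e-8)
})
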