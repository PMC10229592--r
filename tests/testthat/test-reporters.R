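makePlate <- function(gfp, od, timeH = seq_len(ncol(gfp))) {
  meta <- data.frame(strain = paste0("s", seq_len(nrow(gfp))),
                     compound = "analyte",
                     concentration_uM = 1,
                     replicate = 1)
  PlateTimeSeries(gfp, od, timeH, meta)
}

test_that("per-cell signal is fluorescence over density with a death cutoff", {
  gfp <- rbind(c(1000, 2000, 4000))
  od <- rbind(c(0.5, 1, 2))
  plate <- makePlate(gfp, od, timeH = c(1, 2, 3))
  sig <- perCellSignal(plate)
  expect_equal(as.numeric(sig$signal), c(2000, 2000, 2000))
  cut <- perCellSignal(plate, cutoff_h = 3)
  expect_equal(ncol(cut$signal), 2)
  # commutes with time subsetting
  expect_equal(sig$signal[, 1:2, drop = FALSE], cut$signal)
})

test_that("reporter fold change propagates replicate uncertainty", {
  a <- rbind(c(2, 4), c(2, 4))
  b <- rbind(c(1, 2), c(1, 2))
  fc <- reporterFoldChange(a, b)
  expect_equal(fc$fc, c(2, 2))
  expect_equal(fc$sd, c(0, 0))
  expect_equal(reporterFoldChange(c(5, 5), c(5, 5))$fc, c(1, 1))
  # first-order delta-method oracle
  set.seed(61)
  tr <- matrix(rnorm(30, 100, 5), 3)
  ct <- matrix(rnorm(30, 50, 2), 3)
  fc2 <- reporterFoldChange(tr, ct)
  mt <- colMeans(tr); mc <- colMeans(ct)
  oracle <- (mt / mc) * sqrt(apply(tr, 2, var) / mt^2 +
                             apply(ct, 2, var) / mc^2)
  expect_equal(fc2$sd, oracle, tolerance = 1e-12)
})

test_that("maximal fold change time point handles direction and ties", {
  expect_equal(maxFoldChangeTimepoint(c(1.1, 1.5, 2, 3)), 4)
  expect_equal(maxFoldChangeTimepoint(c(1, 3, 1.2)), 2)
  # repressed reporter: strongest deviation below 1
  expect_equal(maxFoldChangeTimepoint(c(0.9, 0.4, 0.8)), 2)
  expect_equal(maxFoldChangeTimepoint(c(2, 2, 1.5)), 1)  # earliest tie
})

test_that("Hill curve midpoint identity and closed-form inversion hold", {
  p <- c(yMin = 100, yMax = 300, KM = 0.8, n = 2.5)
  expect_equal(hillCurve(0.8, p), 200)             # y(KM) = midpoint
  expect_equal(hillCurve(0, p), 100)
  cs <- c(0.05, 0.2, 0.8, 1.7, 5)
  fit <- new("HillFit", yMin = 100, yMax = 300, KM = 0.8, n = 2.5,
             residualSSE = 0, converged = TRUE)
  inv <- invertHill(fit, hillCurve(cs, p))
  expect_equal(inv$concentration_uM, cs, tolerance = 1e-10)
  expect_false(any(inv$saturated))
  # signals beyond the asymptotes flag saturation
  sat <- invertHill(fit, c(99, 301, 300))
  expect_true(all(sat$saturated))
  expect_true(all(is.na(sat$concentration_uM)))
  expect_equal(invertHill(fit, 200)$concentration_uM, 0.8, tolerance = 1e-10)
})

test_that("Hill fitting recovers noiseless parameters to high accuracy", {
  conc <- c(0, 0.1, 0.3, 0.6, 1, 2)
  truth <- c(yMin = 100, yMax = 200, KM = 1, n = 2)
  fit <- fitHill(conc, hillCurve(conc, truth))
  expect_equal(hillParams(fit), truth, tolerance = 1e-6)
  expect_true(fit@converged)
  # repressed reporter: direction is free
  truth_rep <- c(yMin = 500, yMax = 120, KM = 0.4, n = 1.8)
  fit_rep <- fitHill(conc, hillCurve(conc, truth_rep))
  expect_equal(hillParams(fit_rep), truth_rep, tolerance = 1e-5)
  expect_error(fitHill(c(0, 1, 1, 2), c(1, 2, 2, 3)), "4 distinct")
})

test_that("growth statistics detect the exponential phase", {
  # OD doubling every hour: rate ln 2, doubling time 1 h
  tt <- seq(0, 5, by = 0.25)
  od <- 0.1 * 2^tt
  gs <- growthStats(od, tt)
  expect_equal(gs$rate, log(2), tolerance = 1e-10)
  expect_equal(gs$doubling_h, 1, tolerance = 1e-10)
  expect_equal(gs$ratePaperSign, -log(2), tolerance = 1e-10)
  # flat OD: zero rate, undefined doubling
  flat <- growthStats(rep(0.2, 10), 1:10)
  expect_equal(flat$rate, 0)
  expect_true(is.na(flat$doubling_h))
  # noisy pure exponential: endpoint rate within 5% of the log-linear
  # regression oracle
  set.seed(62)
  tt2 <- seq(0, 6, by = 0.25)
  od2 <- 0.08 * exp(0.6 * tt2) * exp(rnorm(length(tt2), 0, 0.01))
  gs2 <- growthStats(od2, tt2)
  slope <- coef(lm(log(od2) ~ tt2))[[2]]
  expect_lt(abs(gs2$rate - slope) / slope, 0.05)
  # lag + exponential + plateau: the detected window stays out of the
  # flat phases and the rate tracks the true exponential rate
  tt3 <- seq(0, 10, by = 0.25)
  od3 <- pmin(0.08 * exp(pmax(tt3 - 2, 0) * 0.6), 1.2) *
    exp(rnorm(length(tt3), 0, 0.01))
  gs3 <- growthStats(od3, tt3)
  expect_gt(tt3[gs3$window[1]], 1)
  expect_lt(tt3[gs3$window[2]], 8)
  expect_lt(abs(gs3$rate - 0.6) / 0.6, 0.15)
})

test_that("compound correlations match the per-reporter Pearson oracle", {
  set.seed(63)
  ref <- matrix(rnorm(40), 4)
  rownames(ref) <- paste0("s", 1:4)
  expect_equal(compoundCorrelation(ref, ref), setNames(rep(1, 4), rownames(ref)))
  expect_equal(unname(compoundCorrelation(ref, -ref)), rep(-1, 4))
  other <- matrix(rnorm(40), 4)
  got <- compoundCorrelation(ref, other)
  for (i in 1:4) expect_equal(unname(got[i]), cor(ref[i, ], other[i, ]))
})

test_that("plate CSV reader assembles the well x time grid", {
  plate_f <- withr::local_tempfile(fileext = ".csv")
  map_f <- withr::local_tempfile(fileext = ".csv")
  grid <- expand.grid(well = c("A1", "A2"), time_h = c(0, 0.5, 1))
  grid$od600 <- c(0.1, 0.2, 0.15, 0.3, 0.2, 0.4)
  grid$gfp <- grid$od600 * 1000
  write.csv(grid, plate_f, row.names = FALSE)
  write.csv(data.frame(well = c("A1", "A2"), strain = c("x", "y"),
                       compound = "m", concentration_uM = c(0, 1),
                       replicate = 1), map_f, row.names = FALSE)
  plate <- readPlateData(plate_f, map_f)
  expect_s4_class(plate, "PlateTimeSeries")
  expect_equal(dim(plate@gfp), c(2, 3))
  expect_equal(perCellSignal(plate)$signal[1, ], rep(1000, 3),
               ignore_attr = TRUE)
})
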