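## Reporter characterization: per-cell signal, fold changes, Hill transfer
## curves and their inversion, growth statistics, specificity correlations.

#' Per-cell fluorescence signal
#'
#' Normalizes fluorescence by optical density, `gfp / od600`, giving the
#' average per-cell signal; time points at or beyond `cutoff_h` (cell death /
#' media evaporation) are dropped.
#'
#' @param plate A [PlateTimeSeries-class].
#' @param cutoff_h Optional time cutoff in hours; only points strictly
#'   before it are kept.
#' @return List: `signal` (wells x kept timepoints), `timeH`, `wellMeta`.
#' @export
perCellSignal <- function(plate, cutoff_h = NULL) {
  keep <- if (is.null(cutoff_h)) rep(TRUE, length(plate@timeH)) else
    plate@timeH < cutoff_h
  if (!any(keep)) stop("cutoff removes all time points")
  sig <- plate@gfp[, keep, drop = FALSE] / plate@od600[, keep, drop = FALSE]
  list(signal = sig, timeH = plate@timeH[keep], wellMeta = plate@wellMeta)
}

#' Reporter fold change with propagated uncertainty
#'
#' Elementwise ratio of treated over control per-cell signal at matched
#' times. With replicate matrices (wells x timepoints), the ratio of
#' replicate means is returned along with a first-order (delta-method)
#' standard deviation:
#' `sd(a/b)^2 ~ (a/b)^2 (var(a)/a^2 + var(b)/b^2)` with replicate-mean a, b.
#'
#' @param treated,control Numeric vectors (single series) or replicate
#'   matrices with matching timepoint columns.
#' @return List: `fc` (fold-change series), `sd` (propagated standard
#'   deviation; zeros for single series).
#' @export
reporterFoldChange <- function(treated, control) {
  treated <- rbind(treated); control <- rbind(control)
  if (ncol(treated) != ncol(control))
    stop("treated and control must share the time grid")
  mt <- colMeans(treated); mc <- colMeans(control)
  if (any(mc == 0)) stop("control signal contains zeros")
  fc <- mt / mc
  vt <- if (nrow(treated) > 1) apply(treated, 2, var) else
    numeric(ncol(treated))
  vc <- if (nrow(control) > 1) apply(control, 2, var) else
    numeric(ncol(control))
  sdfc <- abs(fc) * sqrt(vt / mt^2 + vc / mc^2)
  list(fc = fc, sd = sdfc)
}

#' Time index of maximal fold change
#'
#' Returns the index of the largest deviation of the fold-change series from
#' unity on the side of its overall direction (maximum for activated,
#' minimum for repressed); ties resolve to the earliest index.
#'
#' @param fc Fold-change series.
#' @return Integer time index.
#' @export
maxFoldChangeTimepoint <- function(fc) {
  dev <- abs(log(fc))
  which.max(dev)
}

#' Evaluate a Hill transfer curve
#'
#' `y(c) = yMin + (yMax - yMin) c^n / (KM^n + c^n)`. Repressed reporters are
#' expressed with yMax < yMin.
#'
#' @param c Concentrations (>= 0).
#' @param fit A [HillFit-class], or a numeric vector `(yMin, yMax, KM, n)`.
#' @return Response values.
#' @export
hillCurve <- function(c, fit) {
  p <- if (is(fit, "HillFit")) hillParams(fit) else
    setNames(as.numeric(fit), c("yMin", "yMax", "KM", "n"))
  cn <- ifelse(c > 0, c^p["n"], 0)
  unname(p["yMin"] + (p["yMax"] - p["yMin"]) * cn / (p["KM"]^p["n"] + cn))
}

#' Fit a four-parameter Hill transfer curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with multi-start
#' initialization over log-spaced KM and a grid of Hill coefficients, since
#' Hill fits are multi-modal; the direction (activated vs repressed) is free.
#' Non-convergence of every start returns the best residual with
#' `converged = FALSE`; a KM pinned at the concentration-range boundary is
#' flagged with a warning (saturated/degenerate data).
#'
#' @param concentrations Analyte concentrations (uM), >= 4 distinct values.
#' @param responses Signal at each concentration.
#' @param weights Optional fitting weights (e.g. 1/sd^2).
#' @param n_starts Number of multi-start initializations (default 16).
#' @return A [HillFit-class].
#' @export
fitHill <- function(concentrations, responses, weights = NULL,
                    n_starts = 16) {
  conc <- as.numeric(concentrations)
  y <- as.numeric(responses)
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations for 4 free parameters")
  if (is.null(weights)) weights <- rep(1, length(y))
  pos <- conc[conc > 0]
  km_grid <- exp(seq(log(max(min(pos), 1e-6)), log(max(pos)),
                     length.out = max(2, ceiling(n_starts / 4))))
  n_grid <- c(0.5, 1.5, 3, 6)
  starts <- expand.grid(KM = km_grid, n = n_grid)
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  yr <- range(y)
  span <- max(diff(yr), abs(yr[2]), 1e-8)
  lower <- c(yMin = yr[1] - 2 * span, yMax = yr[1] - 2 * span,
             KM = 1e-8, n = 0.1)
  upper <- c(yMin = yr[2] + 2 * span, yMax = yr[2] + 2 * span,
             KM = max(pos) * 1e3, n = 20)
  best <- NULL
  df <- data.frame(conc = conc, y = y)
  for (i in seq_len(nrow(starts))) {
    start <- list(yMin = y[which.min(conc)], yMax = y[which.max(conc)],
                  KM = starts$KM[i], n = starts$n[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ yMin + (yMax - yMin) * ifelse(conc > 0, conc^n, 0) /
          (KM^n + ifelse(conc > 0, conc^n, 0)),
        data = df, start = start, weights = weights,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse,
                   converged = fit$convInfo$isConv)
    if (!is.null(best) && best$sse <= 1e-20 * max(1, sum(weights * y^2)))
      break
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  p <- coef(best$fit)
  if (p[["KM"]] <= lower[["KM"]] * (1 + 1e-6) ||
      p[["KM"]] >= upper[["KM"]] * (1 - 1e-6))
    warning("KM at boundary: data saturated or degenerate")
  new("HillFit", yMin = p[["yMin"]], yMax = p[["yMax"]], KM = p[["KM"]],
      n = p[["n"]], residualSSE = best$sse,
      converged = isTRUE(best$converged))
}

#' Invert a Hill transfer curve
#'
#' Closed-form inverse `c = KM * ((y - yMin) / (yMax - y))^(1/n)` for an
#' observed signal strictly between the asymptotes. Signals at or beyond the
#' asymptotes return `NA` with `saturated = TRUE`: beyond saturation the
#' analyte concentration is not discernable from the reporter.
#'
#' @param fit A [HillFit-class].
#' @param y_observed Observed signal(s).
#' @return data.frame: `y`, `concentration_uM`, `saturated`.
#' @export
invertHill <- function(fit, y_observed) {
  p <- hillParams(fit)
  lo <- min(p["yMin"], p["yMax"]); hi <- max(p["yMin"], p["yMax"])
  inside <- y_observed > lo & y_observed < hi
  conc <- rep(NA_real_, length(y_observed))
  ratio <- (y_observed[inside] - p["yMin"]) / (p["yMax"] - y_observed[inside])
  conc[inside] <- p["KM"] * ratio^(1 / p["n"])
  data.frame(y = y_observed, concentration_uM = unname(conc),
             saturated = !inside)
}

#' Growth rate and doubling time from an OD time course
#'
#' Detects the exponential phase as the maximum-slope rolling window on
#' log-OD (window size a quarter of the series, at least `min_points`),
#' then reports the endpoint rate
#' `ln(OD_final / OD_initial) / (t_final - t_initial)` over that window
#' (positive during growth), the same quantity with the opposite
#' initial/final orientation (`ratePaperSign`), the regression slope, and
#' the doubling time `ln(2) / rate`. A warning is raised when the window's
#' log-linear fit falls below `phase_r2` (no clean exponential phase).
#'
#' @param od_series Optical-density series (> 0).
#' @param time Time stamps (hours).
#' @param phase_r2 R-squared threshold below which the detected window is
#'   flagged as non-exponential.
#' @param min_points Minimum rolling-window size for slope detection.
#' @return List: `rate` (per h), `ratePaperSign`, `rateRegression`,
#'   `doubling_h` (NA when the rate is not positive), `window` (index
#'   range).
#' @export
growthStats <- function(od_series, time, phase_r2 = 0.99, min_points = 4) {
  od <- as.numeric(od_series); tt <- as.numeric(time)
  stopifnot(length(od) == length(tt), all(od > 0))
  ly <- log(od)
  n <- length(od)
  winR2 <- function(i, j) {
    yy <- ly[i:j]
    if (sd(yy) == 0) return(0)
    cor(tt[i:j], yy)^2
  }
  winSlope <- function(i, j) {
    if (sd(ly[i:j]) == 0) return(0)
    coef(lm(ly[i:j] ~ tt[i:j]))[[2]]
  }
  h <- min(n, max(min_points, ceiling(n / 4)))
  if (h < 2 || sd(ly) == 0) {
    i <- 1; j <- n
  } else {
    starts <- seq_len(n - h + 1)
    slopes <- vapply(starts, function(i) winSlope(i, i + h - 1), numeric(1))
    i <- which.max(slopes); j <- i + h - 1
    if (winR2(i, j) < phase_r2)
      warning("no clean exponential phase: window fit R^2 below ", phase_r2)
  }
  dt <- tt[j] - tt[i]
  rate <- (ly[j] - ly[i]) / dt
  slope <- winSlope(i, j)
  list(rate = rate, ratePaperSign = -rate, rateRegression = slope,
       doubling_h = if (rate > 0) log(2) / rate else NA_real_,
       window = c(i, j))
}

#' Reporter-wise correlation of responses across compounds
#'
#' Pearson correlation of each reporter's fold-change time course under the
#' reference analyte with its time course under another compound, probing
#' reporter specificity.
#'
#' @param fc_reference reporters x timepoints fold-change matrix (reference
#'   analyte).
#' @param fc_other reporters x timepoints matrix (other compound), same
#'   shape and row order.
#' @return Named numeric vector of per-reporter correlations.
#' @export
compoundCorrelation <- function(fc_reference, fc_other) {
  fc_reference <- as.matrix(fc_reference); fc_other <- as.matrix(fc_other)
  stopifnot(all(dim(fc_reference) == dim(fc_other)))
  out <- vapply(seq_len(nrow(fc_reference)), function(i)
    cor(fc_reference[i, ], fc_other[i, ]), numeric(1))
  names(out) <- rownames(fc_reference)
  out
}

#' Read plate-reader data from long-format CSV files
#'
#' @param plate_file CSV with columns `well`, `time_h`, `od600`, `gfp`.
#' @param map_file CSV with columns `well`, `strain`, `compound`,
#'   `concentration_uM`, `replicate`.
#' @return A [PlateTimeSeries-class].
#' @export
readPlateData <- function(plate_file, map_file) {
  long <- read.delim(plate_file, sep = ",")
  map <- read.delim(map_file, sep = ",")
  need <- c("well", "time_h", "od600", "gfp")
  if (!all(need %in% colnames(long)))
    stop("plate file needs columns: ", paste(need, collapse = ", "))
  wells <- unique(long$well)
  times <- sort(unique(long$time_h))
  shape <- function(col) {
    m <- matrix(NA_real_, length(wells), length(times),
                dimnames = list(wells, NULL))
    m[cbind(match(long$well, wells), match(long$time_h, times))] <- long[[col]]
    if (any(is.na(m))) stop("incomplete well x time grid in plate file")
    m
  }
  map <- map[match(wells, map$well), , drop = FALSE]
  PlateTimeSeries(gfp = shape("gfp"), od600 = shape("od600"), timeH = times,
                  wellMeta = map)
}
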