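## Preprocessing: counts -> TPM, low-expression filtering, fold change,
## standardization of the cell state.

#' Convert raw counts to transcripts per million (TPM)
#'
#' TPM normalizes for both gene length and sequencing depth: per column,
#' `TPM_g = 1e6 * (count_g / length_g) / sum_h(count_h / length_h)`, so each
#' column sums to one million.
#'
#' @param counts An [ExpressionTimeSeries-class] in counts, or a nonnegative
#'   count matrix.
#' @param gene_lengths_bp Positive gene lengths in base pairs, one per gene.
#' @return An `ExpressionTimeSeries` in TPM (or a matrix if a matrix was
#'   given).
#' @examples
#' computeTPM(matrix(c(10, 10), ncol = 1), c(1000, 2000))
#' @export
computeTPM <- function(counts, gene_lengths_bp) {
  mat <- if (is(counts, "ExpressionTimeSeries")) exprValues(counts) else
    as.matrix(counts)
  if (length(gene_lengths_bp) != nrow(mat))
    stop("need exactly one gene length per gene")
  if (any(gene_lengths_bp <= 0)) stop("gene lengths must be positive")
  if (any(mat < 0)) stop("counts must be nonnegative")
  rate <- mat / gene_lengths_bp
  denom <- colSums(rate)
  bad <- which(denom == 0)
  if (length(bad))
    stop("all-zero count column(s): ", paste(bad, collapse = ", "))
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  if (is(counts, "ExpressionTimeSeries")) {
    ExpressionTimeSeries(tpm, time_min = timeMin(counts),
                         replicate = replicateIds(counts),
                         condition = conditionLabel(counts), unit = "TPM",
                         gene_ids = rownames(mat))
  } else tpm
}

#' Filter genes with low average expression in every condition
#'
#' A gene is kept iff its average TPM is at least `threshold` in at least one
#' of the two conditions; genes below the threshold in all conditions are
#' discarded. Both matrices are subset consistently.
#'
#' @param perturbed,control [ExpressionTimeSeries-class] objects in TPM with
#'   identical gene ordering.
#' @param threshold Average-TPM threshold (default 100).
#' @return A list with elements `perturbed`, `control` (filtered), and
#'   `kept_gene_ids`.
#' @export
filterLowExpression <- function(perturbed, control, threshold = 100) {
  stopifnot(is(perturbed, "ExpressionTimeSeries"),
            is(control, "ExpressionTimeSeries"))
  if (exprUnit(perturbed) != "TPM" || exprUnit(control) != "TPM")
    stop("both inputs must be in TPM")
  if (!identical(rownames(perturbed), rownames(control)))
    stop("gene lists of the two conditions do not match")
  keep <- rowMeans(exprValues(perturbed)) >= threshold |
    rowMeans(exprValues(control)) >= threshold
  list(perturbed = perturbed[keep, ], control = control[keep, ],
       kept_gene_ids = rownames(perturbed)[keep])
}

checkPairedGrids <- function(perturbed, control) {
  if (!identical(rownames(perturbed), rownames(control)))
    stop("gene lists of the two conditions do not match")
  if (!identical(dim(perturbed), dim(control)))
    stop("condition matrices have mismatched shapes")
  if (!isTRUE(all.equal(timeMin(perturbed), timeMin(control))) ||
      !identical(replicateIds(perturbed), replicateIds(control)))
    stop("time grid / replicate pairing differs between conditions")
}

#' Pseudocounted fold change of perturbed over control
#'
#' Computes `z = (x_perturbed + 1) / (x_control + 1)` elementwise for matched
#' (time, replicate) snapshot columns; the +1 pseudocount keeps the ratio
#' finite and strictly positive. The pre-induction t = 0 sample is dropped by
#' default since the perturbation is introduced only after it is collected.
#'
#' @param perturbed,control Paired [ExpressionTimeSeries-class] objects (TPM).
#' @param drop_preinduction Drop the first (t = 0) column of every replicate.
#' @return A list: `z` (positive matrix), `time_min`, `replicate` per column.
#' @export
foldChange <- function(perturbed, control, drop_preinduction = TRUE) {
  checkPairedGrids(perturbed, control)
  z <- (exprValues(perturbed) + 1) / (exprValues(control) + 1)
  tm <- timeMin(perturbed)
  rep <- replicateIds(perturbed)
  if (drop_preinduction) {
    t0 <- min(tm)
    keep <- tm != t0
    z <- z[, keep, drop = FALSE]
    rep <- rep[keep]
    tm <- tm[keep]
  }
  list(z = z, time_min = tm, replicate = rep)
}

#' Background-subtracted expression (perturbed minus control)
#'
#' Elementwise TPM difference for display/reporting of selected biomarker
#' trajectories.
#'
#' @param perturbed,control Paired [ExpressionTimeSeries-class] objects.
#' @return Matrix of differences (perturbed - control).
#' @export
backgroundSubtract <- function(perturbed, control) {
  checkPairedGrids(perturbed, control)
  exprValues(perturbed) - exprValues(control)
}

#' Standardize the fold-change cell state
#'
#' Per gene, subtracts the time-average and divides by the time-standard
#' deviation (population convention by default), pooling all snapshot columns
#' of all replicates so a single standardization applies to every trajectory
#' entering one dynamical model. The removed mean corresponds to the
#' ever-present unit eigenvalue of the evolution operator; the variance
#' normalization stops fold-change magnitude from dictating the learned
#' connectivity. Genes with zero variance are dropped with a warning.
#'
#' @param z Positive fold-change matrix, or the list from [foldChange()].
#' @param time_min,replicate Per-column annotations (taken from the list if
#'   `z` is one).
#' @param sd_type `"population"` (divide by column count; default) or
#'   `"sample"`.
#' @return A [FoldChangeState-class].
#' @export
standardizeFoldChange <- function(z, time_min = NULL, replicate = NULL,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.list(z) && !is.null(z$z)) {
    time_min <- z$time_min; replicate <- z$replicate; z <- z$z
  }
  z <- as.matrix(z)
  if (ncol(z) < 2) stop("need at least 2 time points to standardize")
  if (any(z <= 0)) stop("fold changes must be strictly positive")
  if (is.null(time_min)) time_min <- seq_len(ncol(z))
  if (is.null(replicate)) replicate <- rep("rep1", ncol(z))
  mu <- rowMeans(z)
  ss <- rowSums((z - mu)^2)
  sigma <- sqrt(ss / if (sd_type == "population") ncol(z) else (ncol(z) - 1))
  zero <- sigma == 0
  if (all(zero)) stop("all genes are constant; nothing to standardize")
  dropped <- rownames(z)[zero]
  if (is.null(dropped)) dropped <- as.character(which(zero))
  if (any(zero))
    warning(sprintf("dropping %d constant gene(s) with sigma = 0", sum(zero)))
  zbar <- (z[!zero, , drop = FALSE] - mu[!zero]) / sigma[!zero]
  new("FoldChangeState", zbar = zbar, mu = mu[!zero], sigma = sigma[!zero],
      rawZ = z[!zero, , drop = FALSE], timeMin = as.numeric(time_min),
      replicate = as.character(replicate), dropped = as.character(dropped))
}

#' Invert the standardization exactly
#'
#' @param state A [FoldChangeState-class].
#' @param zbar Optional standardized matrix (defaults to the stored one).
#' @return The unstandardized fold-change matrix `zbar * sigma + mu`.
#' @export
destandardize <- function(state, zbar = stateMatrix(state)) {
  zbar * stateSigma(state) + stateMu(state)
}

## ---- delimited-text I/O -------------------------------------------------

#' Read an expression matrix from delimited text
#'
#' Expects genes as rows (first column = gene id) and a header encoding each
#' snapshot as `condition:time_min:replicate`.
#'
#' @param file Path to a TSV/CSV file.
#' @param unit `"counts"` or `"TPM"`.
#' @param sep Field separator (default tab).
#' @return An [ExpressionTimeSeries-class].
#' @export
readExpressionMatrix <- function(file, unit = c("counts", "TPM"),
                                 sep = "\t") {
  unit <- match.arg(unit)
  df <- read.delim(file, sep = sep, check.names = FALSE, row.names = 1)
  parts <- strsplit(colnames(df), ":", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("header columns must be 'condition:time_min:replicate'")
  condition <- unique(vapply(parts, `[`, "", 1))
  if (length(condition) != 1)
    stop("a file must hold exactly one condition; found: ",
         paste(condition, collapse = ", "))
  ExpressionTimeSeries(as.matrix(df),
                       time_min = as.numeric(vapply(parts, `[`, "", 2)),
                       replicate = vapply(parts, `[`, "", 3),
                       condition = condition, unit = unit,
                       gene_ids = rownames(df))
}

#' Write an expression matrix (or any gene x snapshot matrix) as TSV
#'
#' @param x An [ExpressionTimeSeries-class] or a matrix.
#' @param file Output path.
#' @export
writeExpressionMatrix <- function(x, file) {
  mat <- if (is(x, "ExpressionTimeSeries")) exprValues(x) else as.matrix(x)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
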