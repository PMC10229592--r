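#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' ExpressionTimeSeries: gene x (time x replicate) expression values
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' nonnegative expression matrix (raw counts or TPM) for one experimental
#' condition. Columns are (time point, replicate) snapshots; `colData` carries
#' `time_min` and `replicate`, and `metadata` carries `condition` and `unit`.
#'
#' @slot . inherits all SummarizedExperiment slots; the single assay is named
#'   `"values"`.
#' @export
setClass("ExpressionTimeSeries", contains = "SummarizedExperiment")

setValidity("ExpressionTimeSeries", function(object) {
  msg <- character()
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  v <- SummarizedExperiment::assay(object, "values")
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "expression values must be finite and nonnegative")
  cd <- colData(object)
  if (!all(c("time_min", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'time_min' and 'replicate'")
  unit <- metadata(object)$unit
  if (is.null(unit) || !unit %in% c("counts", "TPM"))
    msg <- c(msg, "metadata 'unit' must be 'counts' or 'TPM'")
  if (is.null(metadata(object)$condition))
    msg <- c(msg, "metadata 'condition' label is required")
  if (length(msg) == 0 && nrow(cd) > 0) {
    for (rep in unique(cd$replicate)) {
      tm <- cd$time_min[cd$replicate == rep]
      if (any(diff(tm) <= 0)) {
        msg <- c(msg, sprintf(
          "time stamps must be strictly increasing within replicate '%s'", rep))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionTimeSeries
#'
#' @param values Nonnegative matrix, genes x (time x replicate). Columns must
#'   be ordered replicate-block-wise with increasing time inside each block.
#' @param time_min Numeric vector of time stamps (minutes), one per column.
#' @param replicate Character/factor vector of replicate ids, one per column.
#' @param condition Condition label, e.g. `"perturbed"` or `"control"`.
#' @param unit `"counts"` or `"TPM"`.
#' @param gene_ids Optional row names; defaults to existing rownames of
#'   `values` or `gene_1..gene_n`.
#' @return An [ExpressionTimeSeries-class] object.
#' @examples
#' m <- matrix(rpois(20, 50), nrow = 2)
#' ets <- ExpressionTimeSeries(m, time_min = rep(seq(0, 40, 10), 2),
#'                             replicate = rep(c("r1", "r2"), each = 5),
#'                             condition = "control", unit = "counts")
#' @export
ExpressionTimeSeries <- function(values, time_min, replicate,
                                 condition = c("perturbed", "control"),
                                 unit = c("counts", "TPM"),
                                 gene_ids = NULL) {
  values <- as.matrix(values)
  condition <- match.arg(condition)
  unit <- match.arg(unit)
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(rownames(values))) rownames(values) else
      paste0("gene_", seq_len(nrow(values)))
  rownames(values) <- gene_ids
  replicate <- as.character(replicate)
  colnames(values) <- paste(condition, time_min, replicate, sep = ":")
  se <- SummarizedExperiment(
    assays = list(values = values),
    colData = DataFrame(time_min = as.numeric(time_min),
                        replicate = replicate),
    metadata = list(condition = condition, unit = unit))
  new("ExpressionTimeSeries", se)
}

#' @describeIn ExpressionTimeSeries expression matrix accessor
#' @param object,x An `ExpressionTimeSeries`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "values")

#' @describeIn ExpressionTimeSeries time stamps (minutes) per column
#' @export
timeMin <- function(x) colData(x)$time_min

#' @describeIn ExpressionTimeSeries replicate id per column
#' @export
replicateIds <- function(x) colData(x)$replicate

#' @describeIn ExpressionTimeSeries condition label
#' @export
conditionLabel <- function(x) metadata(x)$condition

#' @describeIn ExpressionTimeSeries expression unit ("counts" or "TPM")
#' @export
exprUnit <- function(x) metadata(x)$unit

#' FoldChangeState: standardized fold-change cell state
#'
#' Holds the standardized fold-change matrix together with the per-gene
#' time-mean and time-standard-deviation removed during standardization, so
#' the transformation is exactly invertible, plus the unstandardized
#' (pseudocounted, strictly positive) fold changes.
#'
#' @slot zbar Standardized fold-change matrix, genes x (m x r).
#' @slot mu Per-gene fold-change time averages (pooled over replicates).
#' @slot sigma Per-gene fold-change time standard deviations (population
#'   convention, pooled over replicates); strictly positive.
#' @slot rawZ Unstandardized fold-change matrix (> 0 elementwise).
#' @slot timeMin Time stamps per column (minutes).
#' @slot replicate Replicate id per column.
#' @slot dropped Ids of genes removed because sigma = 0.
#' @export
setClass("FoldChangeState", representation(
  zbar = "matrix", mu = "numeric", sigma = "numeric", rawZ = "matrix",
  timeMin = "numeric", replicate = "character", dropped = "character"))

setValidity("FoldChangeState", function(object) {
  msg <- character()
  if (!all(dim(object@zbar) == dim(object@rawZ)))
    msg <- c(msg, "zbar and rawZ dimensions differ")
  if (length(object@mu) != nrow(object@zbar) ||
      length(object@sigma) != nrow(object@zbar))
    msg <- c(msg, "mu/sigma length must equal gene count")
  if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be strictly positive")
  if (any(object@rawZ <= 0)) msg <- c(msg, "rawZ must be > 0 elementwise")
  if (length(object@timeMin) != ncol(object@zbar) ||
      length(object@replicate) != ncol(object@zbar))
    msg <- c(msg, "timeMin/replicate length must equal column count")
  if (length(msg)) msg else TRUE
})

#' @describeIn FoldChangeState standardized matrix accessor
#' @param x A `FoldChangeState`.
#' @export
stateMatrix <- function(x) x@zbar

#' @describeIn FoldChangeState per-gene fold-change means
#' @export
stateMu <- function(x) x@mu

#' @describeIn FoldChangeState per-gene fold-change standard deviations
#' @export
stateSigma <- function(x) x@sigma

#' @describeIn FoldChangeState unstandardized fold changes
#' @export
rawFoldChange <- function(x) x@rawZ

#' DMDModel: exact dynamic mode decomposition factors
#'
#' Rank-r factorization of the best-fit linear evolution operator of the
#' standardized fold-change state: projection basis U (left singular vectors
#' of the past-shifted snapshot matrix), reduced operator Khat, dynamic modes
#' V = U s, eigenvalues lambda, and amplitudes b.
#'
#' @slot rank Truncation rank r.
#' @slot basisU genes x r matrix with orthonormal columns.
#' @slot reducedK r x r reduced operator.
#' @slot modes genes x r complex matrix of dynamic modes (columns v_i).
#' @slot eigenvalues Complex vector lambda, ordered by descending modulus
#'   (conjugate pairs adjacent).
#' @slot amplitudes Complex vector b = pinv(V) z0 for the reference initial
#'   condition (replicate average).
#' @slot singularValues Retained singular values of the past snapshot matrix.
#' @slot z0 Reference initial condition used for the amplitudes.
#' @slot z0Reps genes x replicates matrix of per-replicate initial conditions.
#' @slot geneIds Gene identifiers.
#' @export
setClass("DMDModel", representation(
  rank = "integer", basisU = "matrix", reducedK = "matrix",
  modes = "matrix", eigenvalues = "complex", amplitudes = "complex",
  singularValues = "numeric", z0 = "numeric", z0Reps = "matrix",
  geneIds = "character"))

setValidity("DMDModel", function(object) {
  msg <- character()
  r <- object@rank
  if (ncol(object@basisU) != r) msg <- c(msg, "basisU must have r columns")
  if (!all(dim(object@reducedK) == c(r, r)))
    msg <- c(msg, "reducedK must be r x r")
  utu <- crossprod(object@basisU)
  if (max(abs(utu - diag(r))) > 1e-8)
    msg <- c(msg, "basisU columns must be orthonormal")
  if (length(object@eigenvalues) != r)
    msg <- c(msg, "need r eigenvalues")
  if (length(msg)) msg else TRUE
})

#' @describeIn DMDModel eigenvalues accessor
#' @param x A `DMDModel`.
#' @export
dmdEigenvalues <- function(x) x@eigenvalues

#' @describeIn DMDModel dynamic modes (genes x r, complex)
#' @export
dmdModes <- function(x) x@modes

#' @describeIn DMDModel amplitudes b
#' @export
dmdAmplitudes <- function(x) x@amplitudes

#' @describeIn DMDModel truncation rank
#' @export
dmdRank <- function(x) x@rank

#' @describeIn DMDModel projection basis U
#' @export
dmdBasis <- function(x) x@basisU

#' @describeIn DMDModel reduced operator Khat
#' @export
dmdReducedOperator <- function(x) x@reducedK

#' GramMatrix: finite-horizon observability Gram matrix
#'
#' @slot G Symmetric positive-semidefinite matrix (genes x genes, or r x r
#'   for the reduced-order route).
#' @slot horizon Finite horizon m (the sum runs i = 0..m).
#' @slot reduced Whether `G` lives in the reduced (mode) coordinates.
#' @export
setClass("GramMatrix", representation(
  G = "matrix", horizon = "integer", reduced = "logical"))

setValidity("GramMatrix", function(object) {
  msg <- character()
  if (nrow(object@G) != ncol(object@G)) msg <- c(msg, "G must be square")
  if (max(abs(object@G - t(object@G))) >
      1e-10 * max(1, max(abs(object@G))))
    msg <- c(msg, "G must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @describeIn GramMatrix matrix accessor
#' @param x A `GramMatrix`.
#' @export
gramValues <- function(x) x@G

#' @describeIn GramMatrix finite horizon
#' @export
gramHorizon <- function(x) x@horizon

#' GeneWeights: observability-optimal gene sampling weights
#'
#' Rows of `weightsW` are the top-p eigenvectors of the Gram matrix; the
#' primary weight vector w = q1 maximizes the total output signal energy over
#' the enriched initial conditions and ranks genes by their contribution to
#' observability.
#'
#' @slot weightsW p x genes matrix with orthonormal rows.
#' @slot primaryW The leading eigenvector q1 (unit norm).
#' @slot normalizedW q1 divided elementwise by the per-gene fold-change
#'   standard deviation (display/ranking variant).
#' @slot gramEigenvalues Descending eigenvalues of the Gram matrix.
#' @slot horizon Finite horizon used for the Gram matrix.
#' @slot nSyntheticICs Number of enriched initial conditions.
#' @slot seed RNG seed used for enrichment (NA if none).
#' @slot geneIds Gene identifiers.
#' @export
setClass("GeneWeights", representation(
  weightsW = "matrix", primaryW = "numeric", normalizedW = "numeric",
  gramEigenvalues = "numeric", horizon = "integer",
  nSyntheticICs = "integer", seed = "integer", geneIds = "character"))

setValidity("GeneWeights", function(object) {
  msg <- character()
  WWt <- tcrossprod(object@weightsW)
  if (max(abs(WWt - diag(nrow(object@weightsW)))) > 1e-8)
    msg <- c(msg, "rows of weightsW must be orthonormal")
  if (abs(sqrt(sum(object@primaryW^2)) - 1) > 1e-8)
    msg <- c(msg, "primaryW must have unit norm")
  if (is.unsorted(rev(object@gramEigenvalues)))
    msg <- c(msg, "gramEigenvalues must be sorted descending")
  if (any(object@gramEigenvalues < -1e-10 *
          max(1, abs(object@gramEigenvalues[1]))))
    msg <- c(msg, "gramEigenvalues must be nonnegative within tolerance")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneWeights primary sampling-weight vector (q1)
#' @param x A `GeneWeights`.
#' @export
primaryWeights <- function(x) setNames(x@primaryW, x@geneIds)

#' @describeIn GeneWeights sigma-normalized weights
#' @export
normalizedWeights <- function(x) setNames(x@normalizedW, x@geneIds)

#' @describeIn GeneWeights Gram-matrix eigenvalue spectrum
#' @export
gramSpectrum <- function(x) x@gramEigenvalues

#' HillFit: four-parameter Hill transfer curve
#'
#' y(c) = yMin + (yMax - yMin) * c^n / (KM^n + c^n). Repressed reporters are
#' represented with yMax < yMin (direction is free during fitting).
#'
#' @slot yMin Signal at zero analyte (signal units).
#' @slot yMax Asymptotic signal at saturating analyte.
#' @slot KM Half-maximal (Michaelis) constant, same units as the
#'   concentrations (uM).
#' @slot n Hill coefficient (cooperativity), dimensionless.
#' @slot residualSSE Sum of squared residuals of the fit.
#' @slot converged Whether the optimizer reported convergence.
#' @export
setClass("HillFit", representation(
  yMin = "numeric", yMax = "numeric", KM = "numeric", n = "numeric",
  residualSSE = "numeric", converged = "logical"))

setValidity("HillFit", function(object) {
  msg <- character()
  if (object@KM <= 0) msg <- c(msg, "KM must be positive")
  if (object@n <= 0) msg <- c(msg, "n must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn HillFit named parameter vector (yMin, yMax, KM, n)
#' @param x A `HillFit`.
#' @export
hillParams <- function(x) c(yMin = x@yMin, yMax = x@yMax, KM = x@KM, n = x@n)

#' PlateTimeSeries: plate-reader fluorescence/OD time courses
#'
#' @slot gfp wells x timepoints fluorescence matrix (arbitrary units).
#' @slot od600 wells x timepoints optical density matrix (> 0).
#' @slot timeH Time stamps in hours, strictly increasing.
#' @slot wellMeta Per-well metadata: `strain`, `compound`, `concentration_uM`,
#'   `replicate`.
#' @export
setClass("PlateTimeSeries", representation(
  gfp = "matrix", od600 = "matrix", timeH = "numeric",
  wellMeta = "DataFrame"))

setValidity("PlateTimeSeries", function(object) {
  msg <- character()
  if (!all(dim(object@gfp) == dim(object@od600)))
    msg <- c(msg, "gfp and od600 must have matching shapes")
  if (length(object@timeH) != ncol(object@gfp))
    msg <- c(msg, "timeH length must equal number of timepoints")
  if (any(diff(object@timeH) <= 0))
    msg <- c(msg, "timeH must be strictly increasing")
  if (nrow(object@wellMeta) != nrow(object@gfp))
    msg <- c(msg, "wellMeta rows must match wells")
  if (!all(c("strain", "compound", "concentration_uM", "replicate") %in%
           colnames(object@wellMeta)))
    msg <- c(msg, paste("wellMeta needs strain, compound,",
                        "concentration_uM, replicate"))
  if (length(msg)) msg else TRUE
})

#' Construct a PlateTimeSeries
#'
#' @param gfp,od600 wells x timepoints matrices.
#' @param timeH Time stamps (hours).
#' @param wellMeta data.frame or DataFrame of per-well metadata with columns
#'   `strain`, `compound`, `concentration_uM`, `replicate`.
#' @return A [PlateTimeSeries-class].
#' @export
PlateTimeSeries <- function(gfp, od600, timeH, wellMeta) {
  obj <- new("PlateTimeSeries", gfp = as.matrix(gfp),
             od600 = as.matrix(od600), timeH = as.numeric(timeH),
             wellMeta = DataFrame(wellMeta))
  validObject(obj)
  obj
}

## ---- show methods -------------------------------------------------------

setMethod("show", "FoldChangeState", function(object) {
  cat(sprintf(
    "FoldChangeState: %d genes x %d snapshots (%d replicates)\n",
    nrow(object@zbar), ncol(object@zbar),
    length(unique(object@replicate))))
  if (length(object@dropped))
    cat(sprintf("  %d constant genes dropped (sigma = 0)\n",
                length(object@dropped)))
})

setMethod("show", "DMDModel", function(object) {
  lam <- object@eigenvalues
  cat(sprintf("DMDModel: rank %d, %d genes\n",
              object@rank, nrow(object@modes)))
  cat(sprintf("  |lambda| range: [%.4f, %.4f]; %d unstable (|lambda| > 1)\n",
              min(Mod(lam)), max(Mod(lam)), sum(Mod(lam) > 1 + 1e-9)))
})

setMethod("show", "GramMatrix", function(object) {
  cat(sprintf("GramMatrix (%s): %d x %d, horizon %d\n",
              if (object@reduced) "reduced" else "full",
              nrow(object@G), ncol(object@G), object@horizon))
})

setMethod("show", "GeneWeights", function(object) {
  cat(sprintf(
    "GeneWeights: %d genes, %d orthonormal weight vectors, horizon %d\n",
    length(object@primaryW), nrow(object@weightsW), object@horizon))
  top <- head(order(abs(object@primaryW), decreasing = TRUE), 5)
  cat("  top |w| genes:", paste(object@geneIds[top], collapse = ", "), "\n")
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf(
    "HillFit: yMin = %.4g, yMax = %.4g, KM = %.4g, n = %.3g (SSE %.4g)%s\n",
    object@yMin, object@yMax, object@KM, object@n, object@residualSSE,
    if (object@converged) "" else " [not converged]"))
})

setMethod("show", "PlateTimeSeries", function(object) {
  cat(sprintf("PlateTimeSeries: %d wells x %d timepoints (%.2f-%.2f h)\n",
              nrow(object@gfp), ncol(object@gfp),
              min(object@timeH), max(object@timeH)))
})
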