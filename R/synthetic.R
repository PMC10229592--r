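## Ground-truth-known generators emulating the study design: a planted
## low-rank linear fold-change system inside a two-condition count
## experiment, and noisy Hill-shaped dose-response curves.

#' Construct a planted linear fold-change system
#'
#' Builds a genes x genes transition matrix whose dynamics live entirely on
#' a designated responsive gene set: a random non-normal operator on that
#' block with a real, decaying spectrum (eigenvalues drawn uniformly from
#' `eig_range`), all other rows and columns zero, so non-responsive genes
#' stay at the neutral standardized fold change up to noise. Replicate
#' initial conditions share one base excursion plus small per-replicate
#' jitter: biological replicates of the same perturbation see the same
#' response, which is what makes the response identifiable against
#' replicate-incoherent count noise.
#'
#' @param n_genes Total number of genes.
#' @param responsive_set Indices of perturbation-responsive genes (or a
#'   single integer count, taken from the front).
#' @param r_reps Number of replicate initial conditions.
#' @param eig_range Range of the (real) planted eigenvalues; the default
#'   c(0.8, 0.98) gives slow relative decay, i.e. dysregulation persisting
#'   across the sampled window.
#' @param ic_jitter_sd Standard deviation of the per-replicate jitter around
#'   the shared base initial condition.
#' @param noise_sd Observation noise standard deviation stored with the
#'   system (used by [simulateLinearSystem()]).
#' @param seed RNG seed.
#' @return List with `K_true`, `spectrum`, `responsive_set`, `z0_true`
#'   (genes x r_reps), `noise_sd`, `seed`.
#' @export
plantedSystem <- function(n_genes, responsive_set, r_reps = 2,
                          eig_range = c(0.8, 0.98), ic_jitter_sd = 0.1,
                          noise_sd = 0, seed = 0) {
  if (length(responsive_set) == 1 && responsive_set >= 1 &&
      responsive_set == round(responsive_set) && responsive_set <= n_genes &&
      length(responsive_set) != n_genes)
    responsive_set <- seq_len(responsive_set)
  responsive_set <- sort(unique(as.integer(responsive_set)))
  k <- length(responsive_set)
  withSeed(seed, {
    lam <- sort(runif(k, eig_range[1], eig_range[2]), decreasing = TRUE)
    Q <- matrix(rnorm(k * k), k, k)
    A <- Q %*% (lam * solve(Q))
    K <- matrix(0, n_genes, n_genes)
    K[responsive_set, responsive_set] <- A
    z0base <- rnorm(k)
    z0 <- matrix(0, n_genes, r_reps)
    for (j in seq_len(r_reps))
      z0[responsive_set, j] <- z0base + rnorm(k, 0, ic_jitter_sd)
    list(K_true = K, spectrum = as.complex(lam),
         responsive_set = responsive_set, z0_true = z0,
         noise_sd = noise_sd, seed = seed)
  })
}

#' Simulate trajectories of a planted linear system
#'
#' `z_t = K_true^t z0 + N(0, noise_sd)` per replicate, for t = 0..m-1;
#' replicate blocks are concatenated column-wise (the layout
#' [buildShiftMatrices()] expects).
#'
#' @param system A list from [plantedSystem()].
#' @param m Number of time points per replicate.
#' @param r_reps Number of replicates (<= columns of `z0_true`).
#' @param seed RNG seed for the noise.
#' @return List: `z` (genes x (m * r_reps)), `time`, `replicate`.
#' @export
simulateLinearSystem <- function(system, m, r_reps = ncol(system$z0_true),
                                 seed = 0) {
  K <- system$K_true
  n <- nrow(K)
  blocks <- list()
  for (j in seq_len(r_reps)) {
    x <- system$z0_true[, j]
    block <- matrix(0, n, m)
    for (t in seq_len(m)) {
      block[, t] <- x
      x <- as.numeric(K %*% x)
    }
    blocks[[j]] <- block
  }
  z <- do.call(cbind, blocks)
  if (system$noise_sd > 0)
    z <- z + withSeed(seed, matrix(rnorm(length(z), 0, system$noise_sd),
                                   nrow(z)))
  list(z = z, time = rep(seq_len(m) - 1, r_reps),
       replicate = rep(paste0("rep", seq_len(r_reps)), each = m))
}

#' Generate a two-condition count experiment with planted responders
#'
#' Emulates the study design: two conditions (perturbed, control) sampled at
#' `m` post-induction time points plus one shared pre-induction t = 0
#' sample, over `r_reps` biological replicates, with negative-binomial count
#' noise around gene-specific baselines. Responsive genes multiply their
#' baseline in the perturbed condition by `exp(effect_size * s_g(t))`, where
#' `s_g(t)` are trajectories of a planted stable linear system normalized to
#' RMS 0.5 per gene, so `effect_size = 2` yields log-fold-change excursions
#' of order one (fold changes up to several-fold, as strong responders
#' show).
#'
#' @param n_genes Number of genes (default 624, the modeled dataset's
#'   shape).
#' @param m Post-induction time points per replicate (default 9).
#' @param r_reps Replicates (default 2).
#' @param frac_responsive Fraction of genes carrying planted signal
#'   (default 0.1).
#' @param effect_size Log-scale amplitude multiplier on the planted
#'   trajectories (default 2).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2; default 0.05).
#' @param seed RNG seed; the whole experiment is a pure function of seed and
#'   parameters.
#' @param baseline_range Range of gene baseline expression (TPM-scale,
#'   log-uniform; default c(200, 2000), emulating the high-abundance
#'   post-filter universe).
#' @param time_step_min Sampling interval in minutes (default 10).
#' @return List: `perturbed`, `control` ([ExpressionTimeSeries-class] in
#'   counts, including the t = 0 column), `gene_lengths_bp`,
#'   `truth_responsive` (logical per gene), `system`, `baseline`.
#' @export
generateTwoConditionExperiment <- function(n_genes = 624, m = 9, r_reps = 2,
                                           frac_responsive = 0.1,
                                           effect_size = 2,
                                           dispersion = 0.05, seed = 0,
                                           baseline_range = c(200, 2000),
                                           time_step_min = 10) {
  n_resp <- round(frac_responsive * n_genes)
  withSeed(seed, {
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    lengths_bp <- round(runif(n_genes, 500, 3000))
    baseline <- exp(runif(n_genes, log(baseline_range[1]),
                          log(baseline_range[2])))
    responsive <- rep(FALSE, n_genes)
    if (n_resp > 0) responsive[sample.int(n_genes, n_resp)] <- TRUE
    ## planted log-fold-change trajectories on the responsive genes
    logfc <- matrix(0, n_genes, m * r_reps)
    system <- NULL
    if (n_resp > 0) {
      system <- plantedSystem(n_genes, which(responsive), r_reps = r_reps,
                              seed = seed + 1L)
      sim <- simulateLinearSystem(system, m = m, r_reps = r_reps)
      s <- sim$z
      rms <- sqrt(rowMeans(s^2))
      scale <- ifelse(rms > 0, 0.5 / rms, 0)
      logfc <- s * scale * effect_size
    }
    ## each replicate contributes the shared pre-induction t = 0 sample
    ## followed by the m post-induction samples
    col_time <- as.numeric(unlist(lapply(seq_len(r_reps), function(j)
      c(0, seq_len(m) * time_step_min))))
    col_rep <- rep(paste0("rep", seq_len(r_reps)), each = m + 1)
    mu_gene <- baseline * lengths_bp / 1000
    draw <- function(mu) {
      size <- 1 / dispersion
      matrix(rnbinom(length(mu), mu = mu, size = size), nrow = n_genes)
    }
    mu_ctrl <- matrix(mu_gene, n_genes, (m + 1) * r_reps)
    mu_pert <- mu_ctrl
    post_cols <- which(col_time != 0)
    ## map post-induction columns to logfc columns (same replicate order)
    mu_pert[, post_cols] <- mu_ctrl[, post_cols] * exp(logfc)
    control <- ExpressionTimeSeries(draw(mu_ctrl), time_min = col_time,
                                    replicate = col_rep,
                                    condition = "control", unit = "counts",
                                    gene_ids = gene_ids)
    perturbed <- ExpressionTimeSeries(draw(mu_pert), time_min = col_time,
                                      replicate = col_rep,
                                      condition = "perturbed",
                                      unit = "counts", gene_ids = gene_ids)
    list(perturbed = perturbed, control = control,
         gene_lengths_bp = setNames(lengths_bp, gene_ids),
         truth_responsive = setNames(responsive, gene_ids),
         system = system, baseline = setNames(baseline, gene_ids))
  })
}

#' Generate noisy Hill dose-response data
#'
#' Evaluates a Hill transfer curve at the given concentrations and applies
#' multiplicative Gaussian noise with coefficient of variation `noise_cv`
#' per replicate.
#'
#' @param hill A [HillFit-class] or parameter vector `(yMin, yMax, KM, n)`.
#' @param concentrations Analyte concentrations (uM).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 for exact curves).
#' @param reps Number of replicates.
#' @param seed RNG seed.
#' @return Matrix reps x concentrations of responses.
#' @export
generateDoseResponse <- function(hill, concentrations, noise_cv = 0.05,
                                 reps = 3, seed = 0) {
  y <- hillCurve(concentrations, hill)
  out <- withSeed(seed, {
    noise <- matrix(rnorm(reps * length(y), 0, noise_cv), reps)
    sweep(1 + noise, 2, y, "*")
  })
  colnames(out) <- as.character(concentrations)
  out
}
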