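## End-to-end orchestration: preprocess -> DMD -> weights -> reconstruction
## -> selection, with a machine-readable run manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list [runPipeline()] consumes, pre-filled with
#' the analysis defaults (TPM threshold 100, rank 10, horizon = number of
#' modeled time points, enrichment size = gene count, seed 0, top-half
#' random search with k = 15 at T = 8).
#'
#' @param ... Named overrides merged over the defaults.
#' @return Named list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    perturbed = NULL, control = NULL, lengths = NULL,
    synthetic = NULL,                  # list of generator overrides, or TRUE
    tpm_threshold = 100,
    drop_preinduction = TRUE,
    rank_r = 10,
    horizon = NULL, n_ics = NULL,
    mc_reps = 100, mc_genes_per_draw = 50,
    seed = 0L,
    selection = list(strategy = "search", threshold = 0.5, k = 15,
                     trials = 200, pool_fraction = 0.5, T_steps = 8),
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: load (or synthesize) the paired count matrices, TPM
#' conversion, low-expression filtering, fold change (dropping the
#' pre-induction sample), standardization, exact DMD at the configured rank,
#' initial-condition enrichment and Gram-matrix sampling weights, the
#' category Monte Carlo reconstruction experiment, and the configured
#' gene-set selection strategy. Every stochastic stage derives its seed from
#' the master seed and the manifest records all of them, so a rerun with the
#' same configuration is identical.
#'
#' @param config List from [defaultConfig()], or a path to a YAML file with
#'   the same fields.
#' @return List: `manifest` (parameters, seeds, per-stage summaries),
#'   `state`, `model`, `weights`, `selection`, `category_mc`; tables are
#'   also written under `out_dir` when it is set.
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- defaultConfig() |>
      modifyList(yaml::read_yaml(config))
  cfg <- config
  seed <- as.integer(cfg$seed)
  stage <- "load"
  res <- tryCatch({
    if (!is.null(cfg$synthetic)) {
      args <- if (is.list(cfg$synthetic)) cfg$synthetic else list()
      args$seed <- seed
      sim <- do.call(generateTwoConditionExperiment, args)
      perturbed <- sim$perturbed; control <- sim$control
      lengths <- sim$gene_lengths_bp
      truth <- sim$truth_responsive
    } else {
      perturbed <- readExpressionMatrix(cfg$perturbed, unit = "counts")
      control <- readExpressionMatrix(cfg$control, unit = "counts")
      ltab <- read.delim(cfg$lengths)
      lengths <- setNames(ltab[[2]], ltab[[1]])[rownames(perturbed)]
      truth <- NULL
    }
    stage <- "preprocess"
    pert_tpm <- computeTPM(perturbed, lengths)
    ctrl_tpm <- computeTPM(control, lengths)
    filt <- filterLowExpression(pert_tpm, ctrl_tpm,
                                threshold = cfg$tpm_threshold)
    fc <- foldChange(filt$perturbed, filt$control,
                     drop_preinduction = cfg$drop_preinduction)
    state <- standardizeFoldChange(fc)
    stage <- "dmd"
    model <- fitExactDMD(state, rank_r = cfg$rank_r)
    r2 <- modelR2(model, state)
    stage <- "weights"
    weights <- computeGeneWeights(model, state, horizon_m = cfg$horizon,
                                  n_ics = cfg$n_ics, seed = seed + 1L)
    ranking <- rankGenes(weights)
    stage <- "reconstruction"
    K <- fullOperator(model)
    mc <- categoryMonteCarlo(weights, K, model@z0,
                             T_steps = cfg$selection$T_steps,
                             genes_per_draw = cfg$mc_genes_per_draw,
                             reps = cfg$mc_reps, seed = seed + 2L)
    mc_means <- tapply(mc$r2, mc$category, mean)
    stage <- "selection"
    sel_cfg <- cfg$selection
    sel <- switch(sel_cfg$strategy,
      top = selectTopK(weights, stateMatrix(state), k = sel_cfg$k,
                       model = model, state = state,
                       T_steps = sel_cfg$T_steps),
      corr = selectCorrelationThreshold(weights, stateMatrix(state),
                                        threshold = sel_cfg$threshold,
                                        k = sel_cfg$k, model = model,
                                        state = state,
                                        T_steps = sel_cfg$T_steps),
      search = {
        rs <- randomSetSearch(weights, stateMatrix(state), model, state,
                              k = sel_cfg$k,
                              pool_fraction = sel_cfg$pool_fraction,
                              trials = sel_cfg$trials,
                              T_steps = sel_cfg$T_steps, seed = seed + 3L)
        best <- rs$best_by_r2
        list(gene_ids = rs$sets[[best]],
             C_metric = rs$trials$C[best],
             recon_r2 = rs$trials$r2[best],
             strategy = "random_search",
             r2_percentile = rs$trials$r2_percentile[best],
             trials = rs$trials)
      },
      stop("unknown selection strategy: ", sel_cfg$strategy))
    list(state = state, model = model, weights = weights, ranking = ranking,
         selection = sel, category_mc = mc, truth = truth, r2 = r2,
         mc_means = mc_means)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)))
  })
  manifest <- list(
    package_version = as.character(packageVersion("obsight")),
    parameters = list(tpm_threshold = cfg$tpm_threshold,
                      rank_r = cfg$rank_r,
                      horizon = res$weights@horizon,
                      n_ics = res$weights@nSyntheticICs,
                      selection = cfg$selection[
                        setdiff(names(cfg$selection), "trials_table")]),
    seeds = list(master = seed, enrichment = seed + 1L,
                 monte_carlo = seed + 2L, selection = seed + 3L),
    summary = list(
      n_genes_modeled = nrow(stateMatrix(res$state)),
      dmd_r2 = res$r2,
      n_unstable = sum(Mod(dmdEigenvalues(res$model)) > 1 + 1e-9),
      gram_spectrum_head = head(gramSpectrum(res$weights), 5),
      mc_mean_r2 = as.list(res$mc_means),
      selected_set = res$selection$gene_ids,
      selection_C = res$selection$C_metric,
      selection_recon_r2 = res$selection$recon_r2))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeExpressionMatrix(stateMatrix(res$state),
                          file.path(cfg$out_dir, "state_zbar.tsv"))
    write.table(res$ranking, file.path(cfg$out_dir, "gene_ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$category_mc,
                file.path(cfg$out_dir, "category_monte_carlo.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(list(manifest = manifest), res)
}
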