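# obsight

Observability-based biomarker discovery from time-series transcriptomics.

## The problem

Given a perturbation experiment — RNA-seq time courses of a perturbed and
a control culture, few biological replicates — which genes are the best
*reporters* of the perturbation? Differential expression loses power with
two replicates and does not say which genes, once measured, would let you
infer the rest of the transcriptional state. `obsight` answers the
question with tools from dynamical systems:

1. **Model.** The cell state is the standardized fold change
   `z = (x_perturbed + 1) / (x_control + 1)` (TPM, low-expression genes
   filtered). Exact dynamic mode decomposition (DMD) fits the best rank-r
   linear evolution `z_{t+1} ≈ K z_t` from time-shifted snapshot
   matrices: `K̂ = Uᵀ Z_f T Σ⁻¹` from the truncated SVD
   `Z_p = U Σ Tᵀ`, with modes `V = U·eigvec(K̂)`, eigenvalues `λ`, and
   spectral prediction `ẑ_t = V Λᵗ V† z₀`.
2. **Rank.** Measuring genes with weights `w` yields the output
   `y_t = wᵀ Kᵗ z₀` with signal energy `Σ y_t² = z₀ᵀ 𝒳ₒ z₀`, a quadratic
   form in the observability Gramian. The unit-norm `w` maximizing total
   energy over (enriched) initial conditions is the leading eigenvector
   of the finite-horizon Gram matrix `G = Σᵢ Kⁱ Z₀ Z₀ᵀ (Kⁱ)ᵀ`; the entry
   magnitudes rank genes by contribution to observability.
3. **Validate.** Masking `w` to a gene subset, simulating outputs, and
   applying the Moore–Penrose pseudoinverse of the observability matrix
   `𝒪_T = [wᵀ; wᵀK; …; wᵀK^T]` reconstructs the initial cell state;
   reconstruction R² and the set-correlation metric
   `C = ‖1 − |R|‖_F` score candidate biomarker panels.
4. **Characterize.** Reporter strains' plate-reader dose-responses are
   fit with four-parameter Hill transfer curves
   `y(c) = y_min + (y_max − y_min)·cⁿ/(K_Mⁿ + cⁿ)` and inverted in closed
   form to infer analyte concentrations from observed signals.

A seeded synthetic-data generator emulates the whole study design
(two-condition count matrices with planted perturbation-responsive
genes, noisy Hill curves), so every stage is testable without any
download.

## Worked example

```r
library(obsight)

sim   <- generateTwoConditionExperiment(n_genes = 624, seed = 7)
tpm_p <- computeTPM(sim$perturbed, sim$gene_lengths_bp)
tpm_c <- computeTPM(sim$control,   sim$gene_lengths_bp)
kept  <- filterLowExpression(tpm_p, tpm_c, threshold = 100)
state <- standardizeFoldChange(foldChange(kept$perturbed, kept$control))
state
#> FoldChangeState: 624 genes x 18 snapshots (2 replicates)

model <- fitExactDMD(state, rank_r = 10)
model
#> DMDModel: rank 10, 624 genes
#>   |lambda| range: [0.3664, 0.7505]; 0 unstable (|lambda| > 1)
modelR2(model, state)
#> [1] 0.185

w <- computeGeneWeights(model, state, seed = 7)
head(rankGenes(w), 3)
#>             gene_id         w w_normalized rank_raw rank_normalized
#> gene_0180 gene_0180 0.1263440   0.06201114        1             373
#> gene_0031 gene_0031 0.1247704   0.06840945        2             355
#> gene_0279 gene_0279 0.1226943   0.04679189        3             438
```

Reading the numbers: 624 genes × 9 post-induction time points × 2
replicates enter one standardized fold-change state; the rank-10 model is
stable (no eigenvalue outside the unit circle) and explains 18.5% of the
pooled variance — low here because 90% of the synthetic genes are pure
count noise by construction (on coherent real data this number is far
higher). The ranking is what matters: of this run's 62 planted responder
genes, 37 sit in the top decile of the raw-|w| ranking, and across 20
generator seeds the planted/non-planted AUC averages 0.91. The
`w_normalized` column shows why raw |w| is the default ranking: dividing
by each gene's raw fold-change spread demotes genuine responders (see the
methods vignette).

Downstream, `categoryMonteCarlo()` and `genesByTimeSweep()` quantify how
reconstruction accuracy depends on which and how many genes are sampled
for how long, `selectTopK()` / `selectCorrelationThreshold()` /
`randomSetSearch()` turn the ranking into candidate reporter panels, and
`fitHill()` / `invertHill()` characterize the resulting reporter strains:

```r
conc <- c(0, 0.035, 0.07, 0.14, 0.28, 0.56, 1.12, 2.24)   # uM
fit  <- fitHill(conc, hillCurve(conc, c(yMin = 200, yMax = 1200,
                                        KM = 0.5, n = 2)))
fit
#> HillFit: yMin = 200, yMax = 1200, KM = 0.5, n = 2 (SSE 4.445e-21)
invertHill(fit, 700)          # midpoint signal -> c = KM
#>     y concentration_uM saturated
#> 1 700              0.5     FALSE
```

`runPipeline(defaultConfig(synthetic = TRUE, seed = 0))` chains all
stages and writes a manifest recording every parameter and seed; a thin
command-line front end lives in `exec/obsight`.

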