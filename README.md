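# cfmr — cross-fitted instruments for one-sample Mendelian randomization

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of an exposure on an outcome. The gold
standard, two-sample MR, requires two disjoint cohorts — one to select the
instruments, one to estimate the effect — because selecting and applying
instruments in the *same* sample induces endogeneity bias (weak-instrument
bias plus winner's curse), which pulls the estimate toward the confounded
association and inflates the type-I error.

`cfmr` implements a conservative one-sample alternative built on
**cross-fitted instruments (CFI)**. Under the linear structural model

    Y = β₀ X + U,        X = Z Π + V,       Cov(U, V) = σ_UV ≠ 0,

the cohort is split into K random folds; for each fold k an exposure
predictor is trained on the fold's complement (marginal exposure GWAS →
greedy LD clumping → p-value selection → L1-penalized regression with a
cross-validated penalty), and the exposure of fold k is predicted
out-of-fold. The concatenated predictions X̆ instrument a two-stage least
squares:

    β̂₀ = [XᵗX̆ (X̆ᵗX̆)⁻¹ X̆ᵗX]⁻¹ XᵗX̆ (X̆ᵗX̆)⁻¹ X̆ᵗY        (CFMR2)

Because no individual's data (and never the outcome) enters the model that
predicts that individual, the instrument is independent of the second-stage
error: the leading endogeneity-bias term (Υ/N)·σ_UV vanishes, and any
residual finite-sample bias points toward the null. A fold-averaged variant
(CFMR1), the naive one-sample baseline (1SMR), a jackknife-IV limit (K = N),
per-population estimation with fixed-effect meta-analysis, a synthetic
cohort generator with heritability-calibrated effect sizes, and a
Monte-Carlo scenario driver (type-I error, bias, power, convergence) are all
included. Audience: statistical geneticists and epidemiologists running MR
in a single cohort, and methodologists studying weak-instrument behavior.

## Worked example

```r
library(cfmr)

# a synthetic cohort: N = 5000, 300 independent variants at MAF 0.3,
# five causal variants explaining h² = 20% of the exposure, β₀ = 0.05,
# confounded errors (σ_UV = 0.8)
cohort <- simulateDataset(simulationConfig(
    nIndividuals = 5000, h2 = 0.2, beta0 = 0.05, seed = 1))

part <- makeFolds(5000, k = 10, seed = 1)
cfi  <- buildCFI(cohort, partition = part)
cfi
#> CrossFittedInstrument: n=5000, k=10, held-out R2 0.1965 (mean), 0 degenerate fold(s)

cfiDiagnostics(cfi, exposure(cohort))$variance_explained_pct
#> [1] 19.42
cfmr2(exposure(cohort), outcome(cohort), cfi)
#> CFMR2 estimate: 0.0199 (SE 0.0291), 95% CI [-0.0371, 0.0769], p = 0.494
#>   n=5000, instruments=1, folds=10
```

The instrument recovers the calibrated 20% of exposure variance out-of-fold,
and the CFMR2 estimate brackets the generative effect 0.05 with an honest
confidence interval. The endogeneity-bias term the cross-fitting removes can
be inspected directly: `nagarBiasTerm(300, 5000, 0.8)` → `0.048`, the bias
scale a naive 300-instrument 2SLS would face at this sample size.

A thin command line covers the same pipeline
(`system.file("scripts", "cfmr.R", package = "cfmr")`):

```sh
Rscript cfmr.R simulate  --out sim --n 5000 --h2 0.2 --beta0 0.05 --seed 1
Rscript cfmr.R cfmr      --genotypes sim/cohort_genotypes.tsv \
                         --phenotypes sim/cohort_phenotypes.tsv --out est
Rscript cfmr.R benchmark --out bench --n 2000 --beta0 0,0.08 --replicates 100
```

Every run writes its fully resolved configuration (`run_config.yaml`) next
to its outputs.

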