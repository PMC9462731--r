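---
title: "Cross-fitted instruments for one-sample Mendelian randomization: methods and design"
author: "cfmr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-fitted instruments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmr)
```

## The problem

Mendelian randomization (MR) estimates the causal effect of a modifiable
exposure $X$ on an outcome $Y$ by using genetic variants $Z$ as instrumental
variables. The working structural model is linear:

$$Y = \beta_0 X + U, \qquad X = Z \Pi + V,$$

with $E[U \mid \Pi, Z] = 0$ and $E[V \mid Z] = 0$. The errors $(U, V)$ may be
correlated — that correlation, $\sigma_{UV}$, is exactly the confounding that
makes the naive regression of $Y$ on $X$ invalid and motivates the
instrument.

Two-sample MR selects instruments in one cohort and estimates $\beta_0$ in a
second, disjoint cohort; this keeps the estimate conservative even when the
instruments are weak. One-sample MR — selecting and applying the instruments
in the same cohort — is tempting whenever no second cohort exists, but it
suffers *endogeneity bias*: weak-instrument bias plus the winner's curse. The
leading term of that bias in naive two-stage least squares (2SLS) with
$\Upsilon$ instruments on $n$ samples is

$$\frac{\Upsilon}{n}\,\sigma_{UV},$$

the quantity returned by `nagarBiasTerm()`. It pulls the estimate *toward the
confounded association*, which is the dangerous direction: it manufactures
false positives.

## The cross-fitted instrument

The package implements the cross-fitting repair. Split the cohort into $K$
random folds $I_1, \dots, I_K$ (`makeFolds()`; fold sizes differ by at most
one, the first $n \bmod K$ folds taking the extra element). For each fold
$k$:

1. run a GWAS-style marginal scan of the exposure on every variant using
   only the complement $I_k^c$ (`marginalScan()`);
2. thin the hits to approximately independent variants by greedy clumping
   and a p-value threshold (`greedyClump()`, `selectByPvalue()`);
3. train an exposure predictor on $I_k^c$ (`fitPredictor()`; by default an
   L1-penalized regression with its penalty chosen by cross-validated
   prediction error);
4. predict the exposure on the held-out fold $I_k$.

The concatenation of the out-of-fold predictions is the *cross-fitted
instrument* $\breve X$ (`buildCFI()`). Because the model that predicts
individual $i$ never saw individual $i$ — and never saw the outcome at all —
$\breve X$ is independent of the second-stage error $U$, which removes the
endogeneity-bias term above. Two estimators use it:

- **CFMR1** (`cfmr1()`): a single-instrument 2SLS within each fold, averaged
  with equal weights across folds;
- **CFMR2** (`cfmr2()`): one 2SLS on the whole cohort with $\breve X$ as the
  instrument,
  $$\hat\beta_0 = [X^t \breve X (\breve X^t \breve X)^{-1} \breve X^t X]^{-1}
    X^t \breve X (\breve X^t \breve X)^{-1} \breve X^t Y.$$

The two are asymptotically equivalent; CFMR2 behaves better in finite
samples (CFMR1 averages noisy small-fold estimates) and is the one to use in
practice. With $K = n$ and leave-one-out least-squares predictors, CFMR2
coincides with the jackknife IV estimator — a property the test suite checks
against an independently coded leave-one-out oracle.

The payoff is *conservativeness*: when the instrument is weak, the
cross-fitted estimate is at worst biased toward zero, never toward the
confounded effect, and the type-I error stays controlled even at zero
heritability. The naive baseline (`oneSampleMR()`, which trains one
predictor on all data and instruments with its in-sample prediction) is
provided deliberately so the contrast can be measured.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `k` (folds) | 10 | 2–5 splits suffice for very large cohorts and heritable exposures; 20–30 can help below ~5,000 samples. 10 is a robust rule of thumb. `k = n` gives jackknife IV. |
| `pThreshold` | 1e-6 | GWAS inclusion cutoff (strict `<`). Looser thresholds admit more weakly associated variants; in applications they also risk instruments associated with confounders, which `cfiDiagnostics()` screens for. |
| `clumpR2` | 0.1 | greedy clumping cutoff on squared dosage correlation; `NULL` disables. |
| `windowBp` | NULL (infinite) | clumping window; finite windows require variant positions. |
| predictor `method` | "lasso" | alternatives: "allele-score" (marginal slopes as fixed weights), "ols", "fixed" (for oracle checks). |
| `cvFolds` | 10 | inner CV folds for the lasso penalty, chosen at the CV-error minimum; the CV seed is explicit for reproducibility. |
| `alpha` | 0.05 | nominal test size for rejection rates. |

Units: `beta0` is outcome units per exposure unit; variance parameters are on
the phenotype scale; `maf` is an allele frequency in $(0, 0.5]$.

## The synthetic-data generator

`simulateDataset()` draws independent biallelic dosages as Binomial(2, maf)
(Hardy–Weinberg, no linkage disequilibrium), gives the first `nCausal`
variants a common effect $\pi$, and adds bivariate-normal errors. The default
scenario — 300 variants at MAF 0.3, five causal, error variances 5 with
covariance 0.8 (4.9 in the strong-confounding overlap design) — is the
package's standard study condition. The effect size is calibrated in closed
form so the causal variants explain exactly the requested fraction $h^2$ of
the exposure variance:

$$n_c\,\pi^2\,2\,\mathrm{maf}(1-\mathrm{maf})
  = \frac{h^2}{1-h^2}\,\sigma_V^2,$$

an identity the tests verify both algebraically and empirically (the
empirical $R^2$ at $n = 10^6$ matches $h^2$ to within 0.01). Genotypes are
kept as unstandardized dosages; variance-explained statements are honored
through this calibration rather than through scaling.

What the generator does *not* emulate: linkage disequilibrium, realistic
allele-frequency spectra, binary traits, pleiotropy, population
stratification within a stratum, relatedness. Passing tests therefore
certify the estimator's behavior under the stated linear model with
independent variants — they do not certify robustness to pleiotropy or
LD-induced instrument correlation in real data (clumping handles the latter
operationally, but the simulations do not stress it).

Each dataset is bit-for-bit regenerable from one integer seed; scenario
grids derive replicate $r$'s seed as `baseSeed + r`, so any replicate can be
reproduced in isolation and cells with the same generative parameters share
matched seeds (method contrasts are within-replicate).

## Numerical and design choices

- **2SLS standard error.** Homoskedastic second-stage formula:
  $e = Y - X\hat\beta$ on the covariate-residualized frame,
  $\hat\sigma^2 = e^te/(n - q - 2)$, $Var(\hat\beta) =
  \hat\sigma^2 [X^tZ(Z^tZ)^{-1}Z^tX]^{-1}$. A sandwich variant is available
  via `robust = TRUE`. The normal approximation is known to be conservative
  for weak instruments at modest $n$, which contributes to the tight type-I
  control.
- **CFMR1 variance** sums per-fold variances over the folds used and divides
  by their squared count; this treats folds as independent although their
  training complements overlap, and is documented as an approximation.
  CFMR2 needs no such approximation.
- **Covariates** are handled by Frisch–Waugh residualization of exposure,
  outcome and instrument on `[1, C]`, equivalent to carrying the covariates
  through both stages. The per-fold scans residualize dosages and exposure
  the same way. Predictors themselves are trained on dosages only.
- **Clumping determinism.** Candidates are processed in ascending p-value
  order with ties broken by variant index. `buildCFI()` thresholds before
  clumping among the survivors; this is provably the same retained set as
  clumping first, because a sub-threshold variant always has a larger
  p-value than every super-threshold variant and so can never shadow one.
- **Degenerate folds.** A fold whose selection is empty, or whose penalty
  removes every coefficient, yields an intercept-only predictor flagged
  `degenerate`. CFMR1 drops such folds with a warning; CFMR2 uses the
  instrument as concatenated and reports the count; `buildCFI()` fails when
  *every* fold is degenerate (no identification) unless `strict = FALSE`
  requests the flagged object for inspection.
- **Single-variant lasso.** `glmnet` requires two or more columns, so a
  one-variant selection is fitted by unpenalized simple regression — with
  one strong predictor and a CV-minimal penalty, the lasso solution is
  essentially that regression anyway.
- **Remainder rule.** Fold size $n/K$ is not generally an integer; this
  package assigns the extra elements to the first $n \bmod K$ folds.
- **Meta-analysis** across populations is fixed-effect inverse-variance
  (the target is one shared causal effect); Cochran's Q is reported so
  heterogeneity of the *effect* (as opposed to the genetic architecture,
  which per-stratum instruments absorb by design) can be detected. Strata
  below a configurable size floor (default 100) are excluded with a
  warning.
- **Failure accounting.** In scenario grids a failed replicate (for
  example, an all-degenerate instrument at $h^2 = 0$) is recorded and
  counts as a non-rejection; its rate is itself a reported diagnostic.

## Desk-scale Monte-Carlo settings

The package's own test suite exercises the full simulation studies at sizes
chosen for a single-CPU desk run; all Monte-Carlo bounds use binomial or
empirical standard errors at the replicate counts actually run:

- type-I error at $N = 5{,}000$, $K = 10$, 100 replicates, at $h^2 = 20\%$
  and at $h^2 = 0$. For the $h^2 = 0$ cell the selection threshold is
  relaxed to $p < 0.01$ so that folds retain a handful of noise variants:
  with a stringent threshold every fold would be degenerate and the check
  would never exercise inference with a genuinely uninformative instrument.
- the complete-overlap bias contrast at $N = 1{,}000$ (the grid point where
  endogeneity bias is largest), $\sigma_{UV} = 4.9$, $\beta_0 = 0.08$,
  $h^2 \in \{10\%, 20\%\}$, 50 matched-seed replicates, with the lasso fit
  over all 300 variants and no pre-threshold in both arms — the in-sample
  overfitting of the full lasso is precisely the mechanism the naive
  baseline's bias comes from, so pre-thresholding would change the object
  of study.
- power at $N = 10{,}000$, $\beta_0 \in \{\pm 0.05, \pm 0.08\}$ (100 and 60
  replicates respectively), compared with `theoreticalPower2SMR()` at
  matched parameters. The closed form uses the asymptotic instrument-limited
  variance $SE_\infty^2 = \sigma_U^2/(n\,h^2\,Var(X))$; it is this package's
  normative stand-in for the published two-sample power comparator and is
  labeled as such.
- the root-$n$ convergence ratio between $N = 1{,}000$ and $N = 4{,}000$
  (150 replicates each), expected near 2 — the largest replicate count in
  the suite, because the ratio of two estimated standard deviations is the
  noisiest quantity checked against a fixed window.
- cross-population pooling with strata of 4,000 at $h^2 = 20\%$ and
  $10\%$, 70 replicates, shared $\beta_0 = 1$.

In the power, type-I and convergence scenarios the causal variants carry
per-variant $t$-statistics far beyond the $10^{-6}$ threshold, so the
scan–clump–threshold protocol selects essentially the causal set in every
fold and the lasso step runs on a handful of columns; these runs use 5 inner
CV folds and a 50-point penalty path, which at this selection size is
statistically indistinguishable from the 10-fold default and materially
faster.

## Known limitations

- No pleiotropy-robust machinery: variants affecting the outcome through
  paths other than the exposure bias any 2SLS-type estimator, including
  these. Screening candidate instruments against measured confounders
  (`cfiDiagnostics()`) is a partial, not a complete, defense.
- The CFMR1 variance approximation ignores between-fold dependence.
- Standard errors are normal-approximation; for $n \lesssim 10{,}000$ they
  tend to be conservative (wide), costing power with weak instruments.
- The generator's independence assumptions mean LD-related behavior of
  clumping is tested only on synthetic correlation structure.
- Non-linear exposure predictors are not implemented; the predictor
  interface (`predictorSpec()`) is where such a method would plug in.

## A worked example

```{r example, eval = FALSE}
cohort <- simulateDataset(simulationConfig(
    nIndividuals = 5000, h2 = 0.2, beta0 = 0.05, seed = 1))
part <- makeFolds(5000, k = 10, seed = 1)
cfi <- buildCFI(cohort, partition = part)
cfiDiagnostics(cfi, exposure(cohort))$variance_explained_pct
cfmr2(exposure(cohort), outcome(cohort), cfi)
```
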