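---
title: "Polygenic scoring with continuous shrinkage priors: model, sampler and design notes"
author: "csprs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scoring with continuous shrinkage priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csprs)
```

## The problem

A polygenic risk score (PRS) predicts a phenotype from a weighted sum of
allele counts, `PRS_i = sum_j X_ij b_j`. The weights that maximize
prediction accuracy are not the marginal GWAS effect estimates: marginal
estimates are inflated by linkage disequilibrium (LD) between nearby SNPs
and by winner's-curse noise. csprs infers posterior mean effect sizes from
GWAS *summary statistics* (per-SNP effects, p-values and sample size) plus
an external LD reference panel, so no individual-level GWAS data are
needed.

## Model

With standardized phenotype `y` and standardized genotype matrix `Z`
(N individuals, M SNPs),

    y = Z beta + e,  e ~ N(0, sigma2 I),  p(sigma2) ∝ 1/sigma2.

Each effect carries a global-local scale-mixture-of-normals prior

    beta_j ~ N(0, (sigma2/N) * phi * psi_j),
    psi_j ~ Gamma(a, rate = delta_j),  delta_j ~ Gamma(b, rate = 1).

`phi` is a global scale shared by all markers and controls overall
sparsity; `psi_j` is a marker-specific local scale that lets individual
signals escape shrinkage. The gamma-gamma hierarchy on `psi_j` is
equivalent, by change of variables, to a three-parameter beta (TPB) prior
on the shrinkage factor `tau_j = 1/(1 + phi psi_j)` — `tau_j = 1` means
total shrinkage to zero, `tau_j = 0` none. A note on parameterization: the
TPB equivalence holds for the *rate* parameterization of both gamma laws
(we verified this by re-deriving the induced density of `tau`), and the
package's prior-reproduction tests confirm the sampled `tau` follows the
TPB law.

The shipped default `a = 1, b = 1/2` is the Strawderman-Berger prior; with
`a = b = 1/2` one obtains the horseshoe. Both put substantial mass near
zero *and* heavy, Cauchy-like tails on `beta_j` — strong shrinkage of
noise, little shrinkage of real signals. `marginalPriorDensity()` evaluates
the implied marginal prior by quadrature for diagnostics; for `a <= 1/2`
it has a pole at the origin, which the function reports as `Inf`.

Given the variance parameters and the marginal estimates
`bhat = Z'y/N`, the posterior mean is the matrix shrinkage estimator

    E[beta | bhat] = (D + T^{-1})^{-1} bhat,   T = diag(phi psi_j),

with `D = Z'Z/N` the LD matrix (`posteriorMeanFixedScales()`). With
`D = I` this reduces componentwise to `(1 - tau_j) bhat_j`, and with
`psi_j ≡ 1` it is ridge regression — the closed-form infinitesimal-model
baseline `ldpredInfWeights()` is exactly this with `T = N h2 / M`. (The infinitesimal baseline solves per partition block;
sliding-window variants with an LD radius exist elsewhere, but the block
partition is reused here so every method sees identical LD information.)

## Gibbs sampler

`runShrinkageGibbs()` cycles through full conditionals that we re-derived
from the model (they are verified in the test suite against an
individual-level sampler on raw genotypes and against directly evaluated
conditional densities):

* `beta`, block by block in genomic order:
  `N((D + T^{-1})^{-1} bhat, (sigma2/N)(D + T^{-1})^{-1})` per LD block,
  one Cholesky factorization per block and sweep;
* `psi_j ~ GIG(a - 1/2, N beta_j^2/(sigma2 phi), 2 delta_j)` and
  `delta_j ~ Gamma(a + b, rate psi_j + 1)`;
* `sigma2 ~ InvGamma((N + M)/2, N/2 [(1 - 2 beta'bhat + beta'D beta) +
  sum_j beta_j^2/(phi psi_j)])`;
* in auto mode, `phi` via the inverse-gamma auxiliary representation of a
  standard half-Cauchy prior on `phi^{1/2}`:
  `w | phi ~ InvGamma(1, 1 + 1/phi)`, then
  `phi | w ~ InvGamma((M+1)/2, 1/w + N/(2 sigma2) sum_j beta_j^2/psi_j)`.

The generalized inverse Gaussian draws use a uniformly fast rejection
sampler, with the gamma / inverse-gamma boundary cases dispatched
analytically and the `|p| = 1/2` case (the default prior's hot path)
drawn through the inverse-Gaussian shortcut.

### Choosing and learning phi

Two modes mirror common practice. In grid mode
(`runShrinkageGibbsGrid()`), the sampler runs at
`phi^{1/2} ∈ {1e-4, 1e-3, 1e-2, 0.1, 1}` — roughly "proportion of causal
variants" — and the value with the best validation-cohort accuracy is
selected by `tunePrs()`, ties resolved toward stronger shrinkage. In auto
mode, the half-Cauchy prior lets `phi` be learnt from the summary
statistics alone; no validation cohort is needed. On sparse simulated
architectures the auto posterior mean of `phi` is reliably smaller than on
dense ones.

### Numerical choices

* **Regularization floor.** Reference-panel LD matrices are rank-deficient
  for long blocks. The sampler enforces `1/(phi psi_j) >= rho`
  (equivalently `T_jj <= 1/rho`) before each block solve, with `rho = 1`
  by default; this bounds the per-SNP prior variance by `sigma2/N`. The
  floor is applied to the solve only — the `psi`, `sigma2` and `phi`
  conditionals keep the unfloored model, which keeps them conjugate.
* **Jitter ladder.** Cholesky factorizations retry with diagonal jitter
  `1e-10 → 1e-8 → 1e-6` before raising a numerical error naming the block.
* **Quadratic-form clamp.** Panel mismatch can drive the
  summary-statistics residual quadratic form `1 - 2 beta'bhat + beta'D
  beta` slightly negative; it is clamped at `1e-6` with a warning.
* **Run lengths.** Defaults are 1000 iterations with 500 burn-in, which is
  sufficient for prediction-grade posterior means at simulation scale;
  10000/5000 is recommended for real-data analyses. Post-burn-in samples
  are averaged without thinning by default (`thin` is configurable);
  thinning only discards information when plain averages are the target.
* **Determinism.** A single seeded RNG stream drives the whole chain;
  identical inputs and seed give bitwise-identical posterior means.
* **Sample size in the likelihood.** Per-SNP N is used when standardizing
  marginal effects, but a single effective N (the median) enters the
  likelihood, matching the single-N model above.

## Summary-statistics handling

`readSumstats()` accepts headered whitespace text (`SNP A1 A2 BETA P [N]
[MAF]`, `OR` accepted and log-transformed), drops non-ACGT and
strand-ambiguous (A/T, C/G) SNPs, and clamps p-values of exactly zero to
the smallest representable double. `harmonizeSumstats()` intersects with a
PLINK reference panel, flips effect signs for swapped alleles, drops
irreconcilable pairs and SNPs below 1% reference MAF, and fills
coordinates and MAF from the reference.

Restricting the analysis to a SNP panel (e.g. a HapMap3-style whitelist,
commonly used to bound memory at biobank scale) is supported through the
`whitelist` argument of `harmonizeSumstats()` rather than hard-coded.

Standardized marginal effects are recovered as
`sign(beta) * |z(p)| / sqrt(N)` from the p-value, sign and sample size
rather than from `beta/SE`, because summary files disagree about SE
conventions while the two-sided p-value pins down `|z|` unambiguously; a
`beta/se` route exists behind the `method` flag. Standardized magnitudes
are capped at 1 (they cannot exceed 1 for a standardized trait). Case-
control effects stay on the observed log-odds scale throughout.

## Genome partition and LD

`loadPartition()` reads BED-dialect interval files (0-based, half-open),
the format of published LD-block partitions (about 1700 blocks genome-wide
for European panels); `mapSnpsToBlocks()` places 1-based variant positions
into blocks, attaching gap SNPs to the nearest preceding block so no
signal is silently lost. Cross-block LD is assumed zero — this is the
modeling assumption that makes blockwise multivariate updates exact within
blocks and cheap overall. Per-block correlations come from mean-imputed,
standardized reference genotypes (`computeBlockLD()`); monomorphic
reference SNPs are dropped. No shrinkage toward the identity is applied by
default — stability is the floor's job.

## The simulator

The simulator exists so that every layer is testable at desk scale without
external downloads; it is first-class, tested code.

* **Genotypes** (`simulateGenotypes()`): within each equally sized block,
  two latent haplotypes per individual follow a stationary AR(1) Gaussian
  process with correlation `ld_decay^|i-j|` (default 0.6), thresholded at
  the normal quantile of a per-SNP allele frequency drawn uniformly from
  `[0.05, 0.5]`; the two haplotype indicators are summed, so genotype
  frequencies satisfy Hardy-Weinberg exactly. Blocks are independent.
  This produces controllable, block-structured LD but **not** human LD:
  no long-range LD, no allele-frequency/LD coupling, no recombination
  hotspots. Passing benchmarks here demonstrate correct inference under
  the model's own assumptions, not performance on real genomes.
* **Effects** (`drawEffects()`): point-normal, point-t (4 df), point-gamma
  (shape 2, draws keep the gamma's sign, giving the asymmetric positively
  skewed law), and a three-group normal mixture whose group variances are
  scaled so expected heritability shares are met (defaults 10/20/70%).
  Effects are drawn on the standardized-genotype scale, consistent with
  the standardized model above.
* **Phenotypes** (`simulatePhenotype()`): genetic values are rescaled to
  variance `h2` exactly and unit-variance noise added, fixing realized
  heritability up to noise sampling (0.5 by default; 0.2 and 0.8 as
  secondary settings).
* **Summary statistics**: the individual-level route runs marginal
  regressions on a simulated cohort (`gwasSumstats()`); the direct route
  (`rssSumstats()`) draws `bhat_l ~ N(D_l beta_l, (1 - h2)/n * D_l)` per
  block, which is the exact sampling law when the GWAS cohort's LD equals
  `D`, and lets nominal GWAS sizes of 50,000+ be simulated in
  milliseconds.

## Evaluation harness

`scoreIndividuals()` computes additive scores with allele-frame
reconciliation and mean imputation. Metrics (`prsMetrics()`) are
covariate-adjusted throughout: incremental R² for quantitative traits
(full model minus covariates-only — our reading of "adjusted for
covariates in all metrics"; residualization is the other option and gives
slightly different values), Nagelkerke R² from the full-versus-restricted
logistic likelihoods, AUC of the full-model linear predictor, PR-AUC and
the top-decile odds ratio on the covariate-residualized score, and the
calibration slope (phenotype regressed on PRS; 1 is well calibrated).
`tunePrs()` selects on a validation cohort and reports on testing only;
`repeatedSplitEval()` averages 1/3-validation / 2/3-testing random splits.

## The benchmark

`benchmarkMethods()` replicates the simulation protocol end to end at desk
scale: a fixed reference panel of 503 individuals (matching the size of
the European reference sample commonly used for LD), fixed validation and
testing cohorts of 3000 each drawn from the same allele-frequency frame,
and per replicate: draw effects, generate summary statistics at nominal
N = 50,000 by the RSS route, fit all methods, tune where applicable,
evaluate on testing. The default problem size is M = 5000 SNPs in 100
blocks of 50 (block span 250 kb at the 5 kb default spacing) with 20
replicates — sizes chosen to make the full comparison, including five
grid runs and one auto run of the sampler per replicate, complete in
minutes on a single core. The true `h2` is handed to the infinitesimal
baseline (heritability estimation is an input here, not part of the
package's scope).

The qualitative expectations at the sparse end (100 causal out of 5000,
h2 = 0.5): the shrinkage sampler beats the unadjusted score, clumping +
thresholding, and the infinitesimal closed form in testing R², and the
auto-mode score is approximately calibrated (slope within [0.8, 1.2]).
These are exactly the checks the acceptance suite runs; `scripts/
acceptance.R` recomputes the underlying numbers from scratch.

## Known limitations

* **The regularization floor biases the largest effects.** `rho = 1`
  bounds every SNP's prior variance at `sigma2/N`, so an effect whose LD
  block offers little eigenvalue support can be shrunk by up to one half
  no matter how significant it is (for an unlinked SNP,
  `(D + T^{-1})^{-1}` with `T_jj <= 1` is at most `1/2`). On LD-rich data
  the strong signals live in high-eigenvalue subspaces and the floor costs
  little, but under the simulator's weak block LD it dominates: the
  benchmark's auto-mode calibration slope is about 1.8 at `rho = 1`,
  versus about 1.0 when the floor is released (`rhoFloor = 1e-6`, same
  data and seed — the test suite checks exactly this). Users analyzing
  sparse traits with thin LD panels should be aware that the default floor
  trades top-hit accuracy for numerical safety.
* The AR(1)-block genotype model understates the difficulty of real LD;
  see above.
* Cross-block LD is ignored by construction; block partitions with
  substantial inter-block LD will leak signal between blocks.
* Nagelkerke R² is only approximately invariant to monotone PRS
  transformations (AUC and OR are exactly invariant; only those are
  tested for invariance).
* No liability-scale transformation is applied to case-control traits;
  effects stay on the observed scale.
* Heritability is an input to the infinitesimal baseline, never estimated.
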