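# csprs

Bayesian polygenic risk scores from GWAS summary statistics under a
continuous shrinkage prior.

## What it does, for whom

Polygenic risk scores (PRS) summarize an individual's genetic liability as
a weighted sum of allele counts, `PRS_i = Σ_j X_ij b_j`. Raw marginal GWAS
effect estimates make poor weights: they are correlated through linkage
disequilibrium (LD) and noisy for small effects. csprs is for statistical
geneticists who have **summary statistics only** (per-SNP effect, alleles,
p-value, sample size) plus an LD reference panel in PLINK format, and want
posterior mean effect sizes that account for LD and for the sparseness of
the genetic architecture.

The model places a global-local scale mixture of normals on each
standardized effect,

    beta_j | psi_j ~ N(0, (sigma2/N) * phi * psi_j),
    psi_j ~ Gamma(a, delta_j),   delta_j ~ Gamma(b, 1)     (rate form),

equivalent to a three-parameter beta prior on the shrinkage factor
`tau_j = 1/(1 + phi psi_j)`. The default `a = 1, b = 1/2`
(Strawderman-Berger) is sharply peaked at zero with heavy tails, so noise
is crushed while genuine signals pass through. Inference is a Gibbs
sampler with **multivariate block updates**: within each LD block,

    beta_block ~ N((D + T^{-1})^{-1} bhat, (sigma2/N)(D + T^{-1})^{-1}),

where `D` is the reference LD matrix of the block, `bhat = Z'y/N` the
standardized marginal effects and `T = diag(phi psi_j)` (floored so
`1/(phi psi_j) >= rho`, `rho = 1`). The global scale `phi` is either tuned
over the grid `phi^(1/2) ∈ {1e-4, ..., 1}` on a validation cohort, or
learnt fully Bayesianly through a half-Cauchy prior on `phi^(1/2)` (auto
mode — no validation data needed).

The package also ships the standard comparators (unadjusted marginal
weights, LD clumping + p-value thresholding, the infinitesimal-model
closed form), a genetic-architecture simulator (block-LD genotypes,
point-normal / point-t / point-gamma / normal-mixture effects, phenotypes
at fixed heritability, and a fast direct summary-statistics route), and an
evaluation harness (scoring, R², Nagelkerke R², AUC, PR-AUC, top-decile
odds ratio, calibration slope, validation/testing tuning, repeated
splits). A command-line entry point (`exec/csprs`) wires these into
`infer`, `simulate`, `score`, `evaluate` and `benchmark` subcommands.

## Worked example

Everything below is simulated, so it runs anywhere in seconds:

```r
library(csprs)
# reference panel and cohorts from one allele-frequency frame
ref   <- simulateGenotypes(503, 1000, 20, seed = 1)
train <- simulateGenotypes(5000, 1000, 20, seed = 2, maf = ref@map$maf_target)
beta  <- drawEffects(architectureSpec(nCausal = 50, h2 = 0.5), 1000, seed = 3)
train <- simulatePhenotype(train, beta, h2 = 0.5, seed = 4)
gw    <- gwasSumstats(train)      # marginal GWAS on the training cohort

blocks <- buildLDBlocks(gw$sst, cohortPartition(ref), ref@genotypes)$blocks
cfg  <- gibbsConfig(nEff = 5000, seed = 7, prior = priorSpec(phi = "auto"))
post <- runShrinkageGibbs(gw$hstats, blocks, cfg,
                          snpInfo = sumstatsTable(gw$sst))
post
#> PosteriorEffects for 1000 SNPs
#>   posterior samples averaged: 500
#>   posterior mean phi: 0.05445
#>   posterior mean sigma2: 0.5368

test   <- simulateGenotypes(2000, 1000, 20, seed = 5, maf = ref@map$maf_target)
test   <- simulatePhenotype(test, train@betaTrue, h2 = 0.5, seed = 6)
scored   <- scoreIndividuals(test, post, phenotype = test@y)
marginal <- scoreIndividuals(test, unadjustedWeights(gw$sst),
                             phenotype = test@y)
prsMetrics(scored)
#> EvalReport
#>   r2                   0.44585
#>   calibration_slope    1.6238
prsMetrics(marginal)
#> EvalReport
#>   r2                   0.33799
#>   calibration_slope    0.47984
relativeImprovement(0.44585, 0.33799)
#> [1] 0.319138
```

Reading the output: the sampler learnt `phi ≈ 0.054` from the summary
statistics alone — a small global scale, reflecting the sparse
architecture (50 causal SNPs out of 1000). On an independent testing
cohort the posterior-mean score explains 44.6% of phenotypic variance
against an h² ceiling of 50%, a 32% relative improvement over the
unadjusted marginal score (33.8%). The calibration slope above 1 says the
shrunk score still *under*-predicts at this modest training size
(N = 5000); slopes approach 1 as N grows.

Posterior weights go to disk in a 6-column text format any scoring tool
understands:

```r
writePosteriorEffects(post, "weights.txt")
```

The same pipeline from the shell:

```sh
exec/csprs simulate --out_prefix sim --n 2000 --m 1000 --n_causal 50 --seed 1
exec/csprs infer --sst_file sim.sumstats --ref_panel sim \
  --partition sim.blocks.bed --n_gwas 2000 --phi auto --out_prefix run
exec/csprs score --weights run_pst_eff_phiauto.txt --bfile sim --out prs.txt
```

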