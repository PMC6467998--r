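# The shrinkage Gibbs sampler operating on GWAS summary statistics.
#
# One sweep updates, in order: the effect sizes beta block by block in
# genomic order (multivariate normal, one Cholesky factorization of
# D + T^{-1} per block), the local scales psi_j and delta_j (generalized
# inverse Gaussian and gamma full conditionals), the residual variance
# sigma2 (inverse gamma), and in auto mode the global scale phi through the
# half-Cauchy auxiliary representation.

#' Draw from the generalized inverse Gaussian distribution
#'
#' Density proportional to `x^(p-1) exp(-(chi/x + psi x)/2)` on `x > 0`.
#' The degenerate boundaries dispatch analytically: `chi = 0, p > 0` is
#' Gamma(p, rate psi/2); `psi = 0, p < 0` is inverse-gamma(-p, rate chi/2).
#' `|p| = 1/2` uses the (reciprocal) inverse-Gaussian shortcut; the general
#' case uses a uniformly fast rejection sampler.
#'
#' @param n number of draws.
#' @param p real order parameter.
#' @param chi,psi non-negative parameters (recycled; not both zero).
#' @return numeric vector of positive draws.
#' @export
sampleGIG <- function(n, p, chi, psi) {
  if (any(chi < 0) || any(psi < 0))
    stopUsage("sampleGIG: chi and psi must be non-negative")
  chi <- rep_len(as.numeric(chi), max(length(chi), 1L))
  psi <- rep_len(as.numeric(psi), max(length(psi), 1L))
  .cppSampleGIG(as.integer(n), as.numeric(p), chi, psi)
}

#' Block update of effect sizes
#'
#' Draws `beta_block ~ N((D + T^{-1})^{-1} bhat, (sigma2/nEff)
#' (D + T^{-1})^{-1})` with `T_jj = min(phi psi_j, 1/rho)`; the floor
#' `1/(phi psi_j) >= rho` bounds the per-SNP prior variance and protects the
#' factorization against collinear reference panels.
#'
#' @param block an [LDBlock-class] (or a bare LD matrix).
#' @param betahatBlock standardized marginal effects of the block's SNPs.
#' @param psi local scales; @param phi global scale; @param sigma2 residual
#'   variance; @param nEff effective GWAS sample size.
#' @param rho regularization floor (default 1).
#' @param nDraws number of draws (matrix of `nDraws` columns when > 1).
#' @return a draw vector, or an m x nDraws matrix.
#' @export
updateBetaBlock <- function(block, betahatBlock, psi, phi, sigma2, nEff,
                            rho = 1, nDraws = 1) {
  D <- if (is(block, "LDBlock")) block@D else as.matrix(block)
  stopifnot(length(betahatBlock) == nrow(D), length(psi) == nrow(D))
  out <- .cppUpdateBetaBlock(D, as.numeric(betahatBlock), as.numeric(psi),
                             phi, sigma2, nEff, rho, as.integer(nDraws))
  if (nDraws == 1) drop(out) else out
}

#' Update local shrinkage scales
#'
#' `psi_j | . ~ GIG(a - 1/2, nEff beta_j^2/(sigma2 phi), 2 delta_j)` and
#' `delta_j | psi_j ~ Gamma(a + b, rate psi_j + 1)`; vectorized over SNPs.
#'
#' @param beta current standardized effects.
#' @param delta current delta values.
#' @param a,b prior shapes; @param phi,sigma2,nEff current model scales.
#' @return list with updated `psi` and `delta`.
#' @export
updatePsiDelta <- function(beta, delta, a, b, phi, sigma2, nEff) {
  m <- length(beta)
  chi <- nEff * beta^2 / (sigma2 * phi)
  psi <- .cppSampleGIG(m, a - 0.5, chi, 2 * delta)
  delta <- stats::rgamma(m, shape = a + b, rate = psi + 1)
  list(psi = psi, delta = delta)
}

#' Update the residual variance
#'
#' `sigma2 | . ~ InvGamma((nEff + M)/2, nEff/2 [quad + sum_j
#' beta_j^2/(phi psi_j)])` where `quad = 1 - 2 beta' bhat + beta' D beta` is
#' the summary-statistics residual sum of squares per sample. Reference
#' panel mismatch can drive `quad` slightly negative; it is clamped below at
#' `clamp` with a warning.
#'
#' @param beta,betahat current and marginal standardized effects (full
#'   vectors).
#' @param bDb the quadratic form `beta' D beta` accumulated over blocks.
#' @param psi local scales; @param phi global scale; @param nEff effective
#'   sample size; @param clamp lower clamp for the quadratic form.
#' @return a draw of sigma2.
#' @export
updateSigma2 <- function(beta, betahat, bDb, psi, phi, nEff, clamp = 1e-6) {
  quad <- 1 - 2 * sum(beta * betahat) + bDb
  if (quad < clamp) {
    if (quad < 0)
      warning(sprintf("negative summary-statistics quadratic form (%.3g) clamped",
                      quad))
    quad <- clamp
  }
  m <- length(beta)
  shape <- (nEff + m) / 2
  rate <- nEff / 2 * (quad + sum(beta^2 / (phi * psi)))
  rate / stats::rgamma(1, shape = shape)
}

#' Auto-mode update of the global shrinkage scale
#'
#' Implements the standard half-Cauchy prior on `phi^(1/2)` through its
#' inverse-gamma auxiliary representation: `w | phi ~ InvGamma(1, 1 + 1/phi)`
#' then `phi | w, . ~ InvGamma((M + 1)/2, 1/w + nEff/(2 sigma2) sum_j
#' beta_j^2/psi_j)`. With no data contribution (`M = 0`,
#' `sumBeta2OverPsi = 0`) the stationary law of `phi^(1/2)` is C+(0, 1).
#' Vectorized over parallel chains.
#'
#' @param phi,w current values (vectors of equal length for parallel
#'   chains).
#' @param sumBeta2OverPsi `sum_j beta_j^2 / psi_j` (per chain).
#' @param M number of markers contributing to the conditional.
#' @param sigma2,nEff current residual variance and effective sample size.
#' @return list with updated `phi` and `w`.
#' @export
updatePhiAuto <- function(phi, w, sumBeta2OverPsi = 0, M = 0, sigma2 = 1,
                          nEff = 1) {
  k <- length(phi)
  w <- (1 + 1 / phi) / stats::rgamma(k, shape = 1)
  rate <- 1 / w + nEff * sumBeta2OverPsi / (2 * sigma2)
  phi <- rate / stats::rgamma(k, shape = (M + 1) / 2)
  if (any(!is.finite(phi)) || any(phi <= 0))
    stopNumeric("auto update of phi produced a non-finite value")
  list(phi = phi, w = w)
}

#' Run the continuous-shrinkage Gibbs sampler
#'
#' Runs `cfg@nIter` full sweeps over the LD blocks and model scales, with a
#' fixed seed giving bitwise-identical results, and averages the post-burn-in
#' (optionally thinned) samples into posterior mean effect sizes. The
#' per-allele scale is attached from reference allele frequencies when
#' `snpInfo` is supplied.
#'
#' @param hstats a [StandardizedEffects-class] object.
#' @param blocks list of [LDBlock-class] covering exactly the SNPs of
#'   `hstats`, in genomic order.
#' @param cfg a [GibbsConfig-class].
#' @param snpInfo optional data.frame with `snp_id`, `chrom`, `pos`, `a1`,
#'   `a2`, `maf` (e.g. the table of a harmonized [SummaryStats-class]);
#'   enables the per-allele output scale.
#' @return A [PosteriorEffects-class] object, SNPs in `hstats` order.
#' @export
runShrinkageGibbs <- function(hstats, blocks, cfg, snpInfo = NULL) {
  ids <- unlist(lapply(blocks, snpIds), use.names = FALSE)
  pos <- match(ids, hstats@snpId)
  if (anyNA(pos) || length(ids) != length(hstats@snpId))
    stopData("blocks must cover exactly the SNPs of hstats")
  bhat <- hstats@betahatStd[pos]
  offsets <- c(0, cumsum(vapply(blocks, nSnps, integer(1))))
  bhatList <- lapply(seq_along(blocks), function(k)
    bhat[(offsets[k] + 1):offsets[k + 1]])

  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  prior <- cfg@prior
  res <- .cppRunGibbs(lapply(blocks, ldMatrix), bhatList, prior@a, prior@b,
                      if (prior@phiAuto) 1 else prior@phi, prior@phiAuto,
                      cfg@nEff, cfg@nIter, cfg@nBurnin, cfg@thin,
                      cfg@rhoFloor, cfg@keepTrace)

  betaStd <- numeric(length(bhat))
  betaStd[pos] <- res$beta_mean  # back to hstats order
  ord <- order(pos)

  if (is.null(snpInfo)) {
    info <- data.frame(snp_id = hstats@snpId, chrom = NA_character_,
                       pos = NA_real_, a1 = NA_character_,
                       a2 = NA_character_, maf = NA_real_,
                       stringsAsFactors = FALSE)
  } else {
    info <- snpInfo[match(hstats@snpId, snpInfo$snp_id),
                    c("snp_id", "chrom", "pos", "a1", "a2", "maf")]
  }
  perAllele <- convertEffectScale(betaStd, info$maf, from = "standardized")
  trace <- res$trace
  if (cfg@keepTrace) colnames(trace) <- c("iter", "sigma2", "phi",
                                          "mean_abs_beta")
  PosteriorEffects(info, betaStd, perAllele,
                   phiPosteriorMean = if (prior@phiAuto) res$phi_mean
                                      else NA_real_,
                   sigma2PosteriorMean = res$sigma2_mean,
                   nSamplesUsed = res$n_save, trace = trace)
}

#' Gibbs runs over a grid of global shrinkage values
#'
#' Runs the sampler once per fixed `phi`; the recommended grid is
#' `phi^(1/2) in {1e-4, 1e-3, 1e-2, 0.1, 1}`, spanning very sparse to
#' infinitesimal architectures. The value with the best predictive
#' performance in a validation cohort is then selected with [tunePrs()].
#'
#' @param hstats,blocks,cfg,snpInfo as in [runShrinkageGibbs()] (`cfg`'s
#'   prior phi is overridden per grid point; the same seed is reused so runs
#'   differ only through phi).
#' @param phiGrid vector of phi values, ordered by increasing phi
#'   (decreasing shrinkage).
#' @return named list of [PosteriorEffects-class], names `phi=<value>`.
#' @export
runShrinkageGibbsGrid <- function(hstats, blocks, cfg,
                                  phiGrid = c(1e-4, 1e-3, 1e-2, 0.1, 1)^2,
                                  snpInfo = NULL) {
  out <- lapply(phiGrid, function(ph) {
    cfg@prior <- priorSpec(a = cfg@prior@a, b = cfg@prior@b, phi = ph)
    runShrinkageGibbs(hstats, blocks, cfg, snpInfo = snpInfo)
  })
  names(out) <- sprintf("phi=%g", phiGrid)
  out
}
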