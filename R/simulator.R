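# Genetic-architecture simulator. Generates genotype panels with block LD,
# effect sizes under several architecture families, phenotypes at fixed
# heritability, and GWAS summary statistics by either an individual-level
# route (marginal regressions on a simulated cohort) or a direct
# summary-level route (multivariate normal draws around D beta).
#
# Genotypes are built from two latent haplotypes per individual: within a
# block each haplotype is a stationary AR(1) Gaussian process with
# correlation ld_decay^|i-j|, thresholded at the normal quantile of the
# per-SNP allele frequency, so genotype frequencies satisfy Hardy-Weinberg
# exactly and LD decays geometrically inside blocks while blocks are
# independent. This is a controllable stand-in for real LD, not a model of
# human haplotype structure.

#' Simulate a genotype cohort with block-wise AR(1) LD
#'
#' @param n individuals; @param m SNPs; @param nBlocks number of equally
#'   sized contiguous LD blocks (`m` must be divisible by `nBlocks`).
#' @param ldDecay latent AR(1) correlation between adjacent SNPs in [0, 1).
#' @param mafRange range of per-SNP allele frequencies, within [0.01, 0.5].
#' @param maf optional vector of per-SNP allele frequencies overriding
#'   `mafRange` (to simulate several cohorts from one population).
#' @param seed integer seed (`NULL` leaves the RNG state untouched).
#' @param chrom chromosome label; @param posSpacing base-pair spacing
#'   between adjacent SNPs.
#' @return A [SimulatedCohort-class] (no phenotype attached yet).
#' @export
simulateGenotypes <- function(n, m, nBlocks, ldDecay = 0.6,
                              mafRange = c(0.05, 0.5), maf = NULL,
                              seed = NULL, chrom = "1", posSpacing = 5000) {
  if (m %% nBlocks != 0)
    stopUsage("m must be divisible into nBlocks contiguous blocks")
  if (ldDecay < 0 || ldDecay >= 1) stopUsage("ldDecay must lie in [0, 1)")
  if (mafRange[1] < 0.01 || mafRange[2] > 0.5)
    stopUsage("mafRange must lie within [0.01, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- stats::runif(m, mafRange[1], mafRange[2])
  mb <- m / nBlocks
  thr <- stats::qnorm(maf)

  haplo <- function(cols) {
    H <- matrix(0, n, length(cols))
    H[, 1] <- stats::rnorm(n)
    if (length(cols) > 1) {
      innov <- sqrt(1 - ldDecay^2)
      for (j in 2:length(cols))
        H[, j] <- ldDecay * H[, j - 1] + innov * stats::rnorm(n)
    }
    H
  }
  G <- matrix(0L, n, m)
  for (k in seq_len(nBlocks)) {
    cols <- ((k - 1) * mb + 1):(k * mb)
    t_k <- matrix(thr[cols], n, mb, byrow = TRUE)
    G[, cols] <- (haplo(cols) < t_k) + (haplo(cols) < t_k)
  }
  af <- colMeans(G) / 2
  map <- data.frame(snp_id = sprintf("snp%06d", seq_len(m)), chrom = chrom,
                    pos = seq_len(m) * posSpacing, a1 = "A", a2 = "G",
                    maf = pmin(af, 1 - af), af1 = af, maf_target = maf,
                    block = rep(seq_len(nBlocks), each = mb),
                    stringsAsFactors = FALSE)
  colnames(G) <- map$snp_id
  new("SimulatedCohort", genotypes = G, map = map, betaTrue = numeric(0),
      y = numeric(0))
}

#' Draw SNP effect sizes under a genetic architecture
#'
#' Point-mass-at-zero mixtures with normal, Student-t (heavy tails) or
#' gamma (asymmetric, positively skewed; draws keep the gamma's sign) causal
#' effects, or a three-group normal mixture whose group variances are scaled
#' so the expected heritability shares match `mixtureShares`. The absolute
#' scale is arbitrary here; [simulatePhenotype()] and [rssSumstats()] rescale
#' the genetic values to the target heritability.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param m number of SNPs.
#' @param seed integer seed.
#' @return numeric vector with exactly the specified number of non-zero
#'   entries at uniformly chosen positions.
#' @export
drawEffects <- function(spec, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- numeric(m)
  if (spec@family == "normal_mixture") {
    counts <- spec@mixtureCounts
    if (sum(counts) > m) stopUsage("mixture counts exceed number of SNPs")
    idx <- sample.int(m, sum(counts))
    grp <- rep(seq_along(counts), counts)
    v <- spec@mixtureShares / counts  # per-SNP variance per group
    beta[idx] <- stats::rnorm(sum(counts), 0, sqrt(v[grp]))
    group <- integer(m)
    group[idx] <- grp
    attr(beta, "group") <- group
  } else {
    if (spec@nCausal > m) stopUsage("nCausal exceeds number of SNPs")
    idx <- sample.int(m, spec@nCausal)
    beta[idx] <- switch(spec@family,
      point_normal = stats::rnorm(spec@nCausal),
      point_t = stats::rt(spec@nCausal, df = spec@df),
      point_gamma = stats::rgamma(spec@nCausal, shape = spec@shape, rate = 1))
  }
  beta
}

standardizedGenotypes <- function(G) {
  mu <- colMeans(G)
  sdv <- sqrt(colMeans(G^2) - mu^2)
  if (any(sdv == 0)) stopData("monomorphic SNP in cohort")
  sweep(sweep(G, 2, mu, "-"), 2, sdv, "/")
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Attach a phenotype at fixed heritability
#'
#' The genetic value `g = Z beta` (standardized genotypes) is rescaled to
#' variance `h2`, and independent normal noise of variance `1 - h2` is
#' added, so the realized phenotypic variance is approximately 1 and the
#' realized heritability is `h2` up to the noise sampling. The rescaled
#' standardized effects are stored as the cohort's `betaTrue`.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param betaTrue effect sizes on the standardized scale (any overall
#'   scale).
#' @param h2 target heritability in (0, 1]; @param seed integer seed.
#' @return the cohort with `y` and rescaled `betaTrue` attached.
#' @export
simulatePhenotype <- function(cohort, betaTrue, h2, seed = NULL) {
  if (h2 <= 0 || h2 > 1) stopUsage("h2 must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  Z <- standardizedGenotypes(cohort@genotypes)
  g <- drop(Z %*% betaTrue)
  sg <- popSd(g)
  if (sg == 0) stopData("zero genetic variance with h2 > 0")
  scale <- sqrt(h2) / sg
  g <- g * scale
  e <- if (h2 < 1) stats::rnorm(length(g), 0, sqrt(1 - h2)) else 0
  cohort@y <- g + e
  cohort@betaTrue <- betaTrue * scale
  cohort
}

#' GWAS on a simulated cohort
#'
#' Marginal least-squares effects on standardized genotypes and a
#' standardized phenotype (`bhat = Z'y/N`), with two-sided normal p-values
#' from `z = sqrt(N) bhat` and per-allele effects on the sample allele
#' frequency frame.
#'
#' @param cohort a [SimulatedCohort-class] with phenotype attached.
#' @return list with `sst` ([SummaryStats-class]) and `hstats`
#'   ([StandardizedEffects-class]).
#' @export
gwasSumstats <- function(cohort) {
  if (!length(cohort@y)) stopUsage("cohort has no phenotype")
  n <- nrow(cohort@genotypes)
  ys <- (cohort@y - mean(cohort@y)) / popSd(cohort@y)
  Z <- standardizedGenotypes(cohort@genotypes)
  bhat <- drop(crossprod(Z, ys)) / n
  z <- sqrt(n) * bhat
  pval <- pmax(2 * stats::pnorm(-abs(z)), 1e-323)
  tb <- cohort@map[, c("snp_id", "chrom", "pos", "a1", "a2", "maf")]
  tb$beta_marginal <- convertEffectScale(bhat, tb$maf, "standardized")
  tb$pval <- pval
  tb$n_gwas <- n
  list(sst = SummaryStats(tb),
       hstats = StandardizedEffects(tb$snp_id, bhat, n))
}

#' Direct summary-statistics simulation (RSS route)
#'
#' Draws marginal effect estimates from their sampling law given the true
#' effects and block LD, `bhat_l ~ N(D_l beta_l, (sigma2/n) D_l)` per block,
#' with `beta` first rescaled so its genetic variance `beta' D beta` equals
#' `h2` and `sigma2 = 1 - h2`. Orders of magnitude faster than simulating a
#' cohort when the nominal GWAS size is large.
#'
#' @param betaTrue effect sizes (standardized scale, any overall scale).
#' @param blocks list of [LDBlock-class]; @param map variant table aligned
#'   with `betaTrue` (block-concatenated order) providing ids, coordinates
#'   and MAF.
#' @param n nominal GWAS sample size.
#' @param h2 target heritability (`NULL`: use `betaTrue` as given with
#'   `sigma2 = 1`).
#' @param seed integer seed.
#' @return list with `sst`, `hstats` and the rescaled `betaTrue`.
#' @export
rssSumstats <- function(betaTrue, blocks, map, n, h2 = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(blocks, nSnps, integer(1))
  if (sum(sizes) != length(betaTrue))
    stopData("blocks must cover betaTrue")
  offsets <- c(0, cumsum(sizes))
  sigma2 <- 1
  if (!is.null(h2)) {
    gvar <- 0
    for (k in seq_along(blocks)) {
      b <- betaTrue[(offsets[k] + 1):offsets[k + 1]]
      gvar <- gvar + drop(crossprod(b, blocks[[k]]@D %*% b))
    }
    if (gvar <= 0) stopData("zero genetic variance with h2 set")
    betaTrue <- betaTrue * sqrt(h2 / gvar)
    sigma2 <- 1 - h2
  }
  bhat <- numeric(length(betaTrue))
  for (k in seq_along(blocks)) {
    i <- (offsets[k] + 1):offsets[k + 1]
    D <- blocks[[k]]@D
    R <- attr(blocks[[k]], "cholD")
    if (is.null(R)) R <- cholWithJitter(D, "RSS draw")
    bhat[i] <- drop(D %*% betaTrue[i]) +
      sqrt(sigma2 / n) * drop(crossprod(R, stats::rnorm(length(i))))
  }
  z <- sqrt(n) * bhat
  pval <- pmax(2 * stats::pnorm(-abs(z)), 1e-323)
  tb <- map[, c("snp_id", "chrom", "pos", "a1", "a2", "maf")]
  tb$beta_marginal <- convertEffectScale(bhat, tb$maf, "standardized")
  tb$pval <- pval
  tb$n_gwas <- n
  list(sst = SummaryStats(tb),
       hstats = StandardizedEffects(tb$snp_id, bhat, n),
       betaTrue = betaTrue)
}

#' Write a simulated cohort as a PLINK fileset plus phenotype
#'
#' @param cohort a [SimulatedCohort-class].
#' @param prefix output prefix; writes `.bed/.bim/.fam`, a `.pheno` file
#'   and, when effects are attached, a `.truth` file of true standardized
#'   effects.
#' @export
writeCohort <- function(cohort, prefix) {
  writePlink(prefix, cohort@genotypes,
             cohort@map[, c("chrom", "snp_id", "pos", "a1", "a2")],
             phenotype = if (length(cohort@y)) cohort@y else NULL)
  if (length(cohort@y)) {
    ids <- sprintf("id%05d", seq_len(nrow(cohort@genotypes)))
    utils::write.table(data.frame(ids, ids, cohort@y),
                       paste0(prefix, ".pheno"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  if (length(cohort@betaTrue))
    utils::write.table(data.frame(cohort@map$snp_id, cohort@betaTrue),
                       paste0(prefix, ".truth"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Equal-sized block partition matching a simulated cohort
#'
#' @param cohort a [SimulatedCohort-class].
#' @return a [BlockPartition-class] whose intervals reproduce the cohort's
#'   block structure.
#' @export
cohortPartition <- function(cohort) {
  map <- cohort@map
  sp <- split(map$pos, map$block)
  start0 <- vapply(sp, min, numeric(1)) - 1
  end <- vapply(sp, max, numeric(1))
  gr <- GenomicRanges::GRanges(unique(map$chrom),
                               IRanges::IRanges(start = start0 + 1,
                                                end = end))
  new("BlockPartition", ranges = gr)
}
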