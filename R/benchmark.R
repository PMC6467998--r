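# Simulation benchmark comparing polygenic scoring methods under a chosen
# genetic architecture: a fixed reference panel provides block LD, summary
# statistics are drawn per replicate by the fast summary-level (RSS) route
# at a nominal GWAS sample size, tuning parameters are selected in a
# validation cohort and accuracy is reported on an independent testing
# cohort.

#' Benchmark polygenic scoring methods on simulated architectures
#'
#' For each replicate: draw effect sizes from `spec`, generate summary
#' statistics around the reference LD at nominal sample size `nGwas`,
#' compute weights for each method (marginal/unadjusted, clumping +
#' thresholding with the threshold tuned in validation, the infinitesimal
#' closed form with the true h2, the shrinkage sampler over the phi grid
#' tuned in validation, and the auto sampler), score the validation and
#' testing cohorts, and record the testing R-squared and calibration slope.
#'
#' @param nReplicates simulation replicates.
#' @param m SNPs; @param nBlocks LD blocks; @param ldDecay AR(1) LD decay.
#' @param nRef reference panel size (503 mirrors the 1000 Genomes European
#'   sample); @param nVal,nTest validation/testing cohort sizes.
#' @param nGwas nominal GWAS sample size of the summary statistics.
#' @param spec an [ArchitectureSpec-class].
#' @param phiGrid global-scale grid for the tuned sampler.
#' @param nIter,nBurnin MCMC run lengths.
#' @param methods subset of
#'   `c("unadjusted", "pt", "ldpred_inf", "prscs", "prscs_auto")`.
#' @param seed master seed; replicate r uses seed + r internally.
#' @return list with `results` (per replicate x method: test R-squared,
#'   calibration slope, selected tuning parameter) and `summary` (mean/SD
#'   per method).
#' @export
benchmarkMethods <- function(nReplicates = 20, m = 5000, nBlocks = 100,
                             ldDecay = 0.6, nRef = 503, nVal = 3000,
                             nTest = 3000, nGwas = 50000,
                             spec = architectureSpec(nCausal = 100, h2 = 0.5),
                             phiGrid = c(1e-4, 1e-3, 1e-2, 0.1, 1)^2,
                             nIter = 1000, nBurnin = 500,
                             methods = c("unadjusted", "pt", "ldpred_inf",
                                         "prscs", "prscs_auto"),
                             seed = 42) {
  set.seed(seed)
  maf <- stats::runif(m, 0.05, 0.5)
  ref <- simulateGenotypes(nRef, m, nBlocks, ldDecay = ldDecay, maf = maf)
  valCohort <- simulateGenotypes(nVal, m, nBlocks, ldDecay = ldDecay,
                                 maf = maf)
  testCohort <- simulateGenotypes(nTest, m, nBlocks, ldDecay = ldDecay,
                                  maf = maf)
  map <- ref@map
  blocks <- lapply(split(seq_len(m), map$block), function(i) {
    b <- computeBlockLD(ref@genotypes[, i, drop = FALSE],
                        snpIds = map$snp_id[i])
    attr(b, "cholD") <- cholWithJitter(b@D, "reference LD")
    b
  })
  ldLookup <- ldProvider(blocks)
  h2 <- spec@h2

  Gval <- valCohort@genotypes
  Gtest <- testCohort@genotypes

  rows <- list()
  for (r in seq_len(nReplicates)) {
    beta0 <- drawEffects(spec, m, seed = seed + r)
    ss <- rssSumstats(beta0, blocks, map, n = nGwas, h2 = h2)
    sst <- ss$sst; hstats <- ss$hstats
    snpInfo <- sst@table

    # per-cohort phenotypes from the same standardized truth
    yVal <- phenotypeFromTruth(valCohort, ss$betaTrue, h2)
    yTest <- phenotypeFromTruth(testCohort, ss$betaTrue, h2)

    weightSets <- list()
    selected <- list()
    if ("unadjusted" %in% methods)
      weightSets$unadjusted <- weightsTable(unadjustedWeights(sst))
    if ("pt" %in% methods) {
      retained <- clumpSnps(sst, ldLookup)
      W <- thresholdGrid(sst, retained)
      prsV <- scoreColumns(Gval, snpInfo, W)
      prsT <- scoreColumns(Gtest, snpInfo, W)
      tuned <- tunePrs(prsV, yVal, prsT, yTest)
      selected$pt <- tuned$selected
      wt <- snpInfo[, c("chrom", "snp_id", "pos", "a1", "a2")]
      wt$beta <- W[, tuned$selected]
      weightSets$pt <- wt
    }
    if ("ldpred_inf" %in% methods)
      weightSets$ldpred_inf <-
        weightsTable(ldpredInfWeights(hstats, blocks, h2 = h2,
                                      nGwas = nGwas, snpInfo = snpInfo))
    if ("prscs" %in% methods) {
      cfg <- gibbsConfig(nEff = nGwas, nIter = nIter, nBurnin = nBurnin,
                         seed = seed + 500000 + r)
      pes <- runShrinkageGibbsGrid(hstats, blocks, cfg, phiGrid = phiGrid,
                                   snpInfo = snpInfo)
      Wcs <- vapply(pes, function(pe) weightsTable(pe)$beta,
                    numeric(nSnps(pes[[1]])))
      rownames(Wcs) <- weightsTable(pes[[1]])$snp_id
      ordIds <- weightsTable(pes[[1]])[, c("chrom", "snp_id", "pos", "a1",
                                           "a2")]
      prsV <- scoreColumns(Gval, snpInfo, Wcs, ids = ordIds)
      prsT <- scoreColumns(Gtest, snpInfo, Wcs, ids = ordIds)
      tuned <- tunePrs(prsV, yVal, prsT, yTest)
      selected$prscs <- tuned$selected
      wt <- ordIds
      wt$beta <- Wcs[, tuned$selected]
      weightSets$prscs <- wt
    }
    if ("prscs_auto" %in% methods) {
      cfg <- gibbsConfig(nEff = nGwas, nIter = nIter, nBurnin = nBurnin,
                         seed = seed + 600000 + r,
                         prior = priorSpec(phi = "auto"))
      pe <- runShrinkageGibbs(hstats, blocks, cfg, snpInfo = snpInfo)
      weightSets$prscs_auto <- weightsTable(pe)
      selected$prscs_auto <- sprintf("phi=%.3g", pe@phiPosteriorMean)
    }

    for (meth in names(weightSets)) {
      sc <- scoreIndividuals(Gtest, weightSets[[meth]], map = snpInfo,
                             phenotype = yTest)
      rep_ <- metricsTable(prsMetrics(sc))
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = r, method = meth, r2 = rep_[["r2"]],
                   slope = rep_[["calibration_slope"]],
                   selected = selected[[meth]] %||% NA_character_,
                   stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$method),
    function(d) data.frame(method = d$method[1], mean_r2 = mean(d$r2),
                           sd_r2 = stats::sd(d$r2),
                           mean_slope = mean(d$slope))))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}

# phenotype for an evaluation cohort given standardized true effects whose
# genetic variance is already h2 on the reference frame
phenotypeFromTruth <- function(cohort, betaTrue, h2) {
  Z <- standardizedGenotypes(cohort@genotypes)
  g <- drop(Z %*% betaTrue)
  g + stats::rnorm(length(g), 0, sqrt(max(1 - h2, 0)))
}

# score one cohort against many weight columns at once (standardized
# per-allele weights share the cohort allele frame by construction here)
scoreColumns <- function(G, snpInfo, W, ids = NULL) {
  sn <- if (is.null(ids)) snpInfo$snp_id else ids$snp_id
  as.matrix(G[, sn, drop = FALSE] %*% W)
}
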