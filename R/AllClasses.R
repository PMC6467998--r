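#' @import methods
NULL

chromSortOrder <- function(chrom, pos) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", chrom)))
  if (anyNA(num)) num <- match(chrom, unique(chrom))
  order(num, pos)
}

#' Harmonized GWAS summary statistics
#'
#' Per-SNP marginal association results kept in a reference allele frame.
#' The table holds one row per SNP with the effect allele (`a1`), the other
#' allele (`a2`), the marginal per-allele effect (`beta_marginal`, log odds
#' ratio for case-control traits), the two-sided association p-value, the
#' GWAS sample size and, once harmonized against a reference panel, the
#' chromosome, position and reference minor allele frequency.
#'
#' @slot table data.frame with columns `snp_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `beta_marginal`, `pval`, `n_gwas`, `maf`.
#' @slot harmonization list of bookkeeping counts from [harmonizeSumstats()].
#' @export
setClass("SummaryStats",
         representation(table = "data.frame", harmonization = "list"),
         prototype(harmonization = list()))

setValidity("SummaryStats", function(object) {
  tb <- object@table
  need <- c("snp_id", "chrom", "pos", "a1", "a2", "beta_marginal", "pval",
            "n_gwas", "maf")
  missing_cols <- setdiff(need, names(tb))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(tb$snp_id))
    return(paste("duplicated snp_id:",
                 tb$snp_id[duplicated(tb$snp_id)][1L]))
  if (nrow(tb) && any(tb$a1 == tb$a2))
    return("a1 and a2 must differ for every SNP")
  if (nrow(tb) && (any(tb$pval <= 0) || any(tb$pval > 1)))
    return("p-values must lie in (0, 1]")
  if (nrow(tb) && !anyNA(tb$chrom)) {
    ord <- chromSortOrder(tb$chrom, tb$pos)
    if (!identical(ord, seq_len(nrow(tb))))
      return("rows must be sorted by (chrom, pos)")
  }
  TRUE
})

#' Construct a SummaryStats object
#'
#' Rows with known coordinates are sorted by (chromosome, position); rows
#' lacking coordinates (summary files before harmonization) keep file order.
#'
#' @param table data.frame; missing optional columns (`chrom`, `pos`, `maf`)
#'   are filled with `NA`.
#' @return A [SummaryStats-class] object.
#' @export
SummaryStats <- function(table) {
  for (cc in c("chrom", "pos", "maf")) if (is.null(table[[cc]])) table[[cc]] <- NA
  table <- table[, c("snp_id", "chrom", "pos", "a1", "a2", "beta_marginal",
                     "pval", "n_gwas", "maf")]
  if (nrow(table) && !anyNA(table$chrom))
    table <- table[chromSortOrder(table$chrom, table$pos), , drop = FALSE]
  rownames(table) <- NULL
  new("SummaryStats", table = table)
}

#' Standardized marginal effect estimates
#'
#' Marginal least-squares effects on the standardized-genotype,
#' standardized-phenotype scale, i.e. the scale on which bhat = Z'y/N.
#'
#' @slot snpId character vector of SNP identifiers.
#' @slot betahatStd numeric vector of standardized marginal effects.
#' @slot nGwas numeric vector of per-SNP GWAS sample sizes.
#' @export
setClass("StandardizedEffects",
         representation(snpId = "character", betahatStd = "numeric",
                        nGwas = "numeric"))

setValidity("StandardizedEffects", function(object) {
  if (length(object@snpId) != length(object@betahatStd) ||
      length(object@snpId) != length(object@nGwas))
    return("snpId, betahatStd and nGwas must have equal length")
  if (length(object@betahatStd) && !all(is.finite(object@betahatStd)))
    return("betahatStd must be finite")
  TRUE
})

#' @param snpId,betahatStd,nGwas see slots.
#' @rdname StandardizedEffects-class
#' @export
StandardizedEffects <- function(snpId, betahatStd, nGwas) {
  new("StandardizedEffects", snpId = as.character(snpId),
      betahatStd = as.numeric(betahatStd),
      nGwas = rep_len(as.numeric(nGwas), length(betahatStd)))
}

#' Genome partition into LD blocks
#'
#' An ordered set of non-overlapping genomic intervals (the ldetect BED
#' dialect: 0-based, half-open on disk; stored 1-based closed).
#'
#' @slot ranges a [GenomicRanges::GRanges] with one range per block.
#' @export
setClass("BlockPartition", representation(ranges = "GRanges"))

setValidity("BlockPartition", function(object) {
  gr <- object@ranges
  if (length(gr) > 1) {
    byChrom <- split(gr, as.character(GenomicRanges::seqnames(gr)))
    for (g in byChrom) {
      if (length(g) > 1) {
        s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
        if (is.unsorted(s)) return("blocks must be sorted within chromosome")
        if (any(s[-1] <= e[-length(e)]))
          return("blocks within a chromosome must not overlap")
      }
    }
  }
  TRUE
})

#' LD block: SNP set with its correlation matrix
#'
#' @slot snpIds ordered SNP identifiers of the block.
#' @slot D symmetric SNP correlation matrix with unit diagonal, estimated as
#'   Z'Z/n from standardized reference genotypes.
#' @slot nRef reference panel sample size.
#' @export
setClass("LDBlock",
         representation(snpIds = "character", D = "matrix", nRef = "integer"))

setValidity("LDBlock", function(object) {
  D <- object@D
  if (nrow(D) != ncol(D)) return("D must be square")
  if (nrow(D) != length(object@snpIds))
    return("length(snpIds) must equal nrow(D)")
  if (nrow(D)) {
    if (max(abs(D - t(D))) > 1e-8) return("D must be symmetric")
    if (max(abs(diag(D) - 1)) > 1e-6) return("D must have unit diagonal")
  }
  TRUE
})

#' @param snpIds,D,nRef see slots.
#' @rdname LDBlock-class
#' @export
LDBlock <- function(snpIds, D, nRef) {
  dimnames(D) <- NULL
  new("LDBlock", snpIds = as.character(snpIds), D = D, nRef = as.integer(nRef))
}

#' Continuous shrinkage prior specification
#'
#' The gamma-gamma (three-parameter beta) prior on the local shrinkage
#' scales. The default `a = 1`, `b = 1/2` is the Strawderman-Berger prior;
#' `a = b = 1/2` gives the horseshoe. `phi = "auto"` requests the fully
#' Bayesian half-Cauchy update of the global scale.
#'
#' @slot a shape controlling prior behaviour near zero effect.
#' @slot b shape controlling the prior tails.
#' @slot phi numeric global scale (`NA` in auto mode).
#' @slot phiAuto logical; `TRUE` when phi is learnt from the data.
#' @export
setClass("PriorSpec",
         representation(a = "numeric", b = "numeric", phi = "numeric",
                        phiAuto = "logical"))

setValidity("PriorSpec", function(object) {
  if (object@a <= 0 || object@b <= 0) return("a and b must be positive")
  if (!object@phiAuto && (is.na(object@phi) || object@phi <= 0))
    return("phi must be positive when fixed")
  TRUE
})

#' @param a,b positive TPB shape parameters.
#' @param phi positive global scale, or the string `"auto"`.
#' @rdname PriorSpec-class
#' @export
priorSpec <- function(a = 1, b = 0.5, phi = "auto") {
  auto <- identical(phi, "auto")
  new("PriorSpec", a = as.numeric(a), b = as.numeric(b),
      phi = if (auto) NA_real_ else as.numeric(phi), phiAuto = auto)
}

#' MCMC configuration for the shrinkage Gibbs sampler
#'
#' @slot nIter total iterations; @slot nBurnin burn-in iterations;
#' @slot thin post-burn-in thinning interval; @slot seed RNG seed (`NA` to
#'   leave the RNG state untouched); @slot rhoFloor lower bound rho on the
#'   per-SNP regularization 1/(phi psi_j); @slot prior a [PriorSpec-class];
#' @slot nEff effective GWAS sample size entering the likelihood;
#' @slot keepTrace record (iteration, sigma2, phi, mean|beta|) each sweep.
#' @export
setClass("GibbsConfig",
         representation(nIter = "integer", nBurnin = "integer",
                        thin = "integer", seed = "integer",
                        rhoFloor = "numeric", prior = "PriorSpec",
                        nEff = "numeric", keepTrace = "logical"))

setValidity("GibbsConfig", function(object) {
  if (object@nBurnin >= object@nIter) return("nBurnin must be < nIter")
  if (object@thin < 1L) return("thin must be >= 1")
  if (object@rhoFloor <= 0) return("rhoFloor must be positive")
  if (object@nEff <= 1) return("nEff must exceed 1")
  TRUE
})

#' @param nIter,nBurnin,thin MCMC run lengths (defaults follow the
#'   simulation-scale recommendation of 1000 iterations, 500 burn-in).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param rhoFloor regularization floor rho (default 1).
#' @param prior a [PriorSpec-class].
#' @param nEff effective GWAS sample size.
#' @param keepTrace logical.
#' @rdname GibbsConfig-class
#' @export
gibbsConfig <- function(nEff, nIter = 1000, nBurnin = 500, thin = 1,
                        seed = NULL, rhoFloor = 1, prior = priorSpec(),
                        keepTrace = FALSE) {
  new("GibbsConfig", nIter = as.integer(nIter), nBurnin = as.integer(nBurnin),
      thin = as.integer(thin),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      rhoFloor = as.numeric(rhoFloor), prior = prior,
      nEff = as.numeric(nEff), keepTrace = keepTrace)
}

#' Posterior SNP effect sizes
#'
#' Posterior mean effects on the standardized and per-allele scales, plus
#' run-level diagnostics.
#'
#' @slot snpInfo data.frame with `snp_id`, `chrom`, `pos`, `a1`, `a2`, `maf`.
#' @slot betaStdMean posterior mean effects, standardized scale.
#' @slot betaPerAlleleMean posterior mean effects per allele copy.
#' @slot phiPosteriorMean posterior mean of phi (`NA` unless auto mode).
#' @slot sigma2PosteriorMean posterior mean residual variance.
#' @slot nSamplesUsed number of post-burn-in samples averaged.
#' @slot trace optional iteration trace matrix.
#' @export
setClass("PosteriorEffects",
         representation(snpInfo = "data.frame", betaStdMean = "numeric",
                        betaPerAlleleMean = "numeric",
                        phiPosteriorMean = "numeric",
                        sigma2PosteriorMean = "numeric",
                        nSamplesUsed = "integer", trace = "matrix"))

setValidity("PosteriorEffects", function(object) {
  n <- nrow(object@snpInfo)
  if (length(object@betaStdMean) != n)
    return("betaStdMean must align with snpInfo")
  if (length(object@betaPerAlleleMean) != n)
    return("betaPerAlleleMean must align with snpInfo")
  if (n && !all(is.finite(object@betaStdMean)))
    return("betaStdMean must be finite")
  TRUE
})

#' @param snpInfo,betaStdMean,betaPerAlleleMean,phiPosteriorMean,sigma2PosteriorMean,nSamplesUsed,trace see slots.
#' @rdname PosteriorEffects-class
#' @export
PosteriorEffects <- function(snpInfo, betaStdMean, betaPerAlleleMean,
                             phiPosteriorMean = NA_real_,
                             sigma2PosteriorMean = NA_real_,
                             nSamplesUsed = 0L,
                             trace = matrix(numeric(0), 0, 0)) {
  rownames(snpInfo) <- NULL
  new("PosteriorEffects", snpInfo = snpInfo,
      betaStdMean = as.numeric(betaStdMean),
      betaPerAlleleMean = as.numeric(betaPerAlleleMean),
      phiPosteriorMean = as.numeric(phiPosteriorMean),
      sigma2PosteriorMean = as.numeric(sigma2PosteriorMean),
      nSamplesUsed = as.integer(nSamplesUsed), trace = trace)
}

#' Genetic architecture specification for simulation
#'
#' @slot family one of `point_normal`, `point_t`, `point_gamma`,
#'   `normal_mixture`.
#' @slot nCausal number of causal SNPs (ignored for `normal_mixture`).
#' @slot df degrees of freedom of the point-t family.
#' @slot shape gamma shape of the point-gamma family.
#' @slot h2 SNP heritability of the simulated trait.
#' @slot mixtureCounts,mixtureShares causal counts and heritability shares of
#'   the three normal-mixture groups.
#' @export
setClass("ArchitectureSpec",
         representation(family = "character", nCausal = "integer",
                        df = "numeric", shape = "numeric", h2 = "numeric",
                        mixtureCounts = "integer", mixtureShares = "numeric"))

setValidity("ArchitectureSpec", function(object) {
  fams <- c("point_normal", "point_t", "point_gamma", "normal_mixture")
  if (!object@family %in% fams)
    return(paste("family must be one of:", paste(fams, collapse = ", ")))
  if (object@h2 <= 0 || object@h2 >= 1) return("h2 must lie in (0, 1)")
  if (object@family == "normal_mixture") {
    if (length(object@mixtureCounts) != length(object@mixtureShares))
      return("mixtureCounts and mixtureShares must align")
    if (abs(sum(object@mixtureShares) - 1) > 1e-8)
      return("mixtureShares must sum to 1")
  } else if (object@nCausal < 1L) {
    return("nCausal must be >= 1")
  }
  TRUE
})

#' @param family,nCausal,df,shape,h2,mixtureCounts,mixtureShares see slots.
#' @rdname ArchitectureSpec-class
#' @export
architectureSpec <- function(family = "point_normal", nCausal = 100, df = 4,
                             shape = 2, h2 = 0.5,
                             mixtureCounts = c(10, 1000, 10000),
                             mixtureShares = c(0.10, 0.20, 0.70)) {
  new("ArchitectureSpec", family = family, nCausal = as.integer(nCausal),
      df = as.numeric(df), shape = as.numeric(shape), h2 = as.numeric(h2),
      mixtureCounts = as.integer(mixtureCounts),
      mixtureShares = as.numeric(mixtureShares))
}

#' Simulated genotype cohort
#'
#' @slot genotypes n x m matrix of allele counts (0/1/2) of allele `a1`.
#' @slot map data.frame with `snp_id`, `chrom`, `pos`, `a1`, `a2`, `maf`
#'   (sample frequency of the minor allele) and `block` assignment.
#' @slot betaTrue simulated true effects on the standardized scale (empty
#'   until a phenotype has been attached).
#' @slot y simulated phenotype (variance approximately 1).
#' @export
setClass("SimulatedCohort",
         representation(genotypes = "matrix", map = "data.frame",
                        betaTrue = "numeric", y = "numeric"))

#' Individual polygenic scores with phenotype and covariates
#'
#' @slot sampleIds sample identifiers.
#' @slot prs polygenic score per individual.
#' @slot phenotype quantitative or 0/1 phenotype (may be empty).
#' @slot covariates numeric covariate matrix (may have zero columns).
#' @export
setClass("ScoreSet",
         representation(sampleIds = "character", prs = "numeric",
                        phenotype = "numeric", covariates = "matrix"))

setValidity("ScoreSet", function(object) {
  n <- length(object@prs)
  if (length(object@sampleIds) != n) return("sampleIds must align with prs")
  if (length(object@phenotype) && length(object@phenotype) != n)
    return("phenotype must align with prs")
  if (anyNA(object@prs)) return("prs must not contain missing values")
  TRUE
})

#' @param prs,phenotype,covariates see slots; @param sampleIds identifiers.
#' @rdname ScoreSet-class
#' @export
ScoreSet <- function(prs, phenotype = numeric(0), covariates = NULL,
                     sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- as.character(seq_along(prs))
  if (is.null(covariates)) covariates <- matrix(numeric(0), length(prs), 0)
  new("ScoreSet", sampleIds = as.character(sampleIds), prs = as.numeric(prs),
      phenotype = as.numeric(phenotype), covariates = as.matrix(covariates))
}

#' Predictive performance report
#'
#' @slot metrics named numeric vector of point metrics.
#' @slot perSplit per-split metric table for repeated-split evaluation.
#' @export
setClass("EvalReport",
         representation(metrics = "numeric", perSplit = "data.frame"))

#' @param metrics,perSplit see slots.
#' @rdname EvalReport-class
#' @export
EvalReport <- function(metrics, perSplit = data.frame()) {
  new("EvalReport", metrics = metrics, perSplit = perSplit)
}
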