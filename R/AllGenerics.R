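#' Accessors for csprs data classes
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sumstatsTable", function(x) standardGeneric("sumstatsTable"))

#' @rdname accessors
#' @export
setMethod("sumstatsTable", "SummaryStats", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setMethod("nSnps", "SummaryStats", function(x) nrow(x@table))

#' @rdname accessors
#' @export
setMethod("nSnps", "LDBlock", function(x) length(x@snpIds))

#' @rdname accessors
#' @export
setMethod("nSnps", "PosteriorEffects", function(x) nrow(x@snpInfo))

#' @rdname accessors
#' @export
setMethod("nSnps", "SimulatedCohort", function(x) ncol(x@genotypes))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setMethod("snpIds", "SummaryStats", function(x) x@table$snp_id)

#' @rdname accessors
#' @export
setMethod("snpIds", "LDBlock", function(x) x@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "StandardizedEffects", function(x) x@snpId)

#' @rdname accessors
#' @export
setGeneric("ldMatrix", function(x) standardGeneric("ldMatrix"))

#' @rdname accessors
#' @export
setMethod("ldMatrix", "LDBlock", function(x) x@D)

#' @rdname accessors
#' @export
setGeneric("blockRanges", function(x) standardGeneric("blockRanges"))

#' @rdname accessors
#' @export
setMethod("blockRanges", "BlockPartition", function(x) x@ranges)

#' Posterior weight table
#'
#' One row per SNP: chromosome, identifier, position, effect allele, other
#' allele and the posterior mean per-allele effect — the layout consumed by
#' standard scoring tools.
#'
#' @param x a [PosteriorEffects-class] object.
#' @return data.frame.
#' @export
setGeneric("weightsTable", function(x) standardGeneric("weightsTable"))

#' @rdname weightsTable
#' @export
setMethod("weightsTable", "PosteriorEffects", function(x) {
  data.frame(chrom = x@snpInfo$chrom, snp_id = x@snpInfo$snp_id,
             pos = x@snpInfo$pos, a1 = x@snpInfo$a1, a2 = x@snpInfo$a2,
             beta = x@betaPerAlleleMean, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname accessors
#' @export
setMethod("metricsTable", "EvalReport", function(x) x@metrics)

setMethod("show", "SummaryStats", function(object) {
  tb <- object@table
  cat("SummaryStats with", nrow(tb), "SNPs\n")
  if (nrow(tb)) {
    cat("  harmonized:", ifelse(anyNA(tb$chrom), "no", "yes"), "\n")
    print(utils::head(tb, 4))
    if (nrow(tb) > 4) cat("  ...\n")
  }
  if (length(object@harmonization))
    cat("  harmonization counts:",
        paste(names(object@harmonization), unlist(object@harmonization),
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LDBlock", function(object) {
  cat("LDBlock:", length(object@snpIds), "SNPs, reference n =",
      object@nRef, "\n")
})

setMethod("show", "BlockPartition", function(object) {
  cat("BlockPartition with", length(object@ranges), "blocks on",
      length(unique(as.character(GenomicRanges::seqnames(object@ranges)))),
      "chromosome(s)\n")
})

setMethod("show", "PriorSpec", function(object) {
  cat(sprintf("Continuous shrinkage prior: a = %g, b = %g, phi = %s\n",
              object@a, object@b,
              if (object@phiAuto) "auto (half-Cauchy on phi^{1/2})"
              else format(object@phi)))
})

setMethod("show", "PosteriorEffects", function(object) {
  cat("PosteriorEffects for", nrow(object@snpInfo), "SNPs\n")
  cat(sprintf("  posterior samples averaged: %d\n", object@nSamplesUsed))
  if (!is.na(object@phiPosteriorMean))
    cat(sprintf("  posterior mean phi: %.4g\n", object@phiPosteriorMean))
  if (!is.na(object@sigma2PosteriorMean))
    cat(sprintf("  posterior mean sigma2: %.4g\n",
                object@sigma2PosteriorMean))
})

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort:", nrow(object@genotypes), "individuals x",
      ncol(object@genotypes), "SNPs in",
      length(unique(object@map$block)), "LD blocks\n")
  if (length(object@betaTrue))
    cat("  causal SNPs:", sum(object@betaTrue != 0), "\n")
  if (length(object@y)) cat("  phenotype attached\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  for (nm in names(object@metrics))
    cat(sprintf("  %-20s %.5g\n", nm, object@metrics[[nm]]))
  if (nrow(object@perSplit))
    cat("  (", nrow(object@perSplit), "splits )\n")
})
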