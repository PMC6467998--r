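#' Read GWAS summary statistics from a whitespace-delimited text file
#'
#' The canonical header is `SNP A1 A2 BETA P` with optional `N` and `MAF`
#' columns; `OR` is accepted in place of `BETA` and is log-transformed.
#' Rows with alleles outside A/C/G/T and strand-ambiguous SNPs (A/T, C/G)
#' are dropped with a message. Column names can be remapped through
#' `dialect`.
#'
#' @param path path to the summary statistics file.
#' @param dialect named character vector mapping canonical names
#'   (`SNP`, `A1`, `A2`, `BETA`, `OR`, `P`, `N`, `MAF`, `CHR`, `BP`) to the
#'   column names used in the file.
#' @param nGwas global GWAS sample size, required when the file has no `N`
#'   column.
#' @return A [SummaryStats-class] object (coordinates are `NA` until
#'   [harmonizeSumstats()] fills them from a reference panel unless the file
#'   carries `CHR`/`BP` columns).
#' @export
readSumstats <- function(path, dialect = NULL, nGwas = NULL) {
  if (!file.exists(path)) stopData("summary statistics file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  canon <- c(SNP = "SNP", A1 = "A1", A2 = "A2", BETA = "BETA", OR = "OR",
             P = "P", N = "N", MAF = "MAF", CHR = "CHR", BP = "BP")
  if (!is.null(dialect)) canon[names(dialect)] <- dialect
  col <- function(nm) if (canon[[nm]] %in% names(raw)) raw[[canon[[nm]]]] else NULL

  for (req in c("SNP", "A1", "A2", "P"))
    if (is.null(col(req)))
      stopData("required column missing from ", path, ": ", canon[[req]])
  hasBeta <- !is.null(col("BETA")); hasOr <- !is.null(col("OR"))
  if (!hasBeta && !hasOr)
    stopData("required column missing from ", path, ": ", canon[["BETA"]],
             " (or ", canon[["OR"]], ")")

  asNum <- function(x, nm) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & x != "NA")
    if (length(bad))
      stopData("unparseable numeric in column ", nm, " at line ",
               bad[1L] + 1L, ": '", x[bad[1L]], "'")
    out
  }

  beta <- if (hasBeta) asNum(col("BETA"), canon[["BETA"]])
          else log(asNum(col("OR"), canon[["OR"]]))
  pval <- asNum(col("P"), canon[["P"]])
  n <- if (!is.null(col("N"))) asNum(col("N"), canon[["N"]]) else {
    if (is.null(nGwas))
      stopData("file has no sample-size column; supply nGwas")
    rep(as.numeric(nGwas), nrow(raw))
  }

  tb <- data.frame(snp_id = col("SNP"),
                   chrom = if (!is.null(col("CHR"))) col("CHR") else NA_character_,
                   pos = if (!is.null(col("BP"))) asNum(col("BP"), canon[["BP"]]) else NA_real_,
                   a1 = toupper(col("A1")), a2 = toupper(col("A2")),
                   beta_marginal = beta, pval = pval, n_gwas = n,
                   maf = if (!is.null(col("MAF"))) asNum(col("MAF"), canon[["MAF"]]) else NA_real_,
                   stringsAsFactors = FALSE)

  ok_allele <- tb$a1 %in% c("A", "C", "G", "T") & tb$a2 %in% c("A", "C", "G", "T")
  if (any(!ok_allele)) {
    message(sum(!ok_allele), " SNP(s) dropped: non-ACGT alleles")
    tb <- tb[ok_allele, , drop = FALSE]
  }
  ambi <- isAmbiguousPair(tb$a1, tb$a2)
  if (any(ambi)) {
    message(sum(ambi), " SNP(s) dropped: strand-ambiguous (A/T or C/G)")
    tb <- tb[!ambi, , drop = FALSE]
  }
  if (anyDuplicated(tb$snp_id))
    stopData("duplicated snp_id in ", path, ": ",
             tb$snp_id[duplicated(tb$snp_id)][1L])
  if (nrow(tb) && any(tb$pval == 0)) {
    warning("p-values of 0 clamped to 1e-323")
    tb$pval[tb$pval == 0] <- 1e-323
  }
  if (nrow(tb) && (any(tb$pval < 0) || any(tb$pval > 1)))
    stopData("p-values outside (0, 1] in ", path)
  SummaryStats(tb)
}

isAmbiguousPair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics against a reference variant table
#'
#' Intersects the SNP sets, reorders alleles to the reference frame (flipping
#' the sign of the effect when the alleles are swapped), removes
#' strand-ambiguous SNPs and SNPs below the reference MAF threshold, and
#' fills chromosome, position and MAF from the reference. Counts of kept,
#' flipped and dropped SNPs are stored in the `harmonization` slot.
#'
#' @param sst a [SummaryStats-class] object.
#' @param ref reference variant table: data.frame with `snp_id`, `chrom`,
#'   `pos`, `a1`, `a2`, `maf` (see [refVariantTable()]).
#' @param minMaf SNPs with reference MAF below this are removed (default 1%).
#' @param whitelist optional character vector of SNP ids to restrict the
#'   analysis to (e.g. a genotyping-array or HapMap3 panel); applied before
#'   intersection.
#' @return A harmonized [SummaryStats-class] object.
#' @export
harmonizeSumstats <- function(sst, ref, minMaf = 0.01, whitelist = NULL) {
  tb <- sst@table
  if (!is.null(whitelist)) tb <- tb[tb$snp_id %in% whitelist, , drop = FALSE]
  idx <- match(tb$snp_id, ref$snp_id)
  nAbsent <- sum(is.na(idx))
  keep <- !is.na(idx)
  tb <- tb[keep, , drop = FALSE]
  rr <- ref[idx[keep], , drop = FALSE]

  ambi <- isAmbiguousPair(tb$a1, tb$a2) | isAmbiguousPair(rr$a1, rr$a2)
  same <- tb$a1 == rr$a1 & tb$a2 == rr$a2
  swap <- tb$a1 == rr$a2 & tb$a2 == rr$a1
  reconcilable <- (same | swap) & !ambi
  nAmbiguous <- sum(ambi)
  nIrreconcilable <- sum(!(same | swap) & !ambi)

  tb <- tb[reconcilable, , drop = FALSE]
  rr <- rr[reconcilable, , drop = FALSE]
  flip <- (tb$a1 == rr$a2)
  tb$beta_marginal[flip] <- -tb$beta_marginal[flip]
  tb$a1 <- rr$a1
  tb$a2 <- rr$a2
  tb$chrom <- as.character(rr$chrom)
  tb$pos <- rr$pos
  tb$maf <- rr$maf

  lowMaf <- tb$maf < minMaf
  nLowMaf <- sum(lowMaf)
  tb <- tb[!lowMaf, , drop = FALSE]

  out <- SummaryStats(tb)
  out@harmonization <- list(kept = nrow(tb), flipped = sum(flip & !lowMaf),
                            absent = nAbsent, ambiguous = nAmbiguous,
                            irreconcilable = nIrreconcilable,
                            low_maf = nLowMaf)
  message(sprintf(paste("harmonization: %d kept (%d sign-flipped);",
                        "dropped %d absent, %d ambiguous, %d irreconcilable,",
                        "%d below MAF %.3g"),
                  nrow(tb), out@harmonization$flipped, nAbsent, nAmbiguous,
                  nIrreconcilable, nLowMaf, minMaf))
  out
}

#' Standardized marginal effects from p-value, sign and sample size
#'
#' Computes `betahat_std_j = sign(beta_j) * |z_j| / sqrt(N_j)`, where `z_j`
#' is the two-sided standard-normal quantile of the p-value. This places the
#' marginal estimates on the scale of a regression of a standardized
#' phenotype on standardized genotypes (bhat = Z'y/N) regardless of the
#' trait units used by the GWAS. A direct `beta/se` route is available when
#' the summary file's standard errors are trusted.
#'
#' @param sst a [SummaryStats-class] object.
#' @param method `"pz"` (default; p-value + sign + N) or `"beta_se"`.
#' @param se numeric vector of standard errors (required for `"beta_se"`).
#' @param cap upper bound on `|betahat_std|` (standardized effects cannot
#'   exceed 1; default 1).
#' @return A [StandardizedEffects-class] object.
#' @export
standardizeEffects <- function(sst, method = c("pz", "beta_se"), se = NULL,
                               cap = 1) {
  method <- match.arg(method)
  tb <- sst@table
  if (method == "pz") {
    p <- tb$pval
    if (any(p == 0)) {
      warning("p-values of 0 clamped to 1e-323")
      p[p == 0] <- 1e-323
    }
    z <- stats::qnorm(p / 2, lower.tail = FALSE)
    bstd <- sign(tb$beta_marginal) * z / sqrt(tb$n_gwas)
    bstd[tb$beta_marginal == 0] <- 0
  } else {
    if (is.null(se) || length(se) != nrow(tb))
      stopUsage("method 'beta_se' requires one standard error per SNP")
    bstd <- (tb$beta_marginal / se) / sqrt(tb$n_gwas)
  }
  over <- abs(bstd) > cap
  if (any(over)) {
    warning(sum(over), " standardized effect(s) capped at ", cap)
    bstd[over] <- sign(bstd[over]) * cap
  }
  StandardizedEffects(tb$snp_id, bstd, tb$n_gwas)
}

#' Convert between standardized and per-allele effect scales
#'
#' On the reference MAF frame, `per_allele = standardized /
#' sqrt(2 maf (1 - maf))` (the genotype standard deviation under
#' Hardy-Weinberg equilibrium).
#'
#' @param beta effect sizes.
#' @param maf allele frequencies.
#' @param from scale of `beta`.
#' @return effects on the other scale.
#' @export
convertEffectScale <- function(beta, maf, from = c("standardized", "per_allele")) {
  from <- match.arg(from)
  sd_g <- sqrt(2 * maf * (1 - maf))
  if (from == "standardized") beta / sd_g else beta * sd_g
}

#' Write posterior effects as a 6-column weight file
#'
#' Tab-separated text, one row per SNP: chromosome, identifier, position,
#' effect allele, other allele, posterior per-allele effect; sorted by
#' (chromosome, position). Directly consumable by standard scoring tools.
#'
#' @param pe a [PosteriorEffects-class] object.
#' @param path output path.
#' @export
writePosteriorEffects <- function(pe, path) {
  wt <- weightsTable(pe)
  wt <- wt[chromSortOrder(wt$chrom, wt$pos), , drop = FALSE]
  wt$beta <- sprintf("%.10g", wt$beta)
  ok <- tryCatch({
    utils::write.table(wt, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopData("cannot write weight file: ", path)
  invisible(path)
}

#' Read a 6-column posterior weight file
#'
#' @param path path written by [writePosteriorEffects()].
#' @return data.frame with `chrom`, `snp_id`, `pos`, `a1`, `a2`, `beta`.
#' @export
readPosteriorEffects <- function(path) {
  if (!file.exists(path)) stopData("weight file not found: ", path)
  tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "snp_id", "pos", "a1", "a2",
                                        "beta"))
  tb$chrom <- as.character(tb$chrom)
  tb
}
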