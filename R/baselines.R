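# Comparator polygenic scoring methods: unadjusted marginal weights,
# LD clumping + p-value thresholding (P+T), and the infinitesimal-model
# closed form (a per-block ridge solve).

#' Unadjusted polygenic score weights
#'
#' Every SNP keeps its marginal per-allele effect estimate.
#'
#' @param sst harmonized [SummaryStats-class].
#' @return A [PosteriorEffects-class] whose weights equal the marginal
#'   effects.
#' @export
unadjustedWeights <- function(sst) {
  tb <- sst@table
  betaStd <- convertEffectScale(tb$beta_marginal, tb$maf, from = "per_allele")
  PosteriorEffects(tb[, c("snp_id", "chrom", "pos", "a1", "a2", "maf")],
                   betaStd, tb$beta_marginal)
}

#' Pairwise r-squared provider backed by block LD matrices
#'
#' Returns a function `(idA, idsB) -> r2 vector`. Pairs in different blocks
#' are treated as unlinked (r2 = 0); SNPs absent from every block are
#' unlinked with a counted warning.
#'
#' @param blocks list of [LDBlock-class].
#' @return lookup function.
#' @export
ldProvider <- function(blocks) {
  ids <- unlist(lapply(blocks, snpIds), use.names = FALSE)
  blk <- rep(seq_along(blocks), vapply(blocks, nSnps, integer(1)))
  within <- unlist(lapply(blocks, function(b) seq_len(nSnps(b))),
                   use.names = FALSE)
  missed <- new.env(); missed$n <- 0L
  function(idA, idsB) {
    ia <- match(idA, ids)
    ib <- match(idsB, ids)
    if (is.na(ia) || anyNA(ib)) {
      missed$n <- missed$n + sum(is.na(c(ia, ib)))
      warning("SNP absent from LD reference treated as unlinked")
    }
    out <- numeric(length(idsB))
    ok <- !is.na(ib) & !is.na(ia) & blk[ib] == blk[ia]
    if (any(ok)) {
      D <- blocks[[blk[ia]]]@D
      out[ok] <- D[within[ia], within[ib[ok]]]^2
    }
    out
  }
}

#' Greedy LD clumping
#'
#' Iterates index SNPs by ascending p-value (ties: smaller position, then
#' lexicographic id); for each index SNP, every not-yet-removed SNP on the
#' same chromosome with center-to-center distance strictly below `windowBp`
#' and r-squared above `r2Threshold` and a larger p-value is removed.
#'
#' @param sst harmonized [SummaryStats-class].
#' @param ldLookup function from [ldProvider()] (or compatible).
#' @param r2Threshold r-squared above which the less significant SNP is
#'   removed (default 0.1).
#' @param windowBp physical window in base pairs (default 250 kb).
#' @return character vector of retained SNP ids, in `sst` row order.
#' @export
clumpSnps <- function(sst, ldLookup, r2Threshold = 0.1, windowBp = 250000) {
  tb <- sst@table
  m <- nrow(tb)
  ord <- order(tb$pval, tb$pos, tb$snp_id)
  removed <- logical(m)
  for (i in ord) {
    if (removed[i]) next
    near <- which(tb$chrom == tb$chrom[i] &
                    abs(tb$pos - tb$pos[i]) < windowBp & !removed)
    near <- setdiff(near, i)
    if (!length(near)) next
    worse <- near[tb$pval[near] > tb$pval[i] |
                    (tb$pval[near] == tb$pval[i] &
                       (tb$pos[near] > tb$pos[i] |
                          (tb$pos[near] == tb$pos[i] &
                             tb$snp_id[near] > tb$snp_id[i])))]
    if (!length(worse)) next
    r2 <- ldLookup(tb$snp_id[i], tb$snp_id[worse])
    removed[worse[r2 > r2Threshold]] <- TRUE
  }
  tb$snp_id[!removed]
}

#' Default p-value threshold grid for P+T
#' @export
defaultPThresholds <- function() {
  c(1e-8, 1e-7, 1e-6, 1e-5, 3e-5, 1e-4, 3e-4, 0.001, 0.003, 0.01, 0.03,
    0.1, 0.3, 1)
}

#' P-value thresholding on a clumped SNP set
#'
#' For each threshold `P_T`, weights are the marginal per-allele effects of
#' the retained SNPs with `p <= P_T` and zero otherwise.
#'
#' @param sst harmonized [SummaryStats-class].
#' @param retained SNP ids kept by [clumpSnps()].
#' @param pThresholds threshold grid, ascending.
#' @return matrix of per-allele weights (SNPs x thresholds, columns named
#'   by threshold) with an attribute `n_nonzero`.
#' @export
thresholdGrid <- function(sst, retained, pThresholds = defaultPThresholds()) {
  if (is.unsorted(pThresholds)) stopUsage("pThresholds must be ascending")
  tb <- sst@table
  keep <- tb$snp_id %in% retained
  W <- vapply(pThresholds, function(pt)
    ifelse(keep & tb$pval <= pt, tb$beta_marginal, 0), numeric(nrow(tb)))
  colnames(W) <- sprintf("pt=%g", pThresholds)
  rownames(W) <- tb$snp_id
  nz <- colSums(W != 0)
  if (any(nz == 0))
    warning("empty score at threshold(s): ",
            paste(colnames(W)[nz == 0], collapse = ", "))
  attr(W, "n_nonzero") <- nz
  W
}

#' Infinitesimal-model posterior mean weights (per-block ridge)
#'
#' Closed-form posterior means under a normal prior on every effect:
#' `E[beta_l | bhat_l, D_l] = (D_l + M/(N h2) I)^{-1} bhat_l` per LD block.
#' Equivalent to [posteriorMeanFixedScales()] with constant prior scale
#' `T_jj = N h2 / M`.
#'
#' @param hstats [StandardizedEffects-class].
#' @param blocks list of [LDBlock-class] covering the SNPs of `hstats`.
#' @param h2 SNP heritability (supplied, e.g. from LD score regression).
#' @param nGwas GWAS sample size N (default: median of the per-SNP N).
#' @param mTotal number of markers M (default: number of SNPs).
#' @param snpInfo optional variant table enabling the per-allele scale.
#' @return A [PosteriorEffects-class].
#' @export
ldpredInfWeights <- function(hstats, blocks, h2, nGwas = NULL, mTotal = NULL,
                             snpInfo = NULL) {
  if (h2 <= 0 || h2 >= 1) stopUsage("h2 must lie in (0, 1)")
  if (is.null(nGwas)) nGwas <- stats::median(hstats@nGwas)
  if (is.null(mTotal)) mTotal <- length(hstats@snpId)
  ridge <- mTotal / (nGwas * h2)
  ids <- unlist(lapply(blocks, snpIds), use.names = FALSE)
  pos <- match(ids, hstats@snpId)
  if (anyNA(pos) || length(ids) != length(hstats@snpId))
    stopData("blocks must cover exactly the SNPs of hstats")
  betaStd <- numeric(length(pos))
  off <- 0
  for (b in blocks) {
    m <- nSnps(b)
    i <- pos[(off + 1):(off + m)]
    betaStd[i] <- posteriorMeanFixedScales(hstats@betahatStd[i], b@D,
                                           rep(1 / ridge, m))
    off <- off + m
  }
  if (is.null(snpInfo)) {
    info <- data.frame(snp_id = hstats@snpId, chrom = NA_character_,
                       pos = NA_real_, a1 = NA_character_,
                       a2 = NA_character_, maf = NA_real_,
                       stringsAsFactors = FALSE)
  } else {
    info <- snpInfo[match(hstats@snpId, snpInfo$snp_id),
                    c("snp_id", "chrom", "pos", "a1", "a2", "maf")]
  }
  PosteriorEffects(info, betaStd,
                   convertEffectScale(betaStd, info$maf, "standardized"))
}
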