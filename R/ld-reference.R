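#' Load a genome partition from a BED-dialect interval file
#'
#' Intervals are 0-based half-open on disk (the ldetect convention); they are
#' validated, sorted, and stored 1-based closed. Gaps between blocks are
#' permitted; SNPs falling in a gap attach to the nearest preceding block on
#' the same chromosome (see [mapSnpsToBlocks()]).
#'
#' @param path interval file with columns chrom, start, end (no header
#'   required; a `track`/header line is skipped).
#' @return A [BlockPartition-class] object.
#' @export
loadPartition <- function(path) {
  if (!file.exists(path)) stopData("partition file not found: ", path)
  tb <- utils::read.table(path, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "numeric", "numeric"))
  if (any(tb$end <= tb$start))
    stopData("partition has an empty or inverted interval at line ",
             which(tb$end <= tb$start)[1L])
  tb <- tb[chromSortOrder(tb$chrom, tb$start), , drop = FALSE]
  for (ch in unique(tb$chrom)) {
    sub <- tb[tb$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1) {
      bad <- which(sub$start[-1] < sub$end[-nrow(sub)])
      if (length(bad))
        stopData("overlapping partition intervals on chromosome ", ch, ": [",
                 sub$start[bad[1L]], ",", sub$end[bad[1L]], ") and [",
                 sub$start[bad[1L] + 1L], ",", sub$end[bad[1L] + 1L], ")")
    }
  }
  gr <- GenomicRanges::GRanges(tb$chrom,
                               IRanges::IRanges(start = tb$start + 1,
                                                end = tb$end))
  new("BlockPartition", ranges = gr)
}

#' Write a block partition in the BED dialect
#'
#' @param part a [BlockPartition-class].
#' @param path output path (0-based half-open intervals).
#' @export
writePartition <- function(part, path) {
  gr <- part@ranges
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1, GenomicRanges::end(gr)),
    path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compute the LD matrix of one block from reference genotypes
#'
#' Missing calls are mean-imputed per SNP, columns are standardized to mean
#' zero and unit variance, and D = Z'Z/n. Monomorphic SNPs are dropped with
#' a warning. An optional convex shrinkage toward the identity,
#' `(1 - s) D + s I`, is available; the default `s = 0` leaves raw
#' correlations, since numerical stability is handled by the regularization
#' floor inside the sampler.
#'
#' @param genotypes n x m genotype matrix for the block (allele counts;
#'   `NA` = missing); column names are used as SNP ids.
#' @param shrinkTarget shrinkage weight toward the identity in [0, 1).
#' @param snpIds SNP identifiers (defaults to column names).
#' @return An [LDBlock-class] object.
#' @export
computeBlockLD <- function(genotypes, shrinkTarget = 0, snpIds = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (n < 2) stopData("at least 2 reference samples are required")
  if (is.null(snpIds)) snpIds <- colnames(genotypes)
  if (is.null(snpIds)) snpIds <- sprintf("snp%d", seq_len(ncol(genotypes)))

  if (anyNA(genotypes)) {
    mu <- colMeans(genotypes, na.rm = TRUE)
    idx <- which(is.na(genotypes), arr.ind = TRUE)
    genotypes[idx] <- mu[idx[, 2]]
  }
  mu <- colMeans(genotypes)
  sdv <- sqrt(colMeans(genotypes^2) - mu^2)  # 1/n variance
  mono <- sdv == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped from block")
    genotypes <- genotypes[, !mono, drop = FALSE]
    snpIds <- snpIds[!mono]
    mu <- mu[!mono]; sdv <- sdv[!mono]
  }
  Z <- sweep(sweep(genotypes, 2, mu, "-"), 2, sdv, "/")
  D <- crossprod(Z) / n
  if (shrinkTarget > 0)
    D <- (1 - shrinkTarget) * D + shrinkTarget * diag(ncol(D))
  # guard against rounding on the diagonal
  diag(D) <- 1
  LDBlock(snpIds, D, n)
}

#' Assign harmonized SNPs to partition blocks
#'
#' Every SNP maps to exactly one block: SNPs inside an interval map there;
#' SNPs in inter-block gaps (or beyond the last interval) attach to the
#' nearest preceding block on the same chromosome, and SNPs before the first
#' interval attach to the first block. A SNP on a chromosome absent from the
#' partition is an error.
#'
#' @param sst a harmonized [SummaryStats-class] (or a data.frame with
#'   `chrom` and `pos`).
#' @param part a [BlockPartition-class].
#' @return named list of integer vectors; element `"k"` holds the row
#'   indices of the SNPs in partition block `k`. Empty blocks are omitted.
#' @export
mapSnpsToBlocks <- function(sst, part) {
  tb <- if (is(sst, "SummaryStats")) sst@table else sst
  if (anyNA(tb$chrom) || anyNA(tb$pos))
    stopData("SNPs must carry coordinates; harmonize against a reference first")
  gr <- part@ranges
  partChroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  bad <- setdiff(unique(as.character(tb$chrom)), partChroms)
  if (length(bad))
    stopData("chromosome absent from partition: ", bad[1L])

  snps <- GenomicRanges::GRanges(as.character(tb$chrom),
                                 IRanges::IRanges(tb$pos, tb$pos))
  hit <- GenomicRanges::findOverlaps(snps, gr, select = "first")
  miss <- which(is.na(hit))
  if (length(miss)) {
    pre <- GenomicRanges::follow(snps[miss], gr)  # nearest preceding block
    first <- GenomicRanges::precede(snps[miss], gr)
    hit[miss] <- ifelse(is.na(pre), first, pre)
  }
  split(seq_len(nrow(tb)), hit)
}

#' Build per-block LD matrices for a harmonized SNP set
#'
#' Maps the SNPs of `sst` onto the partition and computes one [LDBlock-class]
#' per non-empty block from the matching columns of the reference genotypes.
#'
#' @param sst harmonized [SummaryStats-class].
#' @param part [BlockPartition-class].
#' @param refGenotypes reference genotype matrix with SNP-id column names.
#' @param shrinkTarget passed to [computeBlockLD()].
#' @return list with `blocks` (list of [LDBlock-class], genomic order) and
#'   `index` (list of row indices of `sst` per block).
#' @export
buildLDBlocks <- function(sst, part, refGenotypes, shrinkTarget = 0) {
  idx <- mapSnpsToBlocks(sst, part)
  tb <- sst@table
  blocks <- lapply(idx, function(i) {
    ids <- tb$snp_id[i]
    missing <- setdiff(ids, colnames(refGenotypes))
    if (length(missing))
      stopData("SNP absent from reference genotypes: ", missing[1L])
    computeBlockLD(refGenotypes[, ids, drop = FALSE],
                   shrinkTarget = shrinkTarget, snpIds = ids)
  })
  list(blocks = blocks, index = idx)
}
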