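# PLINK 1 binary genotype files. The .bed format stores genotypes
# SNP-major, two bits per sample, four samples per byte (low bits first):
# 00 = two copies of allele 1, 10 = one copy, 11 = zero copies,
# 01 = missing. Genotype matrices in this package count copies of the
# .bim allele-1 column.

plinkMagic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write a genotype matrix as PLINK .bed/.bim/.fam
#'
#' @param prefix output path prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @param genotypes n x m matrix of allele-1 counts (0/1/2, `NA` = missing).
#' @param map data.frame with `chrom`, `snp_id`, `pos`, `a1`, `a2`.
#' @param sampleIds optional sample identifiers (used as FID and IID).
#' @param phenotype optional phenotype written to the .fam sixth column.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(prefix, genotypes, map, sampleIds = NULL,
                       phenotype = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (nrow(map) != m) stopData("map rows must match genotype columns")
  if (is.null(sampleIds)) sampleIds <- sprintf("id%05d", seq_len(n))
  if (is.null(phenotype)) phenotype <- rep(-9, n)

  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, m)
  code[genotypes == 1] <- 2L
  code[genotypes == 2] <- 0L
  code[is.na(genotypes)] <- 1L
  nbytes <- ceiling(n / 4)
  pad <- nbytes * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  i4 <- matrix(seq_len(nbytes * 4), nrow = 4)
  packed <- code[i4[1, ], , drop = FALSE] +
    4L * code[i4[2, ], , drop = FALSE] +
    16L * code[i4[3, ], , drop = FALSE] +
    64L * code[i4[4, ], , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(plinkMagic, con)
  writeBin(as.raw(packed), con)

  bim <- data.frame(map$chrom, map$snp_id, 0, map$pos, map$a1, map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(sampleIds, sampleIds, 0, 0, 0, phenotype)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK .bed/.bim/.fam genotypes
#'
#' @param prefix path prefix of the fileset.
#' @return list with `genotypes` (n x m allele-1 counts, `NA` = missing),
#'   `map` (from the .bim: `chrom`, `snp_id`, `pos`, `a1`, `a2`) and `fam`.
#' @export
readPlink <- function(prefix) {
  bedPath <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stopData("PLINK file not found: ", f)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"))
  bim$chrom <- as.character(bim$chrom)
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pid", "mid", "sex",
                                         "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  nbytes <- ceiling(n / 4)
  raw <- readBin(bedPath, "raw", n = 3 + nbytes * m)
  if (length(raw) < 3 || !identical(raw[1:3], plinkMagic))
    stopData("not a SNP-major PLINK 1 .bed file: ", bedPath)
  b <- as.integer(raw[-(1:3)])
  if (length(b) != nbytes * m)
    stopData("truncated .bed file: ", bedPath)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L,
                 (b %/% 64L) %% 4L)
  dim(codes) <- c(nbytes * 4L, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2, NA, 1, 0)  # code 0,1,2,3 -> dosage of allele 1
  geno <- matrix(lut[codes + 1L], n, m)
  dimnames(geno) <- list(fam$iid, bim$snp_id)
  list(genotypes = geno,
       map = bim[, c("chrom", "snp_id", "pos", "a1", "a2")],
       fam = fam)
}

#' Reference variant table from a PLINK fileset
#'
#' Combines the .bim variant records with allele frequencies computed from
#' the .bed genotypes; the result is the reference frame used by
#' [harmonizeSumstats()].
#'
#' @param x a PLINK prefix or the list returned by [readPlink()].
#' @return data.frame with `snp_id`, `chrom`, `pos`, `a1`, `a2`, `af1`
#'   (frequency of allele 1) and `maf`.
#' @export
refVariantTable <- function(x) {
  if (is.character(x)) x <- readPlink(x)
  af1 <- colMeans(x$genotypes, na.rm = TRUE) / 2
  data.frame(snp_id = x$map$snp_id, chrom = x$map$chrom, pos = x$map$pos,
             a1 = x$map$a1, a2 = x$map$a2, af1 = af1,
             maf = pmin(af1, 1 - af1), row.names = NULL,
             stringsAsFactors = FALSE)
}
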