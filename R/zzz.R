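#' @useDynLib csprs, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps follow precede
#' @importFrom IRanges IRanges
#' @importFrom stats rnorm rgamma runif qnorm pnorm rt integrate median sd var cov quantile lm glm binomial coef predict logLik
#' @importFrom utils read.table write.table head
NULL
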