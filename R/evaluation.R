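# Scoring and predictive evaluation of polygenic weights: additive scores
# on allele counts, quantitative and case-control metrics (all covariate
# adjusted when covariates are supplied), validation/testing tuning, and
# repeated random splits.

#' Score individuals with a weight table
#'
#' Additive dot product of allele counts and per-allele weights. Weight
#' alleles are matched to the genotype allele coding: swapped alleles flip
#' the weight's sign (plus a constant offset), irreconcilable SNPs are
#' dropped with a count. Missing genotypes are mean-imputed.
#'
#' @param genotypes n x m allele-count matrix with SNP-id column names (or a
#'   [SimulatedCohort-class]).
#' @param map variant table (`snp_id`, `a1`, `a2`) describing the genotype
#'   allele coding; defaults to the cohort's map.
#' @param weights a [PosteriorEffects-class] or a data.frame with `snp_id`,
#'   `a1`, `a2`, `beta`.
#' @param phenotype,covariates optional, stored in the result.
#' @return A [ScoreSet-class].
#' @export
scoreIndividuals <- function(genotypes, weights, map = NULL,
                             phenotype = NULL, covariates = NULL) {
  if (is(genotypes, "SimulatedCohort")) {
    if (is.null(map)) map <- genotypes@map
    genotypes <- genotypes@genotypes
  }
  if (is.null(map))
    stopUsage("a variant table describing the genotype alleles is required")
  wt <- if (is(weights, "PosteriorEffects")) weightsTable(weights) else weights

  idx <- match(wt$snp_id, map$snp_id)
  present <- !is.na(idx)
  wt <- wt[present, , drop = FALSE]
  gm <- map[idx[present], , drop = FALSE]
  same <- wt$a1 == gm$a1 & wt$a2 == gm$a2
  swap <- wt$a1 == gm$a2 & wt$a2 == gm$a1
  nDropped <- sum(!present) + sum(!(same | swap))
  if (nDropped)
    message(nDropped, " weight SNP(s) dropped (absent or allele mismatch)")
  wt <- wt[same | swap, , drop = FALSE]
  flip <- (wt$a1 == gm$a2[same | swap])
  w <- ifelse(flip, -wt$beta, wt$beta)
  offset <- 2 * sum(wt$beta[flip])

  G <- genotypes[, wt$snp_id, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    nai <- which(is.na(G), arr.ind = TRUE)
    G[nai] <- mu[nai[, 2]]
  }
  prs <- drop(G %*% w) + offset
  ScoreSet(prs, phenotype = if (is.null(phenotype)) numeric(0) else phenotype,
           covariates = covariates,
           sampleIds = if (!is.null(rownames(genotypes))) rownames(genotypes)
                       else as.character(seq_len(nrow(genotypes))))
}

logLik2 <- function(fit) as.numeric(stats::logLik(fit))

#' Nagelkerke pseudo R-squared of a polygenic score
#'
#' `R2_nag = R2 / R2_max` with `R2 = 1 - (L_res/L_full)^(2/N)` and
#' `R2_max = 1 - L_res^(2/N)`, where the restricted logistic model holds the
#' covariates only and the full model adds the PRS.
#'
#' @param prs polygenic scores; @param phenotype 0/1 vector;
#' @param covariates optional covariate matrix.
#' @return Nagelkerke R-squared.
#' @export
nagelkerkeR2 <- function(prs, phenotype, covariates = NULL) {
  if (!all(phenotype %in% c(0, 1)))
    stopUsage("nagelkerkeR2 requires a 0/1 phenotype")
  n <- length(phenotype)
  X <- if (is.null(covariates) || NCOL(covariates) == 0) NULL
       else as.matrix(covariates)
  fitRes <- if (is.null(X)) stats::glm(phenotype ~ 1, family = stats::binomial())
            else stats::glm(phenotype ~ X, family = stats::binomial())
  fitFull <- if (is.null(X))
    stats::glm(phenotype ~ prs, family = stats::binomial())
  else stats::glm(phenotype ~ X + prs, family = stats::binomial())
  if (!fitFull$converged ||
      any(abs(stats::coef(fitFull))[-1] > 50, na.rm = TRUE))
    warning("possible separation in the full logistic model")
  r2 <- 1 - exp(2 / n * (logLik2(fitRes) - logLik2(fitFull)))
  r2max <- 1 - exp(2 / n * logLik2(fitRes))
  r2 / r2max
}

prAuc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  recall <- tp / sum(lab)
  sum(diff(c(0, recall)) * precision)
}

residualize <- function(x, covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0) return(x)
  stats::lm.fit(cbind(1, as.matrix(covariates)), x)$residuals
}

#' Odds ratio comparing the top PRS decile with the remainder
#'
#' @param prs scores (covariate-residualized upstream when applicable);
#' @param phenotype 0/1 vector.
#' @return odds ratio, or `NA` (with a warning) when the top decile holds
#'   fewer than 10 cases.
#' @export
orTopDecile <- function(prs, phenotype) {
  top <- prs >= stats::quantile(prs, 0.9)
  a <- sum(phenotype == 1 & top); b <- sum(phenotype == 0 & top)
  c_ <- sum(phenotype == 1 & !top); d <- sum(phenotype == 0 & !top)
  if (a < 10) {
    warning("fewer than 10 cases in the top decile; OR undefined")
    return(NA_real_)
  }
  (a * d) / (b * c_)
}

#' Calibration slope of a polygenic predictor
#'
#' Ordinary least-squares slope of the observed phenotype on the PRS; a
#' slope close to one indicates a well calibrated predictor.
#'
#' @param y observed phenotype; @param prs predictor.
#' @return the regression slope.
#' @export
calibrationSlope <- function(y, prs) {
  if (stats::var(prs) == 0)
    stopNumeric("calibration slope undefined for a constant PRS")
  stats::cov(y, prs) / stats::var(prs)
}

#' Predictive performance metrics of a score set
#'
#' Quantitative phenotypes: incremental R-squared (full linear model minus
#' covariates-only) and calibration slope. Case-control phenotypes:
#' Nagelkerke R-squared, AUC of the full-model linear predictor, area under
#' the precision-recall curve and the top-decile odds ratio (both on the
#' covariate-residualized PRS). All metrics account for the supplied
#' covariates.
#'
#' @param scores a [ScoreSet-class] with phenotype attached.
#' @return An [EvalReport-class].
#' @export
prsMetrics <- function(scores) {
  y <- scores@phenotype
  if (!length(y)) stopUsage("score set has no phenotype")
  prs <- scores@prs
  X <- if (ncol(scores@covariates)) scores@covariates else NULL
  binary <- all(y %in% c(0, 1))
  if (binary) {
    fitFull <- if (is.null(X))
      stats::glm(y ~ prs, family = stats::binomial())
    else stats::glm(y ~ X + prs, family = stats::binomial())
    lp <- drop(stats::predict(fitFull, type = "link"))
    auc <- as.numeric(pROC::auc(pROC::roc(y, lp, quiet = TRUE,
                                          direction = "<")))
    prsAdj <- residualize(prs, X)
    metrics <- c(nagelkerke_r2 = nagelkerkeR2(prs, y, X), auc = auc,
                 pr_auc = prAuc(y, prsAdj),
                 or_top_decile = orTopDecile(prsAdj, y))
  } else {
    r2 <- if (is.null(X)) {
      summary(stats::lm(y ~ prs))$r.squared
    } else {
      summary(stats::lm(y ~ X + prs))$r.squared -
        summary(stats::lm(y ~ X))$r.squared
    }
    metrics <- c(r2 = r2,
                 calibration_slope = calibrationSlope(residualize(y, X),
                                                      residualize(prs, X)))
  }
  EvalReport(metrics)
}

primaryMetric <- function(y) if (all(y %in% c(0, 1))) "nagelkerke_r2" else "r2"

evalOne <- function(prs, y, covariates) {
  prsMetrics(ScoreSet(prs, phenotype = y, covariates = covariates))
}

#' Select a tuning parameter in validation, report on testing
#'
#' Computes the primary metric (R-squared, or Nagelkerke R-squared for
#' case-control phenotypes) for each column of `prsVal` on the validation
#' phenotype, selects the best column — ties broken toward the first, so
#' order the grid with stronger shrinkage (smaller phi, smaller P_T) first —
#' and reports the full metric set of the selected column on the testing
#' samples only.
#'
#' @param prsVal,prsTest score matrices (individuals x grid points, shared
#'   column names).
#' @param yVal,yTest phenotypes of the two cohorts.
#' @param covVal,covTest optional covariate matrices.
#' @param idsVal,idsTest optional sample ids; overlap is an error.
#' @return list with `selected` (column name), `validation` (named metric
#'   vector) and `report` (an [EvalReport-class] on testing).
#' @export
tunePrs <- function(prsVal, yVal, prsTest, yTest, covVal = NULL,
                    covTest = NULL, idsVal = NULL, idsTest = NULL) {
  prsVal <- as.matrix(prsVal); prsTest <- as.matrix(prsTest)
  if (!is.null(idsVal) && length(intersect(idsVal, idsTest)))
    stopUsage("validation and testing samples overlap")
  metric <- primaryMetric(yVal)
  valScores <- apply(prsVal, 2, function(p) {
    if (stats::var(p) == 0) return(-Inf)
    metricsTable(evalOne(p, yVal, covVal))[[metric]]
  })
  best <- which.max(valScores)
  list(selected = colnames(prsVal)[best], validation = valScores,
       report = evalOne(prsTest[, best], yTest, covTest))
}

#' Relative improvement of one method over another
#'
#' `(R2_A - R2_B) / R2_B`.
#'
#' @param r2a,r2b the two methods' R-squared values (`r2b > 0`).
#' @return the relative increase (negative for a decrease).
#' @export
relativeImprovement <- function(r2a, r2b) {
  if (any(r2b == 0)) stopUsage("relative improvement undefined for r2b = 0")
  (r2a - r2b) / r2b
}

#' Repeated random-split evaluation
#'
#' Repeatedly splits the sample into a validation fraction and a testing
#' remainder, tunes on validation (when several score columns are given)
#' and evaluates on testing; reports per-split metrics and their mean/SD.
#'
#' @param prs score vector or matrix (individuals x grid points).
#' @param y phenotype; @param covariates optional covariate matrix.
#' @param nSplits number of random splits (default 100).
#' @param valFrac validation fraction (default 1/3).
#' @param seed integer seed.
#' @return An [EvalReport-class]; `metrics` holds the across-split mean and
#'   SD of the primary metric, `perSplit` the individual splits.
#' @export
repeatedSplitEval <- function(prs, y, covariates = NULL, nSplits = 100,
                              valFrac = 1 / 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prs <- as.matrix(prs)
  n <- length(y)
  metric <- primaryMetric(y)
  rows <- lapply(seq_len(nSplits), function(s) {
    val <- sort(sample.int(n, round(valFrac * n)))
    test <- setdiff(seq_len(n), val)
    covV <- if (is.null(covariates)) NULL else covariates[val, , drop = FALSE]
    covT <- if (is.null(covariates)) NULL else covariates[test, , drop = FALSE]
    if (ncol(prs) > 1) {
      tuned <- tunePrs(prs[val, , drop = FALSE], y[val],
                       prs[test, , drop = FALSE], y[test], covV, covT)
      data.frame(split = s, selected = tuned$selected,
                 value = metricsTable(tuned$report)[[metric]])
    } else {
      data.frame(split = s, selected = colnames(prs)[1L] %||% "score",
                 value = metricsTable(evalOne(prs[test, 1], y[test],
                                              covT))[[metric]])
    }
  })
  perSplit <- do.call(rbind, rows)
  EvalReport(c(mean = mean(perSplit$value), sd = stats::sd(perSplit$value)),
             perSplit = perSplit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
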