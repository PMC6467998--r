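test_that("scoring is the additive allele-count dot product", {
  map <- data.frame(snp_id = c("s1", "s2"), a1 = c("A", "C"), a2 = "G",
                    stringsAsFactors = FALSE)
  G <- cbind(s1 = c(0, 1, 2), s2 = c(2, 2, 0))
  wt <- data.frame(snp_id = "s1", a1 = "A", a2 = "G", beta = 0.5)
  sc <- scoreIndividuals(G, wt, map = map)
  expect_equal(sc@prs, c(0, 0.5, 1.0))

  wt0 <- data.frame(snp_id = c("s1", "s2"), a1 = c("A", "C"), a2 = "G",
                    beta = 0)
  expect_equal(scoreIndividuals(G, wt0, map = map)@prs, c(0, 0, 0))

  # flipping alleles and negating the weight shifts scores by the constant
  # 2 * beta_flipped (counting the other allele): ranking is unchanged
  wtFlip <- data.frame(snp_id = "s1", a1 = "G", a2 = "A", beta = -0.5)
  scFlip <- scoreIndividuals(G, wtFlip, map = map)
  expect_equal(scFlip@prs - sc@prs, rep(-1.0, 3))

  # allele mismatches are dropped; missing genotypes mean-imputed
  wtBad <- data.frame(snp_id = c("s1", "s2"), a1 = c("A", "T"), a2 = "G",
                      beta = c(0.5, 9))
  expect_message(scBad <- scoreIndividuals(G, wtBad, map = map), "dropped")
  expect_equal(scBad@prs, sc@prs)
  Gna <- G; Gna[1, 1] <- NA
  scNa <- scoreIndividuals(Gna, wt, map = map)
  expect_equal(scNa@prs[1], 0.5 * 1.5)  # mean of remaining (1, 2)
})

test_that("Nagelkerke R2 follows the likelihood-ratio definition", {
  set.seed(101)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  prs <- y + rnorm(n, 0, 1.2)
  r2 <- nagelkerkeR2(prs, y)
  # hand-computed from the two model likelihoods
  llFull <- as.numeric(logLik(glm(y ~ prs, family = binomial())))
  llRes <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
  expect_equal(r2, (1 - exp(2 / n * (llRes - llFull))) /
                     (1 - exp(2 / n * llRes)), tolerance = 1e-10)

  # a PRS with a zero coefficient contributes exactly nothing
  expect_equal(nagelkerkeR2(rep(0.3, n), y), 0, tolerance = 1e-10)
  # independence gives a near-zero value
  set.seed(102)
  expect_lt(nagelkerkeR2(rnorm(n * 20), rep(c(0, 1), n * 10)), 0.05)
  expect_error(nagelkerkeR2(prs, y + 0.5), "0/1")
})

test_that("binary metrics: AUC endpoints, odds ratio arithmetic, monotone invariance", {
  set.seed(103)
  y <- rep(c(0, 1), each = 500)
  perfect <- y + seq(0, 0.5, length.out = 1000)  # separates classes
  rep1 <- suppressWarnings(prsMetrics(ScoreSet(perfect, phenotype = y)))
  expect_equal(unname(metricsTable(rep1)[["auc"]]), 1)

  random <- rnorm(1000)
  rep2 <- prsMetrics(ScoreSet(random, phenotype = y))
  expect_lt(abs(metricsTable(rep2)[["auc"]] - 0.5), 0.06)

  # contingency oracle: top decile 30 cases / 70 controls, rest 100/800
  prs <- c(rnorm(100, 10), rnorm(900, 0))
  yy <- c(rep(1, 30), rep(0, 70), rep(1, 100), rep(0, 800))
  expect_equal(orTopDecile(prs, yy), (30 * 800) / (70 * 100),
               tolerance = 1e-12)

  # AUC and OR are invariant under monotone transformation of the PRS
  z <- rnorm(1000, y, 1.5)
  m1 <- metricsTable(suppressWarnings(prsMetrics(ScoreSet(z, phenotype = y))))
  m2 <- metricsTable(suppressWarnings(prsMetrics(ScoreSet(exp(2 * z),
                                                          phenotype = y))))
  expect_equal(m1[["auc"]], m2[["auc"]], tolerance = 1e-5)
  expect_equal(m1[["or_top_decile"]], m2[["or_top_decile"]],
               tolerance = 1e-10)

  # fewer than 10 cases in the top decile: OR reported missing
  yRare <- c(rep(1, 5), rep(0, 995))
  expect_warning(v <- orTopDecile(rnorm(1000), yRare), "decile")
  expect_true(is.na(v))
})

test_that("calibration slope is the OLS slope of phenotype on score", {
  y <- rnorm(200)
  expect_equal(calibrationSlope(y, y), 1, tolerance = 1e-12)
  expect_equal(calibrationSlope(y, y / 2), 2, tolerance = 1e-12)
  expect_error(calibrationSlope(y, rep(1, 200)), "constant")
})

test_that("quantitative metrics use incremental R2 over covariates", {
  set.seed(104)
  n <- 500
  cov <- cbind(age = rnorm(n))
  prs <- rnorm(n)
  y <- 0.8 * cov[, 1] + 0.5 * prs + rnorm(n, 0, 0.5)
  rep_ <- prsMetrics(ScoreSet(prs, phenotype = y, covariates = cov))
  full <- summary(lm(y ~ cov + prs))$r.squared
  restr <- summary(lm(y ~ cov))$r.squared
  expect_equal(unname(metricsTable(rep_)[["r2"]]), full - restr,
               tolerance = 1e-10)
})

test_that("tuning selects on validation only and reports on testing", {
  set.seed(105)
  nv <- 300; nt <- 400
  yV <- rnorm(nv); yT <- rnorm(nt)
  # column 2 is genuinely informative, others are noise
  prsV <- cbind(a = rnorm(nv), b = yV + rnorm(nv, 0, 0.5), c = rnorm(nv))
  prsT <- cbind(a = rnorm(nt), b = yT + rnorm(nt, 0, 0.5), c = rnorm(nt))
  tuned <- tunePrs(prsV, yV, prsT, yT)
  expect_equal(tuned$selected, "b")
  # no peeking: the testing metric never beats the testing-oracle best
  oracleBest <- max(apply(prsT, 2, function(p) cor(p, yT)^2))
  expect_lte(metricsTable(tuned$report)[["r2"]], oracleBest + 1e-12)

  # a grid of one returns that parameter
  t1 <- tunePrs(prsV[, 2, drop = FALSE], yV, prsT[, 2, drop = FALSE], yT)
  expect_equal(t1$selected, "b")
  expect_error(tunePrs(prsV, yV, prsT, yT, idsVal = 1:nv, idsTest = nv:(nv + nt)),
               "overlap")
})

test_that("relative improvement is the plain ratio definition", {
  expect_equal(relativeImprovement(0.10, 0.08), 0.25)
  expect_equal(relativeImprovement(0.08, 0.10), -0.2)
  expect_equal(relativeImprovement(0.3, 0.3), 0)
  expect_error(relativeImprovement(0.1, 0), "undefined")
})

test_that("repeated splits are reproducible and reduce to a single tune+test", {
  set.seed(106)
  n <- 300
  y <- rnorm(n)
  prs <- cbind(p1 = y + rnorm(n), p2 = rnorm(n))
  r1 <- repeatedSplitEval(prs, y, nSplits = 5, seed = 9)
  r2 <- repeatedSplitEval(prs, y, nSplits = 5, seed = 9)
  expect_identical(r1@perSplit, r2@perSplit)
  expect_equal(nrow(r1@perSplit), 5)
  single <- repeatedSplitEval(prs, y, nSplits = 1, seed = 10)
  expect_equal(unname(metricsTable(single)[["sd"]]), NA_real_)
})

test_that("the true-effect PRS attains R2 = 1 on a noiseless phenotype", {
  cohort <- simulateGenotypes(400, 60, 3, seed = 107)
  beta <- drawEffects(architectureSpec(nCausal = 10, h2 = 0.5), 60,
                      seed = 108)
  cohort <- simulatePhenotype(cohort, beta, 1, seed = 109)  # h2 = 1
  wt <- cohort@map[, c("snp_id", "a1", "a2")]
  G <- cohort@genotypes
  sdg <- sqrt(colMeans(G^2) - colMeans(G)^2)
  wt$beta <- cohort@betaTrue / sdg  # exact per-allele truth on this cohort
  sc <- scoreIndividuals(cohort, wt, phenotype = cohort@y)
  r2 <- suppressWarnings(metricsTable(prsMetrics(sc))[["r2"]])
  expect_equal(unname(r2), 1, tolerance = 1e-3)
})
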