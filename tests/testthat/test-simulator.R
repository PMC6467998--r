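test_that("genotype frequencies follow Hardy-Weinberg at the target MAF", {
  n <- 4000
  cohort <- simulateGenotypes(n, 10, 1, ldDecay = 0, seed = 71,
                              maf = rep(0.3, 10))
  counts <- apply(cohort@genotypes, 2, function(g) tabulate(g + 1, 3)) / n
  hwe <- c((1 - 0.3)^2, 2 * 0.3 * 0.7, 0.3^2)
  for (k in 1:3) {
    se <- sqrt(hwe[k] * (1 - hwe[k]) / n)
    expect_true(all(abs(counts[k, ] - hwe[k]) < 3.5 * se))
  }
})

test_that("LD structure: decay inside blocks, independence across and at decay zero", {
  cohort0 <- simulateGenotypes(2000, 20, 2, ldDecay = 0, seed = 72)
  r0 <- cor(cohort0@genotypes)
  expect_lt(mean(abs(r0[upper.tri(r0)])), 3 / sqrt(2000))

  cohort <- simulateGenotypes(3000, 40, 2, ldDecay = 0.7, seed = 73)
  r <- cor(cohort@genotypes)
  within <- r[1, 2]
  expect_gt(within, 0.3)  # adjacent SNPs strongly correlated
  cross <- r[cohort@map$block == 1, cohort@map$block == 2]
  expect_lt(max(abs(cross)), 4 / sqrt(3000))  # blocks independent

  # deterministic given the seed
  again <- simulateGenotypes(3000, 40, 2, ldDecay = 0.7, seed = 73)
  expect_identical(cohort@genotypes, again@genotypes)
})

test_that("effect draws respect causal counts and family shapes", {
  b <- drawEffects(architectureSpec(nCausal = 100, h2 = 0.5), 10000,
                   seed = 74)
  expect_equal(sum(b != 0), 100)  # exactly the requested causal count

  bt <- drawEffects(architectureSpec(family = "point_t", nCausal = 500,
                                     h2 = 0.5), 2000, seed = 75)
  expect_equal(sum(bt != 0), 500)
  # heavy tails: excess kurtosis of t(4) draws well above normal
  z <- bt[bt != 0]
  expect_gt(mean(z^4) / mean(z^2)^2, 4)

  bg <- drawEffects(architectureSpec(family = "point_gamma", nCausal = 500,
                                     h2 = 0.5), 2000, seed = 76)
  nz <- bg[bg != 0]
  expect_true(all(nz > 0))  # gamma draws keep their sign
  expect_gt(mean((nz - mean(nz))^3) / sd(nz)^3, 0.5)  # positively skewed

  expect_error(drawEffects(architectureSpec(nCausal = 11, h2 = 0.5), 10),
               "exceeds")
})

test_that("normal-mixture groups realize their heritability shares", {
  spec <- architectureSpec(family = "normal_mixture",
                           mixtureCounts = c(10, 100, 1000),
                           mixtureShares = c(0.10, 0.20, 0.70))
  set.seed(77)
  shares <- replicate(50, {
    b <- drawEffects(spec, 3000)
    grp <- attr(b, "group")
    tapply(b^2, grp, sum)[c("1", "2", "3")] / sum(b^2)
  })
  m3 <- rowMeans(shares)
  expect_equal(unname(m3[3]), 0.70, tolerance = 0.03)
  expect_equal(unname(m3[2]), 0.20, tolerance = 0.10)
  expect_equal(unname(m3[1]), 0.10, tolerance = 0.25)
})

test_that("phenotypes realize the target heritability", {
  cohort <- simulateGenotypes(4000, 500, 10, seed = 78)
  beta <- drawEffects(architectureSpec(nCausal = 50, h2 = 0.5), 500,
                      seed = 79)
  for (h2 in c(0.2, 0.5, 0.8)) {
    ch <- simulatePhenotype(cohort, beta, h2, seed = 80)
    Z <- scale(ch@genotypes)
    g <- drop(Z %*% ch@betaTrue)
    realized <- var(g) / var(ch@y)
    expect_equal(realized, h2, tolerance = 0.05)
    expect_equal(var(ch@y), 1, tolerance = 0.1)
  }
  # h2 = 1 limit: no noise at all
  ch1 <- simulatePhenotype(cohort, beta, 1, seed = 81)
  Z <- scale(ch1@genotypes) * sqrt(4000 / 3999)
  expect_equal(drop(Z %*% ch1@betaTrue), ch1@y, tolerance = 1e-10)
  # determinism
  expect_identical(simulatePhenotype(cohort, beta, 0.5, seed = 82)@y,
                   simulatePhenotype(cohort, beta, 0.5, seed = 82)@y)
})

test_that("GWAS summary statistics behave under null and strong signal", {
  cohort <- simulateGenotypes(2000, 400, 8, seed = 83)
  # null phenotype independent of genotypes
  cohort@y <- rnorm(2000)
  gw <- gwasSumstats(cohort)
  frac <- mean(sumstatsTable(gw$sst)$pval < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  # definitional identity betahat = Z'y/N
  Z <- scale(cohort@genotypes) * sqrt(2000 / 1999)
  ys <- (cohort@y - mean(cohort@y)) / sqrt(mean((cohort@y - mean(cohort@y))^2))
  expect_equal(gw$hstats@betahatStd, unname(drop(crossprod(Z, ys))) / 2000,
               tolerance = 1e-12)

  # a large causal effect at strong sample size reaches genome-wide signif.
  big <- simulateGenotypes(50000, 20, 1, seed = 84)
  beta <- c(1, rep(0, 19))
  big <- simulatePhenotype(big, beta, 0.3, seed = 85)
  gw2 <- gwasSumstats(big)
  expect_lt(sumstatsTable(gw2$sst)$pval[1], 5e-8)
})

test_that("direct summary simulation matches individual-level moments", {
  set.seed(86)
  m <- 40
  ref <- simulateGenotypes(600, m, 2, seed = 86)
  blocks <- lapply(split(seq_len(m), ref@map$block), function(i)
    computeBlockLD(ref@genotypes[, i, drop = FALSE],
                   snpIds = ref@map$snp_id[i]))
  beta0 <- drawEffects(architectureSpec(nCausal = 8, h2 = 0.4), m, seed = 87)

  # RSS draws: mean should approach D beta as n grows
  ssBig <- rssSumstats(beta0, blocks, ref@map, n = 1e9, h2 = 0.4, seed = 88)
  Dbeta <- unlist(lapply(seq_along(blocks), function(k) {
    i <- split(seq_len(m), ref@map$block)[[k]]
    drop(ldMatrix(blocks[[k]]) %*% ssBig$betaTrue[i])
  }))
  expect_equal(ssBig$hstats@betahatStd, unname(Dbeta), tolerance = 1e-3)

  # zero effects give zero-mean marginals
  ss0 <- rssSumstats(rep(0, m), blocks, ref@map, n = 1000, seed = 89)
  expect_lt(max(abs(colMeans(replicate(50, {
    rssSumstats(rep(0, m), blocks, ref@map, n = 1000)$hstats@betahatStd
  })))), 5 / sqrt(1000 * 50))

  # sampling moments: with the GWAS cohort's genotypes held fixed across
  # noise replicates, betahat = D beta + Z'e/n and the RSS law
  # N(D beta, sigma2 D / n) is exact for the cohort's own D
  nRep <- 300; nInd <- 400
  ch <- simulateGenotypes(nInd, m, 2, maf = ref@map$maf_target, seed = 93)
  Z <- scale(ch@genotypes) * sqrt(nInd / (nInd - 1))
  Dcoh <- crossprod(Z) / nInd
  bs <- ssBig$betaTrue
  g <- drop(Z %*% bs) * sqrt(0.4) / sqrt(mean((Z %*% bs)^2) -
                                           mean(Z %*% bs)^2)
  bTrueCoh <- bs * sqrt(0.4) / sqrt(mean((Z %*% bs)^2) - mean(Z %*% bs)^2)
  emp <- replicate(nRep, {
    ch@y <- g + rnorm(nInd, 0, sqrt(0.6))
    gwasSumstats(ch)$hstats@betahatStd
  })
  empMean <- rowMeans(emp)
  rssMean <- drop(Dcoh %*% bTrueCoh)
  empSe <- apply(emp, 1, sd) / sqrt(nRep)
  expect_gt(mean(abs(empMean - rssMean) < 3.5 * empSe), 0.9)
  # covariance scale: per-SNP sampling variance approximates sigma2 D_jj/n
  expect_equal(mean(apply(emp, 1, var)), 0.6 / nInd, tolerance = 0.1)
})

test_that("cohorts round-trip through PLINK files with partition attached", {
  cohort <- simulateGenotypes(30, 20, 2, seed = 90)
  beta <- drawEffects(architectureSpec(nCausal = 5, h2 = 0.5), 20, seed = 91)
  cohort <- simulatePhenotype(cohort, beta, 0.5, seed = 92)
  prefix <- withr::local_tempfile()
  writeCohort(cohort, prefix)
  back <- readPlink(prefix)
  expect_equal(unname(back$genotypes),
               matrix(as.numeric(cohort@genotypes), 30, 20))
  truth <- utils::read.table(paste0(prefix, ".truth"))
  expect_equal(truth$V2, cohort@betaTrue, tolerance = 1e-6)
  part <- cohortPartition(cohort)
  idx <- mapSnpsToBlocks(cohort@map, part)
  expect_equal(unname(lengths(idx)), c(10, 10))
})
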