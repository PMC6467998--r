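# Independent oracles used to verify the package implementation. These are
# deliberately written from first principles (direct density formulas,
# brute-force rule application, individual-level likelihoods) and never
# call the code paths they check.

# ---- Kolmogorov-Smirnov distance of a sample to a CDF -----------------------

ksDistance <- function(x, cdfFun) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdfFun(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# ---- three-parameter beta law, written independently ------------------------

tpbDensityOracle <- function(x, a, b, phi) {
  gamma(a + b) / (gamma(a) * gamma(b)) * phi^b * x^(b - 1) *
    (1 - x)^(a - 1) * (1 + (phi - 1) * x)^(-(a + b))
}

tpbCdfOracle <- function(a, b, phi) {
  # tabulated CDF by quadrature on a fine grid, returned as a function
  grid <- seq(1e-9, 1 - 1e-9, length.out = 4001)
  cum <- numeric(length(grid))
  cum[1] <- stats::integrate(tpbDensityOracle, 0, grid[1], a = a, b = b,
                             phi = phi, rel.tol = 1e-10)$value
  for (i in 2:length(grid))
    cum[i] <- cum[i - 1] +
      stats::integrate(tpbDensityOracle, grid[i - 1], grid[i], a = a, b = b,
                       phi = phi, rel.tol = 1e-9,
                       subdivisions = 50L)$value
  function(q) stats::approx(grid, cum, xout = q, rule = 2)$y
}

# total mass of a density on (0, 1) with possible endpoint singularities,
# via the substitution x = sin^2(theta) which regularizes both endpoints
unitIntervalMass <- function(dens, rel.tol = 1e-10) {
  stats::integrate(function(th) {
    s <- sin(th)
    dens(s^2) * 2 * s * cos(th)
  }, 0, pi / 2, rel.tol = rel.tol, subdivisions = 2000L)$value
}

# ---- GIG moments from the Bessel-function formula ---------------------------

gigMomentOracle <- function(k, p, chi, psi) {
  omega <- sqrt(chi * psi)
  (chi / psi)^(k / 2) * besselK(omega, p + k) / besselK(omega, p)
}

# ---- psi full-conditional density, evaluated directly -----------------------

# unnormalized: psi^(a - 3/2) exp(-N beta^2 / (2 sigma2 phi psi) - delta psi)
psiConditionalBins <- function(a, beta, delta, sigma2, phi, n, nBins = 20) {
  c1 <- n * beta^2 / (2 * sigma2 * phi)
  logDens <- function(x) (a - 1.5) * log(x) - c1 / x - delta * x
  mode <- ((a - 1.5) + sqrt((a - 1.5)^2 + 4 * c1 * delta)) / (2 * delta)
  shift <- logDens(mode)
  dens <- function(x) exp(logDens(x) - shift)
  Zc <- stats::integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  grid <- exp(seq(log(mode) - 12, log(mode) + 12, length.out = 6000))
  cdf <- cumsum(c(0, diff(grid)) * dens(grid)) / Zc
  # equal-probability bin edges by inverting the numeric CDF
  edges <- stats::approx(cdf, grid, xout = seq_len(nBins - 1) / nBins,
                         ties = "ordered")$y
  c(0, edges, Inf)
}

# ---- individual-level Gibbs sampler on raw genotypes ------------------------

# Same model, but conditioning on y and Z directly: beta block update uses
# Z'Z and Z'y, sigma2 uses the actual residual sum of squares. Serves as the
# ground-truth sampler for the summary-statistics implementation.
indivGibbsOracle <- function(Z, y, a = 1, b = 0.5, phi = 1, nIter = 4000,
                             nBurnin = 1000, rho = 1) {
  n <- nrow(Z); m <- ncol(Z)
  Z <- sweep(sweep(Z, 2, colMeans(Z), "-"), 2,
             sqrt(colMeans(Z^2) - colMeans(Z)^2), "/")
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  ZtZ <- crossprod(Z)
  Zty <- drop(crossprod(Z, y))
  psi <- rep(1, m); delta <- rep(1, m); sigma2 <- 1
  betaSum <- numeric(m); nSave <- 0L
  for (it in seq_len(nIter)) {
    Tj <- pmin(phi * psi, 1 / rho)
    A <- ZtZ + n * diag(1 / Tj, m)
    R <- chol(A)
    mu <- backsolve(R, backsolve(R, Zty, transpose = TRUE))
    beta <- mu + sqrt(sigma2) * backsolve(R, stats::rnorm(m))
    chi <- n * beta^2 / (sigma2 * phi)
    psi <- csprs::sampleGIG(m, a - 0.5, chi, 2 * delta)
    delta <- stats::rgamma(m, shape = a + b, rate = psi + 1)
    resid <- y - drop(Z %*% beta)
    rate <- (sum(resid^2) + n * sum(beta^2 / (phi * psi))) / 2
    sigma2 <- rate / stats::rgamma(1, shape = (n + m) / 2)
    if (it > nBurnin) { betaSum <- betaSum + beta; nSave <- nSave + 1L }
  }
  betaSum / nSave
}

# ---- exhaustive clumping oracle ---------------------------------------------

# Literal, O(M^2) application of the rule: walk SNPs by ascending p (ties:
# position, then id); for a surviving index SNP remove every other surviving
# SNP within the window with r2 above threshold and lower significance.
clumpOracle <- function(tab, r2mat, r2Threshold = 0.1, windowBp = 250000) {
  m <- nrow(tab)
  ord <- order(tab$pval, tab$pos, tab$snp_id)
  alive <- rep(TRUE, m)
  rankOf <- integer(m); rankOf[ord] <- seq_len(m)
  for (i in ord) {
    if (!alive[i]) next
    for (j in seq_len(m)) {
      if (j == i || !alive[j]) next
      if (tab$chrom[j] != tab$chrom[i]) next
      if (abs(tab$pos[j] - tab$pos[i]) >= windowBp) next
      if (r2mat[i, j] <= r2Threshold) next
      if (rankOf[j] > rankOf[i]) alive[j] <- FALSE
    }
  }
  tab$snp_id[alive]
}

# ---- toy summary statistics -------------------------------------------------

toySumstats <- function(m = 20, n = 10000, seed = 1) {
  set.seed(seed)
  data.frame(snp_id = sprintf("rs%03d", seq_len(m)), chrom = "1",
             pos = sort(sample.int(5e5, m)),
             a1 = sample(c("A", "T"), m, TRUE), a2 = "G",
             beta_marginal = stats::rnorm(m, 0, 0.05),
             pval = stats::runif(m), n_gwas = n, maf = stats::runif(m, 0.05, 0.5),
             stringsAsFactors = FALSE)
}

writeSumstatsFile <- function(tb, path, orScale = FALSE) {
  out <- data.frame(SNP = tb$snp_id, A1 = tb$a1, A2 = tb$a2,
                    BETA = tb$beta_marginal, P = tb$pval, N = tb$n_gwas)
  if (orScale) {
    out$BETA <- NULL
    out$OR <- exp(tb$beta_marginal)
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  path
}
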