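# Closed-form machinery of the continuous shrinkage prior.
#
# The prior on each standardized effect is the global-local scale mixture
#   beta_j | psi_j ~ N(0, (sigma2/N) phi psi_j),
#   psi_j ~ Gamma(a, rate delta_j),  delta_j ~ Gamma(b, rate 1),
# which is equivalent to a three-parameter beta (TPB) prior on the
# shrinkage factor tau_j = 1/(1 + phi psi_j). With a = 1, b = 1/2 this is
# the Strawderman-Berger prior; a = b = 1/2 is the horseshoe.

#' Three-parameter beta density on the shrinkage factor
#'
#' `f(x; a, b, phi) = Gamma(a+b)/(Gamma(a)Gamma(b)) phi^b x^(b-1)
#' (1-x)^(a-1) (1 + (phi-1) x)^(-(a+b))` for `0 < x < 1`. At `phi = 1` this
#' is the Beta(b, a) density.
#'
#' @param x evaluation points, strictly inside (0, 1).
#' @param a,b,phi positive TPB parameters.
#' @return density values.
#' @export
tpbDensity <- function(x, a, b, phi) {
  if (a <= 0 || b <= 0 || phi <= 0)
    stopUsage("tpbDensity: a, b and phi must be positive")
  if (any(x <= 0 | x >= 1))
    stopUsage("tpbDensity: x must lie strictly inside (0, 1)")
  exp(lgamma(a + b) - lgamma(a) - lgamma(b) + b * log(phi) +
        (b - 1) * log(x) + (a - 1) * log1p(-x) -
        (a + b) * log1p((phi - 1) * x))
}

#' Shrinkage factor of a marker
#'
#' `tau = 1 / (1 + phi psi)`: 1 is total shrinkage of the marginal estimate
#' to zero, 0 is no shrinkage.
#'
#' @param phi global scale; @param psi local scale (both non-negative).
#' @return tau in [0, 1].
#' @export
shrinkageFactor <- function(phi, psi) {
  if (any(phi < 0) || any(psi < 0))
    stopUsage("shrinkageFactor: phi and psi must be non-negative")
  1 / (1 + phi * psi)
}

cholJitterLadder <- c(0, 1e-10, 1e-8, 1e-6)

cholWithJitter <- function(A, context = "linear solve") {
  for (jit in cholJitterLadder) {
    Aj <- A
    if (jit > 0) diag(Aj) <- diag(Aj) + jit
    R <- tryCatch(chol(Aj), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stopNumeric(context, ": Cholesky factorization failed after jitter ",
              "ladder; condition estimate ", format(kappa(A)))
}

#' Posterior mean effects for fixed shrinkage scales
#'
#' Solves `(D + T^{-1}) x = betahat` with `T = diag(tDiag)` by a symmetric
#' positive-definite factorization (no explicit inverse); the posterior mean
#' is a matrix shrinkage version of the marginal least-squares estimate.
#' With `D = I` this reduces componentwise to `(1 - tau_j) betahat_j`.
#'
#' @param betahatStd standardized marginal effects of the block.
#' @param D LD matrix of the block.
#' @param tDiag per-SNP prior scales `phi * psi_j` (strictly positive).
#' @return posterior mean vector.
#' @export
posteriorMeanFixedScales <- function(betahatStd, D, tDiag) {
  if (any(tDiag <= 0))
    stopUsage("posteriorMeanFixedScales: tDiag must be strictly positive")
  A <- D
  diag(A) <- diag(A) + 1 / tDiag
  R <- cholWithJitter(A, "posterior mean solve")
  backsolve(R, backsolve(R, betahatStd, transpose = TRUE))
}

# gamma-gamma mixing density of psi (beta-prime form)
psiMixingDensity <- function(psi, a, b) {
  exp((a - 1) * log(psi) - (a + b) * log1p(psi) - lbeta(a, b))
}

#' Marginal prior density on a standardized effect size
#'
#' Numerically integrates the normal kernel `N(beta; 0, s phi psi)` (with
#' `s = sigma2/N`) against the gamma-gamma mixing density of `psi`. Used for
#' diagnostics and density plots; the sampler never needs it.
#'
#' @param beta evaluation points.
#' @param a,b,phi prior parameters.
#' @param sigma2OverN scale factor `sigma2 / N` of the prior variance.
#' @param rel.tol quadrature tolerance.
#' @return marginal density values.
#' @export
marginalPriorDensity <- function(beta, a, b, phi, sigma2OverN = 1,
                                 rel.tol = 1e-10) {
  if (a <= 0 || b <= 0 || phi <= 0 || sigma2OverN <= 0)
    stopUsage("marginalPriorDensity: parameters must be positive")
  vapply(beta, function(bb) {
    # beta = 0 is a pole of the marginal when the TPB shape a <= 1/2
    # (e.g. the horseshoe): the mixing density behaves like psi^(a - 3/2)
    if (bb == 0 && a <= 0.5) return(Inf)
    # integrate on the log-psi scale (regular integrand, known peak near
    # the scale where the normal kernel matches |beta|)
    g <- function(t) {
      psi <- exp(t)
      exp(stats::dnorm(bb, 0, sqrt(sigma2OverN * phi * psi), log = TRUE) +
            a * t - (a + b) * log1p(psi) - lbeta(a, b))
    }
    tPeak <- log(max(bb^2 / (sigma2OverN * phi), 1e-6))
    q1 <- tryCatch(stats::integrate(g, -700, tPeak, rel.tol = rel.tol,
                                    subdivisions = 1000L),
                   error = function(e) NULL)
    q2 <- tryCatch(stats::integrate(g, tPeak, 700, rel.tol = rel.tol,
                                    subdivisions = 1000L),
                   error = function(e) NULL)
    if (is.null(q1) || is.null(q2))
      stopNumeric("marginalPriorDensity: quadrature failed at beta = ",
                  format(bb), " (rel.tol = ", rel.tol, ")")
    q1$value + q2$value
  }, numeric(1))
}
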