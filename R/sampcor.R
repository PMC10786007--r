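# Exact sampling distribution of the Pearson sample correlation coefficient
# under bivariate normality. Used both for the exact power function of the
# correlation t-test and as the reduced likelihood in Bayesian estimation of
# a correlation from a sample r.

# log of the Gauss hypergeometric function 2F1(a, b; c; z) by series
# summation; converges for |z| < 1 (here z = (1 + rho*r)/2 in [0, 1)).
log_hyp2f1 <- function(a, b, cc, z, tol = 1e-13, maxit = 100000L) {
  term <- 1; s <- 1; k <- 0
  while (k < maxit) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    k <- k + 1
    if (abs(term) < tol * abs(s)) break
  }
  log(s)
}

#' Density of the sample correlation coefficient
#'
#' Exact density of the Pearson correlation `r` of `n` bivariate-normal
#' pairs with population correlation `rho` (Hotelling's form, evaluated via
#' a Gauss hypergeometric series):
#' \deqn{f(r) = \frac{(n-2)\,\Gamma(n-1)\,(1-\rho^2)^{(n-1)/2}
#'   (1-r^2)^{(n-4)/2}}{\sqrt{2\pi}\,\Gamma(n-\tfrac12)\,
#'   (1-\rho r)^{n-3/2}}\; {}_2F_1\!\left(\tfrac12,\tfrac12;
#'   n-\tfrac12; \tfrac{1+\rho r}{2}\right)}
#'
#' @param r quantiles in `(-1, 1)`; vectorized (recycled against `rho`).
#' @param rho population correlation(s) in `(-1, 1)`.
#' @param n sample size, `n >= 4`.
#' @param log if `TRUE`, return the log density.
#' @return density values (0 outside the open support).
#' @export
dsampcor <- function(r, rho, n, log = FALSE) {
  if (n < 4) stop("dsampcor(): n must be >= 4")
  if (any(abs(rho) >= 1)) stop("dsampcor(): rho must be in (-1, 1)")
  m <- max(length(r), length(rho))
  r <- rep_len(r, m); rho <- rep_len(rho, m)
  out <- numeric(m)
  lc0 <- log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5)
  for (i in seq_len(m)) {
    if (abs(r[i]) >= 1) {
      out[i] <- -Inf
      next
    }
    out[i] <- lc0 + ((n - 1) / 2) * log1p(-rho[i]^2) +
      ((n - 4) / 2) * log1p(-r[i]^2) -
      (n - 1.5) * log1p(-rho[i] * r[i]) +
      log_hyp2f1(0.5, 0.5, n - 0.5, (1 + rho[i] * r[i]) / 2)
  }
  if (log) out else exp(out)
}

# upper-tail probability P(r > q | rho, n) by adaptive quadrature
psampcor_upper <- function(q, rho, n) {
  if (q >= 1) return(0)
  integrate(dsampcor, lower = q, upper = 1, rho = rho, n = n,
            rel.tol = 1e-10, abs.tol = 1e-12)$value
}
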