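# Independent oracles used to validate package computations. These are
# deliberately written with a different toolchain from the implementation:
# uniroot instead of Lambert W / bisection, hand-rolled IRLS instead of glm,
# trapezoid integration instead of Gauss-Hermite quadrature.

# Rogers root via Brent's method on the residual.
oracle_rogers <- function(a, th, tt, n0) {
  if (a == 0) return(0)
  f <- function(ne) n0 * (-expm1(a * th * ne - a * tt)) - ne
  stats::uniroot(f, c(0, n0), tol = 1e-13)$root
}

# Binomial NLL by direct summation of log mass terms (lchoose arithmetic),
# with the same probability clipping convention as the fit.
oracle_nll <- function(a, th, tt, n0, k) {
  p <- vapply(n0, function(n) oracle_rogers(a, th, tt, n) / n, numeric(1))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(lchoose(n0, k) + k * log(p) + (n0 - k) * log1p(-p))
}

# Logistic regression by hand-rolled IRLS on a grouped binomial response.
# Columns are rescaled to unit max so the cubic design stays well
# conditioned; the weighted solve uses QR.
oracle_irls <- function(x, k, n, maxit = 200L) {
  scl <- apply(abs(x), 2, max)
  xs <- sweep(x, 2, scl, "/")
  beta <- rep(0, ncol(xs))
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    z <- eta + (k - n * mu) / w
    beta <- qr.solve(sqrt(w) * xs, sqrt(w) * z)
    mu <- stats::plogis(drop(xs %*% beta))
    dev <- -2 * sum(stats::dbinom(k, n, mu, log = TRUE) -
                      stats::dbinom(k, n, k / n, log = TRUE))
    if (abs(dev_old - dev) < 1e-10) break
    dev_old <- dev
  }
  drop(beta) / scl
}

# Marginal log-likelihood of the observation-level-random-effect binomial
# model by trapezoid integration over the standard-normal latent scale.
oracle_olre_loglik <- function(beta, sigma, x, k, n, lim = 12, step = 1e-3) {
  u <- seq(-lim, lim, by = step)
  eta <- drop(x %*% beta)
  sum(vapply(seq_along(k), function(i) {
    integrand <- stats::dbinom(k[i], n[i], stats::plogis(eta[i] + sigma * u)) *
      stats::dnorm(u)
    log(sum((integrand[-1] + integrand[-length(u)]) / 2) * step)
  }, numeric(1)))
}

# Small deterministic table used by several tests.
toy_trials <- function(seed = 101, cells = fr_reference_params()[1, ],
                       replicates = 2) {
  fr_simulate(cells, replicates = replicates, seed = seed)
}
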