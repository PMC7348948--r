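# Gauss-Hermite nodes/weights for weight function exp(-x^2), by the
# Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1L)
  jac <- matrix(0, n, n)
  jac[cbind(i, i + 1L)] <- sqrt(i / 2)
  jac[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(jac, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1L, ord]^2)
}

# Marginal log-likelihood of the observation-level-random-effect binomial
# model. One latent intercept per observation means the marginal likelihood
# factorizes into independent one-dimensional integrals
#   L_i = \int Binom(k_i; n_i, plogis(eta_i + sigma*u)) phi(u) du,
# each computed by adaptive Gauss-Hermite quadrature centred at the
# conditional mode of u (found by Newton; the integrand is log-concave).
.agq_loglik <- function(beta, sigma, x, k, n, gh) {
  eta <- drop(x %*% beta)
  m <- length(k)
  u <- numeric(m)
  for (it in seq_len(50L)) {
    p <- plogis(eta + sigma * u)
    g <- sigma * (k - n * p) - u
    hpp <- -(sigma^2 * n * p * (1 - p) + 1)
    step <- g / hpp
    step[!is.finite(step)] <- 0
    u <- u - step
    if (max(abs(step)) < 1e-11) break
  }
  p <- plogis(eta + sigma * u)
  tau <- 1 / sqrt(sigma^2 * n * p * (1 - p) + 1)
  uj <- outer(tau, sqrt(2) * gh$x) + u            # m x nodes
  pj <- plogis(eta + sigma * uj)
  pj <- pmin(pmax(pj, 1e-15), 1 - 1e-15)
  hj <- matrix(dbinom(k, n, pj, log = TRUE), nrow = m) + dnorm(uj, log = TRUE)
  lw <- rep(log(gh$w) + gh$x^2, each = m)
  mat <- hj + lw
  mx <- do.call(pmax, as.data.frame(mat))
  sum(log(sqrt(2) * tau) + mx + log(rowSums(exp(mat - mx))))
}

#' Binomial GLMM with an observation-level random intercept
#'
#' Fits killed-out-of-offered counts to fixed effects of prey density,
#' prey distribution and their interaction, plus a random intercept unique
#' to each cage (an observation-level random effect, the standard device
#' for extra-binomial variation when each enemy individual is observed
#' once). Because the latent intercept is per-observation the integrated
#' likelihood factorizes into one-dimensional integrals, which are
#' evaluated by adaptive Gauss-Hermite quadrature centred at each
#' observation's conditional mode; `(beta, log sigma)` is then maximized
#' by quasi-Newton iteration started at the plain-GLM solution.
#'
#' If the variance component collapses to the boundary (`sigma` below
#' 1e-3), the model is refitted as a plain binomial GLM and returned with
#' `olre_sd = 0` and `boundary = TRUE` -- at the boundary the mixed model
#' *is* the GLM, and the GLM's Wald statistics are exact there.
#'
#' @param trials An [fr_trials] table. With both distribution levels
#'   present the design is `~ density * distribution` (aggregate as
#'   reference, coded 0); with a single level it reduces to `~ density`.
#' @param nodes Number of quadrature nodes (odd, >= 5); default 15.
#' @param center Center and scale density to mean 0, sd 1 before fitting?
#'   Default `FALSE` (density in prey counts).
#' @return An object of class `fr_glmm`: `coefficients`, `se`, `z`, `p`
#'   for the fixed effects, `olre_sd`, `log_lik`, `vcov`, `converged`,
#'   `boundary`, `nodes`, `terms`.
#' @examples
#' tab <- fr_simulate_olre(c(-2, 0.01, 0.5, -0.005), olre_sd = 0.8, seed = 1)
#' fr_glmm(tab)
#' @export
fr_glmm <- function(trials, nodes = 15L, center = FALSE) {
  if (!inherits(trials, "fr_trials")) trials <- fr_trials(trials)
  if (!is.numeric(nodes) || nodes < 5L || nodes %% 2L == 0L) {
    stop("fr_glmm(): `nodes` must be an odd integer >= 5")
  }
  dat <- data.frame(
    killed = trials$killed, alive = trials$density - trials$killed,
    density = if (center) drop(scale(trials$density)) else trials$density,
    distribution = factor(trials$distribution,
                          levels = fr_distribution_levels))
  both <- length(unique(dat$distribution[!is.na(dat$distribution)])) == 2L
  form <- if (both) {
    cbind(killed, alive) ~ density * distribution
  } else {
    cbind(killed, alive) ~ density
  }
  glm_fit <- glm(form, family = binomial(), data = dat)
  x <- model.matrix(glm_fit)
  k <- dat$killed; n <- trials$density
  gh <- gauss_hermite(as.integer(nodes))
  np <- ncol(x)

  nll <- function(theta) {
    # line searches can wander to wild values; keep the objective defined
    if (any(!is.finite(theta)) || any(abs(theta[seq_len(np)]) > 1e3) ||
        theta[np + 1L] > log(50)) {
      return(1e12)
    }
    val <- -.agq_loglik(theta[seq_len(np)], exp(theta[np + 1L]), x, k, n, gh)
    if (!is.finite(val)) 1e12 else val
  }
  theta0 <- c(coef(glm_fit), `log_sigma` = log(0.5))
  opt <- optim(theta0, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  sigma_hat <- exp(opt$par[np + 1L])
  converged <- opt$convergence == 0

  # Boundary rule: collapse to the GLM when the variance component is
  # negligible or buys essentially no likelihood -- at sigma = 0 the mixed
  # model *is* the GLM, whose Wald statistics are then exact.
  ll_glm <- as.numeric(stats::logLik(glm_fit))
  if (sigma_hat < 1e-2 || (-opt$value) - ll_glm < 1e-6) {
    sm <- summary(glm_fit)$coefficients
    return(structure(list(
      coefficients = setNames(sm[, 1], colnames(x)),
      se = setNames(sm[, 2], colnames(x)),
      z = setNames(sm[, 3], colnames(x)),
      p = setNames(sm[, 4], colnames(x)),
      olre_sd = 0, log_lik = ll_glm,
      vcov = vcov(glm_fit), converged = TRUE, boundary = TRUE,
      nodes = as.integer(nodes), terms = colnames(x), center = center),
      class = "fr_glmm"))
  }

  hess <- tryCatch(optimHess(opt$par, nll), error = function(e) NULL)
  vc <- matrix(NA_real_, np + 1L, np + 1L)
  if (!is.null(hess)) {
    vc_try <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc_try) && all(is.finite(diag(vc_try))) &&
        all(diag(vc_try) > 0)) {
      vc <- vc_try
    } else {
      converged <- FALSE
    }
  }
  beta <- opt$par[seq_len(np)]
  se <- sqrt(pmax(diag(vc)[seq_len(np)], 0))
  z <- beta / se
  structure(list(
    coefficients = setNames(beta, colnames(x)),
    se = setNames(se, colnames(x)),
    z = setNames(z, colnames(x)),
    p = setNames(2 * pnorm(-abs(z)), colnames(x)),
    olre_sd = as.numeric(sigma_hat), log_lik = -opt$value,
    vcov = vc[seq_len(np), seq_len(np), drop = FALSE],
    converged = converged, boundary = FALSE,
    nodes = as.integer(nodes), terms = colnames(x), center = center),
    class = "fr_glmm")
}

#' Wald table of a fitted observation-level GLMM
#'
#' One row per fixed effect with the estimate, standard error, Wald
#' statistic and two-sided p-value, plus a significance flag at `alpha`.
#'
#' @param fit An [fr_glmm] object.
#' @param alpha Significance threshold for the flag column.
#' @return A data frame with columns `term`, `estimate`, `se`, `z`, `p`,
#'   `signif`.
#' @export
fr_glmm_table <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "fr_glmm")) stop("fr_glmm_table(): expected `fr_glmm`")
  if (!fit$converged) {
    warning("fr_glmm_table(): fit flagged as non-converged")
  }
  data.frame(term = fit$terms, estimate = unname(fit$coefficients),
             se = unname(fit$se), z = unname(fit$z), p = unname(fit$p),
             signif = unname(fit$p < alpha), stringsAsFactors = FALSE)
}

#' @export
print.fr_glmm <- function(x, digits = 4, ...) {
  cat("Binomial GLMM with observation-level random intercept\n")
  print(round(data.frame(estimate = x$coefficients, se = x$se,
                         z = x$z, p = x$p), digits))
  cat("random-intercept SD:", format(x$olre_sd, digits = digits),
      if (x$boundary) "(boundary: refitted as plain GLM)", "\n")
  cat("log-likelihood:", format(x$log_lik, digits = digits),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}
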