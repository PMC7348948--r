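# --- likelihood machinery -------------------------------------------------
#
# The observation model is killed_i ~ Binomial(n0_i, Ne(n0_i)/n0_i) with Ne
# the Rogers depletion root. Fitting is done on (log a, log Th) so the
# positivity constraints vanish. Probabilities are clipped to
# [1e-12, 1 - 1e-12] so boundary parameter values (everything eaten /
# nothing eaten) keep the objective finite.

.p_clip <- 1e-12

# NLL on the log-parameter scale; ud/ui memoize the unique densities so the
# Rogers root is solved once per distinct density, not once per trial.
.rogers_nll <- function(lp, n0, k, tt, ud, ui) {
  a <- exp(lp[1]); th <- exp(lp[2])
  if (!is.finite(a) || !is.finite(th)) return(1e12)
  ne <- .rogers_ne(a, th, tt, ud)
  p <- pmin(pmax(ne / ud, .p_clip), 1 - .p_clip)[ui]
  val <- -sum(dbinom(k, n0, p, log = TRUE))
  if (!is.finite(val)) 1e12 else val
}

# Analytic gradient of .rogers_nll w.r.t. (log a, log Th), via implicit
# differentiation of the Rogers root.
.rogers_nll_grad <- function(lp, n0, k, tt, ud, ui) {
  a <- exp(lp[1]); th <- exp(lp[2])
  ne <- .rogers_ne(a, th, tt, ud)
  d <- .rogers_dne(a, th, tt, ud, ne)
  p <- pmin(pmax(ne / ud, .p_clip), 1 - .p_clip)[ui]
  dp_da <- (d$da / ud)[ui]
  dp_dth <- (d$dth / ud)[ui]
  dnll_dp <- -k / p + (n0 - k) / (1 - p)
  c(sum(dnll_dp * dp_da) * a, sum(dnll_dp * dp_dth) * th)
}

#' Negative log-likelihood of a trial table under the Rogers model
#'
#' Binomial negative log-likelihood of `killed` out of `density` with
#' per-trial success probability `Ne(density)/density`, `Ne` from
#' [rogers_expected()]. Kill probabilities are clipped away from 0 and 1 so
#' the value stays finite at boundary parameters.
#'
#' @param pars An [fr_params] object (its `duration` is ignored in favour
#'   of the table's).
#' @param trials An [fr_trials] table.
#' @return A single finite number (smaller is better).
#' @export
fr_nll <- function(pars, trials) {
  pars <- as_fr_params(pars)
  if (!inherits(trials, "fr_trials")) trials <- fr_trials(trials)
  if (pars$attack_rate <= 0 || pars$handling_time <= 0) {
    # log-scale machinery needs strictly positive parameters; evaluate the
    # limit directly instead
    ne <- .rogers_ne(pars$attack_rate, pars$handling_time,
                     fr_duration(trials), trials$density)
    p <- pmin(pmax(ne / trials$density, .p_clip), 1 - .p_clip)
    return(-sum(dbinom(trials$killed, trials$density, p, log = TRUE)))
  }
  ud <- sort(unique(trials$density))
  ui <- match(trials$density, ud)
  .rogers_nll(log(c(pars$attack_rate, pars$handling_time)),
              trials$density, trials$killed, fr_duration(trials), ud, ui)
}

# Heuristic starting values: attack rate from inverting the random-search
# limit at the lowest density, handling time from the saturation ceiling
# T/Th ~ maximum mean kill.
.fit_start <- function(n0, k, tt) {
  lowest <- n0 == min(n0)
  p_low <- min(max(mean(k[lowest] / n0[lowest]), 1e-3), 1 - 1e-3)
  a0 <- -log(1 - p_low) / tt
  mx <- max(tapply(k, n0, mean))
  th0 <- tt / max(2 * mx, 1)
  c(log(a0), log(th0))
}

# One L-BFGS-B run; returns list(par, value, ok).
.fit_one <- function(start, n0, k, tt, ud, ui) {
  o <- tryCatch(
    optim(start, .rogers_nll, .rogers_nll_grad, method = "L-BFGS-B",
          lower = c(-30, -30), upper = c(10, 10),
          control = list(maxit = 500, factr = 1e4),
          n0 = n0, k = k, tt = tt, ud = ud, ui = ui),
    error = function(e) NULL)
  if (is.null(o)) return(list(par = start, value = Inf, ok = FALSE))
  list(par = o$par, value = o$value, ok = o$convergence == 0)
}

#' Maximum-likelihood fit of the Rogers random-predator equation
#'
#' Estimates the attack rate and handling time by maximizing the binomial
#' likelihood of the observed kills under the depletion model. The
#' objective is optimized over `(log a, log Th)` (positivity built in) with
#' an analytic gradient, starting from a coarse grid around moment-based
#' heuristics plus `n_starts` jittered restarts; the best converged optimum
#' is kept. Standard errors come from the inverse of the numerically
#' differentiated Hessian at the optimum, mapped back to the natural scale
#' by the delta method; Wald z statistics and two-sided p-values are
#' reported per parameter.
#'
#' @param trials An [fr_trials] table with at least two distinct densities
#'   and at least one kill.
#' @param init Optional [fr_params] giving the single starting point (used
#'   by the bootstrap to restart each refit at the original estimates).
#'   When supplied with `n_starts = 0`, only that start is used.
#' @param n_starts Number of additional random restarts, log-uniformly
#'   jittered within +/- 1 of the best grid point; default 10.
#' @param seed Integer seed controlling the jitter (the fit is otherwise
#'   deterministic).
#' @return An object of class `fr_fit` with components `coefficients`
#'   (named `attack_rate`, `handling_time`), `se`, `z`, `p`, `vcov`,
#'   `log_lik`, `converged`, `n_trials`, `duration`, and the fitted
#'   `trials` (retained for bootstrapping).
#' @examples
#' tab <- fr_simulate(fr_reference_params()[1, ], seed = 7)
#' fr_fit(tab)
#' @export
fr_fit <- function(trials, init = NULL, n_starts = 10L, seed = 1L) {
  if (!inherits(trials, "fr_trials")) trials <- fr_trials(trials)
  n0 <- trials$density; k <- trials$killed; tt <- fr_duration(trials)
  if (length(unique(n0)) < 2L) {
    stop("fr_fit(): at least two distinct densities are required")
  }
  if (sum(k) == 0L) {
    stop("fr_fit(): degenerate data, no prey killed in any trial")
  }
  ud <- sort(unique(n0)); ui <- match(n0, ud)

  starts <- list()
  if (!is.null(init)) {
    init <- as_fr_params(init)
    starts <- list(log(c(init$attack_rate, init$handling_time)))
  }
  if (is.null(init) || n_starts > 0L) {
    ctr <- .fit_start(n0, k, tt)
    offs <- seq(-2, 2, length.out = 5L)
    grid <- as.matrix(expand.grid(ctr[1] + offs, ctr[2] + offs))
    gv <- apply(grid, 1L, .rogers_nll, n0 = n0, k = k, tt = tt,
                ud = ud, ui = ui)
    best_grid <- grid[which.min(gv), ]
    starts <- c(starts, list(best_grid))
    if (n_starts > 0L) {
      set.seed(derive_seed(seed, "fit-starts"))
      for (j in seq_len(n_starts)) {
        starts <- c(starts, list(best_grid + runif(2L, -1, 1)))
      }
    }
  }

  best <- NULL
  for (s in starts) {
    o <- .fit_one(s, n0, k, tt, ud, ui)
    if (is.null(best) || (o$ok && !best$ok) ||
        (o$ok == best$ok && o$value < best$value)) {
      best <- o
    }
  }

  est <- exp(best$par)
  hess <- tryCatch(
    optimHess(best$par, .rogers_nll, .rogers_nll_grad,
              n0 = n0, k = k, tt = tt, ud = ud, ui = ui),
    error = function(e) NULL)
  vc <- matrix(NA_real_, 2L, 2L)
  if (!is.null(hess)) {
    vcl <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcl) && all(is.finite(vcl)) && all(diag(vcl) > 0)) {
      vc <- diag(est) %*% vcl %*% diag(est)   # delta method from log scale
    }
  }
  se <- sqrt(pmax(diag(vc), 0))
  z <- est / se
  nm <- c("attack_rate", "handling_time")
  dimnames(vc) <- list(nm, nm)
  structure(list(
    coefficients = setNames(est, nm),
    se = setNames(se, nm),
    z = setNames(z, nm),
    p = setNames(2 * pnorm(-abs(z)), nm),
    vcov = vc,
    log_lik = -best$value,
    converged = best$ok,
    n_trials = length(k),
    duration = tt,
    trials = trials), class = "fr_fit")
}

#' @export
print.fr_fit <- function(x, digits = 4, ...) {
  cat("Rogers random-predator ML fit (", x$n_trials, " trials, T = ",
      format(x$duration), ")\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p)
  print(round(tab, digits))
  cat("log-likelihood:", format(x$log_lik, digits = digits),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
coef.fr_fit <- function(object, ...) object$coefficients

#' @export
vcov.fr_fit <- function(object, ...) object$vcov

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$log_lik, df = 2L, class = "logLik")
}

#' Predicted kills from a fitted Rogers model
#' @param object An `fr_fit` object.
#' @param newdensity Densities at which to predict; defaults to the fitted
#'   table's densities.
#' @param ... Unused.
#' @return Numeric vector of expected kills.
#' @export
predict.fr_fit <- function(object, newdensity = NULL, ...) {
  if (is.null(newdensity)) newdensity <- object$trials$density
  .rogers_ne(object$coefficients[["attack_rate"]],
             object$coefficients[["handling_time"]],
             object$duration, newdensity)
}
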