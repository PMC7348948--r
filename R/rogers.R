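#' Functional-response parameters
#'
#' Bundles the three quantities that determine a type II functional response
#' with prey depletion: the attack rate `a` (successful searches per unit
#' time), the handling time `Th` (time spent per prey captured, during which
#' no searching occurs) and the exposure duration `T`. All three share one
#' time unit; the package convention is one unit = one exposure period
#' (a 24-h cage assay), so an attack rate of 1.5 means 1.5 instantaneous
#' search units per period and a handling time of 0.006 means 0.6% of the
#' period per prey.
#'
#' @param attack_rate Instantaneous search rate, per unit time; `>= 0`.
#' @param handling_time Handling time per prey, same time unit; `>= 0`.
#' @param duration Total exposure duration; `> 0`. Default 1 period.
#' @return An object of class `fr_params`.
#' @examples
#' fr_params(1.590, 0.006)
#' @export
fr_params <- function(attack_rate, handling_time, duration = 1) {
  chk <- function(x, nm, min_ok) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("fr_params(): `", nm, "` must be a single finite number (got ",
           deparse(x), ")")
    }
    if (x < min_ok || (min_ok > 0 && x <= 0)) {
      stop("fr_params(): `", nm, "` must be ",
           if (min_ok > 0) "> 0" else ">= 0", " (got ", x, ")")
    }
    as.numeric(x)
  }
  structure(
    list(attack_rate  = chk(attack_rate, "attack_rate", 0),
         handling_time = chk(handling_time, "handling_time", 0),
         duration      = chk(duration, "duration", 1e-300)),
    class = "fr_params")
}

#' @export
print.fr_params <- function(x, ...) {
  cat("Functional-response parameters:\n",
      "  attack rate   a  =", format(x$attack_rate), "per time unit\n",
      "  handling time Th =", format(x$handling_time), "time units\n",
      "  exposure      T  =", format(x$duration), "time units\n")
  invisible(x)
}

as_fr_params <- function(x) {
  if (inherits(x, "fr_params")) return(x)
  if (is.list(x) && all(c("attack_rate", "handling_time") %in% names(x))) {
    return(fr_params(x$attack_rate, x$handling_time,
                     if (!is.null(x$duration)) x$duration else 1))
  }
  stop("expected an `fr_params` object (see fr_params())")
}

# Vectorised Rogers root. Arguments recycle. Ne solves
#   Ne = n0 * (1 - exp(a*th*Ne - a*tt)),
# computed through the Lambert-W closed form
#   Ne = n0 - W0(a*th*n0 * exp(a*th*n0 - a*tt)) / (a*th).
# The W argument is a*th*n0 * exp(...) >= 0, so the principal branch is the
# only branch in play; for large a*th*n0 the argument overflows double
# precision and the log-domain solver takes over. a == 0 or th == 0 dispatch
# to the explicit limits.
.rogers_ne <- function(a, th, tt, n0) {
  m <- max(length(a), length(th), length(tt), length(n0))
  a  <- rep_len(a, m);  th <- rep_len(th, m)
  tt <- rep_len(tt, m); n0 <- rep_len(n0, m)
  ne <- numeric(m)
  zero <- a == 0
  nohand <- !zero & th == 0
  ne[nohand] <- n0[nohand] * (-expm1(-a[nohand] * tt[nohand]))
  gen <- !zero & !nohand
  if (any(gen)) {
    z  <- a[gen] * th[gen] * n0[gen]
    ly <- log(z) + z - a[gen] * tt[gen]
    w  <- numeric(sum(gen))
    big <- ly > 700
    if (any(!big)) w[!big] <- lambert_w0(exp(ly[!big]))
    if (any(big))  w[big]  <- lambert_w0_log(ly[big])
    ne[gen] <- n0[gen] - w / (a[gen] * th[gen])
  }
  pmin(pmax(ne, 0), n0)
}

# Partial derivatives of the Rogers root w.r.t. a and th, by implicit
# differentiation of Ne = n0*(1 - E), E = exp(a*th*Ne - a*tt):
#   dNe/da  =  n0*E*(tt - th*Ne) / (1 + a*th*n0*E)
#   dNe/dth = -n0*E*a*Ne        / (1 + a*th*n0*E)
.rogers_dne <- function(a, th, tt, n0, ne) {
  e <- 1 - ne / n0
  denom <- 1 + a * th * n0 * e
  list(da  = n0 * e * (tt - th * ne) / denom,
       dth = -n0 * e * a * ne / denom)
}

#' Expected prey killed under the Rogers random-predator equation
#'
#' Solves the implicit depletion model
#' \deqn{N_e = N_0 \left[1 - \exp(a T_h N_e - a T)\right]}
#' for the expected number of prey killed \eqn{N_e} out of \eqn{N_0} offered,
#' using the Lambert-W closed form
#' \eqn{N_e = N_0 - W_0(a T_h N_0 e^{a T_h N_0 - a T})/(a T_h)}. The
#' degenerate cases \eqn{a = 0} (nothing killed) and \eqn{T_h = 0} (explicit
#' random-search model \eqn{N_0(1 - e^{-aT})}) are handled by their limit
#' forms rather than division by zero.
#'
#' @param pars An [fr_params] object.
#' @param n0 Initial prey density (or vector of densities); `> 0`. Real
#'   values are accepted so that prediction curves can be drawn on a fine
#'   grid.
#' @return Numeric vector of expected kills, one per density, each in
#'   `[0, n0]` and bounded by `duration / handling_time` when the handling
#'   time is positive.
#' @seealso [rogers_expected_bisect()] for the bracketed-bisection solver of
#'   the same root, [holling_expected()] for the no-depletion reference.
#' @examples
#' p <- fr_params(1.590, 0.006, duration = 1)
#' rogers_expected(p, c(4, 8, 16, 32, 64, 128, 256))
#' @export
rogers_expected <- function(pars, n0) {
  pars <- as_fr_params(pars)
  if (!is.numeric(n0) || any(!is.finite(n0)) || any(n0 <= 0)) {
    stop("rogers_expected(): `n0` must be finite and > 0")
  }
  .rogers_ne(pars$attack_rate, pars$handling_time, pars$duration, n0)
}

#' Rogers root by bracketed bisection
#'
#' Solves the same implicit equation as [rogers_expected()] by bisection on
#' `[0, n0]`, where the residual
#' \eqn{f(N_e) = N_0(1 - e^{a T_h N_e - a T}) - N_e} changes sign. Kept as a
#' deliberately simple, closed-form-free solver so the two routes can be
#' checked against each other.
#'
#' @inheritParams rogers_expected
#' @param tol Absolute tolerance on the root; `> 0`.
#' @return Numeric vector of roots.
#' @export
rogers_expected_bisect <- function(pars, n0, tol = 1e-10) {
  pars <- as_fr_params(pars)
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    stop("rogers_expected_bisect(): `tol` must be a single number > 0")
  }
  if (!is.numeric(n0) || any(!is.finite(n0)) || any(n0 <= 0)) {
    stop("rogers_expected_bisect(): `n0` must be finite and > 0")
  }
  a <- pars$attack_rate; th <- pars$handling_time; tt <- pars$duration
  vapply(n0, function(n) {
    f <- function(ne) n * (-expm1(a * th * ne - a * tt)) - ne
    lo <- 0; hi <- n
    flo <- f(lo)
    if (flo < 0) {
      stop("rogers_expected_bisect(): no sign change on [0, n0]; ",
           "internal inconsistency for a=", a, ", th=", th, ", n0=", n)
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Holling disc equation (no prey depletion)
#'
#' The classical type II expectation \eqn{N_e = a N_0 T / (1 + a T_h N_0)},
#' valid when prey are continuously replaced. With depletion it
#' overestimates consumption, so it serves as an upper reference and as a
#' source of starting values for the maximum-likelihood fit. Capped at
#' `n0` since no more prey than offered can be killed.
#'
#' @inheritParams rogers_expected
#' @return Numeric vector of expected kills.
#' @export
holling_expected <- function(pars, n0) {
  pars <- as_fr_params(pars)
  if (!is.numeric(n0) || any(!is.finite(n0)) || any(n0 <= 0)) {
    stop("holling_expected(): `n0` must be finite and > 0")
  }
  a <- pars$attack_rate; th <- pars$handling_time; tt <- pars$duration
  pmin(a * n0 * tt / (1 + a * th * n0), n0)
}
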