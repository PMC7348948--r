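#' Non-parametric bootstrap of a Rogers fit
#'
#' Resamples whole trials (cages) with replacement, refits the Rogers model
#' on each resample starting from the original maximum-likelihood
#' estimates, and collects the parameter draws. Percentile 95% confidence
#' intervals are computed from the successful refits; resamples that fail
#' to converge are dropped and counted, and the result is flagged unstable
#' (with a warning) when more than 20% fail. The cage is the exchangeable
#' unit -- cages are independent by design -- which is why the resampling
#' operates on rows rather than residuals.
#'
#' @param fit A converged [fr_fit] object (it carries its trial table).
#' @param n_boot Number of bootstrap resamples; default 2000.
#' @param seed Integer seed; draws are reproducible given it.
#' @param level Confidence level for the percentile intervals.
#' @return An object of class `fr_boot`: `draws` (matrix with columns
#'   `attack_rate`, `handling_time`, one row per successful resample),
#'   `n_requested`, `n_failed`, `ci` (2 x 2 matrix of percentile limits),
#'   `unstable` flag, the point `estimates`, `duration` and the observed
#'   `density_range`.
#' @examples
#' tab <- fr_simulate(fr_reference_params()[1, ], seed = 3)
#' bt <- fr_boot(fr_fit(tab), n_boot = 200, seed = 3)
#' bt$ci
#' @export
fr_boot <- function(fit, n_boot = 2000L, seed = 1L, level = 0.95) {
  if (!inherits(fit, "fr_fit")) stop("fr_boot(): expected an `fr_fit` object")
  if (!fit$converged) stop("fr_boot(): the original fit did not converge")
  if (!is.numeric(n_boot) || n_boot < 1) stop("fr_boot(): `n_boot` must be >= 1")
  trials <- fit$trials
  n0 <- trials$density; k <- trials$killed; tt <- fit$duration
  n <- length(k)
  start <- log(fit$coefficients)
  set.seed(derive_seed(seed, "boot"))
  draws <- matrix(NA_real_, n_boot, 2L,
                  dimnames = list(NULL, c("attack_rate", "handling_time")))
  ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bn0 <- n0[idx]; bk <- k[idx]
    if (sum(bk) == 0L || length(unique(bn0)) < 2L) next  # unfittable resample
    ud <- sort(unique(bn0)); ui <- match(bn0, ud)
    o <- .fit_one(start, bn0, bk, tt, ud, ui)
    if (o$ok && all(is.finite(o$par))) {
      draws[b, ] <- exp(o$par)
      ok[b] <- TRUE
    }
  }
  draws <- draws[ok, , drop = FALSE]
  n_failed <- n_boot - nrow(draws)
  unstable <- n_failed > 0.2 * n_boot
  if (unstable) {
    warning("fr_boot(): ", n_failed, " of ", n_boot,
            " resamples failed to converge; intervals flagged unstable")
  }
  if (nrow(draws) == 0L) stop("fr_boot(): no resample converged")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- apply(draws, 2L, quantile, probs = probs, names = FALSE)
  rownames(ci) <- paste0(format(100 * probs, trim = TRUE), "%")
  structure(list(
    draws = draws, n_requested = as.integer(n_boot),
    n_failed = as.integer(n_failed), ci = ci, unstable = unstable,
    estimates = fit$coefficients, duration = tt,
    density_range = range(trials$density), level = level),
    class = "fr_boot")
}

#' @export
print.fr_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap of Rogers fit: ", nrow(x$draws), "/", x$n_requested,
      " successful resamples", if (x$unstable) " [UNSTABLE]", "\n", sep = "")
  est <- rbind(estimate = x$estimates, x$ci)
  print(round(est, digits))
  invisible(x)
}

#' Pointwise bootstrap confidence band for the response curve
#'
#' Evaluates the Rogers prediction curve under every bootstrap parameter
#' draw and takes pointwise quantiles at each grid density, yielding the
#' shaded 95% band conventionally drawn around functional-response curves.
#'
#' @param boot An [fr_boot] object.
#' @param grid Densities at which to evaluate the band; defaults to the
#'   unit-step grid spanning the observed density range.
#' @return A data frame with columns `density`, `fit` (point-estimate
#'   curve), `lower`, `upper`.
#' @export
fr_band <- function(boot, grid = NULL) {
  if (!inherits(boot, "fr_boot")) stop("fr_band(): expected an `fr_boot`")
  if (is.null(grid)) {
    grid <- seq(boot$density_range[1], boot$density_range[2], by = 1)
  }
  if (length(grid) == 0L || any(!is.finite(grid)) || any(grid <= 0)) {
    stop("fr_band(): `grid` must be positive and finite")
  }
  if (nrow(boot$draws) == 0L) stop("fr_band(): no bootstrap draws")
  probs <- c((1 - boot$level) / 2, 1 - (1 - boot$level) / 2)
  a <- boot$draws[, 1L]; th <- boot$draws[, 2L]
  curves <- vapply(grid, function(g) {
    ne <- .rogers_ne(a, th, boot$duration, g)
    quantile(ne, probs = probs, names = FALSE)
  }, numeric(2L))
  data.frame(
    density = grid,
    fit = .rogers_ne(boot$estimates[["attack_rate"]],
                     boot$estimates[["handling_time"]],
                     boot$duration, grid),
    lower = curves[1L, ], upper = curves[2L, ])
}

#' Density ranges where two bootstrap bands do not overlap
#'
#' Places both treatments' confidence bands on a shared density grid and
#' marks the grid points where the two pointwise intervals are disjoint;
#' consecutive marked points are merged into closed intervals. Band
#' separation over a density range is the operational criterion for the
#' two functional responses differing there, and band overlap for their
#' being statistically indistinguishable.
#'
#' @param boot_a,boot_b Two [fr_boot] objects whose experiments share part
#'   of their density range.
#' @param grid_step Grid spacing in prey units; default 1.
#' @return An object of class `fr_overlap`: `intervals` (data frame with
#'   `density_low`, `density_high`, one row per disjoint run, zero rows if
#'   the bands always overlap), the `grid_step` and shared `range`.
#' @export
fr_band_overlap <- function(boot_a, boot_b, grid_step = 1) {
  if (!inherits(boot_a, "fr_boot") || !inherits(boot_b, "fr_boot")) {
    stop("fr_band_overlap(): expected two `fr_boot` objects")
  }
  lo <- max(boot_a$density_range[1], boot_b$density_range[1])
  hi <- min(boot_a$density_range[2], boot_b$density_range[2])
  if (lo > hi) {
    stop("fr_band_overlap(): the two experiments' density ranges are disjoint")
  }
  grid <- seq(lo, hi, by = grid_step)
  ba <- fr_band(boot_a, grid)
  bb <- fr_band(boot_b, grid)
  disjoint <- ba$upper < bb$lower | bb$upper < ba$lower
  runs <- rle(disjoint)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  intervals <- data.frame(density_low = grid[starts[keep]],
                          density_high = grid[ends[keep]])
  structure(list(intervals = intervals, grid_step = grid_step,
                 range = c(lo, hi)),
            class = "fr_overlap")
}

#' @export
print.fr_overlap <- function(x, ...) {
  cat("Confidence-band comparison on [", x$range[1], ", ", x$range[2],
      "] (step ", x$grid_step, ")\n", sep = "")
  if (nrow(x$intervals) == 0L) {
    cat("bands overlap at every grid density (no detectable difference)\n")
  } else {
    cat("bands disjoint (responses differ) on:\n")
    for (i in seq_len(nrow(x$intervals))) {
      cat("  densities ", x$intervals$density_low[i], " - ",
          x$intervals$density_high[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Plot fitted response curves with bootstrap bands
#'
#' Base-graphics plot of one or two fitted functional responses: shaded
#' pointwise bootstrap bands, the point-estimate curves, and optionally
#' the per-density mean kills of the underlying trials.
#'
#' @param x An [fr_boot] object.
#' @param boot_b Optional second [fr_boot] to overlay for comparison.
#' @param labels Legend labels for the one or two treatments.
#' @param show_data Draw per-density mean kills of the fitted trials?
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot.fr_boot <- function(x, boot_b = NULL, labels = c("A", "B"),
                         show_data = FALSE, ...) {
  band_a <- fr_band(x)
  ylim <- range(0, band_a$upper)
  if (!is.null(boot_b)) {
    band_b <- fr_band(boot_b)
    ylim <- range(ylim, band_b$upper)
  }
  plot(band_a$density, band_a$fit, type = "n", ylim = ylim,
       xlab = "initial prey density", ylab = "prey killed", ...)
  shade <- function(b, col) {
    polygon(c(b$density, rev(b$density)), c(b$lower, rev(b$upper)),
            col = col, border = NA)
  }
  shade(band_a, grDevices::adjustcolor("steelblue", 0.35))
  lines(band_a$density, band_a$fit, lwd = 2, col = "steelblue4")
  if (!is.null(boot_b)) {
    shade(band_b, grDevices::adjustcolor("firebrick", 0.35))
    lines(band_b$density, band_b$fit, lwd = 2, lty = 2, col = "firebrick4")
    legend("topleft", legend = labels, lwd = 2, lty = c(1, 2),
           col = c("steelblue4", "firebrick4"), bty = "n")
  }
  invisible(NULL)
}
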