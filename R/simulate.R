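#' Simulate functional-response cage experiments
#'
#' Generates trial tables with the cage-assay design: every combination of
#' treatment cell, prey density and replicate yields one cage, and the
#' number killed is drawn as `Binomial(n0, Ne/n0)` with `Ne` the Rogers
#' depletion expectation for that cell's parameters. Binomial noise around
#' the Rogers mean is exactly the observation model the maximum-likelihood
#' fit assumes, so parameter-recovery checks against this generator are
#' unconfounded by model misspecification; [fr_simulate_process()] provides
#' a mechanistic alternative for stress-testing.
#'
#' Each cell draws from its own random stream, derived deterministically
#' from `seed` and the cell's labels: adding or removing a cell leaves all
#' other cells' tables unchanged.
#'
#' @param cells Data frame with columns `enemy`, `distribution`,
#'   `attack_rate`, `handling_time` (one row per treatment cell), e.g. a
#'   subset of [fr_reference_params()].
#' @param densities Initial prey densities; default the assay design
#'   `c(4, 8, 16, 32, 64, 128, 256)`.
#' @param replicates Cages per cell-by-density combination; default 10.
#' @param duration Exposure duration (time units); default 1 period.
#' @param seed Master seed (integer).
#' @return An [fr_trials] table with
#'   `nrow(cells) * length(densities) * replicates` rows.
#' @examples
#' cells <- fr_reference_params()[1:2, ]
#' tab <- fr_simulate(cells, seed = 1)
#' table(tab$distribution, tab$density)
#' @export
fr_simulate <- function(cells,
                        densities = c(4, 8, 16, 32, 64, 128, 256),
                        replicates = 10, duration = 1, seed = 1L) {
  cells <- as.data.frame(cells)
  req <- c("enemy", "distribution", "attack_rate", "handling_time")
  if (nrow(cells) == 0L || !all(req %in% names(cells))) {
    stop("fr_simulate(): `cells` must have >= 1 row and columns ",
         paste(req, collapse = ", "))
  }
  if (length(densities) == 0L || any(!is.finite(densities)) ||
      any(densities <= 0) || any(densities != round(densities))) {
    stop("fr_simulate(): `densities` must be positive integers")
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop("fr_simulate(): `replicates` must be >= 1")
  }
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- fr_params(cells$attack_rate[i], cells$handling_time[i], duration)
    key <- paste(cells$enemy[i], cells$distribution[i], sep = "/")
    set.seed(derive_seed(seed, key))
    dens <- rep(densities, each = replicates)
    ne <- .rogers_ne(p$attack_rate, p$handling_time, duration, dens)
    out[[i]] <- data.frame(
      density = dens,
      killed = rbinom(length(dens), dens, ne / dens),
      distribution = cells$distribution[i],
      enemy = cells$enemy[i],
      replicate = rep(seq_len(replicates), length(densities)),
      stringsAsFactors = FALSE)
  }
  fr_trials(do.call(rbind, out), duration = duration)
}

#' Mechanistic foraging simulation (renewal process)
#'
#' Simulates a single forager as a continuous-time renewal process: search
#' times are exponential with rate `a * n` where `n` is the number of prey
#' still alive, each capture removes one prey and is followed by a fixed
#' handling time `Th`, and the clock stops at the exposure duration `T`. A
#' capture occurring before the clock expires counts even if its handling
#' spills past `T`. This is an independent, mechanism-level model whose
#' mean tracks (but does not exactly equal) the deterministic Rogers
#' solution; it is provided as a distribution-level oracle and
#' misspecification stressor for the binomial generator.
#'
#' @param pars An [fr_params] object; `handling_time > 0` unless a finite
#'   `max_captures` is supplied.
#' @param n0 Initial prey density (positive integer).
#' @param seed Integer seed.
#' @param n Number of independent runs to simulate.
#' @param max_captures Optional hard cap on captures per run.
#' @return Integer vector of length `n`: prey killed per run, each in
#'   `[0, min(n0, 1 + floor(T/Th))]`.
#' @export
fr_simulate_process <- function(pars, n0, seed = 1L, n = 1L,
                                max_captures = Inf) {
  pars <- as_fr_params(pars)
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 1 || n0 != round(n0)) {
    stop("fr_simulate_process(): `n0` must be a positive integer")
  }
  if (pars$handling_time <= 0 && !is.finite(max_captures)) {
    stop("fr_simulate_process(): with handling_time = 0 a finite ",
         "`max_captures` is required")
  }
  a <- pars$attack_rate; th <- pars$handling_time; tt <- pars$duration
  set.seed(as.integer(seed %% 2147483647))
  vapply(seq_len(n), function(run) {
    if (a == 0) return(0L)
    t <- 0; alive <- n0; k <- 0L
    while (alive > 0L && k < max_captures) {
      t <- t + rexp(1L, rate = a * alive)
      if (t > tt) break
      k <- k + 1L
      alive <- alive - 1L
      t <- t + th
    }
    k
  }, integer(1))
}

#' Simulate a sigmoidal (type III) response
#'
#' Identical design to [fr_simulate()] but the attack rate grows linearly
#' with the offered density, `a(N0) = slope * N0`, so the proportion killed
#' first rises with density before handling and depletion pull it back
#' down -- the signature of a type III response. Used to verify that the
#' type-selection stage detects a positive linear coefficient on such data.
#'
#' @param slope Increase in attack rate per prey offered; `> 0` (0 allowed,
#'   giving the degenerate no-attack case).
#' @param handling_time Handling time per prey (time units).
#' @inheritParams fr_simulate
#' @return An [fr_trials] table (enemy label `predator_single`).
#' @export
fr_simulate_type3 <- function(slope, handling_time,
                              densities = c(4, 8, 16, 32, 64, 128, 256),
                              replicates = 10, duration = 1, seed = 1L) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope < 0) {
    stop("fr_simulate_type3(): `slope` must be >= 0")
  }
  if (length(densities) == 0L || any(densities <= 0) ||
      any(densities != round(densities))) {
    stop("fr_simulate_type3(): `densities` must be positive integers")
  }
  set.seed(derive_seed(seed, "type3"))
  dens <- rep(densities, each = replicates)
  ne <- .rogers_ne(slope * dens, handling_time, duration, dens)
  fr_trials(data.frame(
    density = dens,
    killed = rbinom(length(dens), dens, ne / dens),
    distribution = "aggregate",
    enemy = "predator_single",
    replicate = rep(seq_len(replicates), length(densities)),
    stringsAsFactors = FALSE), duration = duration)
}

#' Simulate logistic-normal binomial data (observation-level random effect)
#'
#' Generates killed counts from the model the observation-level-random-
#' effect GLMM fits: for each cage,
#' `logit(p) = X beta + u`, `u ~ Normal(0, olre_sd^2)` independently per
#' cage, and `killed ~ Binomial(density, p)`. The fixed-effect design is
#' `~ density * distribution` with `aggregate` as the reference level, so
#' `beta` is (intercept, density slope, uniform-distribution offset,
#' density-by-uniform interaction).
#'
#' @param beta Numeric vector of fixed-effect coefficients, in design order.
#' @param olre_sd Standard deviation of the per-cage random intercept;
#'   `>= 0`.
#' @param design Optional data frame with columns `density` and
#'   `distribution` giving the cages to simulate; if `NULL`, built from
#'   `densities` x `replicates` x both distribution levels.
#' @inheritParams fr_simulate
#' @param enemy Enemy label stamped on the generated trials.
#' @return An [fr_trials] table.
#' @export
fr_simulate_olre <- function(beta, olre_sd, design = NULL,
                             densities = c(4, 8, 16, 32, 64, 128, 256),
                             replicates = 10, duration = 1, seed = 1L,
                             enemy = "predator_single") {
  if (!is.numeric(olre_sd) || length(olre_sd) != 1L || !is.finite(olre_sd) ||
      olre_sd < 0) {
    stop("fr_simulate_olre(): `olre_sd` must be >= 0")
  }
  if (is.null(design)) {
    design <- expand.grid(
      replicate = seq_len(replicates), density = densities,
      distribution = fr_distribution_levels,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    design <- as.data.frame(design)
    if (!all(c("density", "distribution") %in% names(design))) {
      stop("fr_simulate_olre(): `design` needs columns density, distribution")
    }
    if (is.null(design$replicate)) {
      design$replicate <- stats::ave(design$density,
                                     design$density, design$distribution,
                                     FUN = seq_along)
    }
  }
  design$distribution <- factor(design$distribution,
                                levels = fr_distribution_levels)
  x <- model.matrix(~ density * distribution, design)
  if (length(beta) != ncol(x)) {
    stop("fr_simulate_olre(): `beta` must have length ", ncol(x),
         " to match the design matrix (", paste(colnames(x), collapse = ", "),
         ")")
  }
  set.seed(derive_seed(seed, "olre"))
  u <- rnorm(nrow(design), 0, olre_sd)
  p <- plogis(drop(x %*% beta) + u)
  fr_trials(data.frame(
    density = design$density,
    killed = rbinom(nrow(design), design$density, p),
    distribution = as.character(design$distribution),
    enemy = enemy,
    replicate = design$replicate,
    stringsAsFactors = FALSE), duration = duration)
}
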