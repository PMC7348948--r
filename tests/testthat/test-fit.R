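test_that("negative log-likelihood matches brute-force summation", {
  tab <- toy_trials(seed = 51, replicates = 3)
  for (pars in list(c(1.6, 0.006), c(0.5, 0.05), c(0.05, 0.3))) {
    expect_equal(fr_nll(fr_params(pars[1], pars[2], 1), tab),
                 oracle_nll(pars[1], pars[2], 1, tab$density, tab$killed),
                 tolerance = 1e-8)
  }
  # boundary guard: attack rate so large that everything is eaten stays finite
  expect_true(is.finite(fr_nll(fr_params(500, 1e-6, 1), tab)))
  # likelihood peaks near the expectation: a single trial at the model mean
  one <- fr_trials(data.frame(
    density = 64, killed = round(rogers_expected(fr_params(0.8, 0.01, 1), 64)),
    distribution = "aggregate", enemy = "predator_single", replicate = 1))
  near <- fr_nll(fr_params(0.8, 0.01, 1), one)
  expect_lt(near, fr_nll(fr_params(0.45, 0.01, 1), one))
  expect_lt(near, fr_nll(fr_params(1.5, 0.01, 1), one))
})

test_that("analytic gradient matches numerical differentiation", {
  skip_if_not_installed("pracma")
  tab <- toy_trials(seed = 52, replicates = 3)
  ud <- sort(unique(tab$density)); ui <- match(tab$density, ud)
  for (lp in list(log(c(1.6, 0.006)), log(c(0.3, 0.08)))) {
    g <- rogersfr:::.rogers_nll_grad(lp, tab$density, tab$killed, 1, ud, ui)
    gn <- pracma::grad(rogersfr:::.rogers_nll, lp, n0 = tab$density,
                       k = tab$killed, tt = 1, ud = ud, ui = ui)
    expect_equal(g, gn, tolerance = 1e-5)
  }
})

test_that("noiseless data are recovered up to integer rounding", {
  # kills are integers, so "noiseless" data carry the expectation rounded
  # to the nearest count; at the lowest density that rounding alone moves
  # the proportion by ~1/3 of a prey, which caps how exactly the
  # generating values can be recovered (5% here, dominated by density 4)
  p <- fr_params(0.5, 0.05, 1)
  dens <- rep(c(4, 8, 16, 32, 64, 128, 256), each = 10)
  tab <- fr_trials(data.frame(
    density = dens, killed = round(rogers_expected(p, dens)),
    distribution = "aggregate", enemy = "predator_single",
    replicate = rep(1:10, 7)))
  est <- coef(fr_fit(tab))
  expect_lt(abs(est[["attack_rate"]] - 0.5) / 0.5, 0.05)
  expect_lt(abs(est[["handling_time"]] - 0.05) / 0.05, 0.05)
})

test_that("optimizer finds the global optimum located by grid search", {
  tab <- toy_trials(seed = 53, replicates = 2)    # 14 trials
  fit <- fr_fit(tab)
  lp_hat <- log(coef(fit))
  la <- seq(lp_hat[1] - 1.5, lp_hat[1] + 1.5, length.out = 200)
  lth <- seq(lp_hat[2] - 1.5, lp_hat[2] + 1.5, length.out = 200)
  nll <- outer(la, lth, Vectorize(function(u, v) {
    fr_nll(fr_params(exp(u), exp(v), 1), tab)
  }))
  best <- which(nll == min(nll), arr.ind = TRUE)[1, ]
  cell_a <- diff(la)[1]; cell_th <- diff(lth)[1]
  expect_lt(abs(la[best[1]] - lp_hat[1]), cell_a * 1.5)
  expect_lt(abs(lth[best[2]] - lp_hat[2]), cell_th * 1.5)
  expect_lte(fit$log_lik * -1, min(nll) + 1e-8)  # at least as good as lattice
})

test_that("estimates are invariant to reordering and duplicate every trial", {
  tab <- toy_trials(seed = 54, replicates = 10)
  fit <- fr_fit(tab)
  perm <- fr_trials(tab[sample(nrow(tab)), ], fr_duration(tab))
  expect_equal(coef(fr_fit(perm)), coef(fit), tolerance = 1e-6)
  dup <- fr_trials(rbind(as.data.frame(tab), as.data.frame(tab)),
                   fr_duration(tab))
  fit2 <- fr_fit(dup)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-5)
  expect_equal(fit2$se, fit$se / sqrt(2), tolerance = 0.02)
})

test_that("log-scale and box-constrained natural-scale fits agree", {
  tab <- toy_trials(seed = 55, replicates = 10)
  fit <- fr_fit(tab)
  # finite-difference steps must respect the very different parameter
  # scales (attack rate ~1, handling time ~0.006)
  nat <- optim(coef(fit) * 1.3,
               function(p) fr_nll(fr_params(p[1], p[2], 1), tab),
               method = "L-BFGS-B", lower = c(1e-8, 1e-8),
               control = list(factr = 1e4, ndeps = coef(fit) * 1e-7))
  expect_equal(unname(coef(fit)), unname(nat$par), tolerance = 1e-4)
})

test_that("degenerate inputs raise the documented errors", {
  dens <- rep(16, 10)
  tab <- fr_trials(data.frame(density = dens, killed = 0,
                              distribution = "aggregate",
                              enemy = "predator_single", replicate = 1:10))
  expect_error(fr_fit(tab), "distinct densities")
  tab2 <- toy_trials(seed = 56)
  tab2$killed <- 0L
  expect_error(fr_fit(fr_trials(tab2, 1)), "no prey killed")
})

test_that("fit summaries expose Wald inference and predictions", {
  tab <- toy_trials(seed = 57, replicates = 10)
  fit <- fr_fit(tab)
  expect_true(fit$converged)
  expect_true(all(coef(fit) > 0))
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  vc <- vcov(fit)
  expect_equal(vc, t(vc))
  expect_true(all(eigen(vc, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
  expect_equal(fit$p, 2 * pnorm(-abs(fit$z)))
  pr <- predict(fit, c(4, 256))
  expect_true(all(pr > 0) && pr[1] < pr[2])
  expect_output(print(fit), "attack_rate")
})
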