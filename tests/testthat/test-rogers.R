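test_that("closed-form solver reproduces known limits and frozen roots", {
  # zero attack rate kills nothing
  expect_equal(rogers_expected(fr_params(0, 1, 24), 50), 0)
  expect_equal(rogers_expected_bisect(fr_params(0, 1, 24), 50), 0,
               tolerance = 1e-10)
  # zero handling time reduces to the explicit random-search form
  expect_equal(rogers_expected(fr_params(0.1, 0, 24), 100),
               100 * (1 - exp(-2.4)), tolerance = 1e-12)
  # frozen root computed by high-precision Brent iteration on the residual
  expect_equal(rogers_expected(fr_params(0.5, 1, 24), 50), 22.7835939028,
               tolerance = 1e-8)
  # reference-parameter root is interior and shared by both solvers
  p <- fr_params(1.590, 0.006, 1)
  ne <- rogers_expected(p, 4)
  expect_equal(ne, 3.1593379600, tolerance = 1e-8)
  expect_gt(ne, 0); expect_lt(ne, 4)
})

test_that("closed form, bisection and an independent root-finder agree", {
  grid <- expand.grid(a = c(0.01, 0.1, 0.5, 1.59, 5),
                      th = c(0, 0.006, 0.05, 0.5),
                      n0 = c(1, 4, 37, 256, 512))
  for (i in seq_len(nrow(grid))) {
    p <- fr_params(grid$a[i], grid$th[i], 1)
    closed <- rogers_expected(p, grid$n0[i])
    expect_equal(closed, rogers_expected_bisect(p, grid$n0[i], tol = 1e-12),
                 tolerance = 1e-8)
    expect_equal(closed, oracle_rogers(grid$a[i], grid$th[i], 1, grid$n0[i]),
                 tolerance = 1e-7)
  }
})

test_that("the closed-form value satisfies the implicit equation", {
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 0.01, 5); th <- runif(1, 0, 0.5)
    n0 <- sample(1:512, 1); tt <- runif(1, 0.5, 24)
    ne <- rogers_expected(fr_params(a, th, tt), n0)
    resid <- n0 * (-expm1(a * th * ne - a * tt)) - ne
    if (ne < n0 * (1 - 1e-12)) expect_lt(abs(resid), 1e-8)
    expect_gte(ne, 0)
    expect_lte(ne, n0)
    if (th > 0) expect_lte(ne, tt / th + 1e-8)
  }
})

test_that("predictions are monotone in each parameter and bounded", {
  n0 <- c(4, 8, 16, 32, 64, 128, 256)
  base <- rogers_expected(fr_params(0.8, 0.01, 1), n0)
  expect_true(all(diff(base) > 0))                      # increasing in n0
  more_a <- rogers_expected(fr_params(1.2, 0.01, 1), n0)
  expect_true(all(more_a >= base))
  more_t <- rogers_expected(fr_params(0.8, 0.01, 2), n0)
  expect_true(all(more_t >= base))
  more_th <- rogers_expected(fr_params(0.8, 0.05, 1), n0)
  expect_true(all(more_th <= base))
  # depletion-aware prediction never exceeds the disc equation
  disc <- holling_expected(fr_params(0.8, 0.01, 1), n0)
  expect_true(all(base <= disc + 1e-10))
})

test_that("handling-time limit approaches the random-search form", {
  n0 <- c(5, 50, 500)
  lim <- n0 * (1 - exp(-0.7 * 3))
  expect_equal(rogers_expected(fr_params(0.7, 1e-9, 3), n0), lim,
               tolerance = 1e-6)
})

test_that("holling disc equation evaluates directly and caps at n0", {
  expect_equal(holling_expected(fr_params(0, 5, 24), 10), 0)
  expect_equal(holling_expected(fr_params(1, 0, 24), 10), 10)  # min(240, 10)
  expect_equal(holling_expected(fr_params(0.5, 1, 24), 50), 600 / 26,
               tolerance = 1e-12)
})

test_that("internal Lambert W agrees with pracma on both branches of scale", {
  skip_if_not_installed("pracma")
  x <- c(0, 1e-12, 0.1, 1, exp(1), 50, 1e6, 1e300)
  expect_equal(rogersfr:::lambert_w0(x),
               vapply(x, pracma::lambertWp, numeric(1)), tolerance = 1e-10)
  # log-domain solver: w + log(w) = y must invert
  y <- c(705, 1000, 1e5)
  w <- rogersfr:::lambert_w0_log(y)
  expect_equal(w + log(w), y, tolerance = 1e-10)
})

test_that("invalid parameters and densities are rejected with clear errors", {
  expect_error(fr_params(-1, 0.1), "attack_rate")
  expect_error(fr_params(1, NA), "handling_time")
  expect_error(fr_params(1, 0.1, 0), "duration")
  expect_error(rogers_expected(fr_params(1, 0.1), -5), "n0")
  expect_error(rogers_expected_bisect(fr_params(1, 0.1), 5, tol = -1), "tol")
})
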