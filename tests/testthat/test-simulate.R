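test_that("generated tables follow the cage design and are reproducible", {
  cells <- fr_reference_params()[1:2, ]
  tab <- fr_simulate(cells, seed = 5)
  expect_s3_class(tab, "fr_trials")
  expect_equal(nrow(tab), 2 * 7 * 10)      # 70 cages per cell
  counts <- table(tab$distribution, tab$density)
  expect_true(all(counts == 10))
  expect_true(all(tab$killed <= tab$density))
  expect_identical(fr_simulate(cells, seed = 5), tab)     # same seed
  tab2 <- fr_simulate(cells, seed = 6)
  expect_false(identical(tab2$killed, tab$killed))        # different seed
})

test_that("per-cell streams are unaffected by adding another cell", {
  ref <- fr_reference_params()
  one <- fr_simulate(ref[1, ], seed = 9)
  three <- fr_simulate(ref[1:3, ], seed = 9)
  first <- three[three$enemy == one$enemy[1] &
                   three$distribution == one$distribution[1], ]
  expect_equal(first$killed, one$killed)
})

test_that("zero attack rate generates all-zero kills", {
  cells <- data.frame(enemy = "predator_single", distribution = "aggregate",
                      attack_rate = 0, handling_time = 0.01)
  tab <- fr_simulate(cells, seed = 1)
  expect_true(all(tab$killed == 0))
})

test_that("sample means track the Rogers expectation (Monte Carlo)", {
  ref <- fr_reference_params()[1, ]
  tab <- fr_simulate(ref, replicates = 1000, seed = 21)
  p <- fr_params(ref$attack_rate, ref$handling_time, 1)
  for (n0 in unique(tab$density)) {
    ne <- rogers_expected(p, n0)
    se <- sqrt(n0 * (ne / n0) * (1 - ne / n0) / 1000)
    obs <- mean(tab$killed[tab$density == n0])
    expect_lt(abs(obs - ne), 3 * se + 1e-9)
  }
})

test_that("mechanistic foraging process respects caps and matches the mean", {
  p <- fr_params(0, 0.5, 24)
  expect_true(all(fr_simulate_process(p, 10, seed = 1, n = 20) == 0))
  # handling time equal to the whole exposure: the capture-count cap
  # 1 + floor(T/Th) allows at most 2, and handling always consumes the
  # remaining clock after the first capture
  p2 <- fr_params(5, 24, 24)
  k <- fr_simulate_process(p2, 50, seed = 2, n = 200)
  expect_true(all(k <= 2))
  expect_true(any(k == 1))
  # a handling time just under half the exposure leaves room for a second
  # capture whose own handling spills past the clock but still counts
  p2b <- fr_params(50, 11, 24)
  k2 <- fr_simulate_process(p2b, 50, seed = 2, n = 200)
  expect_true(all(k2 <= 3))
  expect_true(any(k2 >= 2))
  # renewal-process mean tracks the deterministic depletion solution
  p3 <- fr_params(0.1, 0.5, 24)
  k3 <- fr_simulate_process(p3, 64, seed = 9, n = 10000)
  expect_lt(abs(mean(k3) - rogers_expected(p3, 64)) / rogers_expected(p3, 64),
            0.05)
  # reproducibility and zero-handling guard
  expect_identical(fr_simulate_process(p3, 64, seed = 4, n = 5),
                   fr_simulate_process(p3, 64, seed = 4, n = 5))
  expect_error(fr_simulate_process(fr_params(1, 0, 1), 10), "max_captures")
})

test_that("type III generator produces a rising-then-falling kill proportion", {
  expect_true(all(fr_simulate_type3(0, 0.01, seed = 3)$killed == 0))
  # expectations on the density grid: proportion at the smallest density is
  # below the proportion at an intermediate density
  prop <- function(n0) rogers_expected(fr_params(0.005 * n0, 0.01, 1), n0) / n0
  expect_lt(prop(4), prop(64))
  expect_gt(prop(64), prop(4))
  tab <- fr_simulate_type3(0.005, 0.01, replicates = 200, seed = 3)
  obs <- tapply(tab$killed / tab$density, tab$density, mean)
  expect_lt(obs[["4"]], obs[["64"]])
})

test_that("logistic-normal generator matches its stated moments", {
  # all-zero coefficients, no random effect: p = 1/2 everywhere
  tab <- fr_simulate_olre(c(0, 0, 0, 0), 0, seed = 4, replicates = 5)
  expect_true(all(tab$killed <= tab$density))
  # intercept -2 only: mean proportion ~ plogis(-2) over many cages
  tab2 <- fr_simulate_olre(c(-2, 0, 0, 0), 0, seed = 5, replicates = 400)
  expect_equal(mean(tab2$killed / tab2$density), plogis(-2), tolerance = 0.02)
  # larger olre_sd inflates the variance of observed proportions
  v <- vapply(c(0, 0.5, 1.5), function(s) {
    t3 <- fr_simulate_olre(c(0, 0, 0, 0), s, seed = 6, replicates = 300,
                           densities = 64)
    var(t3$killed / t3$density)
  }, numeric(1))
  expect_true(all(diff(v) > 0))
  expect_error(fr_simulate_olre(c(0, 0), 0.5, seed = 1), "length 4")
})

test_that("trial-table validation names offending rows and labels", {
  df <- data.frame(density = c(4, 8, 16), killed = c(1, 9, 2),
                   distribution = "aggregate", enemy = "predator_single",
                   replicate = 1:3)
  expect_error(fr_trials(df), "row\\(s\\): 2")
  df$killed <- c(1, 2, 3)
  df$distribution <- c("aggregate", "clumped", "uniform")
  expect_error(fr_trials(df), "distribution")
  expect_error(fr_trials(df[0, ]), "")
})
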