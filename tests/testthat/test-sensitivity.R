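test_that("one-way bounds follow the kind-specific ranges with clipping", {
  expect_equal(one_way_bounds(0.88, "utility"), c(0.792, 0.968))
  expect_equal(one_way_bounds(5000, "cost"), c(3500, 6500))
  expect_equal(one_way_bounds(0.2, "probability"), c(0.14, 0.26))
  expect_equal(one_way_bounds(0.95, "utility"), c(0.855, 1))  # clipped
  expect_equal(one_way_bounds(0.9, "probability"), c(0.63, 1))
  expect_equal(one_way_bounds(0.05, "discount"), c(0.03, 0.07))
  expect_error(one_way_bounds(1, "weather"), "unknown parameter kind")
})

test_that("a parameter with no influence produces a zero-width tornado bar", {
  inp <- fixture_inputs()
  # single-agent rituximab is costed but not part of any modelled pathway
  entry <- one_way(inp, "cost.drug_rituximab",
                   pairwise_outcome("RT+CVP", "RT", "inmb"))
  expect_equal(entry$bar_width, 0)
})

test_that("tornado entries are sorted and bracket the base case for monotone parameters", {
  inp <- fixture_inputs()
  outcome <- pairwise_outcome("RT+R-CVP", "RT", "inmb", wtp = 50000)
  base <- outcome(inp)
  params <- fl_sa_parameters(inp)[c("cost.asct", "utility.u_ffs",
                                    "p.RT.progression",
                                    "cost.drug_rcvp")]
  tor <- tornado(inp, outcome, params)
  expect_true(all(diff(tor$bar_width) <= 0))
  for (i in seq_len(nrow(tor))) {
    lo <- min(tor$outcome_at_low[i], tor$outcome_at_high[i])
    hi <- max(tor$outcome_at_low[i], tor$outcome_at_high[i])
    expect_lte(lo, base + 1e-9)
    expect_gte(hi, base - 1e-9)
  }
  expect_error(one_way(inp, "cost.helicopter", identity),
               "unknown parameter name")
})

test_that("gamma fits hit the requested mean analytically and by sampling", {
  g <- fit_gamma(5000, 0.30)
  expect_equal(g$shape / g$rate, 5000, tolerance = 1e-12)  # analytic mean
  expect_equal(g$sd, 0.30 * 5000 / 1.96)
  expect_equal(g$sd, 765.3061, tolerance = 1e-4)
  expect_equal(g$shape, (1.96 / 0.30)^2, tolerance = 1e-12)
  expect_equal(g$shape, 42.68444, tolerance = 1e-4)
  set.seed(42)
  draws <- rgamma(1e5, shape = g$shape, rate = g$rate)
  se <- g$sd / sqrt(1e5)
  expect_lt(abs(mean(draws) - 5000), 3 * se)
  expect_error(fit_gamma(0), "positive")
  expect_error(fit_gamma(-5), "positive")
})

test_that("beta fits hit the requested mean with a feasible variance", {
  b <- fit_beta(0.5, 0.30)
  expect_equal(b$shape1, b$shape2)  # symmetric at mean 0.5
  b2 <- fit_beta(0.88, 0.10)
  expect_equal(b2$shape1 / (b2$shape1 + b2$shape2), 0.88,
               tolerance = 1e-9)
  expect_equal(b2$sd, 0.10 * 0.88 / 1.96)
  expect_equal(b2$sd, 0.04490, tolerance = 1e-4)
  set.seed(43)
  draws <- rbeta(1e5, b2$shape1, b2$shape2)
  expect_lt(abs(mean(draws) - 0.88), 3 * b2$sd / sqrt(1e5))
  # infeasible spreads are capped below the bernoulli variance bound
  b3 <- fit_beta(0.97, 0.30)
  expect_lt(b3$sd^2, 0.97 * 0.03)
  expect_gt(b3$shape1, 0)
  expect_gt(b3$shape2, 0)
  expect_error(fit_beta(0), "strictly in")
  expect_error(fit_beta(1), "strictly in")
})

test_that("zero spreads collapse the PSA onto the base case", {
  inp <- fixture_inputs()
  psa <- run_psa(inp, n_iter = 3, seed = 7, spread_cost = 0,
                 spread_prob = 0, spread_util = 0)
  base <- run_all_strategies(inp)
  for (s in fl_strategies()) {
    expect_equal(psa$samples[[paste0("cost_", s)]],
                 rep(base[[s]]$discounted_cost, 3))
    expect_equal(psa$samples[[paste0("qaly_", s)]],
                 rep(base[[s]]$discounted_qaly, 3))
  }
  expect_equal(psa$rejections, 0L)
})

test_that("a fixed seed reproduces the PSA sample set exactly", {
  inp <- fixture_inputs()
  a <- run_psa(inp, n_iter = 5, seed = 11)
  b <- run_psa(inp, n_iter = 5, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$params, b$params)
  c <- run_psa(inp, n_iter = 5, seed = 12)
  expect_false(identical(a$params, c$params))
})

test_that("PSA parameter means converge on the fitted means", {
  inp <- fixture_inputs()
  psa <- run_psa(inp, n_iter = 1000, seed = 3)
  defs <- fl_sa_parameters(inp)
  # spot-check one parameter of each distribution family at 4 SE
  for (nm in c("cost.asct", "utility.u_ffs", "p.RT.progression")) {
    base <- defs[[nm]]$get(inp)
    draws <- psa$params[, nm]
    expect_lt(abs(mean(draws) - base), 4 * sd(draws) / sqrt(1000))
  }
  # sampled probabilities and utilities stay in [0, 1], costs positive
  expect_true(all(psa$params[, grepl("^p\\.", colnames(psa$params))] >= 0 &
                  psa$params[, grepl("^p\\.", colnames(psa$params))] <= 1))
  expect_true(all(psa$params[, grepl("^cost\\.", colnames(psa$params))] > 0))
})

test_that("quadrant fractions are exact for a constructed two-point sample", {
  costs <- cbind(ref = c(100, 100), alt = c(50, 150))
  qalys <- cbind(ref = c(1, 1), alt = c(2, 0.5))
  psa <- fake_psa(costs, qalys)
  q <- quadrant_summary(psa, c("alt", "ref"), wtp = 100)
  expect_equal(q$lower_right, 0.5)   # cheaper, more effective
  expect_equal(q$upper_left, 0.5)    # dearer, less effective
  expect_equal(q$upper_right + q$lower_left, 0)
  expect_equal(q$upper_right + q$lower_right + q$upper_left +
               q$lower_left, 1)
  expect_equal(q$cost_effective, 0.5)
  expect_error(quadrant_summary(psa, c("x", "y")), "no PSA samples")
})

test_that("an all-dominant sample set lands entirely in the lower-right quadrant", {
  costs <- cbind(ref = rep(100, 4), alt = rep(60, 4))
  qalys <- cbind(ref = rep(1, 4), alt = rep(1.5, 4))
  q <- quadrant_summary(fake_psa(costs, qalys), c("alt", "ref"), 50000)
  expect_equal(q$lower_right, 1)
  expect_equal(q$cost_effective, 1)
})

test_that("CEAC probabilities are normalised and step at the pairwise ICER", {
  # deterministic draws: ICER of alt vs ref = (150-100)/(2-1) = 50
  costs <- cbind(ref = rep(100, 3), alt = rep(150, 3))
  qalys <- cbind(ref = rep(1, 3), alt = rep(2, 3))
  psa <- fake_psa(costs, qalys)
  cc <- ceac(psa, wtp_grid = c(0, 25, 49, 51, 100))
  expect_equal(rowSums(cc[, c("ref", "alt")]), rep(1, 5))
  expect_equal(cc$alt, c(0, 0, 0, 1, 1))
  # exact tie at wtp = 50 splits equally
  tie <- ceac(psa, wtp_grid = 50)
  expect_equal(tie$alt, 0.5)
  # single strategy: probability one everywhere
  solo <- fake_psa(cbind(only = c(10, 20)), cbind(only = c(1, 2)))
  cc1 <- ceac(solo, wtp_grid = c(0, 50000))
  expect_equal(cc1$only, c(1, 1))
  expect_error(ceac(psa, wtp_grid = numeric(0)), "non-empty")
})

test_that("the CEAC of a strictly dominant strategy rises toward one", {
  set.seed(9)
  n <- 200
  costs <- cbind(ref = rnorm(n, 100, 5), alt = rnorm(n, 80, 5))
  qalys <- cbind(ref = rnorm(n, 1, 0.05), alt = rnorm(n, 1.5, 0.05))
  cc <- ceac(fake_psa(costs, qalys), wtp_grid = seq(0, 2000, 250))
  expect_true(all(diff(cc$alt) >= -1e-12))
  expect_equal(cc$alt[nrow(cc)], 1)
})
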