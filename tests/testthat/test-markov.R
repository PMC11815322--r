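test_that("zero rates and zero background mortality give the identity matrix", {
  inp <- degenerate_inputs()
  M <- build_transition_matrix(inp$rates[["RT"]], inp, 0)
  expect_equal(unname(M), diag(6), ignore_attr = TRUE)
})

test_that("competing exits split the total leaving probability by rate", {
  # closed-form competing-exponential oracle
  r_prog <- 0.04; r_trans <- 0.01; r_die <- 0.005; r_bg <- 0.01
  qx <- 1 - exp(-r_bg)
  inp <- degenerate_inputs(qx = qx)
  rates <- list(progression = r_prog, transformation = r_trans,
                death_disease = r_die)
  M <- build_transition_matrix(rates, inp, 0)
  total <- r_prog + r_trans + r_die + r_bg
  p_exit <- 1 - exp(-total * 0.5)
  expect_equal(p_exit, 0.03198, tolerance = 1e-3)
  expect_equal(M["FFS", "FAILURE"], p_exit * r_prog / total)
  # age 50 < 65: the transforming fraction routes to POST_ASCT
  expect_equal(M["FFS", "POST_ASCT"], p_exit * r_trans / total)
  expect_equal(M["FFS", "TRANSFORMATION"], 0)
  expect_equal(M["FFS", "DEATH_DISEASE"], p_exit * r_die / total)
  expect_equal(M["FFS", "DEATH_BACKGROUND"], p_exit * r_bg / total)
  expect_equal(unname(rowSums(M)), rep(1, 6))
})

test_that("the ASCT age gate redirects transformation at the cut-off", {
  qx <- 0.01
  inp <- degenerate_inputs(config = fl_model_config(start_age = 60),
                           qx = qx)
  rates <- list(progression = 0, transformation = 0.02, death_disease = 0)
  # cycle 9: age 64.5 (< 65) -> ASCT; cycle 10: age 65 -> no ASCT
  M_young <- build_transition_matrix(rates, inp, 9)
  M_old <- build_transition_matrix(rates, inp, 10)
  expect_gt(M_young["FFS", "POST_ASCT"], 0)
  expect_equal(M_young["FFS", "TRANSFORMATION"], 0)
  expect_equal(M_old["FFS", "POST_ASCT"], 0)
  expect_gt(M_old["FFS", "TRANSFORMATION"], 0)
})

test_that("every fixture matrix is row-stochastic to 1e-10", {
  inp <- fixture_inputs()
  for (s in fl_strategies()) {
    for (M in fl_build_matrices(inp, s)) {
      expect_true(all(abs(rowSums(M) - 1) < 1e-10))
      expect_true(all(M >= 0 & M <= 1))
      # death rows are identity rows
      expect_equal(unname(M["DEATH_DISEASE", ]), c(0, 0, 0, 0, 1, 0))
      expect_equal(unname(M["DEATH_BACKGROUND", ]), c(0, 0, 0, 0, 0, 1))
    }
  }
})

test_that("cohort propagation matches the two-state closed form", {
  # constant exit probability p per cycle: FFS occupancy = (1 - p)^t
  rates <- list(progression = 0.08, transformation = 0, death_disease = 0)
  inp <- degenerate_inputs()
  mats <- lapply(0:29, function(t) build_transition_matrix(rates, inp, t))
  cohort <- run_cohort(mats)
  p <- 1 - exp(-0.08 * 0.5)
  expect_equal(cohort$trace[, "FFS"], (1 - p)^(0:30))
  # the first-entry ledger records exactly the FFS outflow
  expect_equal(cohort$entries[, "FAILURE"], (1 - p)^(0:29) * p)
  expect_equal(rowSums(cohort$entries), (1 - p)^(0:29) * p)
})

test_that("identity matrices freeze the cohort in FFS", {
  inp <- degenerate_inputs()
  cohort <- run_cohort(fl_build_matrices(inp, "RT"))
  expect_equal(cohort$trace[, "FFS"], rep(1, 31))
  expect_equal(sum(cohort$entries), 0)
})

test_that("fixture traces conserve mass with monotone FFS and death occupancy", {
  inp <- fixture_inputs()
  for (s in fl_strategies()) {
    cohort <- run_cohort(fl_build_matrices(inp, s))
    expect_true(all(abs(rowSums(cohort$trace) - 1) < 1e-10))
    expect_true(all(cohort$trace >= -1e-15))
    expect_true(all(diff(cohort$trace[, "FFS"]) <= 1e-15))
    death <- cohort$trace[, "DEATH_DISEASE"] +
      cohort$trace[, "DEATH_BACKGROUND"]
    expect_true(all(diff(death) >= -1e-15))
  }
})

test_that("zero utilities and costs accumulate to exactly zero", {
  inp <- degenerate_inputs(costs = zero_cost_inputs(),
                           utilities = fl_utility_inputs(
                             u_ffs = 0, u_progressed = 0, d_rt = 0,
                             d_systemic = 0, d_asct = 0))
  res <- run_strategy(inp, "RT")
  expect_equal(res$discounted_cost, 0)
  expect_equal(res$discounted_qaly, 0)
})

test_that("an absorbing FFS cohort accrues u * horizon undiscounted QALYs", {
  inp <- degenerate_inputs(config = fl_model_config(discount_rate = 0),
                           costs = zero_cost_inputs(),
                           utilities = zero_disutility())
  res <- run_strategy(inp, "RT")
  expect_equal(res$discounted_qaly, 0.88 * 15)
  expect_equal(res$undiscounted_qaly, 0.88 * 15)
})

test_that("discounted QALYs match an independent brute-force summation", {
  inp <- degenerate_inputs(costs = zero_cost_inputs(),
                           utilities = zero_disutility())
  res <- run_strategy(inp, "RT")
  oracle <- 0
  for (t in 0:29) oracle <- oracle + 0.88 * 0.5 * 1.05^(-(t + 0.5) * 0.5)
  expect_equal(res$discounted_qaly, oracle)
})

test_that("front-line one-offs reproduce hand-computed strategy costs", {
  # no disease, no background death, no discounting: cost is the
  # front-line course plus the (here zero) adverse-event expectation
  inp <- degenerate_inputs(config = fl_model_config(discount_rate = 0))
  expect_equal(run_strategy(inp, "RT")$discounted_cost, 8238.20)
  expect_equal(run_strategy(inp, "RT+CVP")$discounted_cost,
               8238.20 + 2159.88)
  expect_equal(run_strategy(inp, "RT+R-CVP")$discounted_cost,
               8238.20 + 5531.88)
  # nonzero adverse-event incidence adds its expected cost in cycle 1
  inp$ae_incidence[["RT"]] <- list(admission = 0.1, g4_neutropenia = 0.2)
  expect_equal(run_strategy(inp, "RT")$discounted_cost,
               8238.20 + 0.1 * 5000 + 0.2 * 142)
})

test_that("identical rates and zero treatment costs make strategies identical", {
  inp <- degenerate_inputs(costs = zero_cost_inputs(),
                           utilities = zero_disutility(),
                           qx = 0.01)
  rates <- list(progression = 0.04, transformation = 0.01,
                death_disease = 0.005)
  inp$rates <- list("RT" = rates, "RT+CVP" = rates, "RT+R-CVP" = rates)
  res <- run_all_strategies(inp)
  for (s in c("RT+CVP", "RT+R-CVP")) {
    expect_equal(res[[s]]$discounted_cost, res[["RT"]]$discounted_cost)
    expect_equal(res[[s]]$discounted_qaly, res[["RT"]]$discounted_qaly)
  }
})

test_that("half-cycle QALYs lie strictly between start- and end-of-cycle accounting", {
  inp <- fixture_inputs()
  for (s in c("RT", "RT+R-CVP")) {
    cohort <- run_cohort(fl_build_matrices(inp, s))
    q_half <- fl_accumulate(cohort, s, inp)$discounted_qaly
    q_start <- fl_accumulate(cohort, s, inp,
                             occupancy = "cycle_start")$discounted_qaly
    q_end <- fl_accumulate(cohort, s, inp,
                           occupancy = "cycle_end")$discounted_qaly
    expect_lt(q_half, q_start)  # occupancy of valued states is falling
    expect_gt(q_half, q_end)
    expect_equal(q_half, (q_start + q_end) / 2)
  }
})

test_that("discounted outcomes are non-increasing in the discount rate", {
  inp <- fixture_inputs()
  rates <- c(0, 0.03, 0.05, 0.07, 0.10)
  for (s in fl_strategies()) {
    out <- sapply(rates, function(r) {
      inp$config$discount_rate <- r
      res <- run_strategy(inp, s)
      c(res$discounted_cost, res$discounted_qaly)
    })
    expect_true(all(diff(out[1, ]) < 0))
    expect_true(all(diff(out[2, ]) < 0))
  }
  # discounted never exceeds undiscounted at positive rates
  res <- run_strategy(inp, "RT")
  expect_lte(res$discounted_cost, res$undiscounted_cost)
  expect_lte(res$discounted_qaly, res$undiscounted_qaly)
})

test_that("unknown strategies and malformed traces are rejected", {
  inp <- fixture_inputs()
  expect_error(run_strategy(inp, "chemo-only"), "unknown strategy")
  expect_error(run_cohort(list(diag(5))), "dimensions")
  expect_error(run_cohort(fl_build_matrices(inp, "RT"),
                          initial = c(1, 0)), "one entry per state")
})
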