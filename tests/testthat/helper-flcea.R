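# Shared fixtures: all built in code, no files beyond the shipped
# parameter fixture.

fixture_inputs <- function() {
  read_params(system.file("extdata", "params.yaml", package = "flcea"))
}

# Inputs with no disease events, no background mortality, no costs other
# than those passed through: isolates single mechanisms.
degenerate_inputs <- function(config = fl_model_config(),
                              costs = fl_cost_inputs(),
                              utilities = fl_utility_inputs(),
                              post_failure_death_rate = 0,
                              qx = 0) {
  arms <- list(
    "RT"       = fl_trial_arm("RT", 10, 0, 0, 0),
    "RT+CVP"   = fl_trial_arm("RT+CVP", 10, 0, 0, 0),
    "RT+R-CVP" = fl_trial_arm("RT+R-CVP", 10, 0, 0, 0))
  lt <- fl_life_table(data.frame(age = 40:90, sex = config$sex, qx = qx))
  fl_inputs(config = config, costs = costs, utilities = utilities,
            arms = arms, life_table = lt,
            ae_incidence = list(
              "RT" = list(admission = 0, g4_neutropenia = 0),
              "RT+CVP" = list(admission = 0, g4_neutropenia = 0),
              "RT+R-CVP" = list(admission = 0, g4_neutropenia = 0)),
            post_failure_death_rate = post_failure_death_rate)
}

zero_cost_inputs <- function() {
  fl_cost_inputs(rt_simulation = 0, rt_planning = 0, rt_fraction = 0,
                 rt_verification = 0, rt_n_fractions = 0, drug_cvp = 0,
                 drug_rcvp = 0, drug_rchop = 0, drug_rituximab = 0,
                 day_care = 0, n_cycles_systemic = 0, asct = 0,
                 ae_admission = 0, pegfilgrastim = 0)
}

zero_disutility <- function(u_ffs = 0.88, u_progressed = 0.74) {
  fl_utility_inputs(u_ffs = u_ffs, u_progressed = u_progressed,
                    d_rt = 0, d_systemic = 0, d_asct = 0)
}

# Published base-case per-strategy (cost, QALY) pairs, used as inputs to
# worked-example incremental arithmetic.
published_results <- function() {
  data.frame(strategy = c("RT", "RT+CVP", "RT+R-CVP"),
             cost = c(43994, 51996, 32043),
             qaly = c(7.520, 7.699, 8.231))
}

# Minimal fl_psa-shaped object for quadrant/CEAC unit tests.
fake_psa <- function(costs, qalys, strategies = colnames(costs)) {
  n <- nrow(costs)
  samples <- data.frame(iter = seq_len(n))
  for (s in strategies) {
    samples[[paste0("cost_", s)]] <- costs[, s]
    samples[[paste0("qaly_", s)]] <- qalys[, s]
  }
  pairs <- list()
  if (length(strategies) >= 2) {
    for (s in strategies[-1]) {
      key <- paste0(s, "_vs_", strategies[1])
      samples[[paste0("dcost_", key)]] <- costs[, s] - costs[, 1]
      samples[[paste0("dqaly_", key)]] <- qalys[, s] - qalys[, 1]
      pairs <- c(pairs, list(c(s, strategies[1])))
    }
  }
  structure(list(samples = samples, params = NULL, pairs = pairs,
                 strategies = strategies, rejections = 0L, seed = NA),
            class = "fl_psa")
}
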