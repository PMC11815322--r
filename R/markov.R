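# Markov cohort engine: per-cycle transition matrices, cohort propagation
# with a first-entry ledger, and half-cycle-corrected discounted rewards.

#' Build one per-cycle transition matrix
#'
#' From FFS, progression, transformation, disease death and background
#' death compete as constant hazards within the cycle: the total leaving
#' probability is `1 - exp(-(sum of rates) * dt)`, apportioned among
#' destinations in proportion to their rates (exact for competing
#' exponentials, and row-stochastic for any rates). The transforming
#' fraction routes to `POST_ASCT` when the cohort is younger than the ASCT
#' age limit at the start of the cycle, otherwise to `TRANSFORMATION`.
#' From the three post-failure states only death transitions apply
#' (post-failure disease death competing with background mortality); the
#' death states are absorbing.
#'
#' @param rates Named list of per-annum rates `progression`,
#'   `transformation`, `death_disease` out of FFS.
#' @param inputs An [fl_inputs()] object (life table, config, post-failure
#'   death rate, ASCT age limit).
#' @param cycle_index Zero-based cycle number; the cohort age at cycle
#'   start is `start_age + cycle_index * cycle_length`.
#' @return A 6x6 row-stochastic matrix over [fl_states()], with attributes
#'   `cycle_index` and `age`.
#' @export
build_transition_matrix <- function(rates, inputs, cycle_index) {
  cfg <- inputs$config
  dt <- cfg$cycle_length
  age <- cfg$start_age + cycle_index * dt
  states <- fl_states()
  M <- matrix(0, 6, 6, dimnames = list(states, states))

  qx <- lookup_qx(inputs$life_table, age, cfg$sex)
  r_bg <- probability_to_rate(min(qx, 1 - 1e-15), 1)

  # FFS row: four competing exit hazards
  r_exit <- c(prog = rates$progression, trans = rates$transformation,
              dis = rates$death_disease, bg = r_bg)
  total <- sum(r_exit)
  if (total > 0) {
    p_exit <- rate_to_probability(total, dt)
    split <- p_exit * r_exit / total
    trans_dest <- if (age < inputs$asct_age_limit) "POST_ASCT"
                  else "TRANSFORMATION"
    M["FFS", "FAILURE"] <- split[["prog"]]
    M["FFS", trans_dest] <- split[["trans"]]
    M["FFS", "DEATH_DISEASE"] <- split[["dis"]]
    M["FFS", "DEATH_BACKGROUND"] <- split[["bg"]]
  }
  M["FFS", "FFS"] <- 1 - sum(M["FFS", -1])

  # Post-failure states: disease death competes with background death
  r_pf <- c(dis = inputs$post_failure_death_rate, bg = r_bg)
  tot_pf <- sum(r_pf)
  for (s in c("FAILURE", "TRANSFORMATION", "POST_ASCT")) {
    if (tot_pf > 0) {
      p_exit <- rate_to_probability(tot_pf, dt)
      M[s, "DEATH_DISEASE"] <- p_exit * r_pf[["dis"]] / tot_pf
      M[s, "DEATH_BACKGROUND"] <- p_exit * r_pf[["bg"]] / tot_pf
    }
    M[s, s] <- 1 - M[s, "DEATH_DISEASE"] - M[s, "DEATH_BACKGROUND"]
  }

  M["DEATH_DISEASE", "DEATH_DISEASE"] <- 1
  M["DEATH_BACKGROUND", "DEATH_BACKGROUND"] <- 1

  if (any(abs(rowSums(M) - 1) > 1e-10) || any(M < 0) || any(M > 1))
    stop("internal error: transition matrix is not row-stochastic",
         call. = FALSE)
  attr(M, "cycle_index") <- cycle_index
  attr(M, "age") <- age
  M
}

#' Build the full sequence of per-cycle matrices for one strategy
#'
#' @param inputs An [fl_inputs()] object.
#' @param strategy One of [fl_strategies()] (must name an arm in
#'   `inputs$rates`).
#' @return List of `n_cycles` transition matrices.
#' @export
fl_build_matrices <- function(inputs, strategy) {
  rates <- inputs$rates[[strategy]]
  if (is.null(rates)) stop("unknown strategy: ", strategy, call. = FALSE)
  lapply(seq_len(inputs$config$n_cycles) - 1L,
         function(t) build_transition_matrix(rates, inputs, t))
}

#' Propagate a unit cohort through the cycle matrices
#'
#' Row `t+1` of the trace is row `t` times matrix `t`. Alongside the
#' occupancy trace a first-entry ledger records, for each cycle, the
#' cohort fraction newly entering `FAILURE`, `TRANSFORMATION` and
#' `POST_ASCT` — the hook on which one-off retreatment costs and the ASCT
#' disutility attach.
#'
#' @param matrices List of transition matrices from [fl_build_matrices()].
#' @param initial Initial distribution over [fl_states()]; defaults to
#'   100% FFS.
#' @return An `fl_cohort` list: `trace` ((n_cycles+1) x 6 occupancy
#'   matrix) and `entries` (n_cycles x 3 inflow matrix).
#' @export
run_cohort <- function(matrices, initial = NULL) {
  states <- fl_states()
  n <- length(matrices)
  if (is.null(initial)) {
    initial <- stats::setNames(numeric(6), states)
    initial["FFS"] <- 1
  }
  if (length(initial) != 6)
    stop("`initial` must have one entry per state", call. = FALSE)
  entry_states <- c("FAILURE", "TRANSFORMATION", "POST_ASCT")
  trace <- matrix(NA_real_, n + 1, 6, dimnames = list(NULL, states))
  entries <- matrix(0, n, 3, dimnames = list(NULL, entry_states))
  trace[1, ] <- initial
  for (t in seq_len(n)) {
    M <- matrices[[t]]
    if (!all(dim(M) == c(6, 6)))
      stop("transition matrix ", t, " has wrong dimensions", call. = FALSE)
    x <- trace[t, ]
    trace[t + 1, ] <- x %*% M
    for (s in entry_states)  # inflow from other states only (no re-entry)
      entries[t, s] <- sum(x[states != s] * M[states != s, s])
    if (abs(sum(trace[t + 1, ]) - 1) > 1e-10)
      stop("cohort mass not conserved at cycle ", t, call. = FALSE)
  }
  structure(list(trace = trace, entries = entries), class = "fl_cohort")
}

# Front-line therapy applied to the whole cohort in the first cycle:
# one-off cost (RT course, systemic regimen, expected adverse-event cost)
# and one-off QALY decrement (treatment disutilities x cycle length).
frontline_oneoff <- function(strategy, inputs) {
  cs <- inputs$costs; ut <- inputs$utilities
  dt <- inputs$config$cycle_length
  rt_cost <- rt_course_cost(cs$rt_simulation, cs$rt_planning,
                            cs$rt_fraction, cs$rt_verification,
                            cs$rt_n_fractions)
  regimen <- switch(strategy,
    "RT"       = 0,
    "RT+CVP"   = regimen_total_cost(cs$drug_cvp, cs$day_care,
                                    cs$n_cycles_systemic),
    "RT+R-CVP" = regimen_total_cost(cs$drug_rcvp, cs$day_care,
                                    cs$n_cycles_systemic),
    stop("unknown strategy: ", strategy, call. = FALSE))
  inc <- inputs$ae_incidence[[strategy]]
  ae <- inc$admission * cs$ae_admission + inc$g4_neutropenia * cs$pegfilgrastim
  dis <- abs(ut$d_rt) * dt
  if (strategy != "RT") dis <- dis + abs(ut$d_systemic) * dt
  list(cost = rt_cost + regimen + ae, disutility_qaly = dis)
}

# Per-state utility weights used by both the cohort engine and the
# microsimulation oracle.
state_utilities <- function(utilities) {
  c(FFS = utilities$u_ffs, FAILURE = utilities$u_progressed,
    TRANSFORMATION = utilities$u_progressed,
    POST_ASCT = utilities$u_progressed,
    DEATH_DISEASE = 0, DEATH_BACKGROUND = 0)
}

# Discount factors for cycle indices 0..n-1: state rewards at mid-cycle,
# one-off flows at cycle start (switchable to mid-cycle).
discount_factors <- function(config, oneoff_timing = "cycle_start") {
  t <- seq_len(config$n_cycles) - 1
  dt <- config$cycle_length
  r <- config$discount_rate
  mid <- (1 + r)^(-(t + 0.5) * dt)
  start <- (1 + r)^(-t * dt)
  list(mid = mid,
       oneoff = if (oneoff_timing == "cycle_start") start else mid)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' State rewards (utility weight x time in state) use half-cycle-corrected
#' occupancy — the average of start- and end-of-cycle occupancy — and are
#' discounted at mid-cycle. One-off flows are exempt from the half-cycle
#' correction and attach to the first-entry ledger: front-line therapy
#' cost, expected adverse-event cost and treatment disutilities in the
#' first cycle; R-CHOP retreatment on first entry into FAILURE,
#' TRANSFORMATION or POST_ASCT; the ASCT cost and one-cycle disutility on
#' entry into POST_ASCT. One-off flows are discounted at cycle start by
#' default (switchable via `oneoff_timing`).
#'
#' @param cohort An `fl_cohort` from [run_cohort()].
#' @param strategy Strategy label (selects front-line cost and disutility
#'   schedule).
#' @param inputs An [fl_inputs()] object.
#' @param occupancy Occupancy accounting: `"half_cycle"` (default),
#'   `"cycle_start"` or `"cycle_end"` (the latter two exist to demonstrate
#'   that the half-cycle correction is bracketed by them).
#' @param oneoff_timing Discount timing for one-off flows.
#' @return An `fl_econ_result`: strategy, discounted and undiscounted cost
#'   and QALY.
#' @export
fl_accumulate <- function(cohort, strategy, inputs,
                          occupancy = c("half_cycle", "cycle_start",
                                        "cycle_end"),
                          oneoff_timing = c("cycle_start", "mid_cycle")) {
  occupancy <- match.arg(occupancy)
  oneoff_timing <- match.arg(oneoff_timing)
  cfg <- inputs$config; cs <- inputs$costs; ut <- inputs$utilities
  n <- cfg$n_cycles; dt <- cfg$cycle_length
  trace <- cohort$trace; entries <- cohort$entries

  occ <- switch(occupancy,
    half_cycle  = (trace[1:n, , drop = FALSE] +
                   trace[2:(n + 1), , drop = FALSE]) / 2,
    cycle_start = trace[1:n, , drop = FALSE],
    cycle_end   = trace[2:(n + 1), , drop = FALSE])

  u <- state_utilities(ut)
  qaly_state <- as.vector(occ %*% u[fl_states()]) * dt

  rchop <- regimen_total_cost(cs$drug_rchop, cs$day_care,
                              cs$n_cycles_systemic)
  cost_oneoff <- entries[, "FAILURE"] * rchop +
    entries[, "TRANSFORMATION"] * rchop +
    entries[, "POST_ASCT"] * (rchop + cs$asct)
  dis_oneoff <- entries[, "POST_ASCT"] * abs(ut$d_asct) * dt

  fl <- frontline_oneoff(strategy, inputs)
  cost_oneoff[1] <- cost_oneoff[1] + fl$cost
  dis_oneoff[1] <- dis_oneoff[1] + fl$disutility_qaly

  disc <- discount_factors(cfg, oneoff_timing)
  structure(list(
    strategy = strategy,
    discounted_cost = sum(cost_oneoff * disc$oneoff),
    discounted_qaly = sum(qaly_state * disc$mid) -
      sum(dis_oneoff * disc$oneoff),
    undiscounted_cost = sum(cost_oneoff),
    undiscounted_qaly = sum(qaly_state) - sum(dis_oneoff)
  ), class = "fl_econ_result")
}

#' Run one strategy end to end
#'
#' Composes [fl_build_matrices()], [run_cohort()] and [fl_accumulate()].
#'
#' @inheritParams fl_accumulate
#' @return An `fl_econ_result` with the cohort attached as attribute
#'   `"cohort"`.
#' @export
run_strategy <- function(inputs, strategy, ...) {
  cohort <- run_cohort(fl_build_matrices(inputs, strategy))
  res <- fl_accumulate(cohort, strategy, inputs, ...)
  attr(res, "cohort") <- cohort
  res
}

#' Run all strategies
#'
#' @param inputs An [fl_inputs()] object.
#' @param ... Passed to [fl_accumulate()].
#' @return Named list of `fl_econ_result`, one per arm in `inputs$arms`.
#' @export
run_all_strategies <- function(inputs, ...) {
  out <- lapply(names(inputs$arms), function(s) run_strategy(inputs, s, ...))
  stats::setNames(out, names(inputs$arms))
}

#' @export
print.fl_econ_result <- function(x, ...) {
  cat(sprintf("%s: cost $%.2f, %.4f QALYs (discounted)\n",
              x$strategy, x$discounted_cost, x$discounted_qaly))
  invisible(x)
}

#' Tabulate per-strategy results
#'
#' @param results List of `fl_econ_result` objects.
#' @return Data frame with one row per strategy.
#' @export
results_table <- function(results) {
  data.frame(
    strategy = vapply(results, `[[`, "", "strategy"),
    cost = vapply(results, `[[`, 0, "discounted_cost"),
    qaly = vapply(results, `[[`, 0, "discounted_qaly"),
    undiscounted_cost = vapply(results, `[[`, 0, "undiscounted_cost"),
    undiscounted_qaly = vapply(results, `[[`, 0, "undiscounted_qaly"),
    row.names = NULL
  )
}
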