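# Synthetic data: competing-exponential trial arms, parameter recovery,
# an individual-level microsimulation oracle for the cohort engine, and a
# synthetic life table.

#' Simulate one trial arm under competing exponential hazards
#'
#' Each patient is exposed to three competing constant hazards
#' (progression, transformation, death). The first event before the
#' administrative censoring time is recorded; patients with no event by
#' then are censored. With total hazard `L`, the expected number of first
#' events of type `k` by time `T` is `n * (lambda_k / L) * (1 - exp(-L T))`.
#'
#' @param n Number of patients.
#' @param hazards Named numeric of per-annum hazards `progression`,
#'   `transformation`, `death` (non-negative).
#' @param followup Administrative censoring time in years.
#' @param seed Integer seed for reproducibility.
#' @return An `fl_synthetic_arm` list: `patients` data frame (one row per
#'   patient: `event_type` of `"progression"`, `"transformation"`,
#'   `"death"` or `"censored"`, `event_time`, `censored` flag) and
#'   `counts` (named vector of event totals), plus the simulation spec.
#' @export
simulate_arm <- function(n, hazards, followup, seed = 1L) {
  stopifnot(n >= 1, followup > 0)
  hazards <- hazards[c("progression", "transformation", "death")]
  if (any(is.na(hazards)) || any(hazards < 0))
    stop("`hazards` must be named non-negative values for progression, ",
         "transformation and death", call. = FALSE)
  set.seed(seed)
  total <- sum(hazards)
  if (total == 0) {
    times <- rep(Inf, n)
    types <- rep(NA_integer_, n)
  } else {
    times <- stats::rexp(n, rate = total)
    types <- sample.int(3L, n, replace = TRUE, prob = hazards / total)
  }
  censored <- times > followup
  event_type <- ifelse(censored, "censored",
                       c("progression", "transformation", "death")[types])
  patients <- data.frame(
    id = seq_len(n),
    event_type = event_type,
    event_time = pmin(times, followup),
    censored = censored
  )
  counts <- c(progressions = sum(event_type == "progression"),
              transformations = sum(event_type == "transformation"),
              deaths = sum(event_type == "death"))
  structure(list(patients = patients, counts = counts, n = n,
                 hazards = hazards, followup = followup, seed = seed),
            class = "fl_synthetic_arm")
}

#' Recover per-annum hazards from simulated arm counts
#'
#' Applies the same person-time approximation the model uses on real
#' counts — events divided by `n * followup` — to a simulated arm,
#' closing the loop on the rate derivation. In the rare-event regime
#' (total hazard times follow-up small) the estimator converges to the
#' true hazard; at trial-like event rates it carries a documented
#' downward person-time bias (patients are counted as at risk for the
#' full follow-up even after their event).
#'
#' @param result An `fl_synthetic_arm` from [simulate_arm()].
#' @return Named list of estimated per-annum hazards `progression`,
#'   `transformation`, `death_disease`.
#' @export
recover_rates <- function(result) {
  stopifnot(inherits(result, "fl_synthetic_arm"))
  arm <- fl_trial_arm("synthetic", result$n,
                      result$counts[["progressions"]],
                      result$counts[["transformations"]],
                      result$counts[["deaths"]],
                      median_followup = result$followup)
  derive_arm_rates(arm)
}

#' Expected first-event counts under competing exponentials
#'
#' Closed form used as the oracle for [simulate_arm()]:
#' `n * (lambda_k / L) * (1 - exp(-L * T))` per event type.
#'
#' @inheritParams simulate_arm
#' @return Named numeric of expected counts.
#' @export
expected_event_counts <- function(n, hazards, followup) {
  total <- sum(hazards)
  if (total == 0)
    return(stats::setNames(numeric(3),
                           c("progressions", "transformations", "deaths")))
  stats::setNames(n * (hazards / total) * (1 - exp(-total * followup)),
                  c("progressions", "transformations", "deaths"))
}

#' Individual-level microsimulation of one strategy
#'
#' Pushes `n_patients` simulated individuals through the identical
#' per-cycle transition matrices the cohort engine uses, accumulating the
#' identical rewards: half-cycle state rewards (the average of the
#' start- and end-of-cycle state indicator plays the role of the averaged
#' occupancy), first-entry one-off costs and disutilities, and the same
#' discounting conventions. The mean cost and QALY therefore estimate the
#' cohort model's outputs exactly, with Monte-Carlo standard errors —
#' this is the package's independent validation oracle for the cohort
#' engine.
#'
#' @param inputs An [fl_inputs()] object.
#' @param strategy Strategy name.
#' @param n_patients Number of simulated individuals.
#' @param seed Integer seed.
#' @param oneoff_timing Discount timing for one-off flows, as in
#'   [fl_accumulate()].
#' @return List with `mean_cost`, `se_cost`, `mean_qaly`, `se_qaly`,
#'   `n_patients`.
#' @export
microsim <- function(inputs, strategy, n_patients = 1e5, seed = 1L,
                     oneoff_timing = c("cycle_start", "mid_cycle")) {
  oneoff_timing <- match.arg(oneoff_timing)
  set.seed(seed)
  cfg <- inputs$config
  n_cycles <- cfg$n_cycles
  dt <- cfg$cycle_length
  mats <- fl_build_matrices(inputs, strategy)
  u <- state_utilities(inputs$utilities)[fl_states()]
  disc <- discount_factors(cfg, oneoff_timing)

  cs <- inputs$costs
  rchop <- regimen_total_cost(cs$drug_rchop, cs$day_care,
                              cs$n_cycles_systemic)
  d_asct_qaly <- abs(inputs$utilities$d_asct) * dt

  cost <- numeric(n_patients)
  qaly <- numeric(n_patients)

  fl <- frontline_oneoff(strategy, inputs)
  cost <- cost + fl$cost * disc$oneoff[1]
  qaly <- qaly - fl$disutility_qaly * disc$oneoff[1]

  s <- rep(1L, n_patients)  # everyone starts in FFS
  for (t in seq_len(n_cycles)) {
    M <- mats[[t]]
    s_new <- s
    for (k in 1:4) {  # death states are absorbing; skip them
      idx <- which(s == k)
      if (length(idx))
        s_new[idx] <- sample.int(6L, length(idx), replace = TRUE,
                                 prob = M[k, ])
    }
    qaly <- qaly + (u[s] + u[s_new]) / 2 * dt * disc$mid[t]
    entered <- s_new != s
    to_fail <- entered & (s_new == 2L | s_new == 3L)
    to_asct <- entered & s_new == 4L
    cost <- cost + (to_fail * rchop + to_asct * (rchop + cs$asct)) *
      disc$oneoff[t]
    qaly <- qaly - to_asct * d_asct_qaly * disc$oneoff[t]
    s <- s_new
  }
  list(mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n_patients),
       mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n_patients),
       n_patients = n_patients)
}

#' Synthetic male life table
#'
#' Gompertz-like annual death probabilities
#' `qx(age) = min(1, base_qx * exp(annual_increase * (age - start_age)))`
#' over the modelled age range. Defaults emulate the magnitude of a
#' national male life table around age 50 (`qx` about 0.3% at 50, rising
#' roughly 9% per year of age). Synthetic: not actuarial data.
#'
#' @param start_age First tabulated age (table extends a little below and
#'   beyond the modelled range for safety).
#' @param horizon Years of follow-up the table must cover.
#' @param base_qx Annual death probability at `start_age`.
#' @param annual_increase Log-linear increase in `qx` per year of age.
#' @param sex Sex label for the table rows.
#' @return An `fl_life_table` data frame.
#' @export
fl_synthetic_life_table <- function(start_age = 50, horizon = 15,
                                    base_qx = 0.0032,
                                    annual_increase = 0.09,
                                    sex = "male") {
  if (base_qx <= 0 || base_qx >= 1)
    stop("`base_qx` must lie in (0, 1)", call. = FALSE)
  ages <- seq(floor(start_age) - 5, ceiling(start_age + horizon) + 5)
  ages <- ages[ages >= 0]
  qx <- pmin(1, base_qx * exp(annual_increase * (ages - start_age)))
  fl_life_table(data.frame(age = ages, sex = sex, qx = qx))
}
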