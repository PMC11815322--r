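#' Health states of the cohort model
#'
#' The model tracks six internal states: failure-free survival (`FFS`),
#' survival with relapsed/progressive disease (`FAILURE`), survival with
#' histologic transformation (`TRANSFORMATION`), survival after autologous
#' stem-cell transplant for transformation (`POST_ASCT`), and two absorbing
#' death states that separate death from disease (`DEATH_DISEASE`) from
#' background mortality (`DEATH_BACKGROUND`). Reporting may merge the two
#' death sources into a single "Death" column.
#'
#' @return Character vector of the six state names, in matrix order.
#' @export
fl_states <- function() {
  c("FFS", "FAILURE", "TRANSFORMATION", "POST_ASCT",
    "DEATH_DISEASE", "DEATH_BACKGROUND")
}

#' @rdname fl_states
#' @export
fl_alive_states <- function() fl_states()[1:4]

#' Strategy labels
#' @return Character vector of the three front-line strategies.
#' @export
fl_strategies <- function() c("RT", "RT+CVP", "RT+R-CVP")

#' Model run configuration
#'
#' @param cycle_length Cycle length in years (default 0.5, i.e. six-month
#'   cycles).
#' @param n_cycles Number of cycles (default 30, giving a 15-year horizon).
#' @param discount_rate Annual discount rate applied to costs and QALYs
#'   (default 0.05).
#' @param wtp Willingness-to-pay threshold in AUD per QALY (default 50000).
#' @param start_age Cohort age in years at model entry (default 50; the
#'   background-mortality reference group is males aged 50).
#' @param sex `"male"` or `"female"`, used for life-table lookup.
#' @param currency_year Year of the cost inputs (AUD 2022).
#' @return A `fl_model_config` list.
#' @export
fl_model_config <- function(cycle_length = 0.5, n_cycles = 30L,
                            discount_rate = 0.05, wtp = 50000,
                            start_age = 50, sex = c("male", "female"),
                            currency_year = 2022) {
  sex <- match.arg(sex)
  stopifnot(cycle_length > 0, n_cycles >= 1)
  if (discount_rate < 0 || discount_rate >= 1)
    stop("`discount_rate` must lie in [0, 1)", call. = FALSE)
  if (wtp <= 0) stop("`wtp` must be positive", call. = FALSE)
  structure(list(
    cycle_length = cycle_length,
    n_cycles = as.integer(n_cycles),
    horizon = cycle_length * n_cycles,
    discount_rate = discount_rate,
    wtp = wtp,
    start_age = start_age,
    sex = sex,
    currency_year = currency_year
  ), class = "fl_model_config")
}

#' Front-line therapy cost inputs (AUD, 2022)
#'
#' Defaults are the Australian payer unit costs for the modelled regimens:
#' an IMRT course of 15 fractions (simulation, dosimetry plan, treatment
#' and verification per fraction), per-cycle drug plus day-care costs for
#' CVP, R-CVP, R-CHOP and single-agent rituximab, the ASCT episode price,
#' and adverse-event costs (a 5-day admission for infection/febrile
#' neutropenia; pegfilgrastim for grade-4 neutropenia).
#'
#' @param rt_simulation,rt_planning,rt_fraction,rt_verification RT cost
#'   components; the fraction and verification costs apply per fraction.
#' @param rt_n_fractions Number of RT fractions (15).
#' @param drug_cvp,drug_rcvp,drug_rchop,drug_rituximab Drug cost per
#'   3-weekly treatment cycle.
#' @param day_care Day-care administration cost per treatment cycle.
#' @param n_cycles_systemic Number of systemic-therapy cycles (6).
#' @param asct Cost of an autologous stem-cell transplant episode.
#' @param ae_admission Cost of a grade 3/4 adverse-event admission.
#' @param pegfilgrastim Cost of pegfilgrastim for grade-4 neutropenia.
#' @return A `fl_cost_inputs` list.
#' @export
fl_cost_inputs <- function(rt_simulation = 739.35, rt_planning = 3448.10,
                           rt_fraction = 190.35, rt_verification = 79.70,
                           rt_n_fractions = 15L,
                           drug_cvp = 249.18, drug_rcvp = 811.18,
                           drug_rchop = 923.28, drug_rituximab = 562.00,
                           day_care = 110.80, n_cycles_systemic = 6L,
                           asct = 45638.63, ae_admission = 5000,
                           pegfilgrastim = 142) {
  vals <- c(rt_simulation, rt_planning, rt_fraction, rt_verification,
            rt_n_fractions, drug_cvp, drug_rcvp, drug_rchop, drug_rituximab,
            day_care, n_cycles_systemic, asct, ae_admission, pegfilgrastim)
  if (any(vals < 0)) stop("costs must be non-negative", call. = FALSE)
  structure(list(
    rt_simulation = rt_simulation, rt_planning = rt_planning,
    rt_fraction = rt_fraction, rt_verification = rt_verification,
    rt_n_fractions = as.integer(rt_n_fractions),
    drug_cvp = drug_cvp, drug_rcvp = drug_rcvp, drug_rchop = drug_rchop,
    drug_rituximab = drug_rituximab, day_care = day_care,
    n_cycles_systemic = as.integer(n_cycles_systemic),
    asct = asct, ae_admission = ae_admission,
    pegfilgrastim = pegfilgrastim
  ), class = "fl_cost_inputs")
}

#' Health-state utilities and treatment disutilities
#'
#' Utility weights are multiplied by time in state; disutilities are
#' decrements applied during the cycles in which the corresponding
#' treatment is delivered (and, for ASCT, the single cycle in which the
#' transplant is performed). Disutilities are stored as negative values.
#'
#' @param u_ffs Utility of failure-free survival (0.88).
#' @param u_progressed Utility after failure/transformation (0.74).
#' @param d_rt Radiotherapy disutility (-0.05).
#' @param d_systemic Systemic-therapy disutility (-0.15); adverse drug
#'   events are already reflected in this value.
#' @param d_asct ASCT disutility (-0.20), applied for one cycle.
#' @return A `fl_utility_inputs` list.
#' @export
fl_utility_inputs <- function(u_ffs = 0.88, u_progressed = 0.74,
                              d_rt = -0.05, d_systemic = -0.15,
                              d_asct = -0.20) {
  if (u_ffs < 0 || u_ffs > 1 || u_progressed < 0 || u_progressed > 1)
    stop("state utilities must lie in [0, 1]", call. = FALSE)
  if (any(c(d_rt, d_systemic, d_asct) > 0) ||
      any(c(d_rt, d_systemic, d_asct) < -1))
    stop("disutilities must lie in [-1, 0]", call. = FALSE)
  if (u_ffs + d_rt + d_systemic < 0 || u_progressed + d_asct < 0)
    stop("utility plus applicable disutility must be non-negative",
         call. = FALSE)
  structure(list(u_ffs = u_ffs, u_progressed = u_progressed,
                 d_rt = d_rt, d_systemic = d_systemic, d_asct = d_asct),
            class = "fl_utility_inputs")
}

#' Arm-level trial event counts
#'
#' Summarises one randomised arm as patient number and counts of first
#' events (progression, transformation, death) over a common median
#' follow-up, from which per-annum event rates are derived.
#'
#' @param name Strategy label.
#' @param n Patients randomised to the arm.
#' @param progressions,transformations,deaths First-event counts.
#' @param median_followup Median follow-up in years (11.3).
#' @return A `fl_trial_arm` list.
#' @export
fl_trial_arm <- function(name, n, progressions, transformations, deaths,
                         median_followup = 11.3) {
  counts <- c(progressions, transformations, deaths)
  if (n < 1) stop("arm size `n` must be at least 1", call. = FALSE)
  if (any(counts < 0) || any(counts > n))
    stop("event counts must lie in [0, n]", call. = FALSE)
  if (median_followup <= 0)
    stop("`median_followup` must be positive", call. = FALSE)
  structure(list(name = name, n = n, progressions = progressions,
                 transformations = transformations, deaths = deaths,
                 median_followup = median_followup),
            class = "fl_trial_arm")
}

#' Default three-arm trial data
#'
#' Event counts observed in the modelled randomised trial: 75 patients
#' treated with RT alone (38 progressions, 11 transformations, 13 deaths),
#' 44 with RT+CVP (22, 4, 5) and 31 with RT+R-CVP (5, 1, 1), at a median
#' follow-up of 11.3 years.
#'
#' @return Named list of three `fl_trial_arm` objects.
#' @export
fl_default_arms <- function() {
  list(
    "RT"       = fl_trial_arm("RT",       75, 38, 11, 13),
    "RT+CVP"   = fl_trial_arm("RT+CVP",   44, 22,  4,  5),
    "RT+R-CVP" = fl_trial_arm("RT+R-CVP", 31,  5,  1,  1)
  )
}

# ---- rate / probability algebra ------------------------------------------

#' Convert a constant event rate to a probability over an interval
#'
#' Under a constant hazard, the probability of the event occurring within
#' `dt` years is `1 - exp(-rate * dt)`.
#'
#' @param rate Event rate per person-year (non-negative).
#' @param dt Interval length in years (non-negative).
#' @return Probability in `[0, 1)`; vectorised over both arguments.
#' @export
rate_to_probability <- function(rate, dt) {
  if (any(rate < 0) || any(dt < 0))
    stop("`rate` and `dt` must be non-negative", call. = FALSE)
  1 - exp(-rate * dt)
}

#' Convert a probability over an interval back to a constant rate
#'
#' Inverse of [rate_to_probability()]: `rate = -log(1 - p) / dt`.
#'
#' @param p Probability in `[0, 1)`.
#' @param dt Interval length in years (positive).
#' @return Event rate per person-year.
#' @export
probability_to_rate <- function(p, dt) {
  if (any(p < 0) || any(p >= 1))
    stop("`p` must lie in [0, 1)", call. = FALSE)
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  -log(1 - p) / dt
}

#' Derive per-annum event rates from arm-level counts
#'
#' Rates are events per person-year, computed against the person-time
#' approximation `n * median_followup`. This treats every patient as
#' observed for the median follow-up; the resulting bias at trial-like
#' event rates is quantified by the parameter-recovery tests (see
#' [recover_rates()]).
#'
#' @param arm A [fl_trial_arm()] object.
#' @return Named list with per-annum rates `progression`,
#'   `transformation`, `death_disease`.
#' @export
derive_arm_rates <- function(arm) {
  stopifnot(inherits(arm, "fl_trial_arm"))
  person_years <- arm$n * arm$median_followup
  list(
    progression    = arm$progressions / person_years,
    transformation = arm$transformations / person_years,
    death_disease  = arm$deaths / person_years
  )
}

# ---- life table -----------------------------------------------------------

#' Validate a life table
#'
#' @param df Data frame with columns `age` (integer years), `sex`, and
#'   `qx` (annual probability of death).
#' @return The validated data frame, classed `fl_life_table`.
#' @export
fl_life_table <- function(df) {
  required <- c("age", "sex", "qx")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("life table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$qx < 0) || any(df$qx > 1))
    stop("life-table qx values must lie in [0, 1]", call. = FALSE)
  for (s in unique(df$sex)) {
    ages <- sort(df$age[df$sex == s])
    if (length(ages) > 1 && any(diff(ages) != 1))
      stop("life-table ages must be contiguous integers within sex",
           call. = FALSE)
  }
  class(df) <- unique(c("fl_life_table", class(df)))
  df
}

#' Read a life table from CSV
#'
#' @param path CSV file with header `age,sex,qx`.
#' @return A validated `fl_life_table` data frame.
#' @export
read_life_table <- function(path) {
  fl_life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Annual death probability at a given age
#'
#' Looks up `qx` for the completed year of age (`floor(age)`); ages
#' outside the table range are an error — no extrapolation is performed.
#'
#' @param table An `fl_life_table`.
#' @param age Age in years (may be fractional; constant hazard is assumed
#'   within each year of age).
#' @param sex `"male"` or `"female"`.
#' @return Annual probability of death.
#' @export
lookup_qx <- function(table, age, sex) {
  yr <- floor(age)
  row <- table$age == yr & table$sex == sex
  if (sum(row) != 1)
    stop("age ", yr, " (", sex, ") outside life-table range", call. = FALSE)
  table$qx[row]
}

#' Background mortality probability per model cycle
#'
#' Converts the annual death probability at the cohort's current age to
#' the cycle-length probability through the constant-hazard algebra:
#' `p_cycle = 1 - (1 - qx)^(cycle_length)` with `cycle_length` in years.
#'
#' @inheritParams lookup_qx
#' @param cycle_length Cycle length in years.
#' @return Probability of background death within one cycle.
#' @export
background_mortality_per_cycle <- function(table, age, sex,
                                           cycle_length = 0.5) {
  qx <- lookup_qx(table, age, sex)
  qx <- min(qx, 1 - 1e-15)  # keep the log finite for qx == 1
  rate_to_probability(probability_to_rate(qx, 1), cycle_length)
}
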