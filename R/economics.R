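# Costing arithmetic, incremental cost-effectiveness analysis with
# dominance classification, and net monetary benefit.

#' Total cost of a multi-cycle systemic regimen
#'
#' @param per_cycle_drug Drug cost per treatment cycle.
#' @param day_care Day-care administration cost per cycle.
#' @param n_cycles Number of treatment cycles.
#' @return `(per_cycle_drug + day_care) * n_cycles`, exact to the cent.
#' @export
regimen_total_cost <- function(per_cycle_drug, day_care, n_cycles) {
  if (any(c(per_cycle_drug, day_care, n_cycles) < 0))
    stop("regimen cost inputs must be non-negative", call. = FALSE)
  (per_cycle_drug + day_care) * n_cycles
}

#' Total cost of a radiotherapy course
#'
#' @param sim Simulation cost (once).
#' @param plan Dosimetry-planning cost (once).
#' @param fraction Treatment cost per fraction.
#' @param verification Verification cost per fraction.
#' @param n_fractions Number of fractions delivered.
#' @return `sim + plan + n_fractions * (fraction + verification)`.
#' @export
rt_course_cost <- function(sim, plan, fraction, verification, n_fractions) {
  if (any(c(sim, plan, fraction, verification, n_fractions) < 0))
    stop("RT cost inputs must be non-negative", call. = FALSE)
  sim + plan + n_fractions * (fraction + verification)
}

#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`: positive increments in NMB at a given
#' willingness-to-pay are equivalent to an ICER below that threshold.
#'
#' @param cost Discounted cost.
#' @param qaly Discounted QALYs.
#' @param wtp Willingness-to-pay per QALY (non-negative).
#' @return Net monetary benefit in currency units; vectorised.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  wtp * qaly - cost
}

# Classify one pairwise comparison. delta_* are comparator minus reference.
classify_increment <- function(delta_cost, delta_qaly, icer, wtp) {
  if (delta_cost == 0 && delta_qaly == 0) return("indifferent")
  if (delta_qaly > 0 && delta_cost < 0) return("dominant")
  if (delta_qaly < 0 && delta_cost > 0) return("dominated")
  if (delta_qaly == 0) return(if (delta_cost > 0) "dominated" else "dominant")
  # remaining: both deltas share sign, ICER finite
  if (delta_qaly > 0) {
    if (icer <= wtp) "icer_below_wtp" else "icer_above_wtp"
  } else {
    # comparator cheaper but less effective: cost saved per QALY forgone
    if (icer >= wtp) "icer_below_wtp" else "icer_above_wtp"
  }
}

#' Pairwise incremental cost-effectiveness analysis
#'
#' For each comparator strategy versus the reference (and any additional
#' requested pairs) computes the incremental cost, incremental QALYs, the
#' ICER where defined, and a verdict: `dominant` (cheaper and more
#' effective), `dominated` (dearer and less effective),
#' `icer_below_wtp` / `icer_above_wtp`, or `indifferent`. When the QALY
#' increment is exactly zero the ICER is reported as signed infinity.
#' Increments are computed from unrounded model outputs; rounding is a
#' reporting concern.
#'
#' @param results List of `fl_econ_result` (or a data frame from
#'   [results_table()]).
#' @param reference Reference strategy name.
#' @param wtp Willingness-to-pay threshold.
#' @param pairs Optional list of additional `c(comparator, reference)`
#'   character pairs beyond each-vs-reference.
#' @return Data frame with one row per comparison: `comparator`,
#'   `reference`, `delta_cost`, `delta_qaly`, `icer`, `verdict`.
#' @export
incremental_analysis <- function(results, reference, wtp = 50000,
                                 pairs = NULL) {
  tab <- if (is.data.frame(results)) results else results_table(results)
  if (anyDuplicated(tab$strategy))
    stop("duplicate strategy names", call. = FALSE)
  if (!reference %in% tab$strategy)
    stop("reference strategy not found: ", reference, call. = FALSE)
  if (nrow(tab) < 2)
    stop("need at least two strategies", call. = FALSE)
  comparisons <- lapply(setdiff(tab$strategy, reference),
                        function(s) c(s, reference))
  comparisons <- c(comparisons, pairs)
  rows <- lapply(comparisons, function(pr) {
    cmp <- tab[tab$strategy == pr[1], ]
    ref <- tab[tab$strategy == pr[2], ]
    dc <- cmp$cost - ref$cost
    de <- cmp$qaly - ref$qaly
    icer <- if (de != 0) dc / de else if (dc == 0) NA_real_
            else sign(dc) * Inf
    data.frame(comparator = pr[1], reference = pr[2],
               delta_cost = dc, delta_qaly = de, icer = icer,
               verdict = classify_increment(dc, de, icer, wtp))
  })
  do.call(rbind, rows)
}

#' Cost-effectiveness efficiency frontier
#'
#' Orders strategies by cost and removes strictly dominated and
#' extendedly dominated strategies, leaving the frontier along which
#' sequential ICERs are increasing.
#'
#' @param results As for [incremental_analysis()].
#' @return Data frame of frontier strategies in increasing cost order,
#'   with the ICER of each against the previous frontier member.
#' @export
efficiency_frontier <- function(results) {
  tab <- if (is.data.frame(results)) results else results_table(results)
  tab <- tab[order(tab$cost, -tab$qaly), ]
  # drop strictly dominated (some cheaper strategy has >= QALYs)
  keep <- rep(TRUE, nrow(tab))
  best_q <- -Inf
  for (i in seq_len(nrow(tab))) {
    if (tab$qaly[i] <= best_q) keep[i] <- FALSE else best_q <- tab$qaly[i]
  }
  tab <- tab[keep, ]
  # extended dominance: sequential ICERs must increase
  repeat {
    if (nrow(tab) < 3) break
    icers <- diff(tab$cost) / diff(tab$qaly)
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    tab <- tab[-(bad[1] + 1), ]
  }
  tab$icer <- c(NA_real_,
                if (nrow(tab) > 1) diff(tab$cost) / diff(tab$qaly))
  tab[, c("strategy", "cost", "qaly", "icer")]
}
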