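# One-way (tornado) sensitivity analysis, gamma/beta PSA distributions,
# Monte-Carlo probabilistic sensitivity analysis, scatter quadrants and
# cost-effectiveness acceptability curves.

# ---- parameter registry ---------------------------------------------------
# Each sensitivity parameter is a (name, kind, get, set) record over an
# fl_inputs object. Rates are exposed on the per-cycle probability scale
# (the scale on which beta distributions and the +/-30% ranges apply) and
# mapped back to per-annum rates on set.

param_def <- function(name, kind, get, set) {
  list(name = name, kind = kind, get = get, set = set)
}

cost_param <- function(field) {
  param_def(paste0("cost.", field), "cost",
            get = function(inp) inp$costs[[field]],
            set = function(inp, v) { inp$costs[[field]] <- v; inp })
}

utility_param <- function(field) {
  # disutilities are handled on their absolute value, then negated
  neg <- startsWith(field, "d_")
  param_def(paste0("utility.", field), "utility",
            get = function(inp) abs(inp$utilities[[field]]),
            set = function(inp, v) {
              inp$utilities[[field]] <- if (neg) -v else v
              inp
            })
}

rate_param <- function(arm, event) {
  param_def(paste0("p.", arm, ".", event), "probability",
            get = function(inp)
              rate_to_probability(inp$rates[[arm]][[event]],
                                  inp$config$cycle_length),
            set = function(inp, v) {
              inp$rates[[arm]][[event]] <-
                probability_to_rate(min(v, 1 - 1e-12),
                                    inp$config$cycle_length)
              inp
            })
}

post_failure_param <- function() {
  param_def("p.post_failure_death", "probability",
            get = function(inp)
              rate_to_probability(inp$post_failure_death_rate,
                                  inp$config$cycle_length),
            set = function(inp, v) {
              inp$post_failure_death_rate <-
                probability_to_rate(min(v, 1 - 1e-12),
                                    inp$config$cycle_length)
              inp
            })
}

ae_param <- function(arm, field) {
  param_def(paste0("p.ae.", arm, ".", field), "probability",
            get = function(inp) inp$ae_incidence[[arm]][[field]],
            set = function(inp, v) {
              inp$ae_incidence[[arm]][[field]] <- v
              inp
            })
}

discount_param <- function() {
  param_def("discount_rate", "discount",
            get = function(inp) inp$config$discount_rate,
            set = function(inp, v) {
              inp$config$discount_rate <- v
              inp
            })
}

#' Default sensitivity-parameter registry
#'
#' Enumerates the tunable model parameters with their sensitivity kind:
#' every cost input (`cost`), state utilities and treatment disutilities
#' on their absolute value (`utility`), every per-cycle transition
#' probability — the nine arm event probabilities, the post-failure death
#' probability and the adverse-event incidences (`probability`) — and the
#' annual discount rate (`discount`).
#'
#' @param inputs An [fl_inputs()] object.
#' @return Named list of parameter definitions.
#' @export
fl_sa_parameters <- function(inputs) {
  defs <- c(
    lapply(c("rt_simulation", "rt_planning", "rt_fraction",
             "rt_verification", "drug_cvp", "drug_rcvp", "drug_rchop",
             "drug_rituximab", "day_care", "asct", "ae_admission",
             "pegfilgrastim"), cost_param),
    lapply(c("u_ffs", "u_progressed", "d_rt", "d_systemic", "d_asct"),
           utility_param),
    unlist(lapply(names(inputs$arms), function(a)
      lapply(c("progression", "transformation", "death_disease"),
             function(e) rate_param(a, e))), recursive = FALSE),
    list(post_failure_param()),
    unlist(lapply(names(inputs$arms), function(a)
      lapply(c("admission", "g4_neutropenia"),
             function(f) ae_param(a, f))), recursive = FALSE),
    list(discount_param())
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

# ---- one-way sensitivity --------------------------------------------------

#' Bounds for one-way sensitivity by parameter kind
#'
#' Costs and probabilities vary by +/-30% of base case, utilities by
#' +/-10% (probabilities and utilities clipped to `[0, 1]`); the discount
#' rate takes the fixed bounds 3% and 7%.
#'
#' @param base Base-case value.
#' @param kind `"cost"`, `"probability"`, `"utility"` or `"discount"`.
#' @return Numeric `c(low, high)`.
#' @export
one_way_bounds <- function(base, kind) {
  switch(kind,
    cost = base * c(0.70, 1.30),
    probability = pmin(pmax(base * c(0.70, 1.30), 0), 1),
    utility = pmin(pmax(base * c(0.90, 1.10), 0), 1),
    discount = c(0.03, 0.07),
    stop("unknown parameter kind: ", kind, call. = FALSE))
}

#' One-way sensitivity of an outcome to a single parameter
#'
#' Re-runs the model with the parameter at its lower and upper bound, all
#' other inputs held at base case.
#'
#' @param inputs An [fl_inputs()] object (base case).
#' @param param Parameter name from [fl_sa_parameters()], or a parameter
#'   definition.
#' @param outcome Function `inputs -> scalar` (e.g. an ICER or an
#'   incremental NMB).
#' @return One-row data frame: parameter, kind, low/high bound, outcome at
#'   each bound, and bar width `|outcome_high - outcome_low|`.
#' @export
one_way <- function(inputs, param, outcome) {
  if (is.character(param)) {
    defs <- fl_sa_parameters(inputs)
    if (!param %in% names(defs))
      stop("unknown parameter name: ", param, call. = FALSE)
    param <- defs[[param]]
  }
  base <- param$get(inputs)
  bounds <- one_way_bounds(base, param$kind)
  at <- vapply(bounds, function(v) outcome(param$set(inputs, v)), 0)
  data.frame(parameter = param$name, kind = param$kind, base = base,
             low = bounds[1], high = bounds[2],
             outcome_at_low = at[1], outcome_at_high = at[2],
             bar_width = abs(at[2] - at[1]))
}

#' Pairwise outcome functions for sensitivity analyses
#'
#' @param comparator,reference Strategy names.
#' @param what `"icer"` for the pairwise ICER or `"inmb"` for the
#'   incremental net monetary benefit at `wtp`.
#' @param wtp Willingness-to-pay (used by `"inmb"`).
#' @return Function mapping an [fl_inputs()] object to a scalar outcome.
#' @export
pairwise_outcome <- function(comparator, reference,
                             what = c("icer", "inmb"), wtp = 50000) {
  what <- match.arg(what)
  function(inputs) {
    a <- run_strategy(inputs, comparator)
    b <- run_strategy(inputs, reference)
    if (what == "icer") {
      de <- a$discounted_qaly - b$discounted_qaly
      if (de == 0) return(NA_real_)
      (a$discounted_cost - b$discounted_cost) / de
    } else {
      net_monetary_benefit(a$discounted_cost, a$discounted_qaly, wtp) -
        net_monetary_benefit(b$discounted_cost, b$discounted_qaly, wtp)
    }
  }
}

#' Tornado analysis over a set of parameters
#'
#' @param inputs Base-case [fl_inputs()].
#' @param outcome Outcome function (see [pairwise_outcome()]).
#' @param params Parameter definitions; defaults to the full registry.
#' @return Data frame of [one_way()] rows sorted by descending bar width.
#' @export
tornado <- function(inputs, outcome, params = fl_sa_parameters(inputs)) {
  rows <- do.call(rbind, lapply(params, one_way,
                                inputs = inputs, outcome = outcome))
  rows <- rows[order(-rows$bar_width), ]
  rownames(rows) <- NULL
  rows
}

# ---- PSA distributions ----------------------------------------------------

#' Fit a gamma distribution to a cost parameter by method of moments
#'
#' The spread fraction defines the standard deviation as
#' `sd = spread * mean / 1.96`, so that the +/-spread range spans
#' approximately a 95% interval; then `shape = mean^2 / sd^2` and
#' `rate = mean / sd^2`.
#'
#' @param mean Target mean (positive; zero-valued cost parameters are held
#'   fixed in the PSA rather than fitted).
#' @param spread Fractional spread (default 0.30).
#' @return List with `shape`, `rate`, `mean`, `sd`.
#' @export
fit_gamma <- function(mean, spread = 0.30) {
  if (mean <= 0) stop("gamma mean must be positive", call. = FALSE)
  if (spread <= 0) stop("`spread` must be positive", call. = FALSE)
  sd <- spread * mean / 1.96
  list(shape = mean^2 / sd^2, rate = mean / sd^2, mean = mean, sd = sd)
}

#' Fit a beta distribution to a probability or utility by method of moments
#'
#' `sd = spread * mean / 1.96`, capped so that `sd^2 < mean * (1 - mean)`
#' (the feasibility bound for a beta distribution); then
#' `alpha = mean * (mean (1 - mean) / sd^2 - 1)` and
#' `beta = (1 - mean) * (mean (1 - mean) / sd^2 - 1)`.
#'
#' @param mean Target mean in (0, 1).
#' @param spread Fractional spread (0.30 for probabilities, 0.10 for
#'   utilities).
#' @return List with `shape1`, `shape2`, `mean`, `sd`.
#' @export
fit_beta <- function(mean, spread = 0.30) {
  if (mean <= 0 || mean >= 1)
    stop("beta mean must lie strictly in (0, 1)", call. = FALSE)
  if (spread <= 0) stop("`spread` must be positive", call. = FALSE)
  sd2 <- (spread * mean / 1.96)^2
  sd2 <- min(sd2, 0.95 * mean * (1 - mean))
  nu <- mean * (1 - mean) / sd2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu,
       mean = mean, sd = sqrt(sd2))
}

# ---- probabilistic sensitivity analysis -----------------------------------

#' Monte-Carlo probabilistic sensitivity analysis
#'
#' Samples every varied parameter independently — gamma for costs, beta
#' for utilities, disutility magnitudes and per-cycle transition
#' probabilities — rebuilds the model and records discounted cost and
#' QALYs for all strategies in each draw, together with the pairwise
#' increments. Parameters whose base value is zero are held fixed. Draws
#' violating the utility constraints (state utility minus applicable
#' disutilities below zero) are rejected and redrawn; the analysis errors
#' if more than 1% of draws are rejected.
#'
#' @param inputs Base-case [fl_inputs()].
#' @param n_iter Number of Monte-Carlo iterations (default 1000).
#' @param seed Integer seed; fixed seeds give identical sample sets.
#' @param spread_cost,spread_prob,spread_util Fractional spreads mapped to
#'   distribution standard deviations via [fit_gamma()] / [fit_beta()];
#'   spreads of zero hold the parameter group at base case.
#' @param pairs List of `c(comparator, reference)` pairs for which
#'   increments are recorded; defaults to all ordered pairs against the
#'   first strategy plus the remaining pair.
#' @return An `fl_psa` list: `samples` (data frame, one row per draw, with
#'   per-strategy `cost_*` / `qaly_*` and per-pair `dcost_*` / `dqaly_*`),
#'   `params` (matrix of sampled parameter values), `rejections`, `seed`.
#' @export
run_psa <- function(inputs, n_iter = 1000, seed = 1L,
                    spread_cost = 0.30, spread_prob = 0.30,
                    spread_util = 0.10, pairs = NULL) {
  set.seed(seed)
  strategies <- names(inputs$arms)
  if (is.null(pairs)) {
    ref <- strategies[1]
    pairs <- lapply(strategies[-1], function(s) c(s, ref))
    if (length(strategies) == 3)
      pairs <- c(pairs, list(c(strategies[3], strategies[2])))
  }

  defs <- fl_sa_parameters(inputs)
  defs <- defs[names(defs) != "discount_rate"]  # structural, not sampled
  spread_for <- function(kind) switch(kind, cost = spread_cost,
                                      probability = spread_prob,
                                      utility = spread_util)
  # pre-fit one distribution per varied parameter
  dists <- lapply(defs, function(d) {
    base <- d$get(inputs)
    sp <- spread_for(d$kind)
    if (base == 0 || sp == 0)
      return(list(type = "fixed", value = base))
    if (d$kind == "cost") c(list(type = "gamma"), fit_gamma(base, sp))
    else c(list(type = "beta"), fit_beta(base, sp))
  })

  draw_one <- function() {
    vapply(dists, function(ds) switch(ds$type,
      fixed = ds$value,
      gamma = stats::rgamma(1, shape = ds$shape, rate = ds$rate),
      beta  = stats::rbeta(1, ds$shape1, ds$shape2)), 0)
  }
  valid_draw <- function(v) {
    v[["utility.u_ffs"]] - v[["utility.d_rt"]] -
      v[["utility.d_systemic"]] >= 0 &&
    v[["utility.u_progressed"]] - v[["utility.d_asct"]] >= 0
  }

  n_params <- length(defs)
  par_mat <- matrix(NA_real_, n_iter, n_params,
                    dimnames = list(NULL, names(defs)))
  rejections <- 0L
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    repeat {
      v <- draw_one()
      if (valid_draw(v)) break
      rejections <- rejections + 1L
      if (rejections > max(10, 0.01 * n_iter))
        stop("more than 1% of PSA draws rejected", call. = FALSE)
    }
    par_mat[i, ] <- v
    inp <- inputs
    for (j in seq_len(n_params)) inp <- defs[[j]]$set(inp, v[[j]])
    res <- run_all_strategies(inp)
    rec <- list(iter = i)
    for (s in strategies) {
      rec[[paste0("cost_", s)]] <- res[[s]]$discounted_cost
      rec[[paste0("qaly_", s)]] <- res[[s]]$discounted_qaly
    }
    for (pr in pairs) {
      key <- paste0(pr[1], "_vs_", pr[2])
      rec[[paste0("dcost_", key)]] <-
        res[[pr[1]]]$discounted_cost - res[[pr[2]]]$discounted_cost
      rec[[paste0("dqaly_", key)]] <-
        res[[pr[1]]]$discounted_qaly - res[[pr[2]]]$discounted_qaly
    }
    rows[[i]] <- as.data.frame(rec, check.names = FALSE)
  }
  structure(list(samples = do.call(rbind, rows), params = par_mat,
                 pairs = pairs, strategies = strategies,
                 rejections = rejections, seed = seed),
            class = "fl_psa")
}

#' Scatter-plot quadrant summary for one strategy pair
#'
#' Classifies each PSA draw's incremental cost / incremental QALY point
#' into the four plane quadrants and reports the fraction cost-effective
#' at the willingness-to-pay threshold (incremental NMB > 0). Points on a
#' quadrant boundary count toward the adjacent quadrant clockwise from
#' "more effective, more costly".
#'
#' @param psa An `fl_psa` from [run_psa()].
#' @param pair `c(comparator, reference)`.
#' @param wtp Willingness-to-pay threshold.
#' @return List with quadrant fractions `upper_right` (dearer, more
#'   effective), `lower_right` (cheaper, more effective — dominance),
#'   `upper_left`, `lower_left`, and `cost_effective`.
#' @export
quadrant_summary <- function(psa, pair, wtp = 50000) {
  key <- paste0(pair[1], "_vs_", pair[2])
  dc <- psa$samples[[paste0("dcost_", key)]]
  de <- psa$samples[[paste0("dqaly_", key)]]
  if (is.null(dc) || !length(dc))
    stop("no PSA samples for pair ", key, call. = FALSE)
  n <- length(dc)
  out <- list(
    upper_right = sum(de >= 0 & dc > 0) / n,
    lower_right = sum(de >= 0 & dc <= 0) / n,
    upper_left  = sum(de < 0 & dc > 0) / n,
    lower_left  = sum(de < 0 & dc <= 0) / n,
    cost_effective = sum(wtp * de - dc > 0) / n
  )
  stopifnot(abs(out$upper_right + out$lower_right +
                out$upper_left + out$lower_left - 1) < 1e-12)
  out
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that each strategy
#' has the maximal net monetary benefit across PSA draws; exact ties split
#' their draw equally among the tied strategies, so the probabilities sum
#' to one at every threshold.
#'
#' @param psa An `fl_psa` from [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay values (default 0 to
#'   100,000 by 2,500).
#' @return Data frame: `wtp` plus one probability column per strategy.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 2500)) {
  if (!length(wtp_grid)) stop("`wtp_grid` must be non-empty", call. = FALSE)
  strategies <- psa$strategies
  costs <- as.matrix(psa$samples[paste0("cost_", strategies)])
  qalys <- as.matrix(psa$samples[paste0("qaly_", strategies)])
  n <- nrow(costs)
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * qalys - costs
    best <- nmb == apply(nmb, 1, max)
    wins <- colSums(best / rowSums(best))
    as.data.frame(c(list(wtp = w),
                    stats::setNames(as.list(wins / n), strategies)),
                  check.names = FALSE)
  })
  do.call(rbind, out)
}
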