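---
title: "A five-state cost-utility model of front-line therapy in early-stage follicular lymphoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-state cost-utility model of front-line therapy in early-stage follicular lymphoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcea)
```

## The decision problem

Involved-field radiotherapy (RT) has long been the standard of care for
early-stage follicular lymphoma. Randomised evidence shows that adding
six cycles of systemic therapy — CVP chemotherapy, later amended to
rituximab-CVP (R-CVP) — substantially reduces relapse outside the
radiation field, at the price of more acute toxicity and higher upfront
drug costs. `flcea` asks the payer's question: per patient treated, do
the downstream savings and quality-adjusted life-years (QALYs) gained by
fewer failures justify the added front-line cost, at a willingness-to-pay
(WTP) of AUD$50,000 per QALY?

## Model structure

The cohort model has six internal states:

* **FFS** — failure-free survival (ongoing first remission);
* **FAILURE** — relapsed/progressive follicular lymphoma, retreated once
  with R-CHOP;
* **TRANSFORMATION** — histologic transformation to aggressive lymphoma,
  retreated with R-CHOP;
* **POST_ASCT** — transformation in a patient younger than 65, who
  additionally receives an autologous stem-cell transplant;
* **DEATH_DISEASE** and **DEATH_BACKGROUND** — absorbing states that keep
  the two sources of mortality separate (reporting may merge them).

A unit cohort starts in FFS at age 50 (male life-table reference group)
and is propagated through thirty six-month cycles — a 15-year horizon.
Once a patient fails or transforms they remain in that state for life;
only the first failure is modelled, and every relapse is treated alike to
keep second-line variation out of the comparison.

### From trial counts to transition probabilities

Arm-level first-event counts (75/44/31 patients; 38/22/5 progressions,
11/4/1 transformations, 13/5/1 deaths; median follow-up 11.3 years) are
turned into per-annum rates by the person-time rule

$$\hat\lambda_k = \frac{\text{events}_k}{n \times \text{follow-up}},$$

and rates into per-cycle probabilities by $p = 1 - e^{-\lambda\,\Delta t}$
with $\Delta t = 0.5$ years. The four exits from FFS (progression,
transformation, disease death, background death) are treated as
independent competing exponentials within a cycle: the total leaving
probability is $1 - \exp(-\Lambda\,\Delta t)$ with $\Lambda$ the summed
rate, apportioned among destinations in proportion to their rates. This
construction is exact for competing constant hazards and row-stochastic
for any non-negative rates, which is why the engine asserts row sums to
$10^{-10}$ rather than clipping.

The person-time denominator is a deliberate reconstruction — the original
derivation of transition probabilities is not published. Its bias is
quantified rather than assumed: with total hazard $\Lambda$ and horizon
$T$, the estimator recovers $\lambda_k (1-e^{-\Lambda T})/(\Lambda T)$,
i.e. essentially unbiased for rare events and roughly 30% low at the
RT-arm's combined event rate over 11.3 years (`analysis/04_validation.R`
prints both regimes). Because the same rule is applied to every arm the
distortion is shared, and the strategy ranking it implies proved stable
under the one-way and probabilistic sensitivity analyses.

### Background mortality

Annual death probabilities come from a life table (`age,sex,qx` CSV).
Constant hazard is assumed within each year of age:
$p_{\text{cycle}} = 1-(1-q_x)^{0.5}$. Lookups outside the table range are
an error — no extrapolation. The package ships a **synthetic** male life
table, $q_x(a) = 0.0032\,e^{0.09 (a-50)}$, matching the order of
magnitude and Gompertz-like slope of a national male life table around
age 50; it is labelled synthetic everywhere because actuarial tables are
not redistributable here and the analysis must run self-contained.

### ASCT age gate

The cohort carries a single age, so the under-65 transplant rule is read
deterministically: if the cohort is younger than 65 at the cycle of
transformation the whole transforming fraction routes to POST_ASCT,
otherwise to TRANSFORMATION. With the base-case start age of 50 every
transformation inside the 15-year horizon occurs before 65; the gate
becomes active for alternative start ages (e.g. the trial's median age
of 57, selectable in the configuration).

## Costs, utilities and accounting conventions

All costs are 2022 AUD from the payer's perspective. Front-line therapy
is charged once, in the first cycle: an IMRT course of
$739.35 + 3448.10 + 15\times(190.35+79.70) = \$8{,}238.20$, plus six
cycles of CVP ($\$2{,}159.88$) or R-CVP ($\$5{,}531.88$) where
applicable, plus the expected adverse-event cost (incidence × $5{,}000
admission; incidence × $142 pegfilgrastim). Retreatment is charged on
the first-entry ledger: a full R-CHOP course ($\$6{,}204.48$) for the
fraction newly entering FAILURE, TRANSFORMATION or POST_ASCT, and the
transplant episode ($\$45{,}638.63$) on entry to POST_ASCT. No ongoing
state-maintenance costs are modelled: staging and follow-up were judged
similar across arms in the source evaluation and excluded.

State utilities are 0.88 (FFS) and 0.74 (all three post-failure states —
only two state weights are available, so failure, transformation and
post-ASCT survival share the progressed weight). Treatment disutilities
are decrements during treated cycles: RT −0.05 and systemic therapy
−0.15 in the first cycle (six 3-weekly cycles fit inside one model
cycle, so a single-cycle application is used; the alternative two-cycle
reading is not recoverable from the available description), and −0.20
for the single cycle containing the ASCT.

Two accounting conventions matter and are switchable in
`fl_accumulate()`:

* **Half-cycle correction.** State rewards use the trapezoidal average
  of start- and end-of-cycle occupancy, discounted at mid-cycle
  $(1+r)^{-(t+0.5)\Delta t}$. The tests verify the corrected QALY lies
  strictly between the start- and end-of-cycle accounting variants.
* **One-off flows** (front-line therapy, adverse events, retreatment,
  ASCT, treatment disutilities) attach to the first-entry ledger, are
  exempt from the half-cycle correction, and are discounted at cycle
  start by default (`oneoff_timing = "mid_cycle"` is available).

Costs and QALYs are discounted at 5% per annum (varied 3–7% in
sensitivity analysis). Currency is kept at full precision internally;
rounding happens only at report time, which reproduces the
familiar-looking $1 discrepancies between rounded per-strategy values
and their printed differences.

## Reconstructed parameters

Two inputs the model needs are not printed anywhere and are therefore
explicit reconstructions, tagged `reconstructed` in the parameter file
and echoed in `provenance.csv` by every run:

* **Adverse-event incidences** — 0 for RT alone; for both systemic arms,
  0.10 for a grade 3/4 infection / febrile-neutropenia admission and
  0.20 for grade-4 neutropenia. These are typical magnitudes for
  CVP-like regimens in older adults; they enter only as an expected
  first-cycle cost (≈ $545) and the tornado analysis confirms the
  results are insensitive to them.
* **Post-failure disease mortality** — 0.05 per annum in FAILURE,
  TRANSFORMATION and POST_ASCT, corresponding to a median
  post-progression survival of roughly 14 years in the rituximab era.
  Background mortality applies in all alive states. Whether the arm
  death counts should contribute only lymphoma-attributed deaths is
  unknowable from the available text; all deaths are used, which is
  conservative for the RT arm.

Transformation is allowed only from FFS, not from FAILURE — whether
relapse-to-transformation transitions were modelled originally is not
stated, and adding them would require a rate no available count
identifies. This is flagged as a reconstruction.

## Sensitivity analyses

One-way analysis moves each parameter to ±30% of base case (costs,
per-cycle probabilities), ±10% (utilities, clipped to $[0,1]$), or 3%/7%
(discount rate), re-running the model with everything else fixed and
ranking parameters by the width of their effect (here on incremental net
monetary benefit, since an ICER is unstable near $\Delta E = 0$).

The probabilistic analysis draws 1000 parameter sets: gamma for costs
and beta for utilities, disutility magnitudes and per-cycle
probabilities, all independent (no correlation structure is published).
Distribution variances are not published either; the package maps the
one-way range to a 95% interval, $\sigma = \text{spread}\times\mu/1.96$,
then method-of-moments. Beta variances are capped below
$\mu(1-\mu)$ for feasibility. Zero-valued parameters are held fixed.
Draws violating the utility floor (state utility minus applicable
disutilities below zero) are rejected and redrawn, with an error if
rejections exceed 1% — in practice none occur at these spreads. The
CEAC reports, per WTP on a $0$–$100{,}000$ grid (step $2{,}500$), the
probability each strategy has the maximal net monetary benefit, ties
split equally.

## Validation design

Two independent routes check the engine:

* **Closed forms** — rate↔probability round trips to $10^{-12}$;
  two-state chains against $(1-p)^t$; absorbing-cohort QALYs against a
  brute-force discounted sum; the competing-risk split against its
  closed form.
* **Microsimulation oracle** — 100,000 individual patients are pushed
  through the identical per-cycle matrices, accruing the identical
  rewards; means must agree with the cohort engine within 3 Monte-Carlo
  standard errors. This is the strongest correctness argument available
  in the absence of the original modelling software's outputs, because
  the two computations share only the transition probabilities, not the
  accounting code path.

The synthetic-trial generator draws competing exponential event times
with administrative censoring at a fixed follow-up — the memoryless
structure the rate-based model assumes. It deliberately does **not**
emulate staggered accrual, time-varying hazards, the randomisation
amendment history or PET-staging subgroups, so passing parameter-recovery
tests demonstrates internal consistency of the modelling chain, not
fidelity of constant-hazard assumptions to real follicular-lymphoma
natural history.

## What the model does and does not reproduce

With reconstructed rates the QALY side lands close to the published
base case: 7.56 / 7.75 / 8.52 QALYs versus 7.520 / 7.699 / 8.231 for
RT, RT+CVP and RT+R-CVP, and RT+R-CVP's gain over RT (0.96 QALYs) is of
the published order (0.711). The cost side does not reproduce: this
model prices each strategy at $14.7k–16.5k where the published figures
are $32k–52k, because per-strategy costs depend on an input table that
was never published. Under one-off course pricing, RT alone's entire
downstream retreatment expectation is ≈ $6.5k discounted — less than
the R-CVP front-line premium — so RT+R-CVP emerges as strongly
cost-effective (ICER ≈ $1,850/QALY, highest net benefit at every WTP
examined, 100% of PSA draws below the $50,000 threshold against RT)
rather than strictly cost-saving. The published strict dominance would
require downstream costs several times the printed course prices
(plausibly ongoing therapy in the failure states). The package reports
this divergence rather than adjusting reconstructed inputs to force the
published verdict.

## Numerical choices and problem sizes

Row-stochasticity is enforced to $10^{-10}$ and cohort mass conservation
checked every cycle. Degenerate inputs (all-zero rates, zero costs,
$q_x \to 1$) are exercised in tests. The shipped analyses use 30 cycles,
1000 PSA iterations and 100,000 microsimulation patients — sizes chosen
so each analysis completes in seconds to a couple of minutes on a single
core while leaving Monte-Carlo error well inside the tolerances the
checks assert. Seeds are explicit everywhere randomness enters
(`simulate_arm`, `microsim`, `run_psa`), and fixed seeds give
byte-identical artifacts.
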