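# flcea — cost-utility modelling of front-line therapy in early-stage follicular lymphoma

`flcea` is an R package plus analysis workflow for the payer's question
raised by randomised evidence in early-stage follicular lymphoma: after
involved-field radiotherapy (RT), is it worth adding six cycles of
systemic therapy — CVP, or rituximab-CVP (R-CVP) — given better
failure-free survival but more toxicity and higher upfront cost? It is
aimed at health-economics and haematology researchers who want a fully
tested, scriptable version of this evaluation instead of a proprietary
modelling file.

## The model

A unit cohort starts in failure-free survival (FFS) at age 50 and moves
through six states — FFS, failure, transformation, post-ASCT, and death
split into disease vs background — over thirty 6-month cycles (15
years). Arm-level trial counts are converted to per-annum rates,
λ = events / (n × follow-up), and to per-cycle probabilities by
p = 1 − e^(−λΔt); the four competing exits from FFS share the total
leaving probability in proportion to their rates. Patients transforming
before age 65 receive an autologous stem-cell transplant. Costs (2022
AUD) and utilities accrue with half-cycle correction and 5% annual
discounting; one-off flows (front-line therapy, adverse events, R-CHOP
retreatment, ASCT) attach to a first-entry ledger. Strategies are
compared by incremental cost-effectiveness ratio
ICER = ΔC/ΔE with dominance classification, and by net monetary benefit
NMB = WTP × QALYs − cost at WTP = AUD$50,000/QALY. One-way (tornado)
analyses, a 1000-draw probabilistic sensitivity analysis (gamma costs,
beta probabilities/utilities) and cost-effectiveness acceptability
curves quantify uncertainty. A synthetic-trial generator and a
100,000-patient microsimulation oracle validate the chain end to end.

Because increments are computed from unrounded model outputs, a table
rounded to whole dollars can disagree with the difference of its own
rounded entries by $1 (e.g. 51,996 − 43,994 = 8,002 against a printed
8,001); this is reporting behaviour, not a model discrepancy.

## Worked example

```r
library(flcea)
inputs <- read_params(system.file("extdata", "params.yaml", package = "flcea"))
res <- run_all_strategies(inputs)
results_table(res)[, c("strategy", "cost", "qaly")]
#>   strategy    cost    qaly
#> 1       RT 14703.4 7.55983
#> 2   RT+CVP 15906.5 7.74596
#> 3 RT+R-CVP 16473.0 8.51667

incremental_analysis(res, "RT", wtp = 50000,
                     pairs = list(c("RT+R-CVP", "RT+CVP")))
#>   comparator reference delta_cost delta_qaly      icer        verdict
#> 1     RT+CVP        RT   1203.044  0.1861328 6463.3620 icer_below_wtp
#> 2   RT+R-CVP        RT   1769.614  0.9568408 1849.4339 icer_below_wtp
#> 3   RT+R-CVP    RT+CVP    566.570  0.7707080  735.1292 icer_below_wtp
```

Read: over 15 discounted years, RT+R-CVP delivers 0.96 more QALYs than
RT alone for $1,770 more — about $1,849 per QALY gained, far below the
$50,000 threshold, and it has the highest net monetary benefit of the
three strategies (every one of 1000 PSA draws prefers it at that
threshold). The published evaluation, whose per-strategy costs rest on
an unpublished input table, additionally found it strictly cost-saving;
this reconstruction reports it as strongly cost-effective instead — the
methods vignette (`vignettes/cost-utility-model.Rmd`) analyses the gap.

The full workflow lives in `analysis/`:
`01_base_case.R`, `02_one_way_sensitivity.R`, `03_psa.R`,
`04_validation.R`, each writing its tables under `results/`.

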