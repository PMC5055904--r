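# uccea

A Markov cohort cost-utility model comparing **adalimumab + standard care**
against **standard care alone** for moderate-to-severe ulcerative colitis,
from the Polish public-payer and societal perspectives. The package
re-implements a published Polish cost-utility analysis as fully testable
code: its default parameter file transcribes the published clinical inputs,
EQ-5D utilities and 2015 PLN unit costs, and a synthetic life table stands
in for the national mortality table so everything runs self-contained.

It is written for health-economics researchers and HTA analysts who want a
transparent, reproducible version of a decision model that originally lived
in a spreadsheet: every transition probability, cost component and
discounting choice is an inspectable function with tests.

## The model in brief

A closed cohort enters at age 39.60 in an induction state and moves among
ten health states - response and remission (on and off the biologic),
active disease, colectomy, transient post-surgical complications, permanent
post-surgical remission, and death - over a 30-year horizon. Cycles are
weekly during induction and 8-weekly thereafter (202 cycles); induction
outcome is assessed after the ninth cycle using trial week-8 rates, with
biologic-arm probabilities obtained by relative-risk scaling. Background
mortality comes from a life table and is identical across alive states.
Costs (discounted at 5%/year) and QALYs (3.5%/year) accumulate per cycle,
and the headline result is the incremental cost-utility ratio

```
ICUR = (C_ada - C_soc) / (Q_ada - Q_soc)   [EUR/QALY, 4.2 PLN = 1 EUR]
```

for each perspective, plus one-way and probabilistic sensitivity analyses
(beta / lognormal / gamma distributions matched to the published ranges)
with cost-effectiveness acceptability curves, and an unlimited-treatment-
duration scenario. The methods vignette
(`vignettes/cost-utility-model.Rmd`) documents every structural and
numerical choice.

## Worked example

```r
library(uccea)

params <- default_parameters()        # published inputs + ranges
table  <- synth_life_table()          # Gompertz table, e0 = 77 y
res    <- run_cea(params, table)

res$cea$delta_qaly          # 0.1635584
res$cea$icur_payer_eur      # 61649.4
res$cea$icur_social_eur     # 50872.12
```

The biologic arm gains 0.164 QALYs per patient over 30 years at an extra
EUR 10,083 in direct costs, i.e. 61,649 EUR per QALY gained from the payer
perspective; indirect costs (productivity losses) partially offset the drug
cost, so the societal ICUR is lower at 50,872 EUR/QALY. The corresponding
published values are 0.140 QALYs, 76,120 and 71,457 EUR/QALY - the deltas
and ratios land within tolerance bands rather than exactly because two of
the study's inputs (the national life-table year and the adverse-event
discontinuation rate) were never published.

## The analysis workflow

The numbered scripts under `analysis/` rebuild the full study from the
package, writing their tables under `results/`:

```sh
Rscript analysis/01_inputs.R               # life table + parameter files
Rscript analysis/02_basecase.R             # base-case table + cohort traces
Rscript analysis/03_owsa.R                 # one-way sensitivity (tornado-ready CSV)
Rscript analysis/04_psa.R                  # 1,000-draw PSA + CEAC
Rscript analysis/05_scenario_unlimited.R   # no treatment-duration cap
```

## Layout

```
R/                  model code: parameters, life tables, Markov engine,
                    economics, sensitivity analyses, drivers
inst/extdata/       shipped fixtures (synthetic life table, parameter files)
analysis/           numbered workflow scripts (above)
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance tests, including an
                    independent 100,000-patient microsimulation oracle
vignettes/          methods vignette
```
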