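---
title: "A Markov cohort cost-utility model for biologic treatment of ulcerative colitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for biologic treatment of ulcerative colitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uccea)
```

## The decision problem

Moderate-to-severe ulcerative colitis (UC) that does not respond to standard
pharmacotherapy (corticosteroids, aminosalicylates, thiopurines) historically
left colectomy as the remaining option. Anti-TNF&alpha; agents offer a
non-surgical alternative, at a drug price that makes reimbursement decisions
contentious. `uccea` implements a cohort-level state-transition model that
compares one year of adalimumab added to standard care against standard care
alone in a Polish setting, from two perspectives: the public payer (direct
medical costs only) and society (direct plus indirect costs). The default
parameter set transcribes the clinical inputs, utilities and 2015 PLN unit
costs of the published Polish cost-utility study this package re-implements;
the headline output is the incremental cost-utility ratio

$$\mathrm{ICUR} = \frac{C_{\mathrm{ADA}} - C_{\mathrm{SoC}}}
{Q_{\mathrm{ADA}} - Q_{\mathrm{SoC}}} \quad [\text{EUR/QALY}],$$

with costs discounted at 5%/year, effects at 3.5%/year, over a 30-year
horizon.

## Model structure

Ten health states (`health_states()`): an induction state, response and
remission states split by whether the patient is still receiving the
biologic, an active-disease state, colectomy (`SURGERY`), transient
post-surgical complications, permanent post-surgical remission, and death.
Time runs on a two-period cycle schedule: weekly cycles during induction
(weeks 0–8), then 8-week cycles; a 30-year horizon is 8 + 194 = 202 cycles.

Key structural choices, made once and documented here:

* **Assessment after the ninth cycle (week 16).** The whole cohort stays in
  `INDUCTION` — on its full regimen — through the eight weekly cycles *and*
  the first 8-week cycle, and the induction outcome (remission, exclusive
  response, or failure) is applied at that cycle's end. The trial-derived
  week-8 outcome probabilities are used for the split. We considered
  assessing at week 8 directly; the later assessment is the reading
  consistent with the source study's printed adalimumab cost share
  (roughly 800 mg-equivalents of drug per entering patient, which requires
  the whole cohort dosed through week 16 — a week-8 split yields only ~660),
  and the package reproduces that cost to within 5% under it.
* **Loss destinations.** Losing response or remission returns the patient to
  `ACTIVE_DISEASE`; there is no direct response-to-remission upgrade. This is
  the conservative reading of the state diagram; one consequence, verified
  by a property test, is that a *higher response-loss* probability can
  slightly *increase* remission occupancy (mass recycles through active
  disease, the only gateway to remission).
* **Within-cycle event order.** The per-cycle probabilities are marginal, so
  competing events are applied sequentially to the mass the previous event
  left: death first, then (from active disease) colectomy, then remission
  gain, then response gain. This keeps every transition-matrix row exactly
  stochastic; the order is a documented implementation convention, checked
  against an independent event-tree enumeration and a patient-level
  microsimulation.
* **Treatment cap.** Biologic dosing and biologic-arm transition
  probabilities (response loss 0.161, remission loss 0.000 per cycle, annual
  colectomy relative risk 0.77) apply to cycles starting before
  `treatment_cap_weeks` (default 52). From the first cycle past the cap the
  arm faces exactly the standard-care dynamics and on-treatment occupancy
  drains into the standard-care response/remission states. Setting the cap
  to `Inf` is the unlimited-duration scenario: treatment until loss of
  response or death.
* **Regained response is on standard care.** Patients who fail and later
  regain response or remission do so under standard care in both arms, so
  the per-cycle gain probabilities are never relative-risk scaled. The
  per-cycle gain relative risks remain in the parameter set (and the
  sensitivity analyses) but do not enter base-case dynamics.
* **Mortality is state-uniform.** UC does not shorten life expectancy, so
  one background life table supplies the death probability of every alive
  state, converted to cycle length by a constant within-year hazard, with
  age advancing continuously from the cohort entry age (39.60 years).

## Parameters and conversions

All inputs live in a validated container (`default_parameters()`, YAML I/O
via `read_parameters()`/`write_parameters()`) with published 95% CIs or
min–max ranges attached where available. Conversions are deliberately tiny,
testable primitives:

* relative risks scale the standard-care probability on the *same timescale*
  it is quoted on, capped at 1 (`apply_relative_risk()`);
* annual probabilities rescale to cycles as $1-(1-p)^{t}$
  (`annual_prob_to_cycle()`);
* colectomy incidence quoted as events per patient-years is read as a simple
  proportion (15/408.1 = 3.68%, 11/231.7 = 4.75%), because that reading
  reproduces the printed per-cycle probability of 0.75% to two decimals;
  a hazard-based option exists;
* all accounting is in PLN; euros appear only at reporting time (divisor
  4.2 PLN/EUR).

The per-cycle adverse-event discontinuation probability is a structural
parameter with default 0: the source trial reported tolerability comparable
to placebo and no usable rate was published. This is a stand-in, not a
published value, and it matters — any positive value drains the biologic
arm's zero-loss remission state and shrinks the incremental QALY gain (see
*Known limitations*).

## Costs and utilities

Per cycle, one unit of occupancy accrues (`cost_components()`):

* **Biologic drug** — 160 mg at week 0, 80 mg at week 2, then 40 mg every
  other week while treatment continues, at 54.55 PLN/mg, charged to the
  dosing calendar weeks that fall inside the cycle and below the cap;
* **Administration** — 468 PLN once, at initiation (charging per injection
  would overshoot the published drug-cost share several-fold);
* **Standard care** — 204.32 PLN per 8-week cycle (25.54 weekly) for states
  under pharmacological management (not post-surgical states);
* **Monitoring** — 121.56 PLN per 8-week cycle (15.20 weekly) for every
  alive state, including post-surgical ones (configurable);
* **Surgery / complication treatment** — 12,480 and 4,160 PLN, one-off on
  entry into their transient states;
* **Indirect costs** (societal perspective only) — 6,523.75 PLN/year for
  response and remission states, 22,934.58 PLN/year for every other alive
  state, including post-surgical ones by default (a documented switch treats
  post-surgical remission at the remission level).

Utilities: remission 0.880, response 0.760, post-surgical remission 0.610,
and 0.420 for induction, active disease, surgery and post-surgical
complications; death 0. QALYs are occupancy x utility x cycle length,
discounted at the effects rate.

State membership is valued at cycle start with no half-cycle correction
(`half_cycle = FALSE` default): the source study's framework gives no
indication of one, and the switch is exposed for anyone who disagrees.

## Background mortality and the synthetic life table

`read_life_table()` accepts any `age,qx` CSV. For a self-contained build the
package generates a Gompertz table, $q_x = 1-\exp(-a e^{bx})$, with
$b = 0.092$/year (a typical adult log-hazard slope) and $a = 4.554\times
10^{-5}$ solved so life expectancy at birth is 77.0 years — the magnitude of
the mid-2010s Polish general population. The synthetic table is a documented
stand-in, not a transcription of a statistical-office table: it has no
infant-mortality spike, no young-adult excess, and no sex structure
(the cohort is 42.7% female; with sex-specific tables a blend would be
appropriate). Over ages 40–70, where this cohort spends the horizon, a
smooth Gompertz tracks a real national table closely, which is why the
base-case comparisons below are tolerance bands rather than exact
reproductions.

## Sensitivity analyses

**One-way (OWSA).** Every parameter with a published range is set to its low
and high bound, all else at base, and both arms rerun (`run_owsa()`).
One-sided published ranges are swept with the missing side held at base. The
published bounds deliberately cross the utility ordering
(response's upper bound 0.94 exceeds remission's 0.88), so the engine does
not enforce that ordering during sweeps; `validate_parameters()` still
checks it by default.

**Probabilistic (PSA).** `build_psa_specs()` assigns beta distributions to
probabilities and utilities (moments matched to the point value and an SD of
range/3.92), lognormal to relative risks (median at the point value, log-SD
from the CI width), gamma to the one cost with a range (surgery), a uniform
fallback when a beta moment match is infeasible, and point masses to
degenerate ranges. Draws are independent across parameters (no correlation
structure was published); a draw failing joint validation (for example a
week-8 response + remission sum above 1) is redrawn and counted. The summary
reports both the ratio of means and the mean of per-draw ratios — they
differ markedly because the per-draw ICUR has heavy tails when the sampled
QALY gain approaches zero — plus a percentile CI of the per-draw ratios and
cost-effectiveness acceptability curves
$\mathrm{CEAC}(\lambda) = \Pr(\lambda\,\Delta Q - \Delta C \ge 0)$ on a
default willingness-to-pay grid of 0–150,000 EUR in 1,000-EUR steps.

## Numerical choices and problem sizes

Trace conservation is enforced at $10^{-9}$ per row; transition-matrix rows
at $10^{-9}$; currency and hazard round-trips at $10^{-9}$–$10^{-12}$. The
analysis scripts and the acceptance script run the full 202-cycle horizon;
the PSA uses 1,000 draws (the source study states no iteration count); the
microsimulation oracle in the test suite uses $10^5$ patients over the full
horizon (3-standard-error agreement per state) and 20,000 patients for a
shorter biologic-arm check. Property tests in the suite run on shortened
horizons where the property under test does not depend on horizon length.

## What the tests do and do not establish

The synthetic-data path (Gompertz life table, transcribed parameter file)
exercises every model component deterministically, so the suite establishes
internal correctness: conservation, oracle equivalence with an independent
microsimulation, closed-form accumulation identities, currency and
perspective separation, seeded reproducibility. Against the published
results, computed at the defaults by `scripts/acceptance.R`:
the incremental QALY gain (0.164 vs published 0.140) and the payer ICUR
(61,649 vs 76,120 EUR/QALY) fall within ±25%, the perspective ordering and
all signs match, the unlimited-duration scenario is more effective and less
cost-effective than the capped run as published (0.607 vs 0.164 QALYs;
69,507 vs 61,649 EUR/QALY), the PSA mean payer ICUR (56,938 EUR/QALY) falls
inside the published 95% CI (56,745–107,058), and the acceptability curve
crosses 50% at 63,000 EUR — in the published ~74,000 EUR region.

## Known limitations

* The societal ICUR (50,872 EUR/QALY) sits about 5% below a ±25% band
  around the published 71,457: the incremental indirect-cost saving and the
  QALY gain are both larger than published. Both discrepancies shrink with
  any positive adverse-event discontinuation probability, which the source
  study used but never printed; with it pinned at 0 the biologic arm's
  remission advantage persists too long. We deliberately did not tune this
  unpublished input.
* Exact QALY *levels* depend on the exact national life table year; only
  increments and ratios are compared.
* No disease-specific mortality, no adverse-event disutilities or costs, no
  price indexation over the horizon, no treatment-sequence modelling
  (infliximab, vedolizumab), and no correlation structure in the PSA.
* The model is a cohort average: individual heterogeneity (weight-based
  exposure, sex-specific mortality) is out of scope, and the
  microsimulation exists only as a test oracle.
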