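---
title: "Methods: the neonatal intensive care cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the neonatal intensive care cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neocea)
```

This vignette documents the model implemented in `neocea`: its structure
and assumptions, the numerical conventions, the choices made where the
design was genuinely open, and what the synthetic inputs do and do not
allow you to conclude.

## Model structure

The model couples two classical pieces of health-economic machinery.

**A neonatal decision tree.** Each gestational-age (GA) cohort faces, under
each strategy (with or without neonatal intensive care), a chance node for
neonatal death and, among survivors, a chance node for long-term
disability category (none / minor / major). The disability probabilities
are *conditional on neonatal survival* — the only reading under which the
published cohort tables are internally consistent — so the four
unconditional outcome probabilities are products along the branches and
sum to one. `evaluate_tree()` is the analytic evaluation;
`microsimulate_tree()` draws individual infants through the same two
stages and serves purely as an independent cross-check (the two must agree
within Monte Carlo error, and the test suite holds them to 3 binomial
standard errors at $n = 10^5$).

**A disability-stratified life table.** Survivors enter an annual life
table at age 0; the neonatal period itself is treated as a cost-only step
with no duration, so the 28-day window contributes mortality risk and
hospital costs but no person-time. The no-disability state uses the
background age-specific mortality $q(a)$; the minor state uses
$q(a) \cdot \mathrm{rr}_{\text{minor}}$ (1 in the base case — the elevated
minor-disability mortality analysis is switched on via the
`minor_mortality_rr` config key); the major state uses
$\min(1, \mathrm{rr}(a)\, q(a))$ with an age-banded relative-risk schedule
(24.6 / 8.5 / 3.6 / 2.2 / 1.5 over ages 0–9, 10–19, 20–39, 40–69, 70+).

## Demographic and numerical conventions

* **Terminal age.** $\omega = 100$ with forced terminal death:
  survivorship is set to 0 at exact age $\omega$. With zero mortality
  throughout, life expectancy is therefore $\omega - 0.5$.
* **Person-years.** Deaths are uniform within each year of age, so
  $L(a) = \tfrac{1}{2}(l(a) + l(a+1))$.
* **Discounting.** Mid-interval: $D(a) = (1+r)^{-(a+0.5)}$, $r = 0.03$
  per annum by default, applied to both health (DALE) and long-term costs.
* **Band expansion.** All age-banded inputs (relative risks, background
  disability weights, long-term cost schedules) use half-open bands
  $[a_0, a_1)$ expanded to annual ages as piecewise-constant values —
  the simplest faithful expansion of abridged inputs.
* **Units.** Probabilities and proportions live on $[0,1]$ internally;
  the printed-percentage inputs are divided by 100 in exactly one
  constructor (`base_case_inputs()`), which removes the classic
  100×-error failure mode and keeps the config round-trip exact. Costs
  are 2005 US$; cohort counts are thousands of live births.

## Health summary measures

For a state with disability weight $w$ and background age-specific
disability weight $b(a)$, a year of age $a$ counts as a healthy fraction
$H(a)$. Two combination rules are available:

* `complement_product` (default): $H(a) = (1-w)(1-b(a))$,
* `literal_product`: $H(a) = 1 - w\,b(a)$.

The phrase "multiplied by background weights" admits both readings; the
default is the complement product because it also adjusts the
*no-disability* state ($w = 0$ still yields $H = 1 - b(a)$), keeping the
background burden meaningful across states, and because it is the
standard multiplicative-utility combination. The literal rule is retained
as a selectable alternative; with $w = 0$ it leaves the healthy state
unadjusted.

Then, per state,
$$\mathrm{LE} = \sum_a L(a), \qquad
  \mathrm{DALE} = \sum_a D(a)\, L(a)\, H(a),$$
and DFLE equals LE for the no-disability state and 0 for disabled states —
a deliberately conservative convention (disabled survivorship contributes
no disability-free years; other conventions exist and the published
disability-free gains are not forced to match). Strategy-level values are
probability-weighted averages over the four neonatal outcomes, with death
contributing zero. **DALYs averted** are the between-strategy difference
in DALE; no age weighting is applied.

## Costing

Ingredients costing throughout: quantities × unit prices.

* **Bed-days** mix survivor and death lengths of stay by the neonatal
  mortality probability, then split by the ventilated share between the
  ventilated and non-ventilated daily prices.
* **Surfactant and surgeries** accrue to *all* live-born infants, not
  survivors only — the only convention that reproduces the published
  per-infant cost cells. The shipped dose counts are final expected doses
  per patient (any dose-size adjustment is already folded in).
* **Infection increment** = P(infection) × 11% markup × the baseline
  initial-hospitalization cost, where the base includes bed-days,
  surfactant and surgery. (The printed cells are robust at one decimal to
  whether surfactant is in the base; the broader base is fixed here.)
* **Rehospitalization** accrues to survivors only, at the same per-GA
  day counts under both strategies (survivor weighting differs).
* **Long-term disability costs** apply age-banded annual schedules
  (minor/major) along the state survival curve with the same mid-interval
  discounting. The schedules ship already rescaled to the Mexican price
  level; `rescale_longterm_costs()` exposes the GDP-ratio rescaling for
  transfers to other settings, and a scalar `longterm_multiplier`
  provides a clean handle for sensitivity analysis.
* Without intensive care, no initial-hospitalization components accrue at
  all. Time costs, caregiver/productivity and educational costs are out
  of scope.

## Decision analysis

ICER = Δcost / ΔDALE per GA group. Sign cases are explicit: a
cost-saving, health-improving intervention is *dominant*; zero effect
difference yields an explicit *undefined* result rather than a number.
Classification follows GDP-per-capita thresholds with "below" read
strictly — an ICER exactly at 1× GDP classifies as *potentially* (ties go
to the weaker class); the closed interval up to 3× is *potentially*;
above, *not cost-effective*. Machine outputs keep unrounded values;
display rendering (thousands at one decimal, `"<0.1"` for positive
sub-threshold cells, two-significant-figure ICERs) happens only in the
CSV writers, and report totals are summed before rounding.

## Sensitivity machinery

* **Tornado** (`tornado()`): one-at-a-time substitution of each parameter
  at its low/high bound, everything else at base, ordered by ICER spread.
  If substituting one member of a morbidity pair pushes
  $p_\text{minor} + p_\text{major}$ above 1, the untouched partner is
  clipped down with a warning.
* **Presets** (`scenario_preset()`): three *cumulative* scenarios biased
  against intensive care — (1) no morbidity benefit (care's disability
  probabilities raised to the no-care values), (2) additionally mortality
  with care at the unfavourable bounds of its ranges (0.75 / 0.51 / 0.14),
  (3) additionally all unit costs doubled. Each stage includes the
  previous, matching how the scenarios are narratively chained.
* **PSA** (`run_psa()`): every ranged parameter sampled independently per
  draw (no correlation structure is asserted by the source material), the
  full pipeline re-run, Δcost and ΔDALE recorded per GA group;
  deterministic given the seed.
* **CEAC** (`ceac()`): $P(\lambda \cdot \Delta E - \Delta C > 0)$ as the
  fraction of draws, over a willingness-to-pay grid defaulting to
  0–3×GDP per capita in US$100 steps.

**Distributions.** The original analysis's distributional families are not
published, so the default is a transparent `uniform(low, high)`. Also
selectable per parameter: `triangular` with mode at the base value;
`beta` rescaled to `[low, high]` with its mean matched to the base value
at a fixed concentration of 4; `gamma` with mean at the base value and
`(low, high)` read as an approximate 95% interval. These are the
package's own pragmatic parameterizations — with only a (low, base, high)
triple there is no information to fit anything richer.

**Ranges.** The shipped config carries, per parameter: the published
upper bounds for mortality-with-care (0.75 / 0.51 / 0.14); halving and
doubling for every unit cost (as the published cost table's footnote
prescribes); and ±25% around base, clipped to legal ranges, for
everything else — a transparent, fully overridable stand-in for the
unpublished range table.

## Synthetic inputs: what they are and are not

Two inputs the model needs were never published and are generated
synthetically:

* **The background mortality schedule** (`make_life_table()`): a
  parametric middle-income-country shape — infant mortality
  $q(0) = 0.018$, a childhood/young-adult floor of $4\times10^{-4}$, and
  a Gompertz adult rise $8\times10^{-5} e^{0.085a}$, capped at 1. These
  defaults give a life expectancy at birth of 73.9 years, consistent with
  mid-2000s Mexico; they are a realism choice, not a fit to any national
  table.
* **Background disability weights** (`make_background_weights()`):
  non-decreasing piecewise-constant weights from 0.03 (childhood) to 0.27
  (80+), emulating the shape of published regional age patterns.
* **Category disability weights**: the shipped $w_\text{minor} = 0.12$,
  $w_\text{major} = 0.40$ are plausible placeholders for the two
  composite categories (the originally derived values are not published)
  and are ordinary config inputs — replace them with
  `disability_weights:` in the YAML.

Consequences: the neonatal-period tables and the per-infant
hospitalization cost components depend only on published inputs and are
reproduced cell-by-cell; everything that flows through the life table
(life expectancies, DALE, long-term costs, ICERs, CEAC probabilities) is
*structurally* faithful but numerically indicative. Those quantities are
therefore tested by properties — brute-force summation oracles (relative
tolerance $10^{-9}$), closed forms (constant $q = 1/2$ gives
$\mathrm{LE} = 1.5$; zero mortality gives $\omega - 0.5$; zero weights and
discount give DALE = LE), equivariances (all ICERs scale exactly with a
common cost factor), monotonicities, and qualitative mirroring (all GA
groups highly cost-effective; preset chain weakly increases ICERs; CEAC at
$\lambda =$ US$1,000 ordered youngest ≤ middle ≤ oldest) — rather than by
value matching. Passing them shows the engine computes its defining
formulas correctly and that the published qualitative conclusions are
robust under a realistic demographic stand-in; it does not certify the
original point estimates.

## Degenerate inputs and tie-breaks

Probability caps ($\mathrm{rr}\cdot q > 1$), certain neonatal death
(`p_mort = 1` → all survivor cells zero, zero life-years and long-term
costs), empty cohorts (all-zero tables), zero prices (zero costs), zero
effect difference (explicit undefined ICER), and all-zero aggregation
frequencies (an error, not NaN) are all pinned by tests. Validation
collects *all* invariant violations with field paths rather than failing
on the first.

## Problem sizes

The default configuration is small by construction — three GA groups, a
100-age life table — so the full pipeline evaluates in milliseconds and
the shipped test suite (including a 20-table oracle sweep, twenty
$10^5$-draw microsimulations, and a few hundred-draw PSAs) completes in
well under a minute. PSA precision scales as $n^{-1/2}$; $n = 1000$
draws give CEAC probabilities to about ±1.5 percentage points, and the
`run_psa()` default is adequate for the curves' qualitative shape.

## Known limitations

* No within-neonatal-period time structure; the 28-day window is one step.
* DFLE for disabled survivors is 0 by convention (see above).
* No cohort-component projection, secular mortality improvement, or
  expected-value-of-perfect-information analysis.
* Parameter uncertainty is sampled independently; real joint uncertainty
  (e.g., mortality and morbidity moving together) is not represented.
* The synthetic demographic inputs make absolute life-course results
  setting-indicative, not estimates for any specific country.
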