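# neocea

Cost-effectiveness analysis of neonatal intensive care for preterm infants,
as a decision-analytic cohort model in R.

Neonatal intensive care units (NICUs) sharply reduce mortality among
preterm infants, but survivors face elevated risks of lifelong disability
and the care itself is resource-intensive — a live question for
middle-income health systems deciding what an insurance benefits package
should cover. `neocea` implements the standard health-economic answer to
that question: a decision-tree / life-table model that follows a birth
cohort, stratified by gestational age (GA) at birth (24–26, 27–29 and
30–33 weeks), from the neonatal period through the rest of life, with and
without intensive care, and prices the difference.

## Model

**Neonatal period.** For each GA group *g* and strategy *s*, a decision
tree distributes the cohort over four outcomes — neonatal death, and
survival to 28 days with no, minor or major disability — from the neonatal
mortality probability *p*<sub>mort</sub> and the disability probabilities
*p*<sub>minor</sub>, *p*<sub>major</sub> (conditional on survival):

```
P(death) = p_mort                P(minor) = (1 − p_mort) · p_minor
P(none)  = (1 − p_mort) ·        P(major) = (1 − p_mort) · p_major
           (1 − p_minor − p_major)
```

**Life course.** Survivors enter an annual life table at age 0. The
no-disability and minor-disability states use the background age-specific
mortality schedule *q(a)* (minor optionally multiplied by an excess-risk
factor); the major-disability state multiplies *q(a)* by an age-banded
relative-risk schedule (24.6 at ages 0–9 down to 1.5 at 70+), capped at 1.
With deaths uniform within each year, person-years are
*L(a) = (l(a)+l(a+1))/2* and life expectancy is Σ *L(a)*. The
disability-adjusted life expectancy (DALE) discounts each year at 3% per
annum at mid-interval and weights it by a healthy fraction combining the
state disability weight *w* with the age-specific background disability
weight *b(a)*: *H(a) = (1−w)(1−b(a))* by default. DALYs averted are the
difference in DALE between strategies.

**Costs** (2005 US$, ingredients approach). With intensive care: ventilated
and non-ventilated bed-days (survivor/death stays mixed by *p*<sub>mort</sub>),
surfactant, four neonatal surgeries, a nosocomial-infection markup
(probability × 11% of the baseline stay cost), first-year rehospitalization
for survivors, and discounted lifetime disability costs from age-banded
annual schedules. Without intensive care only rehospitalization and
long-term disability costs accrue.

**Decision metric.** ICER = Δcost / DALYs averted, classified against the
GDP-per-capita thresholds (below 1× GDP: highly cost-effective; 1–3×:
potentially; above 3×: not cost-effective).

Uncertainty is handled by one-way (tornado) analysis, three cumulative
bias-against-intensive-care scenario presets, Monte Carlo probabilistic
sensitivity analysis, and cost-effectiveness acceptability curves (CEACs).

The published base-case inputs (probabilities, resource quantities, unit
costs, births) ship with the package; the demographic inputs that were
never published — the national mortality schedule and age-specific
background disability weights — are generated synthetically
(`make_life_table()`, `make_background_weights()`), so absolute life-course
results are indicative rather than exact reproductions.

## Worked example

```r
library(neocea)

scenario <- example_scenario(seed = 1)   # base-case inputs + synthetic life table
base_case_report(scenario)
```

```
        ga delta_le delta_dfle dalys_averted delta_cost   icer           classification
1 24-26 wk    26.49      12.14         8.825      10644 1206.1  highly cost-effective
2 27-29 wk    41.41      25.26        14.221       8933  628.1  highly cost-effective
3 30-33 wk    34.17      35.26        12.619       3116  247.0  highly cost-effective
```

Per infant, intensive care adds 26–41 undiscounted life-years and averts
9–14 discounted DALYs at an incremental cost of US$3,100–10,600, giving
ICERs of roughly US$1,200, US$630 and US$250 per DALY averted — all far
below Mexico's 2005 GDP per capita of US$8,200, i.e. highly cost-effective
in every GA group, and most attractive for the oldest (most numerous)
group.

```r
population_table(scenario)        # cohort outcomes in thousands (with/without care)
cost_table(scenario)              # per-infant cost components, US$
tornado(scenario, "24-26 wk")     # one-way ICER ranges
psa <- run_psa(scenario, n = 1000, seed = 1)
ceac(psa, default_lambda_grid(scenario$econ))
```

Even the harshest preset — no morbidity benefit, mortality benefit at the
unfavourable bound, and all unit costs doubled
(`scenario_preset("plus_double_costs", scenario)`) — leaves every ICER
below GDP per capita.

A thin command-line wrapper ships in `inst/cli/neocea`
(`neocea run|tornado|psa|ceac|scenario|synth`).

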