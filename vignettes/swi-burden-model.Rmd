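---
title: "Modelling the hospital burden of sternal-wound infections after CABG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the hospital burden of sternal-wound infections after CABG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swiburden)
```

## The problem

Sternal-wound infections (SWIs) are among the most serious complications
of coronary artery bypass graft (CABG) surgery. From a hospital's
perspective their burden is extra bed-days — in the intensive care unit
(ICU) and on the general ward (GW) — plus readmissions for deep
infections. Published country-level inputs are sparse and heterogeneous:
different surveillance windows, different superficial/deep splits, and
many missing values. This package provides a transparent, testable chain
from such a country table to an annual burden estimate with quantified
uncertainty.

## The cohort model

A closed cohort enters the model on the day of surgery and is propagated
through daily cycles for one year (`horizon_days = 365`; lengths of stay
are reported in days and a one-year horizon matches an annual budgeting
view, which motivates the daily cycle). The care-pathway states are
surgery, ICU with mechanical ventilation (MV), prolonged MV, ICU without
MV, general ward, and out of hospital; superimposed are the SWI treatment
states (in-hospital superficial/deep treatment, outpatient superficial
care, deep-SWI readmission), a recovered compartment and death.

### Sojourn calibration

The infection-free stay is one fixed surgery day followed by geometric
sojourns. The remaining `mean_los_days - 1` days are divided
`icu_fraction_of_los` : remainder between ICU and GW; ICU time divides
`icu_mv_share` : remainder between ventilated and unventilated states; a
fraction `prolonged_mv_fraction` of ventilated patients additionally pass
through prolonged MV with `prolonged_mv_multiplier` times the ordinary MV
sojourn. A geometric state cannot have a mean below one day, so any stage
whose target mean m falls below 1 is *entered* with probability m and left
after a single day; the expected time in every stage — and hence the
expected length of stay — is then met exactly for any target, which the
test suite verifies against the absorbing-chain closed form
(row sums of $(I-Q)^{-1}$) for stays of 5, 9.77, 14.4 and 30 days.

### The incidence curve

Cumulative SWI incidence follows a Hill curve
$CI(t) = i_{max}\, t^n / (t_{50}^n + t^n)$. The shape is shared across
countries; defaults are $t_{50} = 12$ days and $n = 2$, giving onset
concentrated in the first post-operative weeks and a plateau well before
day 90, consistent with the clinical picture of sternal-wound infection
presenting mostly within the first month. Both parameters are exposed in
the configuration and resampled in the sensitivity analysis. The height
$i_{max}$ is solved in closed form per country so the curve passes through
the observed incidence at the end of the surveillance window; if the
closed form exceeds 1 it is clamped with a warning. By default the curve
continues toward $i_{max}$ beyond the surveillance window — an infection
risk does not stop when surveillance stops — but
`extrapolate_incidence = FALSE` caps it at the surveillance-day value for
users who prefer the conservative reading.

The curve enters the daily cycle as conditional hazards
$h_d = (CI(d) - CI(d-1)) / (1 - CI(d-1))$, an exact embedding: the
survival product $\prod_d (1-h_d)$ reproduces $1 - CI(t)$ to machine
precision. Hazards apply equally to every not-yet-infected patient, in
hospital or discharged.

### Costing rules and the readmission decision

* In-hospital superficial SWI: `sswi_extra_los_days` extra days, by
  default all GW, at the country's daily rates.
* In-hospital deep SWI: `dswi_extra_los_days` extra days, by default 30%
  ICU / 70% GW (`dswi_extra_icu_fraction`), at the country's daily rates.
* Out-of-hospital superficial SWI: outpatient, no hospital cost.
* Out-of-hospital deep SWI: a readmission episode.

The readmission episode needed a genuine design decision. We model it as
lasting the country's deep-SWI extra stay (those bed-days are counted in
the extra-GW-day total and in the additional-hospital-days output) but
costed as a **single universal `readmission_cost`** rather than at
country-specific day rates. Two considerations drive this. First, the
extra-stay input is defined as the additional hospitalisation needed to
treat a deep SWI, which does not depend on whether onset happened before
or after discharge; a 10-day token readmission would make roughly half of
all deep SWIs nearly costless in bed-day terms and is inconsistent with
the single-hospital burden figures the model is validated against.
Second, a *universal* readmission cost is only coherent if the episode is
not simultaneously costed at country day rates. The default of €25,000 is
representative of published European costs of a deep sternal-wound
readmission (several weeks of inpatient care plus surgical revision — at a
typical €600–700 European ward rate, a 37-day episode comes to a similar
figure). It is configurable and resampled in the PSA.

Mortality is a small uniform daily in-hospital probability (default
5e-4/day, zero out of hospital); source models report that death is
possible from any state but publish no rates, so this is a declared
assumption, resampled in the PSA, to which burden outputs are insensitive
at the default magnitude.

### Accounting identities

Occupancy is a probability vector every day (conservation is tested at
1e-9 over all 365 cycles). Costs decompose exactly: the baseline component
is the infection-free pathway (computed from a parallel zero-hazard run,
so the baseline of a full run is *identical* to a zero-incidence run), and
the SWI component satisfies

```
swi_cost = swi_icu_days * icu_day_cost
         + (swi_gw_days - readmission_days) * gw_day_cost
         + n_readmissions * readmission_cost
```

which the tests assert to 1e-9. Cost per SWI divides total SWI cost by
*model-realised* SWI events (after mortality), not the input incidence.

## Country data handling

Tables are comma-separated UTF-8 with dot decimals; blank cells are
missing. If `currency` and `cost_year` columns are present and an
adjustment table is supplied, unit costs are converted at the
publication-year average exchange rate first and then inflated to 2017
with country-specific factors (conversion before inflation, since the
conversion rate is anchored to the publication year).

Countries with at least 5 of the 10 inputs are included. Missing inputs
are replaced by the median of the known values — the standard sample
median, i.e. the midpoint of the two central values for even counts — and
the interquartile range is recorded in the imputation report. Medians are
computed over the *included* countries by default (the excluded rows were
judged too sparse to inform the analysis); a `reference` argument lets the
user widen the pool. Imputation is idempotent and never touches known
values.

## The probabilistic sensitivity analysis

Each run redraws all ten inputs of a country: a value is drawn uniformly
between the minimum and maximum of the known values of that input across
countries; where the country itself had a known value, the redrawn input
is the mean of the known value and the draw (so it stays within half the
bound interval around the known value), and where it was missing the draw
is used directly. The uniform distribution is the minimal assumption for a
draw specified only by its bounds. Global parameters are redrawn from
normal distributions centred on the base value with standard deviation
`cv` times the base value (default `cv = 0.10`, a moderate spread in the
absence of a published one), truncated to their domains; ten scalars are
resampled per run. The default is 44 runs per country. Every
(country, run) pair derives its own child seed from the master seed, so
results are order-independent and byte-reproducible.

## The synthetic generator

`generate_country_table()` emulates a realistic sparse country table:
SWI incidence uniform on 1.6–10.4% and superficial share the complement
of a 23.3–76% deep share (the ranges reported across European countries),
surveillance windows drawn from {30, 60, 90, 180} days, and
synthetic-only plausible magnitudes for the rest (ICU €500–3,000/day, GW
€200–1,200/day, populations 0.3–85 million, 20–100 CABG/100k/year, stays
of 7–20 days, superficial extra stay 0–5 days, deep extra stay 14–40
days). Missingness is applied independently per cell with configurable
probability. What it does *not* emulate: correlations between inputs
(richer countries have both higher costs and different incidence),
non-uniform marginals, and reporting biases — so passing tests demonstrate
the machinery on structurally realistic tables, not calibration to any
real country.

## Numerical choices and problem sizes

* All calibrations are closed-form; no iterative optimisation is used.
* Zero extra-stay inputs route SWI patients through a zero-day treatment
  stage (the onset is still counted); zero incidence produces exactly zero
  SWI burden.
* Degenerate PSA bounds (all countries sharing a value) reproduce the
  known value exactly; with `cv = 0` the PSA collapses to the base case.
* The test suite validates the cohort expectations against a
  200,000-patient microsimulation on five random parameter sets (within
  three standard errors), runs the height-calibration round-trip on 1,000
  random triples at 1e-10, and exercises the PSA at the full study scale
  of 26 countries × 44 runs = 1,144 model evaluations.

## Limitations

* A single care pathway and universal non-country constants are assumed
  across all settings; hospital-level variation is not modelled.
* The Hill-curve shape is a clinical judgement exposed as configuration,
  not a fit to patient-level onset times.
* Patient-level risk factors (age, diabetes) enter only through whatever
  the user encodes in the country inputs.
* Outpatient care is costed at zero by design (hospital perspective).
* No quality-of-life or cost-effectiveness outputs are produced.
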