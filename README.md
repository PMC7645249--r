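# swiburden

Estimates the annual hospital cost burden of sternal-wound infections
(SWIs) after coronary artery bypass graft (CABG) surgery across European
countries, from the hospital perspective: SWI-attributable costs, ICU and
general-ward (GW) bed-days, and readmissions. It is aimed at health
economists and infection-control teams who need country-level burden
estimates from sparse, heterogeneous published inputs.

## The model

Patients enter a **daily-cycle Markov cohort model** at the start of
surgery and are followed for one year through the care pathway

```
SURGERY -> ICU on mechanical ventilation (MV) [-> prolonged MV]
        -> ICU off MV -> general ward -> out of hospital
```

with death possible from any in-hospital state. At any point a patient can
develop an SWI, superficial (SSWI) or deep (DSWI). Cumulative SWI
incidence over time since surgery follows a **Hill curve**

> CI(t) = i_max · tⁿ / (t50ⁿ + tⁿ)

whose shape (t50, n) is shared across countries and whose height i_max is
calibrated per country so the curve passes through the observed incidence
at the end of that country's surveillance window. The curve is embedded in
the daily cycle as conditional hazards h_d = (CI(d) − CI(d−1))/(1 − CI(d−1)).
Transition speeds are calibrated from the country's mean length of stay.

Costing: in-hospital SWIs add the country's extra length of stay (SSWI and
DSWI separately) costed at ICU/GW daily rates under a configurable ward
split; an out-of-hospital DSWI triggers a readmission episode lasting the
DSWI extra stay, counted in GW bed-days but costed as a single universal
readmission cost; out-of-hospital SSWI care is outpatient and free.

Around the model sit:

* **Country-data handling** — CSV loading with validation, currency
  conversion and inflation to 2017 euros, the ≥5-of-10 data-point
  inclusion rule, and median imputation of missing inputs with an
  IQR-annotated imputation report.
* **Probabilistic sensitivity analysis (PSA)** — each run redraws every
  country input uniformly between the cross-country bounds of the known
  values (averaged with the known value where one exists) and every global
  parameter from a normal distribution; 44 runs per country by default,
  summarised as median and range.
* **A patient-level microsimulation** implementing the identical daily
  rules, used in the test suite as an oracle for the cohort expectations.
* **A synthetic country-table generator** so the full pipeline is testable
  without any external data.

## Worked example

```r
library(swiburden)

ds  <- generate_country_table(12, missingness = 0.2, seed = 2017)
res <- run_burden_analysis(ds)   # include -> impute -> model -> aggregate
res$summary$totals
#>   n_countries  n_cabg total_swi_cost extra_icu_days extra_gw_days n_readmissions
#> 1          12 178881.     152361914.         22641.       137163.          2989.
```

Twelve synthetic countries with ~179,000 CABG procedures a year lose about
€152 million to SWIs, made up of ~22,600 extra ICU days, ~137,000 extra GW
days and ~3,000 readmissions. The PSA quantifies the uncertainty:

```r
psa <- run_psa_analysis(ds, seed = 1, runs_per_country = 44)
psa$psa$europe
#>   output             median        min        max
#> 1 total_swi_cost 164210920. 114961697. 202565851.
#> 2 extra_icu_days     24720.     15461.     32367.
#> 3 extra_gw_days     147260.    102234.    187802.
#> 4 n_readmissions      2959.      2209.      3895.
```

A published single-hospital cohort (983 CABG patients, 126 SWIs over 60
days, 96 superficial; deep SWIs added 37 hospital days; €1,010 per ward
day) ships as a fixture:

```r
fx <- jena_fixture()
b  <- compute_burden(run_cohort(fx$record, fx$globals), n_cabg = 983)
round(c(b$cost_per_swi, b$extra_icu_days + b$extra_gw_days), 1)
#> 7307.0 1127.0
```

i.e. about €7,300 per SWI and ~1,130 additional hospital days for that
cohort — the model's point of contact with independently published burden
figures.

A thin command-line wrapper with `run`, `psa`, `synth` and `validate`
subcommands is installed at `inst/cli/swiburden.R`; example input files
(synthetic country table, adjustment table, parameter YAML) are under
`inst/extdata/`.

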