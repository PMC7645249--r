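# Shared fixtures: a plausible mid-range country record and small datasets
# built in code.

make_record <- function(...) {
  rec <- list(
    country_id = "T1",
    population = 1e7,
    cabg_rate_per_100k = 60,
    mean_los_days = 10,
    icu_day_cost = 1500,
    gw_day_cost = 600,
    swi_incidence = 0.04,
    surveillance_days = 30,
    sswi_share = 0.6,
    sswi_extra_los_days = 2,
    dswi_extra_los_days = 25
  )
  utils::modifyList(rec, list(...))
}

# one random fully-specified record drawn from the synthetic ranges
random_record <- function() {
  as.list(generate_country_table(1)$data[1, ])
}

make_table_df <- function(n = 4) {
  ds <- generate_country_table(n, missingness = 0, seed = 99)
  ds$data
}

COUNTRY_INPUTS_test <- function() swiburden:::COUNTRY_INPUTS

# expected infection-free length of stay by the absorbing-chain closed form:
# row sums of (I - Q)^{-1} over the transient hospital states, death off
expected_los_oracle <- function(record, globals) {
  gl <- unclass(globals)
  gl$daily_mortality <- 0
  g <- do.call(global_params, gl)
  m <- transition_matrix(record, g, hazard = 0)
  hosp <- c("SURGERY", "ICU_MV", "ICU_MV_PROLONGED", "ICU_NO_MV", "GW")
  q <- m[hosp, hosp]
  n_mat <- solve(diag(length(hosp)) - q)
  sum(n_mat["SURGERY", ])
}
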