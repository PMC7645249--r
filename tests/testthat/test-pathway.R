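test_that("sojourn calibration recovers the target mean length of stay", {
  g <- global_params()
  for (los in c(5, 9.77, 14.4, 30)) {
    soj <- calibrate_sojourns(los, g)
    expect_equal(soj$expected_los, los, tolerance = 0.01)
    # independent fundamental-matrix oracle on the full transition matrix
    rec <- make_record(mean_los_days = los)
    expect_equal(expected_los_oracle(rec, g), los, tolerance = 0.01)
  }
  # a one-day stage is left with certainty
  soj <- calibrate_sojourns(2.25, g) # general-ward target is exactly 1 day
  expect_equal(soj$stages$gw$exit, 1)
  expect_error(calibrate_sojourns(0, g), "mean_los_days")
  expect_error(global_params(icu_fraction_of_los = 1), "icu_fraction_of_los")
})

test_that("transition matrix rows sum to one for any hazard", {
  g <- global_params()
  for (i in 1:10) {
    set.seed(300 + i)
    rec <- random_record()
    for (h in c(0, 0.002, 0.3, 1)) {
      m <- transition_matrix(rec, g, hazard = h)
      expect_lt(max(abs(rowSums(m) - 1)), 1e-12)
      expect_true(all(m >= 0 & m <= 1))
    }
  }
})

test_that("cohort occupancy is conserved over the whole horizon", {
  g <- global_params()
  for (rec in list(make_record(), jena_fixture()$record)) {
    cohort <- run_cohort(rec, g)
    occ <- as.matrix(cohort$trace[, swiburden:::PATHWAY_STATES])
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
    # accruals never decrease
    for (col in c("swi_cost", "swi_icu_days", "swi_gw_days",
                  "n_readmissions", "base_cost")) {
      expect_true(all(diff(cohort$trace[[col]]) >= -1e-15))
    }
  }
})

test_that("zero incidence gives exactly zero SWI burden and the infection-free trace", {
  g <- global_params()
  rec <- make_record(swi_incidence = 0)
  cohort <- run_cohort(rec, g)
  expect_identical(cohort$totals$swi_cost, 0)
  expect_identical(cohort$totals$n_readmissions, 0)
  expect_identical(cohort$totals$realised_swi, 0)
  swi_states <- c("IN_HOSP_SSWI", "IN_HOSP_DSWI", "OUTPATIENT_SSWI",
                  "READMITTED_DSWI", "RECOVERED")
  expect_true(all(as.matrix(cohort$trace[, swi_states]) == 0))
  b <- compute_burden(cohort)
  expect_identical(b$total_swi_cost, 0)
  expect_identical(b$relative_increase, 0)
  expect_true(b$zero_swi)
  expect_true(is.na(b$cost_per_swi))
})

test_that("without death all mass ends out of hospital or recovered", {
  gl <- unclass(global_params())
  gl$daily_mortality <- 0
  g <- do.call(global_params, gl)
  cohort <- run_cohort(make_record(mean_los_days = 8), g)
  fin <- cohort$final_occupancy
  # a sliver of late-onset mass is still in treatment at the horizon
  terminal <- sum(fin[c("OUT_OF_HOSPITAL", "OUTPATIENT_SSWI", "RECOVERED")])
  expect_equal(terminal, 1, tolerance = 5e-4)
  expect_identical(unname(fin["DEAD"]), 0)
})

test_that("SWI cost is non-decreasing in incidence, unit costs and extra stays", {
  g <- global_params()
  sweep_field <- function(field, values) {
    costs <- vapply(values, function(v) {
      rec <- make_record()
      rec[[field]] <- v
      run_cohort(rec, g)$totals$swi_cost
    }, numeric(1))
    expect_true(all(diff(costs) >= -1e-12), label = paste("monotone in", field))
  }
  sweep_field("swi_incidence", seq(0, 0.12, by = 0.02))
  sweep_field("icu_day_cost", c(500, 1000, 2000, 3000))
  sweep_field("gw_day_cost", c(200, 500, 900, 1200))
  sweep_field("sswi_extra_los_days", c(0, 1, 3, 5))
  sweep_field("dswi_extra_los_days", c(10, 20, 30, 40))
})

test_that("costs decompose exactly into baseline plus SWI-attributable parts", {
  g <- global_params()
  rec <- make_record()
  full <- run_cohort(rec, g)
  none <- run_cohort(utils::modifyList(rec, list(swi_incidence = 0)), g)
  # the baseline component of the full run equals the zero-incidence run
  expect_identical(full$totals$base_cost, none$totals$base_cost)
  expect_identical(full$totals$base_icu_days, none$totals$base_icu_days)
  # accounting identity: costed SWI days at country rates plus readmission
  # lumps reproduce the SWI cost exactly
  for (i in 1:5) {
    set.seed(400 + i)
    rec <- random_record()
    t <- run_cohort(rec, g)$totals
    reconstructed <- t$swi_icu_days * rec$icu_day_cost +
      (t$swi_gw_days - t$readmission_days) * rec$gw_day_cost +
      t$n_readmissions * g$readmission_cost
    expect_equal(t$swi_cost, reconstructed, tolerance = 1e-9)
  }
})

test_that("an in-hospital deep SWI costs its extra ward days at the daily rate", {
  # keep the whole cohort in hospital through the onset window so that all
  # deep SWIs are treated in-house: cost per SWI is then the extra stay
  # at the ward rate
  gl <- unclass(global_params())
  gl$daily_mortality <- 0
  gl$dswi_extra_icu_fraction <- 0
  g <- do.call(global_params, gl)
  rec <- make_record(mean_los_days = 200, sswi_share = 0,
                     dswi_extra_los_days = 37, gw_day_cost = 1010,
                     swi_incidence = 0.05, surveillance_days = 30)
  t <- run_cohort(rec, g)$totals
  expect_equal(t$swi_cost / t$realised_swi, 37 * 1010, tolerance = 0.01)
  # only the late Hill-tail onsets fall outside the hospital stay
  expect_lt(t$n_readmissions / t$realised_swi, 0.03)
})

test_that("burden scaling and ratios follow their definitions", {
  g <- global_params()
  cohort <- run_cohort(make_record(), g)
  b <- compute_burden(cohort)
  expect_equal(b$n_cabg, 1e7 * 60 / 1e5) # 6000
  expect_equal(b$relative_increase, b$total_swi_cost / b$baseline_cost)
  expect_equal(b$cost_per_swi, b$total_swi_cost / b$n_swi)
  expect_equal(b$total_swi_cost, b$n_cabg * cohort$totals$swi_cost)
})

test_that("cohort expectations agree with a patient-level microsimulation", {
  g <- global_params()
  rec <- make_record()
  cohort <- run_cohort(rec, g)$totals
  ms <- simulate_cohort_micro(rec, g, n_patients = 30000, seed = 77)
  expected <- c(
    swi_cost = cohort$swi_cost,
    swi_icu_days = cohort$swi_icu_days,
    swi_gw_days = cohort$swi_gw_days,
    n_readmissions = cohort$n_readmissions,
    realised_swi = cohort$realised_swi
  )
  for (o in names(expected)) {
    expect_lt(abs(ms$means[[o]] - expected[[o]]),
              3 * ms$se[[o]] + 1e-12,
              label = paste("microsim agreement for", o))
  }
})

test_that("Europe aggregation sums burdens and summarises distributions", {
  g <- global_params()
  b1 <- compute_burden(run_cohort(make_record(country_id = "A"), g))
  agg1 <- aggregate_europe(b1)
  expect_equal(agg1$totals$total_swi_cost, b1$total_swi_cost)
  # two identical countries double the totals but keep the medians
  b2 <- b1
  b2$country_id <- "B"
  agg2 <- aggregate_europe(dplyr::bind_rows(b1, b2))
  expect_equal(agg2$totals$total_swi_cost, 2 * b1$total_swi_cost)
  expect_equal(agg2$distribution$median,
               agg1$distribution$median)
  # column-sum oracle on a synthetic set
  ds <- generate_country_table(6, seed = 5)
  res <- dplyr::bind_rows(lapply(seq_len(6), function(i) {
    compute_burden(run_cohort(as.list(ds$data[i, ]), g))
  }))
  agg <- aggregate_europe(res)
  expect_equal(agg$totals$extra_icu_days, sum(res$extra_icu_days))
  expect_equal(agg$totals$n_readmissions, colSums(res["n_readmissions"])[[1]])
})

test_that("a short hazard schedule is rejected", {
  g <- global_params()
  p <- hill_params(0.05, 12, 2)
  hs <- hazard_schedule(p, horizon = 100, sswi_share = 0.5)
  expect_error(run_cohort(make_record(), g, hazard = hs), "shorter")
  expect_error(run_cohort(make_record(icu_day_cost = NA), g),
               "not fully specified")
})
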