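#' Patient-level microsimulation of the care pathway
#'
#' Simulates individual patients through exactly the same daily transition
#' rules as the cohort model ([run_cohort()]), drawing each patient's state
#' sequence stochastically. Used as an internal oracle: the cohort model's
#' expectations must agree with the microsimulation means within
#' Monte-Carlo error.
#'
#' @param record One fully-specified country row.
#' @param globals A [global_params()] object.
#' @param n_patients Number of simulated patients.
#' @param seed Optional RNG seed.
#' @param hazard Optional [hazard_schedule()]; derived from the record when
#'   absent.
#' @return A list with per-patient means (`means`), their standard errors
#'   (`se`) and `n_patients`. Outputs: `swi_cost`, `swi_icu_days`,
#'   `swi_gw_days`, `n_readmissions`, `realised_swi`.
#' @export
simulate_cohort_micro <- function(record, globals, n_patients = 200000L,
                                  seed = NULL, hazard = NULL) {
  stopifnot(inherits(globals, "global_params"))
  record <- as.list(record)
  check_record_complete(record)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(hazard)) {
    params <- calibrate_height(record$swi_incidence, record$surveillance_days,
                               t50 = globals$hill_t50, n = globals$hill_n)
    cap <- if (globals$extrapolate_incidence) NULL else record$surveillance_days
    hazard <- hazard_schedule(params, globals$horizon_days,
                              record$sswi_share, cap_day = cap)
  }
  horizon <- globals$horizon_days
  pieces <- transition_pieces(record, globals)

  idx <- setNames(seq_along(PATHWAY_STATES), PATHWAY_STATES)
  at_risk_idx <- idx[AT_RISK_STATES]
  swi_entry_idx <- idx[c("IN_HOSP_SSWI", "IN_HOSP_DSWI", "OUTPATIENT_SSWI",
                         "READMITTED_DSWI", "RECOVERED")]
  n_states <- length(PATHWAY_STATES)

  # per-state daily accrual increments
  inc_icu <- state_vec()
  inc_icu["IN_HOSP_SSWI"] <- globals$sswi_extra_icu_fraction
  inc_icu["IN_HOSP_DSWI"] <- globals$dswi_extra_icu_fraction
  inc_gw <- state_vec()
  inc_gw["IN_HOSP_SSWI"] <- 1 - globals$sswi_extra_icu_fraction
  inc_gw["IN_HOSP_DSWI"] <- 1 - globals$dswi_extra_icu_fraction
  inc_gw["READMITTED_DSWI"] <- 1
  inc_cost <- inc_icu * record$icu_day_cost
  inc_cost[c("IN_HOSP_SSWI", "IN_HOSP_DSWI")] <-
    inc_cost[c("IN_HOSP_SSWI", "IN_HOSP_DSWI")] +
    inc_gw[c("IN_HOSP_SSWI", "IN_HOSP_DSWI")] * record$gw_day_cost

  n <- as.integer(n_patients)
  state <- rep.int(idx[["SURGERY"]], n)
  p_cost <- numeric(n)
  p_icu <- numeric(n)
  p_gw <- numeric(n)
  p_readm <- numeric(n)
  p_swi <- logical(n)
  absorbing <- unname(idx[c("OUTPATIENT_SSWI", "RECOVERED", "DEAD")])
  i_out <- idx[["OUT_OF_HOSPITAL"]]
  i_rec <- idx[["RECOVERED"]]
  i_readm <- idx[["READMITTED_DSWI"]]
  i_ss <- idx[["IN_HOSP_SSWI"]]
  i_ds <- idx[["IN_HOSP_DSWI"]]

  for (d in seq_len(horizon)) {
    h <- hazard$hazard[d]
    m <- pieces$m0 + h * pieces$d
    cpm <- t(apply(m, 1, cumsum))
    cpm[, n_states] <- 1

    in_swi <- which(state == i_ss | state == i_ds | state == i_readm)
    if (length(in_swi) > 0) {
      st_s <- state[in_swi]
      p_cost[in_swi] <- p_cost[in_swi] + inc_cost[st_s]
      p_icu[in_swi] <- p_icu[in_swi] + inc_icu[st_s]
      p_gw[in_swi] <- p_gw[in_swi] + inc_gw[st_s]
    }

    active <- which(!(state %in% absorbing))
    if (length(active) == 0) break
    st_a <- state[active]
    u <- runif(length(active))
    nxt_a <- st_a
    for (s in unique(st_a)) {
      jj <- which(st_a == s)
      nxt_a[jj] <- findInterval(u[jj], cpm[s, ]) + 1L
    }
    # out-of-hospital deep-SWI onsets trigger a readmission episode (the
    # zero-length bypass to RECOVERED still counts as a readmission)
    readm_now <- active[st_a == i_out & (nxt_a == i_readm | nxt_a == i_rec)]
    p_readm[readm_now] <- p_readm[readm_now] + 1
    p_cost[readm_now] <- p_cost[readm_now] + globals$readmission_cost
    # SWI onset: an at-risk patient entering any SWI/recovered compartment
    onset <- active[st_a %in% at_risk_idx & nxt_a %in% swi_entry_idx]
    p_swi[onset] <- TRUE
    state[active] <- nxt_a
  }

  collect <- list(
    swi_cost = p_cost, swi_icu_days = p_icu, swi_gw_days = p_gw,
    n_readmissions = p_readm, realised_swi = as.numeric(p_swi)
  )
  means <- vapply(collect, mean, numeric(1))
  se <- vapply(collect, function(v) stats::sd(v) / sqrt(n), numeric(1))
  structure(
    list(means = means, se = se, n_patients = n),
    class = "microsim_result"
  )
}
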