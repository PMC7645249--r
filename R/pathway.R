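#' Calibrate state sojourn times from a country's mean length of stay
#'
#' The infection-free stay is a fixed one-day surgery cycle followed by
#' geometric sojourns through ICU (ventilated, optionally prolonged
#' ventilation, then unventilated) and the general ward. The remaining
#' `mean_los_days - 1` days are split `icu_fraction_of_los` : rest between
#' ICU and GW, ICU time is split `icu_mv_share` : rest between ventilated
#' and unventilated states, and the prolonged-MV state absorbs
#' `prolonged_mv_fraction` of ventilated patients for
#' `prolonged_mv_multiplier` times the ordinary MV sojourn.
#'
#' A target mean below one day cannot be represented by a state that is
#' occupied for at least one cycle, so such stages are entered only with
#' probability equal to the target (and left after a single day), which
#' preserves the expected time in the stage exactly. The expected
#' infection-free length of stay of the calibrated chain therefore equals
#' `mean_los_days` up to floating-point error.
#'
#' @param mean_los_days Mean infection-free hospital stay, days, > 0.
#' @param globals A [global_params()] object.
#' @return An object of class `sojourn_calibration`: per-stage entry and
#'   daily exit probabilities, the prolonged-MV branch probability, and the
#'   implied expected length of stay.
#' @export
calibrate_sojourns <- function(mean_los_days, globals) {
  stopifnot(inherits(globals, "global_params"))
  if (!is.numeric(mean_los_days) || mean_los_days <= 0) {
    stop("mean_los_days must be > 0", call. = FALSE)
  }
  if (globals$icu_fraction_of_los >= 1) {
    stop("icu_fraction_of_los must be < 1", call. = FALSE)
  }
  rest <- max(mean_los_days - 1, 0)
  t_icu <- globals$icu_fraction_of_los * rest
  t_gw <- rest - t_icu
  t_mv_total <- globals$icu_mv_share * t_icu
  t_nomv <- t_icu - t_mv_total
  p_prol <- globals$prolonged_mv_fraction
  mult <- globals$prolonged_mv_multiplier
  m_mv <- t_mv_total / (1 + p_prol * mult)
  m_prol <- mult * m_mv

  stages <- list(
    surgery = stage_probs(1),
    icu_mv = stage_probs(m_mv),
    icu_mv_prolonged = stage_probs(m_prol),
    icu_no_mv = stage_probs(t_nomv),
    gw = stage_probs(t_gw)
  )
  expected <- 1 +
    stage_mean(stages$icu_mv) +
    p_prol * stage_mean(stages$icu_mv_prolonged) +
    stage_mean(stages$icu_no_mv) +
    stage_mean(stages$gw)
  structure(
    list(stages = stages, p_prolonged = p_prol,
         mean_los_days = mean_los_days, expected_los = expected),
    class = "sojourn_calibration"
  )
}

# Entry/exit probabilities realising an expected occupancy of m days in a
# daily-cycle state: geometric sojourn (exit 1/m) when m >= 1; for m < 1 the
# state is entered with probability m and left after one day.
stage_probs <- function(m) {
  if (m <= 0) {
    list(mean = 0, entry = 0, exit = 1)
  } else if (m < 1) {
    list(mean = m, entry = m, exit = 1)
  } else {
    list(mean = m, entry = 1, exit = 1 / m)
  }
}

stage_mean <- function(st) st$entry / st$exit

state_vec <- function() setNames(numeric(length(PATHWAY_STATES)), PATHWAY_STATES)

# Distribution over downstream states for a patient advancing along the
# infection-free pathway, entered at successive points. Low-mean stages are
# bypassed with the complement of their entry probability, cascading toward
# discharge.
advance_distributions <- function(soj) {
  st <- soj$stages
  p_prol <- soj$p_prolonged

  gw_onward <- state_vec()
  gw_onward["GW"] <- st$gw$entry
  gw_onward["OUT_OF_HOSPITAL"] <- 1 - st$gw$entry

  nomv_onward <- state_vec()
  nomv_onward["ICU_NO_MV"] <- st$icu_no_mv$entry
  nomv_onward <- nomv_onward + (1 - st$icu_no_mv$entry) * gw_onward

  prol_onward <- state_vec()
  prol_onward["ICU_MV_PROLONGED"] <- p_prol * st$icu_mv_prolonged$entry
  pass <- p_prol * (1 - st$icu_mv_prolonged$entry) + (1 - p_prol)
  prol_onward <- prol_onward + pass * nomv_onward

  mv_onward <- state_vec()
  mv_onward["ICU_MV"] <- st$icu_mv$entry
  mv_onward <- mv_onward + (1 - st$icu_mv$entry) * prol_onward

  list(after_surgery = mv_onward, after_mv = prol_onward,
       after_prol = nomv_onward, after_nomv = gw_onward)
}

# Precompute the hazard-independent pieces of the daily transition matrix.
transition_pieces <- function(record, globals) {
  soj <- calibrate_sojourns(record$mean_los_days, globals)
  adv <- advance_distributions(soj)
  st <- soj$stages
  mu <- globals$daily_mortality
  share <- record$sswi_share
  s_stage <- stage_probs(record$sswi_extra_los_days)
  d_stage <- stage_probs(record$dswi_extra_los_days)

  n <- length(PATHWAY_STATES)
  # infection-free movement rows for the at-risk states
  move <- matrix(0, n, n, dimnames = list(PATHWAY_STATES, PATHWAY_STATES))
  move["SURGERY", ] <- adv$after_surgery
  move["ICU_MV", ] <- st$icu_mv$exit * adv$after_mv
  move["ICU_MV", "ICU_MV"] <- move["ICU_MV", "ICU_MV"] + 1 - st$icu_mv$exit
  move["ICU_MV_PROLONGED", ] <- st$icu_mv_prolonged$exit * adv$after_prol
  move["ICU_MV_PROLONGED", "ICU_MV_PROLONGED"] <-
    move["ICU_MV_PROLONGED", "ICU_MV_PROLONGED"] + 1 - st$icu_mv_prolonged$exit
  move["ICU_NO_MV", ] <- st$icu_no_mv$exit * adv$after_nomv
  move["ICU_NO_MV", "ICU_NO_MV"] <-
    move["ICU_NO_MV", "ICU_NO_MV"] + 1 - st$icu_no_mv$exit
  move["GW", "OUT_OF_HOSPITAL"] <- st$gw$exit
  move["GW", "GW"] <- 1 - st$gw$exit
  move["OUT_OF_HOSPITAL", "OUT_OF_HOSPITAL"] <- 1

  # SWI onset destinations; extra-stay stages of zero days route straight to
  # the recovered compartment (the onset is still counted)
  swi_hosp <- state_vec()
  swi_hosp["IN_HOSP_SSWI"] <- share * s_stage$entry
  swi_hosp["IN_HOSP_DSWI"] <- (1 - share) * d_stage$entry
  swi_hosp["RECOVERED"] <- share * (1 - s_stage$entry) +
    (1 - share) * (1 - d_stage$entry)

  swi_out <- state_vec()
  swi_out["OUTPATIENT_SSWI"] <- share
  swi_out["READMITTED_DSWI"] <- (1 - share) * d_stage$entry
  swi_out["RECOVERED"] <- (1 - share) * (1 - d_stage$entry)

  # hazard-independent rows
  fixed <- matrix(0, n, n, dimnames = list(PATHWAY_STATES, PATHWAY_STATES))
  swi_exit <- function(q) {
    v <- state_vec()
    v["RECOVERED"] <- (1 - mu) * q
    v["DEAD"] <- mu
    v
  }
  fixed["IN_HOSP_SSWI", ] <- swi_exit(s_stage$exit)
  fixed["IN_HOSP_SSWI", "IN_HOSP_SSWI"] <- (1 - mu) * (1 - s_stage$exit)
  fixed["IN_HOSP_DSWI", ] <- swi_exit(d_stage$exit)
  fixed["IN_HOSP_DSWI", "IN_HOSP_DSWI"] <- (1 - mu) * (1 - d_stage$exit)
  fixed["READMITTED_DSWI", ] <- swi_exit(d_stage$exit)
  fixed["READMITTED_DSWI", "READMITTED_DSWI"] <- (1 - mu) * (1 - d_stage$exit)
  fixed["OUTPATIENT_SSWI", "OUTPATIENT_SSWI"] <- 1
  fixed["RECOVERED", "RECOVERED"] <- 1
  fixed["DEAD", "DEAD"] <- 1

  pieces <- list(sojourns = soj, move = move, swi_hosp = swi_hosp,
                 swi_out = swi_out, fixed = fixed, mu = mu)
  # the transition matrix is affine in the hazard: M(h) = M0 + h * D
  m0 <- build_transition(pieces, 0)
  pieces$m0 <- unname(m0)
  pieces$d <- unname(build_transition(pieces, 1) - m0)
  pieces
}

#' Daily transition matrix of the care-pathway model
#'
#' Builds the full transition matrix for one daily cycle at a given SWI
#' onset hazard. In-hospital states face the daily mortality first, then
#' the SWI hazard, then pathway movement; out-of-hospital at-risk patients
#' face the hazard only. Every row sums to one.
#'
#' @param record One country row (a one-row data frame or named list with
#'   the ten inputs).
#' @param globals A [global_params()] object.
#' @param hazard SWI onset hazard for the cycle, in \[0, 1\].
#' @return A square matrix over the pathway states.
#' @export
transition_matrix <- function(record, globals, hazard = 0) {
  pieces <- transition_pieces(record, globals)
  build_transition(pieces, hazard)
}

build_transition <- function(pieces, h) {
  m <- pieces$fixed
  mu <- pieces$mu
  for (s in HOSPITAL_STATES) {
    m[s, ] <- (1 - mu) * (h * pieces$swi_hosp + (1 - h) * pieces$move[s, ])
    m[s, "DEAD"] <- m[s, "DEAD"] + mu
  }
  m["OUT_OF_HOSPITAL", ] <- h * pieces$swi_out +
    (1 - h) * pieces$move["OUT_OF_HOSPITAL", ]
  m
}

#' Run the daily-cycle cohort model for one country
#'
#' Propagates a unit cohort entering surgery through the care pathway for
#' `horizon_days` daily cycles, applying the country-calibrated SWI hazard
#' schedule. Tracks state occupancy, SWI-attributable accruals (ICU days,
#' GW days including readmission bed-days, readmission events, costs) and,
#' from a parallel infection-free run, the baseline (no-SWI) accruals.
#'
#' Cost accounting: in-hospital SWI extra days are costed at the country's
#' ICU/GW daily rates according to the configured ward split; a readmission
#' episode for an out-of-hospital deep SWI lasts the country's DSWI
#' extra-stay (counted as GW bed-days) but is costed as the single
#' universal `readmission_cost`; outpatient superficial SWI care is free.
#' Total cost therefore decomposes exactly as baseline plus
#' SWI-attributable.
#'
#' @param record One fully-imputed country row (one-row data frame or named
#'   list with the ten inputs, no missing values).
#' @param globals A [global_params()] object.
#' @param hazard Optional [hazard_schedule()]; derived from the record's
#'   incidence, surveillance window and the global Hill shape when absent.
#'   Must cover at least `horizon_days` cycles.
#' @return An object of class `cohort_trace`: `$trace` (one row per day:
#'   occupancy per state plus cumulative accruals) and `$totals` (unit
#'   cohort accruals at the horizon).
#' @export
run_cohort <- function(record, globals, hazard = NULL) {
  stopifnot(inherits(globals, "global_params"))
  record <- as.list(record)
  check_record_complete(record)

  if (is.null(hazard)) {
    params <- calibrate_height(record$swi_incidence, record$surveillance_days,
                               t50 = globals$hill_t50, n = globals$hill_n)
    cap <- if (globals$extrapolate_incidence) NULL else record$surveillance_days
    hazard <- hazard_schedule(params, globals$horizon_days,
                              record$sswi_share, cap_day = cap)
  }
  stopifnot(inherits(hazard, "hazard_schedule"))
  horizon <- globals$horizon_days
  if (length(hazard$hazard) < horizon) {
    stop("hazard schedule (", length(hazard$hazard),
         " days) is shorter than the model horizon (", horizon, " days)",
         call. = FALSE)
  }

  pieces <- transition_pieces(record, globals)
  tm0 <- t(pieces$m0)
  td <- t(pieces$d)
  mu <- pieces$mu
  share <- record$sswi_share
  icu_frac_s <- globals$sswi_extra_icu_fraction
  icu_frac_d <- globals$dswi_extra_icu_fraction

  sidx <- setNames(seq_along(PATHWAY_STATES), PATHWAY_STATES)
  i_ss <- sidx[["IN_HOSP_SSWI"]]
  i_ds <- sidx[["IN_HOSP_DSWI"]]
  i_re <- sidx[["READMITTED_DSWI"]]
  i_out <- sidx[["OUT_OF_HOSPITAL"]]
  i_gw <- sidx[["GW"]]
  hosp_i <- unname(sidx[HOSPITAL_STATES])
  icu_i <- unname(sidx[ICU_STATES])

  n <- length(PATHWAY_STATES)
  occ <- numeric(n); occ[sidx[["SURGERY"]]] <- 1
  occ0 <- occ

  occ_mat <- matrix(0, horizon, n, dimnames = list(NULL, PATHWAY_STATES))
  cum <- matrix(0, horizon, 9, dimnames = list(NULL, c(
    "swi_icu_days", "swi_gw_days", "readmission_days", "n_readmissions",
    "swi_cost", "realised_swi", "base_icu_days", "base_gw_days", "base_cost"
  )))
  acc <- cum[1, ]
  hvec <- hazard$hazard

  for (d in seq_len(horizon)) {
    h <- hvec[d]
    occ_mat[d, ] <- occ

    # bed-day and cost accrual on the occupancy held during day d
    s_occ <- occ[i_ss]
    d_occ <- occ[i_ds]
    r_occ <- occ[i_re]
    swi_icu <- s_occ * icu_frac_s + d_occ * icu_frac_d
    swi_gw_costed <- s_occ * (1 - icu_frac_s) + d_occ * (1 - icu_frac_d)
    acc[1L] <- acc[1L] + swi_icu
    acc[2L] <- acc[2L] + swi_gw_costed + r_occ
    acc[3L] <- acc[3L] + r_occ
    acc[5L] <- acc[5L] +
      swi_icu * record$icu_day_cost + swi_gw_costed * record$gw_day_cost

    base_icu <- sum(occ0[icu_i])
    base_gw <- occ0[i_gw]
    acc[7L] <- acc[7L] + base_icu
    acc[8L] <- acc[8L] + base_gw
    acc[9L] <- acc[9L] +
      base_icu * record$icu_day_cost + base_gw * record$gw_day_cost

    # events realised during day d's transition
    onsets <- (1 - mu) * h * sum(occ[hosp_i]) + h * occ[i_out]
    readm <- h * occ[i_out] * (1 - share)
    acc[6L] <- acc[6L] + onsets
    acc[4L] <- acc[4L] + readm
    acc[5L] <- acc[5L] + readm * globals$readmission_cost

    cum[d, ] <- acc
    occ <- if (h > 0) drop(tm0 %*% occ + h * (td %*% occ))
           else drop(tm0 %*% occ)
    occ0 <- drop(tm0 %*% occ0)
  }
  names(occ) <- PATHWAY_STATES

  trace <- tibble::as_tibble(cbind(day = seq_len(horizon), occ_mat, cum))
  totals <- as.list(acc)
  totals$total_swi_cost <- totals$swi_cost
  structure(
    list(trace = trace, totals = totals, record = record,
         globals = globals, hazard = hazard, final_occupancy = occ),
    class = "cohort_trace"
  )
}

check_record_complete <- function(record) {
  miss <- COUNTRY_INPUTS[!vapply(
    COUNTRY_INPUTS,
    function(f) !is.null(record[[f]]) && length(record[[f]]) == 1L &&
      !is.na(record[[f]]),
    logical(1)
  )]
  if (length(miss) > 0) {
    stop("record is not fully specified; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(record)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", nrow(x$trace), " daily cycles\n", sep = "")
  t <- x$totals
  cat(sprintf("  realised SWI proportion: %.4f\n", t$realised_swi))
  cat(sprintf("  SWI cost / patient: %.2f EUR (baseline %.2f EUR)\n",
              t$swi_cost, t$base_cost))
  invisible(x)
}

#' Per-country burden of SWIs
#'
#' Scales the unit-cohort accruals of a [run_cohort()] trace by the annual
#' number of CABG procedures (`population * cabg_rate_per_100k / 1e5`,
#' overridable via `n_cabg`) and derives the summary quantities: total
#' SWI-attributable cost, extra ICU and GW days (the latter includes
#' readmission bed-days), readmission count, cost per SWI (total cost over
#' realised SWI events), the infection-free baseline cost, and the relative
#' cost increase.
#'
#' @param cohort A `cohort_trace`.
#' @param n_cabg Optional number of CABG procedures per year.
#' @return A one-row tibble (`burden_result`). When no SWI events are
#'   realised, `cost_per_swi` is `NA` and `zero_swi` is `TRUE`.
#' @export
compute_burden <- function(cohort, n_cabg = NULL) {
  stopifnot(inherits(cohort, "cohort_trace"))
  rec <- cohort$record
  if (is.null(n_cabg)) {
    n_cabg <- rec$population * rec$cabg_rate_per_100k / 1e5
  }
  t <- cohort$totals
  realised_events <- n_cabg * t$realised_swi
  total_cost <- n_cabg * t$swi_cost
  baseline <- n_cabg * t$base_cost
  tibble::tibble(
    country_id = if (is.null(rec$country_id)) NA_character_ else rec$country_id,
    n_cabg = n_cabg,
    swi_incidence = rec$swi_incidence,
    realised_swi_fraction = t$realised_swi,
    n_swi = realised_events,
    total_swi_cost = total_cost,
    extra_icu_days = n_cabg * t$swi_icu_days,
    extra_gw_days = n_cabg * t$swi_gw_days,
    readmission_days = n_cabg * t$readmission_days,
    n_readmissions = n_cabg * t$n_readmissions,
    cost_per_swi = if (realised_events > 0) total_cost / realised_events
                   else NA_real_,
    zero_swi = realised_events == 0,
    baseline_cost = baseline,
    relative_increase = total_cost / baseline
  )
}

#' Aggregate per-country burden results Europe-wide
#'
#' Sums cost, bed-days and readmissions across countries and summarises the
#' across-country distribution of SWI incidence and relative cost increase
#' as median and interquartile range.
#'
#' @param results A tibble of `burden_result` rows (one per country) or a
#'   list of such rows.
#' @return A list with `totals` (one-row tibble) and `distribution`
#'   (median/IQR tibble).
#' @export
aggregate_europe <- function(results) {
  if (is.data.frame(results)) {
    res <- tibble::as_tibble(results)
  } else {
    res <- dplyr::bind_rows(results)
  }
  if (nrow(res) == 0) stop("no burden results to aggregate", call. = FALSE)
  totals <- tibble::tibble(
    n_countries = nrow(res),
    n_cabg = sum(res$n_cabg),
    total_swi_cost = sum(res$total_swi_cost),
    extra_icu_days = sum(res$extra_icu_days),
    extra_gw_days = sum(res$extra_gw_days),
    n_readmissions = sum(res$n_readmissions)
  )
  qs <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  inc <- qs(res$swi_incidence)
  rel <- qs(res$relative_increase)
  distribution <- tibble::tibble(
    quantity = c("swi_incidence", "relative_increase"),
    median = c(inc[2], rel[2]),
    iqr_low = c(inc[1], rel[1]),
    iqr_high = c(inc[3], rel[3])
  )
  list(totals = totals, distribution = distribution)
}
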