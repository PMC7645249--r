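#' Hill-curve parameters for cumulative SWI incidence
#'
#' Cumulative SWI incidence over time since surgery is modelled with a
#' saturating Hill curve \eqn{CI(t) = i_{max} t^n / (t_{50}^n + t^n)}:
#' zero at the day of surgery, rising fastest around `t50` and levelling
#' off at the asymptote `i_max`. The curve shape (`t50`, `n`) is shared
#' across countries; the height `i_max` is calibrated per country (see
#' [calibrate_height()]).
#'
#' @param i_max Asymptotic cumulative incidence, in \[0, 1\].
#' @param t50 Days to half-maximal cumulative incidence, > 0.
#' @param n Hill coefficient, > 0.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(i_max, t50, n) {
  if (!is.numeric(i_max) || i_max < 0 || i_max > 1) {
    stop("i_max must be in [0, 1]", call. = FALSE)
  }
  if (t50 <= 0) stop("t50 must be > 0", call. = FALSE)
  if (n <= 0) stop("Hill coefficient must be > 0", call. = FALSE)
  structure(list(i_max = i_max, t50 = t50, n = n), class = "hill_params")
}

#' Cumulative SWI incidence at time t
#'
#' Evaluates the Hill cumulative-incidence curve. Vectorised over `t`.
#'
#' @param t Days since surgery, >= 0.
#' @param params A `hill_params` object.
#' @return Proportion(s) in \[0, `i_max`\], non-decreasing in `t`.
#' @examples
#' p <- hill_params(0.04, 12, 2)
#' cumulative_incidence(c(0, 12, 30), p)
#' @export
cumulative_incidence <- function(t, params) {
  stopifnot(inherits(params, "hill_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tn <- t^params$n
  out <- params$i_max * tn / (params$t50^params$n + tn)
  out[t == 0] <- 0 # guards n<1 edge where 0^n/0^n could NaN
  out
}

#' Calibrate the curve height from observed incidence and surveillance window
#'
#' Solves for the asymptote `i_max` so that the cumulative incidence at the
#' end of the surveillance window equals the observed incidence:
#' \eqn{i_{max} = obs \cdot (t_{50}^n + s^n) / s^n}. If the closed form
#' exceeds 1 the height is clamped to 1 with a warning (the observed
#' incidence is then not exactly reproducible at the surveillance day).
#'
#' @param observed_incidence Observed cumulative SWI incidence over the
#'   surveillance window, in \[0, 1\].
#' @param surveillance_days Length of the surveillance window, >= 1.
#' @param t50,n Shared curve shape (see [hill_params()]).
#' @return A `hill_params` object passing through
#'   `(surveillance_days, observed_incidence)`.
#' @export
calibrate_height <- function(observed_incidence, surveillance_days,
                             t50 = 12, n = 2) {
  if (!is.numeric(observed_incidence) ||
      observed_incidence < 0 || observed_incidence > 1) {
    stop("observed_incidence must be in [0, 1]", call. = FALSE)
  }
  if (surveillance_days < 1) {
    stop("surveillance_days must be >= 1", call. = FALSE)
  }
  sn <- surveillance_days^n
  i_max <- observed_incidence * (t50^n + sn) / sn
  if (i_max > 1) {
    warning("calibrated curve height ", signif(i_max, 6),
            " exceeds 1; clamping to 1", call. = FALSE)
    i_max <- 1
  }
  hill_params(i_max, t50, n)
}

#' Convert a cumulative incidence curve into a daily hazard schedule
#'
#' The discrete-time embedding of the curve for the daily Markov cycle:
#' the hazard on day \eqn{d} is the conditional probability of SWI onset on
#' that day given no SWI before,
#' \eqn{h_d = (CI(d) - CI(d-1)) / (1 - CI(d-1))}, so that the survival
#' product \eqn{\prod_{d} (1 - h_d)} reproduces \eqn{1 - CI(t)} exactly.
#' When `cap_day` is given the curve is frozen at its `cap_day` value
#' (no onsets beyond the surveillance window).
#'
#' @param params A `hill_params` object.
#' @param horizon Number of daily cycles, >= 1.
#' @param sswi_share Proportion of SWIs that are superficial, in \[0, 1\];
#'   carried with the schedule for the superficial/deep split at onset.
#' @param cap_day Optional day at which the curve is capped.
#' @return An object of class `hazard_schedule`: list with `hazard`
#'   (numeric vector of length `horizon`), `ci` (cumulative incidence at
#'   days 0..horizon), `sswi_share` and `params`.
#' @export
hazard_schedule <- function(params, horizon, sswi_share, cap_day = NULL) {
  stopifnot(inherits(params, "hill_params"))
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  if (sswi_share < 0 || sswi_share > 1) {
    stop("sswi_share must be in [0, 1]", call. = FALSE)
  }
  t <- 0:horizon
  if (!is.null(cap_day)) t <- pmin(t, cap_day)
  ci <- cumulative_incidence(t, params)
  surv_prev <- 1 - ci[-length(ci)]
  h <- ifelse(surv_prev <= 0, 0, diff(ci) / surv_prev)
  h <- pmin(pmax(h, 0), 1)
  structure(
    list(hazard = h, ci = ci, sswi_share = sswi_share, params = params),
    class = "hazard_schedule"
  )
}
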