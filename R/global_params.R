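#' Non-country-specific model parameters
#'
#' Constructs the set of global (non-country-specific) constants used by the
#' care-pathway model. These are held fixed across countries in the base
#' case and resampled from normal distributions in the probabilistic
#' sensitivity analysis (see [sample_global_params()]).
#'
#' @param readmission_cost Cost, in 2017 euros, of one deep-SWI readmission
#'   episode. Readmission episodes are costed with this single universal
#'   value (not with country-specific per-day rates); the bed-days of the
#'   episode are still counted in the extra general-ward day total. Default
#'   25000, representative of published European deep sternal-wound
#'   readmission episode costs.
#' @param prolonged_mv_fraction Proportion of patients on mechanical
#'   ventilation (MV) who enter the prolonged-MV state. Default 0.05.
#' @param prolonged_mv_multiplier Mean sojourn of the prolonged-MV state
#'   expressed as a multiple of the ordinary MV sojourn. Default 2.
#' @param daily_mortality Daily probability of death applied in every
#'   in-hospital state (zero out of hospital). Default 5e-4.
#' @param icu_fraction_of_los Proportion of the infection-free hospital stay
#'   (after the surgery day) spent in the ICU. Default 0.20. Must be < 1.
#' @param icu_mv_share Share of ICU time spent in MV states (ordinary plus
#'   prolonged); the remainder is ICU without ventilation. Default 0.60.
#' @param dswi_extra_icu_fraction Proportion of in-hospital deep-SWI extra
#'   days spent in the ICU; the rest are general-ward days. Default 0.30.
#' @param sswi_extra_icu_fraction Same for superficial SWIs. Default 0.
#' @param hill_t50 Days to half-maximal cumulative SWI incidence (Hill curve
#'   midpoint). Default 12.
#' @param hill_n Hill coefficient (curve steepness). Default 2.
#' @param horizon_days Model horizon in daily cycles. Default 365.
#' @param extrapolate_incidence If `TRUE` (default) the cumulative incidence
#'   curve continues toward its asymptote beyond the surveillance window;
#'   if `FALSE` it is capped at the surveillance-day value.
#'
#' @return An object of class `global_params` (a named list).
#' @examples
#' gp <- global_params()
#' gp$hill_t50
#' @export
global_params <- function(readmission_cost = 25000,
                          prolonged_mv_fraction = 0.05,
                          prolonged_mv_multiplier = 2,
                          daily_mortality = 5e-4,
                          icu_fraction_of_los = 0.20,
                          icu_mv_share = 0.60,
                          dswi_extra_icu_fraction = 0.30,
                          sswi_extra_icu_fraction = 0,
                          hill_t50 = 12,
                          hill_n = 2,
                          horizon_days = 365L,
                          extrapolate_incidence = TRUE) {
  gp <- list(
    readmission_cost = readmission_cost,
    prolonged_mv_fraction = prolonged_mv_fraction,
    prolonged_mv_multiplier = prolonged_mv_multiplier,
    daily_mortality = daily_mortality,
    icu_fraction_of_los = icu_fraction_of_los,
    icu_mv_share = icu_mv_share,
    dswi_extra_icu_fraction = dswi_extra_icu_fraction,
    sswi_extra_icu_fraction = sswi_extra_icu_fraction,
    hill_t50 = hill_t50,
    hill_n = hill_n,
    horizon_days = as.integer(horizon_days),
    extrapolate_incidence = isTRUE(extrapolate_incidence)
  )
  validate_global_params(gp)
  structure(gp, class = "global_params")
}

validate_global_params <- function(gp) {
  props <- c(
    "prolonged_mv_fraction", "icu_fraction_of_los", "icu_mv_share",
    "dswi_extra_icu_fraction", "sswi_extra_icu_fraction", "daily_mortality"
  )
  for (p in props) {
    v <- gp[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("global parameter '", p, "' must be a proportion in [0, 1]",
           call. = FALSE)
    }
  }
  if (gp$icu_fraction_of_los >= 1) {
    stop("icu_fraction_of_los must be < 1", call. = FALSE)
  }
  for (p in c("readmission_cost", "prolonged_mv_multiplier")) {
    if (!is.numeric(gp[[p]]) || gp[[p]] < 0) {
      stop("global parameter '", p, "' must be >= 0", call. = FALSE)
    }
  }
  for (p in c("hill_t50", "hill_n")) {
    if (!is.numeric(gp[[p]]) || gp[[p]] <= 0) {
      stop("global parameter '", p, "' must be > 0", call. = FALSE)
    }
  }
  if (gp$horizon_days < 1L) stop("horizon_days must be >= 1", call. = FALSE)
  invisible(gp)
}

#' Read global parameters from a YAML configuration file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [global_params()].
#'
#' @param path Path to a YAML file whose top-level keys are arguments of
#'   [global_params()].
#' @return A `global_params` object.
#' @export
read_global_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(global_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown global parameter(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(global_params, cfg)
}

#' @export
print.global_params <- function(x, ...) {
  cat("<global_params>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
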