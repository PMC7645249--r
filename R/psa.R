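#' Sampling bounds for the probabilistic sensitivity analysis
#'
#' For every country input, the lower and upper sampling bounds are the
#' minimum and maximum of the *known* values across countries (imputed or
#' sampled cells are ignored).
#'
#' @param x A `country_dataset`.
#' @return A tibble with columns `input`, `lower`, `upper`.
#' @export
compute_bounds <- function(x) {
  stopifnot(inherits(x, "country_dataset"))
  rows <- lapply(COUNTRY_INPUTS, function(col) {
    known <- x$data[[col]][x$provenance[[col]] == "known"]
    if (length(known) < 2) {
      stop("input '", col, "' is known for fewer than two countries; ",
           "sampling bounds are undefined", call. = FALSE)
    }
    tibble::tibble(input = col, lower = min(known), upper = max(known))
  })
  dplyr::bind_rows(rows)
}

#' Resample one country's inputs for a PSA run
#'
#' For every input a value is drawn uniformly between the cross-country
#' bounds. Inputs that were missing in the original dataset take the drawn
#' value directly; inputs with a known value take the mean of the known
#' value and the draw (and therefore stay inside
#' `[(known + lower)/2, (known + upper)/2]`).
#'
#' @param record One country row (named list or one-row data frame).
#' @param known A named logical vector over the ten inputs: `TRUE` where
#'   the original dataset had a known value.
#' @param bounds Bounds tibble from [compute_bounds()].
#' @return A named list: the resampled record (all ten inputs present,
#'   provenance `"sampled"`).
#' @export
sample_country_inputs <- function(record, known, bounds) {
  record <- as.list(record)
  out <- record
  for (col in COUNTRY_INPUTS) {
    b <- bounds[bounds$input == col, ]
    if (nrow(b) != 1) stop("no bounds for input '", col, "'", call. = FALSE)
    u <- runif(1, b$lower, b$upper)
    out[[col]] <- if (isTRUE(known[[col]])) (record[[col]] + u) / 2 else u
  }
  out
}

#' Resample the global parameters for a PSA run
#'
#' Each scalar global parameter is drawn from a normal distribution centred
#' on its base value with standard deviation `cv` times the base value,
#' truncated to its domain (proportions to \[0, 1\], costs and durations to
#' non-negative values). With `cv = 0` the input is returned unchanged.
#' The model horizon and the extrapolation flag are structural and not
#' sampled; ten scalars are resampled per run.
#'
#' @param globals A [global_params()] object.
#' @param cv Coefficient of variation for the draws, >= 0.
#' @return A new `global_params` object.
#' @export
sample_global_params <- function(globals, cv) {
  stopifnot(inherits(globals, "global_params"))
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (cv == 0) return(globals)
  draw <- function(v) rnorm(1, mean = v, sd = cv * v)
  clamp01 <- function(v) min(max(v, 0), 1)
  global_params(
    readmission_cost = max(draw(globals$readmission_cost), 0),
    prolonged_mv_fraction = clamp01(draw(globals$prolonged_mv_fraction)),
    prolonged_mv_multiplier = max(draw(globals$prolonged_mv_multiplier), 0),
    daily_mortality = clamp01(draw(globals$daily_mortality)),
    icu_fraction_of_los = min(clamp01(draw(globals$icu_fraction_of_los)), 0.95),
    icu_mv_share = clamp01(draw(globals$icu_mv_share)),
    dswi_extra_icu_fraction = clamp01(draw(globals$dswi_extra_icu_fraction)),
    sswi_extra_icu_fraction = clamp01(draw(globals$sswi_extra_icu_fraction)),
    hill_t50 = max(draw(globals$hill_t50), 1e-6),
    hill_n = max(draw(globals$hill_n), 1e-6),
    horizon_days = globals$horizon_days,
    extrapolate_incidence = globals$extrapolate_incidence
  )
}

psa_outputs <- c("total_swi_cost", "extra_icu_days", "extra_gw_days",
                 "n_readmissions")

#' Probabilistic sensitivity analysis
#'
#' Performs `runs_per_country` model evaluations per included country. Each
#' run resamples the country's ten inputs between the cross-country bounds
#' of the known values ([sample_country_inputs()]) and the global
#' parameters from normal distributions ([sample_global_params()]), then
#' runs the full cohort model and records the burden outputs. Results are
#' summarised as median, minimum and maximum per country and Europe-wide
#' (country results summed within each run index).
#'
#' Reproducibility: every (country, run) pair derives its own RNG seed from
#' `seed`, so results are independent of evaluation order and identical
#' across repeated calls.
#'
#' @param x An included (and typically imputed) `country_dataset`. The
#'   original known/missing status recorded in its provenance drives the
#'   sampling rule; imputed cells count as missing.
#' @param globals Base-case [global_params()].
#' @param runs_per_country Number of runs per country (default 44).
#' @param seed Master seed (integer).
#' @param cv Coefficient of variation for the global-parameter draws
#'   (default 0.10).
#' @param keep_runs If `TRUE`, the per-run outputs and sampled inputs are
#'   returned under `$runs`.
#' @return An object of class `psa_summary`: `per_country` and `europe`
#'   median/min/max tibbles, `n_evaluations`, and optionally `runs`.
#' @export
run_psa <- function(x, globals, runs_per_country = 44L, seed = 1L,
                    cv = 0.10, keep_runs = FALSE) {
  stopifnot(inherits(x, "country_dataset"), inherits(globals, "global_params"))
  runs_per_country <- as.integer(runs_per_country)
  if (runs_per_country < 1L) stop("runs_per_country must be >= 1", call. = FALSE)
  bounds <- compute_bounds(x)
  n_c <- nrow(x$data)

  run_rows <- vector("list", n_c * runs_per_country)
  k <- 0L
  for (i in seq_len(n_c)) {
    record <- as.list(x$data[i, ])
    known <- vapply(COUNTRY_INPUTS,
                    function(col) x$provenance[[col]][i] == "known",
                    logical(1))
    for (r in seq_len(runs_per_country)) {
      set.seed(child_seed(seed, i, r))
      rec_s <- sample_country_inputs(record, known, bounds)
      glob_s <- sample_global_params(globals, cv)
      cohort <- run_cohort(rec_s, glob_s)
      burden <- compute_burden(cohort)
      k <- k + 1L
      row <- tibble::tibble(
        country_id = record$country_id, run = r,
        total_swi_cost = burden$total_swi_cost,
        extra_icu_days = burden$extra_icu_days,
        extra_gw_days = burden$extra_gw_days,
        n_readmissions = burden$n_readmissions
      )
      if (keep_runs) {
        sampled <- tibble::as_tibble(rec_s[COUNTRY_INPUTS])
        names(sampled) <- paste0("in_", names(sampled))
        row <- dplyr::bind_cols(row, sampled)
      }
      run_rows[[k]] <- row
    }
  }
  runs <- dplyr::bind_rows(run_rows)

  mmm <- function(v) c(median = median(v), min = min(v), max = max(v))
  per_country <- dplyr::bind_rows(lapply(
    unique(runs$country_id),
    function(cid) dplyr::bind_rows(lapply(psa_outputs, function(o) {
      s <- mmm(runs[[o]][runs$country_id == cid])
      tibble::tibble(country_id = cid, output = o,
                     median = s[["median"]], min = s[["min"]], max = s[["max"]])
    }))
  ))

  # Europe-wide: sum countries within each run index, then summarise over runs
  europe <- dplyr::bind_rows(lapply(psa_outputs, function(o) {
    by_run <- rowsum(runs[[o]], runs$run)
    s <- mmm(as.numeric(by_run))
    tibble::tibble(output = o, median = s[["median"]], min = s[["min"]],
                   max = s[["max"]])
  }))

  structure(
    list(per_country = per_country, europe = europe,
         n_evaluations = n_c * runs_per_country,
         runs_per_country = runs_per_country, seed = seed, cv = cv,
         bounds = bounds,
         runs = if (keep_runs) runs else NULL),
    class = "psa_summary"
  )
}

# Deterministic, order-independent child seed for a (country, run) pair,
# kept inside the 32-bit integer range.
child_seed <- function(seed, i, r) {
  as.integer((as.numeric(seed) + 1000003 * i + 2633 * r) %% 2147483647)
}

#' @export
print.psa_summary <- function(x, ...) {
  cat("<psa_summary> ", x$n_evaluations, " model runs (",
      x$runs_per_country, " per country)\n", sep = "")
  print(x$europe)
  invisible(x)
}
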