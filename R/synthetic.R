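#' Default plausible ranges for synthetic country inputs
#'
#' SWI incidence spans the 1.6–10.4% range reported across European
#' countries, the superficial share is the complement of the 23.3–76% deep
#' share, and surveillance windows take the common 30/60/90/180-day values.
#' Unit-cost, population and procedure-rate ranges are synthetic-only
#' plausible magnitudes spanning small to large European settings.
#'
#' @return A named list of `c(lower, upper)` ranges (surveillance_days is a
#'   discrete choice set).
#' @export
synthetic_ranges <- function() {
  list(
    population = c(3e5, 8.5e7),
    cabg_rate_per_100k = c(20, 100),
    mean_los_days = c(7, 20),
    icu_day_cost = c(500, 3000),
    gw_day_cost = c(200, 1200),
    swi_incidence = c(0.016, 0.104),
    surveillance_days = c(30, 60, 90, 180),
    sswi_share = c(0.24, 0.767),
    sswi_extra_los_days = c(0, 5),
    dswi_extra_los_days = c(14, 40)
  )
}

#' Generate a synthetic country input table
#'
#' Draws each of the ten inputs uniformly from its plausible range (the
#' surveillance window is drawn from the discrete 30/60/90/180-day set) for
#' `n_countries` countries, then blanks each cell independently with the
#' per-input missingness probability. The result always passes
#' [validate_country_dataset()] and is reproducible from `seed`.
#'
#' @param n_countries Number of countries (default 34, the Eurostat set
#'   size).
#' @param missingness Per-input probability of a missing cell: a single
#'   number applied to all inputs, or a named vector. Default 0.
#' @param seed Optional RNG seed.
#' @param ranges Named list overriding entries of [synthetic_ranges()].
#' @return A `country_dataset`.
#' @examples
#' ds <- generate_country_table(10, missingness = 0.2, seed = 42)
#' n_known_fields(ds)
#' @export
generate_country_table <- function(n_countries = 34L, missingness = 0,
                                   seed = NULL, ranges = list()) {
  n_countries <- as.integer(n_countries)
  if (n_countries < 1L) stop("n_countries must be >= 1", call. = FALSE)
  rng <- modifyList(synthetic_ranges(), ranges)
  if (length(missingness) == 1L && is.null(names(missingness))) {
    missingness <- setNames(rep(missingness, length(COUNTRY_INPUTS)),
                            COUNTRY_INPUTS)
  }
  if (any(missingness < 0 | missingness > 1)) {
    stop("missingness probabilities must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  df <- tibble::tibble(country_id = sprintf("SYN%02d", seq_len(n_countries)))
  for (col in COUNTRY_INPUTS) {
    r <- rng[[col]]
    v <- if (col == "surveillance_days") {
      sample(r, n_countries, replace = TRUE)
    } else {
      runif(n_countries, r[1], r[2])
    }
    p_miss <- missingness[[col]] %||% 0
    if (p_miss > 0) v[runif(n_countries) < p_miss] <- NA_real_
    df[[col]] <- v
  }
  country_dataset(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-hospital validation fixture (Jena, Germany)
#'
#' A fully-specified country record reproducing the published
#' single-hospital parameterisation used for model validation: 983 CABG
#' patients, 126 SWIs over a 60-day surveillance window of which 96 were
#' superficial, no extra stay for a superficial SWI, 37 extra hospital days
#' for a deep SWI, a mean stay of 14.4 days and a ward cost of 1,010 euros
#' per day. The source prints a single per-day cost, so the ICU rate is set
#' equal to the ward rate (all extra days are costed at 1,010 euros).
#' Population and procedure rate are set so that the annual cohort is
#' exactly 983 patients.
#'
#' @return A list with `record` (named list of the ten inputs plus
#'   `country_id`), `globals` (base-case [global_params()]) and
#'   `n_patients` (983).
#' @examples
#' fx <- jena_fixture()
#' fx$record$swi_incidence # 126/983
#' @export
jena_fixture <- function() {
  list(
    record = list(
      country_id = "DE-jena",
      population = 983,
      cabg_rate_per_100k = 1e5,
      mean_los_days = 14.4,
      icu_day_cost = 1010,
      gw_day_cost = 1010,
      swi_incidence = 126 / 983,
      surveillance_days = 60,
      sswi_share = 96 / 126,
      sswi_extra_los_days = 0,
      dswi_extra_los_days = 37
    ),
    globals = global_params(),
    n_patients = 983
  )
}
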