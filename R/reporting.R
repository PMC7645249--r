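#' Run the base-case burden analysis end to end
#'
#' Loads (or accepts) a country table, applies validation, the five-of-ten
#' inclusion rule and median imputation, runs the cohort model for every
#' included country and aggregates the burden Europe-wide. When `out_dir`
#' is given, writes `results.csv` (one row per country),
#' `summary.json` (totals, across-country medians/IQRs, exclusions),
#' `imputation_report.csv` and `run.log` (one inclusion decision per input
#' row plus any calibration warnings).
#'
#' @param countries Path to a countries CSV or a `country_dataset`.
#' @param params Path to a YAML parameter file, a [global_params()] object,
#'   or `NULL` for defaults.
#' @param adjustments Path to an adjustments YAML, a `cost_adjustments`
#'   object, or `NULL`.
#' @param out_dir Optional output directory (created if absent).
#' @param min_known Inclusion threshold on known fields (default 5).
#' @return Invisibly, a list with `results` (burden tibble), `summary`
#'   (totals and distribution), `excluded`, `dataset` (imputed) and `log`.
#' @export
run_burden_analysis <- function(countries, params = NULL, adjustments = NULL,
                                out_dir = NULL, min_known = 5L) {
  globals <- resolve_params(params)
  adj <- resolve_adjustments(adjustments)
  dataset <- resolve_countries(countries, adj)
  log <- character()
  log <- c(log, sprintf("loaded %d countries", nrow(dataset$data)))

  sel <- select_included_countries(dataset, min_known = min_known)
  nk <- n_known_fields(dataset)
  log <- c(log, sprintf(
    "%s: %d known fields -> %s", names(nk), nk,
    ifelse(names(nk) %in% sel$included$data$country_id, "included", "excluded")
  ))
  imputed <- impute_missing(sel$included)

  results_list <- vector("list", nrow(imputed$data))
  for (i in seq_len(nrow(imputed$data))) {
    rec <- as.list(imputed$data[i, ])
    withCallingHandlers(
      {
        cohort <- run_cohort(rec, globals)
        results_list[[i]] <- compute_burden(cohort)
      },
      warning = function(w) {
        log <<- c(log, sprintf("warning (%s): %s", rec$country_id,
                               conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  results <- dplyr::bind_rows(results_list)
  summary <- aggregate_europe(results)

  out <- list(results = results, summary = summary, excluded = sel$excluded,
              dataset = imputed, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results, file.path(out_dir, "results.csv"))
    write_imputation_report(imputed, file.path(out_dir, "imputation_report.csv"))
    summary_json <- list(
      totals = as.list(summary$totals),
      distribution = summary$distribution,
      excluded = sel$excluded
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  invisible(out)
}

#' Run the probabilistic sensitivity analysis end to end
#'
#' Same input handling as [run_burden_analysis()], followed by [run_psa()].
#' When `out_dir` is given, writes `psa_per_country.csv`, `psa_europe.csv`,
#' `psa_summary.json` and `psa.log` (the log records the evaluation count:
#' included countries times runs per country).
#'
#' @inheritParams run_burden_analysis
#' @param seed Master seed for the PSA.
#' @param runs_per_country Runs per country (default 44).
#' @param cv Coefficient of variation for global-parameter draws.
#' @return Invisibly, a list with `psa` (the `psa_summary`), `excluded`
#'   and `log`.
#' @export
run_psa_analysis <- function(countries, params = NULL, adjustments = NULL,
                             out_dir = NULL, seed = 1L,
                             runs_per_country = 44L, cv = 0.10,
                             min_known = 5L) {
  globals <- resolve_params(params)
  adj <- resolve_adjustments(adjustments)
  dataset <- resolve_countries(countries, adj)
  sel <- select_included_countries(dataset, min_known = min_known)
  imputed <- impute_missing(sel$included)

  psa <- run_psa(imputed, globals, runs_per_country = runs_per_country,
                 seed = seed, cv = cv)
  log <- c(
    sprintf("included %d countries, excluded %d",
            nrow(imputed$data), nrow(sel$excluded)),
    sprintf("performed %d model runs (%d per country), seed %d",
            psa$n_evaluations, psa$runs_per_country, as.integer(seed))
  )
  out <- list(psa = psa, excluded = sel$excluded, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(psa$per_country, file.path(out_dir, "psa_per_country.csv"))
    readr::write_csv(psa$europe, file.path(out_dir, "psa_europe.csv"))
    jsonlite::write_json(
      list(europe = psa$europe, per_country = psa$per_country,
           n_evaluations = psa$n_evaluations, seed = as.integer(seed),
           cv = cv),
      file.path(out_dir, "psa_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    writeLines(log, file.path(out_dir, "psa.log"))
  }
  invisible(out)
}

resolve_params <- function(params) {
  if (is.null(params)) return(global_params())
  if (inherits(params, "global_params")) return(params)
  if (is.character(params)) return(read_global_params(params))
  stop("params must be NULL, a global_params object or a YAML path",
       call. = FALSE)
}

resolve_adjustments <- function(adjustments) {
  if (is.null(adjustments) || inherits(adjustments, "cost_adjustments")) {
    return(adjustments)
  }
  if (is.character(adjustments)) return(read_adjustments(adjustments))
  stop("adjustments must be NULL, a cost_adjustments object or a YAML path",
       call. = FALSE)
}

resolve_countries <- function(countries, adj) {
  if (inherits(countries, "country_dataset")) {
    if (!is.null(adj)) {
      stop("cost adjustments can only be applied when loading from CSV",
           call. = FALSE)
    }
    return(countries)
  }
  if (is.character(countries)) return(read_country_table(countries, adj))
  stop("countries must be a country_dataset or a CSV path", call. = FALSE)
}
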