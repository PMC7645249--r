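#' Country input datasets
#'
#' A country dataset holds one row per country with the ten country-specific
#' model inputs, together with a per-cell provenance flag (`"known"`,
#' `"missing"`, `"imputed"` or `"sampled"`) and, after imputation, a report
#' of what was filled in and from which statistic.
#'
#' The ten inputs, in canonical column order, are: `population` (persons),
#' `cabg_rate_per_100k` (CABG procedures per 100,000 persons per year),
#' `mean_los_days` (mean infection-free hospital stay, days),
#' `icu_day_cost` and `gw_day_cost` (2017 euros per day),
#' `swi_incidence` (proportion in \[0,1\]), `surveillance_days` (length of
#' the post-operative surveillance window, days), `sswi_share` (proportion
#' of SWIs that are superficial), `sswi_extra_los_days` and
#' `dswi_extra_los_days` (additional hospital days to treat a superficial /
#' deep SWI).
#'
#' @param data A data frame with a `country_id` character column and the
#'   ten input columns (numeric; `NA` = missing).
#' @param provenance Optional data frame of the same shape holding flags;
#'   derived from `NA` patterns (`known`/`missing`) when absent.
#' @param imputation_report Optional tibble describing imputed cells.
#' @return An object of class `country_dataset`.
#' @seealso [read_country_table()], [impute_missing()],
#'   [select_included_countries()]
#' @export
country_dataset <- function(data, provenance = NULL, imputation_report = NULL) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c("country_id", COUNTRY_INPUTS), names(data))
  if (length(missing_cols) > 0) {
    stop("country table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, c("country_id", COUNTRY_INPUTS)]
  data$country_id <- as.character(data$country_id)
  for (col in COUNTRY_INPUTS) data[[col]] <- as.numeric(data[[col]])

  if (is.null(provenance)) {
    provenance <- data
    for (col in COUNTRY_INPUTS) {
      provenance[[col]] <- ifelse(is.na(data[[col]]), "missing", "known")
    }
  } else {
    provenance <- tibble::as_tibble(provenance)[, c("country_id", COUNTRY_INPUTS)]
    provenance$country_id <- as.character(provenance$country_id)
  }

  x <- structure(
    list(data = data, provenance = provenance,
         imputation_report = imputation_report),
    class = "country_dataset"
  )
  validate_country_dataset(x)
}

#' Validate a country dataset
#'
#' Checks uniqueness of country identifiers, numeric ranges (non-negative
#' values, proportions in \[0,1\], surveillance window of at least one day)
#' and consistency between values, provenance flags and the imputation
#' report. Errors name the offending country and field.
#'
#' @param x A `country_dataset`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_country_dataset <- function(x) {
  stopifnot(inherits(x, "country_dataset"))
  d <- x$data
  if (nrow(d) == 0) stop("country dataset is empty", call. = FALSE)
  if (anyDuplicated(d$country_id)) {
    stop("duplicate country_id: ",
         paste(unique(d$country_id[duplicated(d$country_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(d$country_id) | d$country_id == "")) {
    stop("empty country_id in country table", call. = FALSE)
  }
  for (col in COUNTRY_INPUTS) {
    v <- d[[col]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      stop("negative value for '", col, "' in country ",
           d$country_id[bad[1]], call. = FALSE)
    }
    if (col %in% PROPORTION_INPUTS) {
      bad <- which(!is.na(v) & v > 1)
      if (length(bad) > 0) {
        stop("'", col, "' must be a proportion in [0, 1]; country ",
             d$country_id[bad[1]], " has ", v[bad[1]], call. = FALSE)
      }
    }
  }
  sv <- d$surveillance_days
  bad <- which(!is.na(sv) & sv < 1)
  if (length(bad) > 0) {
    stop("surveillance_days must be >= 1; country ", d$country_id[bad[1]],
         " has ", sv[bad[1]], call. = FALSE)
  }
  # provenance consistency: a cell is NA iff flagged missing
  p <- x$provenance
  if (!identical(p$country_id, d$country_id)) {
    stop("provenance rows do not match data rows", call. = FALSE)
  }
  for (col in COUNTRY_INPUTS) {
    flags <- p[[col]]
    if (!all(flags %in% c("known", "missing", "imputed", "sampled"))) {
      stop("invalid provenance flag in column '", col, "'", call. = FALSE)
    }
    mism <- which(is.na(d[[col]]) != (flags == "missing"))
    if (length(mism) > 0) {
      stop("provenance flag inconsistent with data for '", col,
           "' in country ", d$country_id[mism[1]], call. = FALSE)
    }
  }
  # imputation report covers exactly the imputed cells
  imputed_cells <- imputed_cell_keys(x)
  if (!is.null(x$imputation_report)) {
    rep_cells <- paste(x$imputation_report$country_id,
                       x$imputation_report$field)
    if (!setequal(rep_cells, imputed_cells)) {
      stop("imputation report does not cover exactly the imputed cells",
           call. = FALSE)
    }
  } else if (length(imputed_cells) > 0) {
    stop("cells flagged imputed but no imputation report present",
         call. = FALSE)
  }
  invisible(x)
}

imputed_cell_keys <- function(x) {
  out <- character()
  for (col in COUNTRY_INPUTS) {
    idx <- which(x$provenance[[col]] == "imputed")
    if (length(idx) > 0) out <- c(out, paste(x$data$country_id[idx], col))
  }
  out
}

#' Number of known fields per country
#'
#' Counts, for each country, how many of the ten inputs carry provenance
#' `"known"` (imputed or sampled cells do not count).
#'
#' @param x A `country_dataset`.
#' @return A named integer vector (names are country ids), values in 0..10.
#' @export
n_known_fields <- function(x) {
  stopifnot(inherits(x, "country_dataset"))
  m <- sapply(COUNTRY_INPUTS, function(col) x$provenance[[col]] == "known")
  if (nrow(x$data) == 1L) m <- matrix(m, nrow = 1L)
  setNames(as.integer(rowSums(m)), x$data$country_id)
}

#' @export
print.country_dataset <- function(x, ...) {
  cat("<country_dataset> ", nrow(x$data), " countries\n", sep = "")
  cat("known fields per country:\n")
  print(n_known_fields(x))
  invisible(x)
}

#' Read a cost-adjustment table (currency conversion and inflation)
#'
#' The YAML file has two top-level maps: `currencies`, mapping a currency
#' code to year-average EUR conversion rates per publication year, and
#' `inflation`, mapping a country id to inflation factors from the
#' publication year to 2017. All factors must be positive.
#'
#' @param path Path to the YAML file.
#' @return An object of class `cost_adjustments`.
#' @export
read_adjustments <- function(path) {
  if (!file.exists(path)) stop("adjustment file not found: ", path, call. = FALSE)
  adj <- yaml::read_yaml(path)
  if (!all(c("currencies", "inflation") %in% names(adj))) {
    stop("adjustment file must contain 'currencies' and 'inflation' maps",
         call. = FALSE)
  }
  rates <- unlist(adj$currencies, use.names = FALSE)
  infl <- unlist(adj$inflation, use.names = FALSE)
  if (any(c(rates, infl) <= 0)) {
    stop("all conversion and inflation factors must be > 0", call. = FALSE)
  }
  structure(adj, class = "cost_adjustments")
}

lookup_factor <- function(map, key, year, what) {
  entry <- map[[key]]
  if (is.null(entry)) stop("no ", what, " entry for '", key, "'", call. = FALSE)
  f <- entry[[as.character(year)]]
  if (is.null(f)) {
    stop("no ", what, " factor for '", key, "' in year ", year, call. = FALSE)
  }
  as.numeric(f)
}

#' Load the per-country input table from CSV
#'
#' Reads a comma-separated, UTF-8, dot-decimal table with one header row and
#' one row per country. Blank cells are missing values. If the table carries
#' `currency` and `cost_year` columns and `adjustments` is supplied, the two
#' unit-cost columns are converted to euros at the publication-year average
#' rate and then inflated to 2017 with the country-specific factor before
#' storage; euro-denominated rows (`currency == "EUR"`) skip conversion but
#' are still inflated.
#'
#' If a provenance sidecar written by [write_country_table()] sits next to
#' the file it is loaded too, restoring imputed/sampled flags.
#'
#' @param path Path to the CSV file.
#' @param adjustments Optional `cost_adjustments` from [read_adjustments()].
#' @return A validated `country_dataset`.
#' @export
read_country_table <- function(path, adjustments = NULL) {
  if (!file.exists(path)) stop("country table not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  char_cols <- intersect(c("country_id", "currency"), hdr)
  spec <- do.call(readr::cols, c(
    setNames(rep(list(readr::col_character()), length(char_cols)), char_cols),
    list(.default = readr::col_double())
  ))
  if (inherits(try(suppressWarnings(
    df <- readr::read_csv(path, col_types = spec, progress = FALSE)
  ), silent = TRUE), "try-error")) {
    stop("could not parse country table ", path, call. = FALSE)
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop("malformed country table ", path, ": row ", probs$row[1],
         ", column ", probs$col[1], " (", probs$expected[1], ")",
         call. = FALSE)
  }
  if ("currency" %in% names(df)) {
    df$currency <- as.character(df$currency)
  }

  if (!is.null(adjustments)) {
    if (!all(c("currency", "cost_year") %in% names(df))) {
      stop("cost adjustment requested but 'currency'/'cost_year' columns ",
           "are absent from ", path, call. = FALSE)
    }
    for (i in seq_len(nrow(df))) {
      cur <- df$currency[i]
      yr <- df$cost_year[i]
      if (is.na(cur) || is.na(yr)) next
      rate <- if (identical(cur, "EUR")) 1 else
        lookup_factor(adjustments$currencies, cur, yr, "currency")
      infl <- lookup_factor(adjustments$inflation, df$country_id[i], yr,
                            "inflation")
      for (col in c("icu_day_cost", "gw_day_cost")) {
        df[[col]][i] <- df[[col]][i] * rate * infl
      }
    }
  }

  prov <- NULL
  report <- NULL
  sidecar <- provenance_sidecar_path(path)
  if (file.exists(sidecar)) {
    prov <- readr::read_csv(sidecar, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
  }
  report_path <- imputation_report_path(path)
  if (!is.null(prov) && file.exists(report_path)) {
    report <- readr::read_csv(report_path, col_types = readr::cols(
      country_id = readr::col_character(), field = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE)
  }
  country_dataset(df, provenance = prov, imputation_report = report)
}

provenance_sidecar_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_provenance.csv")
}

imputation_report_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_imputation.csv")
}

#' Write a country dataset to CSV
#'
#' Writes the data table; when any cell carries a non-trivial provenance
#' flag (imputed or sampled) a `*_provenance.csv` sidecar is written, and
#' the imputation report (if present) goes to `*_imputation.csv`, so that
#' [read_country_table()] round-trips the dataset field-for-field including
#' flags.
#'
#' @param x A `country_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_country_table <- function(x, path) {
  stopifnot(inherits(x, "country_dataset"))
  readr::write_csv(x$data, path, na = "")
  flags <- unlist(x$provenance[COUNTRY_INPUTS])
  if (any(flags %in% c("imputed", "sampled"))) {
    readr::write_csv(x$provenance, provenance_sidecar_path(path))
  }
  if (!is.null(x$imputation_report)) {
    readr::write_csv(x$imputation_report, imputation_report_path(path))
  }
  invisible(path)
}

#' Apply the five-of-ten country inclusion rule
#'
#' Countries with at least `min_known` of the ten inputs identified are
#' included in the analysis; the rest are excluded and listed with their
#' known-field counts.
#'
#' @param x A `country_dataset`.
#' @param min_known Minimum number of known fields for inclusion (default 5).
#' @return A list with `included` (a `country_dataset`) and `excluded`
#'   (a tibble with `country_id` and `n_known`).
#' @export
select_included_countries <- function(x, min_known = 5L) {
  stopifnot(inherits(x, "country_dataset"))
  nk <- n_known_fields(x)
  keep <- nk >= min_known
  excluded <- tibble::tibble(
    country_id = names(nk)[!keep],
    n_known = as.integer(nk[!keep])
  )
  if (!any(keep)) {
    stop("no countries included: every row has fewer than ", min_known,
         " known fields", call. = FALSE)
  }
  included <- country_dataset(
    x$data[keep, ], x$provenance[keep, ],
    imputation_report = subset_report(x$imputation_report, x$data$country_id[keep])
  )
  list(included = included, excluded = excluded)
}

subset_report <- function(report, ids) {
  if (is.null(report)) return(NULL)
  out <- report[report$country_id %in% ids, ]
  if (nrow(out) == 0) NULL else out
}

#' Median-impute missing country inputs
#'
#' For every input, the median of the known values across countries is
#' computed (sample median; midpoint of the two central values for even
#' counts) and substituted for each missing cell. The interquartile range
#' of the known values is recorded alongside each imputed cell in the
#' imputation report. Known values are never modified, and the operation is
#' idempotent: imputed cells keep their `"imputed"` flag and are not
#' re-imputed.
#'
#' @param x A `country_dataset` (normally the included subset).
#' @param reference Optional `country_dataset` from which the medians are
#'   computed; defaults to `x` itself (statistics over included countries
#'   only).
#' @return A `country_dataset` with no missing cells and an updated
#'   imputation report.
#' @export
impute_missing <- function(x, reference = NULL) {
  stopifnot(inherits(x, "country_dataset"))
  ref <- if (is.null(reference)) x else reference
  stopifnot(inherits(ref, "country_dataset"))

  data <- x$data
  prov <- x$provenance
  report <- x$imputation_report
  for (col in COUNTRY_INPUTS) {
    known <- ref$data[[col]][ref$provenance[[col]] == "known"]
    miss <- which(prov[[col]] == "missing")
    if (length(miss) == 0) next
    if (length(known) == 0) {
      stop("cannot impute '", col, "': no country has a known value",
           call. = FALSE)
    }
    med <- median(known)
    iqr <- quantile(known, c(0.25, 0.75), names = FALSE, type = 7)
    data[[col]][miss] <- med
    prov[[col]][miss] <- "imputed"
    report <- dplyr::bind_rows(report, tibble::tibble(
      country_id = data$country_id[miss],
      field = col,
      imputed_value = med,
      median_used = med,
      iqr_low = iqr[1],
      iqr_high = iqr[2]
    ))
  }
  country_dataset(data, prov, imputation_report = report)
}

#' Write the imputation report to CSV
#'
#' Columns: `country_id`, `field`, `imputed_value`, `median_used`,
#' `iqr_low`, `iqr_high`.
#'
#' @param x An imputed `country_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_imputation_report <- function(x, path) {
  stopifnot(inherits(x, "country_dataset"))
  report <- x$imputation_report
  if (is.null(report)) {
    report <- tibble::tibble(
      country_id = character(), field = character(),
      imputed_value = numeric(), median_used = numeric(),
      iqr_low = numeric(), iqr_high = numeric()
    )
  }
  readr::write_csv(report, path)
  invisible(path)
}
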