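test_that("a complete table loads with every field known", {
  df <- make_table_df(26)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "")
  ds <- read_country_table(path)
  expect_equal(nrow(ds$data), 26)
  expect_true(all(n_known_fields(ds) == 10))
  expect_equal(ds$data$icu_day_cost, df$icu_day_cost)
})

test_that("blank cells load as missing and reduce the known count", {
  df <- make_table_df(3)
  df$icu_day_cost[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "")
  ds <- read_country_table(path)
  expect_equal(unname(n_known_fields(ds)), c(10L, 9L, 10L))
  expect_identical(ds$provenance$icu_day_cost[2], "missing")
  expect_true(is.na(ds$data$icu_day_cost[2]))
})

test_that("costs are converted at the publication-year rate then inflated to 2017", {
  df <- make_table_df(2)
  df$icu_day_cost <- c(1000, 800)
  df$gw_day_cost <- c(400, 300)
  df$currency <- c("XCU", "EUR")
  df$cost_year <- c(2015, 2014)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "")
  adj_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "currencies:",
    "  XCU:",
    "    2015: 0.5",
    "inflation:",
    paste0("  ", df$country_id[1], ":"),
    "    2015: 1.10",
    paste0("  ", df$country_id[2], ":"),
    "    2014: 1.05"
  ), adj_path)
  ds <- read_country_table(path, read_adjustments(adj_path))
  expect_equal(ds$data$icu_day_cost[1], 1000 * 0.5 * 1.10) # 550
  expect_equal(ds$data$gw_day_cost[1], 400 * 0.5 * 1.10)
  # euro-denominated costs are inflated only
  expect_equal(ds$data$icu_day_cost[2], 800 * 1.05)
  # without adjustments the raw values are stored
  expect_equal(read_country_table(path)$data$icu_day_cost[1], 1000)
})

test_that("validation names the offending country and field", {
  df <- make_table_df(2)
  bad <- df; bad$icu_day_cost[2] <- -5
  expect_error(country_dataset(bad), "icu_day_cost.*SYN02|SYN02.*icu_day_cost")
  bad <- df; bad$swi_incidence[1] <- 1.4
  expect_error(country_dataset(bad), "swi_incidence")
  bad <- df; bad$surveillance_days[1] <- 0.2
  expect_error(country_dataset(bad), "surveillance_days")
  bad <- df; bad$country_id[2] <- bad$country_id[1]
  expect_error(country_dataset(bad), "duplicate")
  expect_error(country_dataset(df[, -3]), "missing column")
})

test_that("a malformed row is rejected with a row-level diagnostic", {
  df <- make_table_df(3)
  path <- withr::local_tempfile(fileext = ".csv")
  lines <- strsplit(readr::format_csv(df), "\n")[[1]]
  lines <- sub("^SYN02,[0-9.e+]+", "SYN02,not_a_number", lines)
  writeLines(lines, path)
  expect_error(read_country_table(path), "malformed|row")
})

test_that("countries with five or more known fields are included, others excluded", {
  df <- make_table_df(3)
  # row 1: 10 known; row 2: exactly 5 known; row 3: 4 known
  df[2, COUNTRY_INPUTS_test()[1:5]] <- NA
  df[3, COUNTRY_INPUTS_test()[1:6]] <- NA
  ds <- country_dataset(df)
  sel <- select_included_countries(ds)
  expect_setequal(sel$included$data$country_id, df$country_id[1:2])
  expect_equal(sel$excluded$country_id, df$country_id[3])
  expect_equal(sel$excluded$n_known, 4L)

  all_poor <- df
  for (i in 1:3) all_poor[i, COUNTRY_INPUTS_test()[1:6]] <- NA
  expect_error(select_included_countries(country_dataset(all_poor)),
               "no countries included")
})

test_that("median imputation uses the sample median and records the IQR", {
  df <- make_table_df(4)
  df$icu_day_cost <- c(2, 4, 6, NA)
  df$gw_day_cost <- c(2, 4, NA, NA)
  ds <- impute_missing(country_dataset(df))
  expect_equal(ds$data$icu_day_cost[4], 4) # odd count: middle value
  expect_equal(ds$data$gw_day_cost[3], 3)  # even count: midpoint
  expect_equal(ds$data$gw_day_cost[4], 3)
  expect_identical(ds$provenance$icu_day_cost[4], "imputed")
  rep_row <- ds$imputation_report[
    ds$imputation_report$field == "icu_day_cost", ]
  expect_equal(rep_row$median_used, 4)
  expect_equal(rep_row$iqr_low, unname(quantile(c(2, 4, 6), 0.25)))
  # an input with no known value anywhere cannot be imputed
  df$mean_los_days <- NA
  expect_error(impute_missing(country_dataset(df)), "mean_los_days")
})

test_that("imputation matches a brute-force oracle and is idempotent", {
  for (seed in c(11, 12, 13)) {
    ds <- generate_country_table(12, missingness = 0.3, seed = seed)
    sel <- select_included_countries(ds)
    imp <- impute_missing(sel$included)
    expect_true(all(!is.na(imp$data[, COUNTRY_INPUTS_test()])))
    for (col in COUNTRY_INPUTS_test()) {
      known_mask <- sel$included$provenance[[col]] == "known"
      known <- sel$included$data[[col]][known_mask]
      if (any(!known_mask)) {
        # brute-force median: midpoint of the sorted middle pair
        v <- sort(known)
        k <- length(v)
        med <- if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
        expect_equal(unique(imp$data[[col]][!known_mask]), med)
        expect_true(all(imp$data[[col]][!known_mask] >= min(known) &
                          imp$data[[col]][!known_mask] <= max(known)))
      }
      # known values untouched
      expect_identical(imp$data[[col]][known_mask], known)
    }
    # idempotence
    again <- impute_missing(imp)
    expect_equal(again$data, imp$data)
    expect_identical(again$provenance, imp$provenance)
    # imputing a dataset with nothing missing is the identity
    full <- generate_country_table(5, missingness = 0, seed = seed)
    expect_equal(impute_missing(full)$data, full$data)
  }
})

test_that("write/read round-trips values, provenance flags and the report", {
  ds <- generate_country_table(8, missingness = 0.3, seed = 21)
  imp <- impute_missing(select_included_countries(ds)$included)
  path <- withr::local_tempfile(fileext = ".csv")
  write_country_table(imp, path)
  back <- read_country_table(path)
  expect_equal(back$data, imp$data)
  expect_identical(back$provenance, imp$provenance)
  expect_equal(as.data.frame(back$imputation_report),
               as.data.frame(imp$imputation_report))
})
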