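# Exposure assessment: the standard assumption set, the daily-exposure
# product (additive concentration x product consumption), percentile
# summaries of device usage logs over daily/weekly/monthly timeframes, and
# the derivation of the recommended daily-consumption constant from the
# weekly and monthly 95th-percentile daily averages.

#' Standard exposure assumptions
#'
#' The default assumption set used throughout the framework:
#'
#' * `daily_consumption_mg = 100` -- conservative daily cannabis
#'   concentrate consumption for a high-level consumer, the average of the
#'   weekly and monthly 95th-percentile daily averages from smart-device
#'   telemetry (see [recommended_daily_consumption()]).
#' * `bioavailability_fraction = 1` -- conservative complete absorption.
#' * `body_weight_kg = 60` -- conservative adult body weight.
#' * Inhalation volumes 20 m3 (24 h), 6.7 m3 (8-h workday), 0.3 m3
#'   (15 min), used to convert air concentrations to inhaled doses.
#' * `days_per_month = 30.5` for monthly-to-daily averaging.
#'
#' @param daily_consumption_mg,bioavailability_fraction,body_weight_kg,inhalation_volume_24h_m3,inhalation_volume_8h_m3,inhalation_volume_15min_m3,days_per_month
#'   Override any default; all must be positive and the bioavailability a
#'   fraction in (0, 1].
#' @return An `exposure_assumptions` list.
#' @export
exposure_assumptions <- function(daily_consumption_mg = 100,
                                 bioavailability_fraction = 1,
                                 body_weight_kg = 60,
                                 inhalation_volume_24h_m3 = 20,
                                 inhalation_volume_8h_m3 = 6.7,
                                 inhalation_volume_15min_m3 = 0.3,
                                 days_per_month = 30.5) {
  a <- list(
    daily_consumption_mg = daily_consumption_mg,
    bioavailability_fraction = bioavailability_fraction,
    body_weight_kg = body_weight_kg,
    inhalation_volume_24h_m3 = inhalation_volume_24h_m3,
    inhalation_volume_8h_m3 = inhalation_volume_8h_m3,
    inhalation_volume_15min_m3 = inhalation_volume_15min_m3,
    days_per_month = days_per_month
  )
  bad <- names(a)[!vapply(a, function(x) is_scalar_number(x) && x > 0, logical(1))]
  if (length(bad)) {
    abort_validation(sprintf("%s must be a positive number", bad))
  }
  if (bioavailability_fraction > 1) {
    abort_validation("bioavailability_fraction must be in (0, 1]")
  }
  structure(a, class = "exposure_assumptions")
}

#' Daily exposure to an additive
#'
#' The daily additive dose is the additive concentration in the
#' concentrate (mg/g) times the daily concentrate consumption (mg/day),
#' divided by 1000 to reconcile the mass units:
#' `exposure mg/day = concentration x consumption / 1000`. A concentration
#' above 1000 mg/g would be an impossible mass fraction and is rejected.
#'
#' @param concentration_mg_per_g Additive concentration in the finished
#'   concentrate, mg/g (1 mg/g = 0.1% w/w).
#' @param consumption_mg_per_day Daily concentrate consumption, mg/day
#'   (default from [exposure_assumptions()] is 100).
#' @return An `exposure_estimate`: one-row tibble with
#'   `additive_mg_per_day` and the echoed inputs.
#' @export
#' @examples
#' daily_exposure(850, 151) # 128.35 mg THC/day
daily_exposure <- function(concentration_mg_per_g, consumption_mg_per_day) {
  stopifnot(
    is_scalar_number(concentration_mg_per_g), concentration_mg_per_g >= 0,
    is_scalar_number(consumption_mg_per_day), consumption_mg_per_day >= 0
  )
  if (concentration_mg_per_g > 1000) {
    abort(
      "concentration_mg_per_g exceeds 1000 mg/g (an impossible mass fraction)",
      class = "vaportox_bad_units"
    )
  }
  structure(
    tibble(
      additive_mg_per_day = concentration_mg_per_g * consumption_mg_per_day / 1000,
      concentration_mg_per_g = concentration_mg_per_g,
      consumption_mg_per_day = consumption_mg_per_day
    ),
    class = c("exposure_estimate", class(tibble()))
  )
}

usage_log_check <- function(log) {
  stopifnot(is.data.frame(log))
  need <- c("device_id", "date", "consumed_mg")
  if (!all(need %in% names(log))) {
    abort(
      sprintf(
        "Usage log must have columns %s", toString(need)
      ),
      class = "vaportox_format_error"
    )
  }
  if (nrow(log) == 0) {
    abort("Usage log is empty", class = "vaportox_empty_log")
  }
  if (any(log$consumed_mg < 0, na.rm = TRUE)) {
    abort("consumed_mg must be >= 0", class = "vaportox_validation_error")
  }
  if (anyNA(log$consumed_mg) || anyNA(log$date)) {
    abort("Usage log contains missing dates or amounts", class = "vaportox_validation_error")
  }
  if (anyDuplicated(log[c("device_id", "date")])) {
    abort(
      "Usage log must have one record per device-day",
      class = "vaportox_validation_error"
    )
  }
  log$date <- as.Date(log$date)
  log
}

pct_row <- function(x) {
  q <- quantile(x, c(0.5, 0.9, 0.95), type = 7, names = FALSE)
  tibble(mean = mean(x), p50 = q[1], p90 = q[2], p95 = q[3], n_obs = length(x))
}

#' Summarize a device usage log into consumption percentiles
#'
#' Produces the standard habits-and-practices summary over three
#' timeframes plus use frequency:
#'
#' * `daily_use_days`: per-use-day consumption, over device-days with
#'   positive consumption only (most consumers use intermittently, so this
#'   conditions on use).
#' * `weekly_total` / `monthly_total`: per-device totals over
#'   calendar-aligned ISO weeks and calendar months, zero-filled for
#'   non-use days inside each device's observed first-to-last span (so
#'   non-use days count), pooled across devices; the companion
#'   `*_daily_avg` rows divide by 7 and by `days_per_month` (30.5).
#' * `use_days_per_month`: count of positive-consumption days per
#'   device-month.
#'
#' Percentiles are empirical quantiles with linear interpolation between
#' order statistics (type 7). Each device is treated as one consumer.
#'
#' @param log A data frame with columns `device_id`, `date` (Date or
#'   ISO-8601 string), `consumed_mg`.
#' @param assumptions An [exposure_assumptions()] set (supplies
#'   `days_per_month`).
#' @return A `consumption_summary`: tibble with one row per timeframe
#'   (`timeframe`, `unit`, `mean`, `p50`, `p90`, `p95`, `n_obs`) and an
#'   `n_devices` attribute.
#' @export
summarize_usage <- function(log, assumptions = exposure_assumptions()) {
  log <- usage_log_check(log)
  use_days <- log$consumed_mg[log$consumed_mg > 0]
  if (length(use_days) == 0) {
    abort(
      "Usage log has no use days (all consumption zero)",
      class = "vaportox_empty_log"
    )
  }

  # zero-fill non-use days inside each device's observed span (vectorized:
  # expand each device's first-to-last date range, then join the log back)
  spans <- log |>
    group_by(.data$device_id) |>
    summarise(first = min(.data$date), last = max(.data$date), .groups = "drop")
  lens <- as.integer(spans$last - spans$first) + 1L
  filled <- tibble(
    device_id = rep(spans$device_id, lens),
    date = rep(spans$first, lens) + (sequence(lens) - 1L)
  ) |>
    left_join(log, by = c("device_id", "date")) |>
    mutate(consumed_mg = tidyr::replace_na(.data$consumed_mg, 0))

  weekly <- filled |>
    mutate(week = lubridate::floor_date(.data$date, "week", week_start = 1)) |>
    group_by(.data$device_id, .data$week) |>
    summarise(total = sum(.data$consumed_mg), .groups = "drop")

  monthly <- filled |>
    mutate(month = lubridate::floor_date(.data$date, "month")) |>
    group_by(.data$device_id, .data$month) |>
    summarise(
      total = sum(.data$consumed_mg),
      use_days = sum(.data$consumed_mg > 0),
      .groups = "drop"
    )

  dpm <- assumptions$days_per_month
  rows <- bind_rows(
    mutate(pct_row(use_days), timeframe = "daily_use_days", unit = "mg"),
    mutate(pct_row(weekly$total), timeframe = "weekly_total", unit = "mg"),
    mutate(pct_row(weekly$total / 7), timeframe = "weekly_daily_avg", unit = "mg/day"),
    mutate(pct_row(monthly$total), timeframe = "monthly_total", unit = "mg"),
    mutate(pct_row(monthly$total / dpm), timeframe = "monthly_daily_avg", unit = "mg/day"),
    mutate(pct_row(monthly$use_days), timeframe = "use_days_per_month", unit = "days")
  ) |>
    select("timeframe", "unit", "mean", "p50", "p90", "p95", "n_obs")
  structure(
    rows,
    n_devices = length(unique(log$device_id)),
    class = c("consumption_summary", class(rows))
  )
}

#' Convert a period total to a daily average
#'
#' Weekly totals divide by 7; monthly totals divide by the
#' days-per-month assumption (default 30.5).
#'
#' @param total_mg Period total consumption, mg.
#' @param timeframe `"weekly"` or `"monthly"`.
#' @param assumptions An [exposure_assumptions()] set.
#' @return mg/day.
#' @export
#' @examples
#' daily_average_from_period(1743, "monthly") # 57.1...
#' daily_average_from_period(982, "weekly") # 140.3
daily_average_from_period <- function(total_mg, timeframe = c("weekly", "monthly"),
                                      assumptions = exposure_assumptions()) {
  timeframe <- match.arg(timeframe)
  stopifnot(is.numeric(total_mg), all(total_mg >= 0))
  switch(timeframe,
    weekly = total_mg / 7,
    monthly = total_mg / assumptions$days_per_month
  )
}

#' Recommended daily consumption from telemetry percentiles
#'
#' The headline daily-consumption assumption for first-tier exposure
#' assessment is the arithmetic mean of the weekly and monthly
#' 95th-percentile daily averages, rounded to one significant figure
#' (140 and 57 mg/day from the reference telemetry give a mean of 98.5,
#' hence the 100 mg/day default).
#'
#' @param weekly_p95_daily Weekly 95th-percentile daily average, mg/day.
#' @param monthly_p95_daily Monthly 95th-percentile daily average, mg/day.
#' @return One-row tibble with `mean_mg_per_day` (unrounded) and
#'   `headline_mg_per_day` (one significant figure).
#' @export
#' @examples
#' recommended_daily_consumption(140, 57) # headline 100
recommended_daily_consumption <- function(weekly_p95_daily, monthly_p95_daily) {
  stopifnot(
    is_scalar_number(weekly_p95_daily), weekly_p95_daily > 0,
    is_scalar_number(monthly_p95_daily), monthly_p95_daily > 0
  )
  m <- mean(c(weekly_p95_daily, monthly_p95_daily))
  tibble(mean_mg_per_day = m, headline_mg_per_day = signif(m, 1))
}

#' Read / write usage-log CSV
#'
#' The usage-log interchange format is a UTF-8 CSV with columns
#' `device_id`, `date` (ISO-8601), `consumed_mg`.
#'
#' @param path CSV path.
#' @return A validated usage-log tibble.
#' @export
read_usage_log <- function(path) {
  log <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      device_id = readr::col_character(),
      date = readr::col_date(),
      consumed_mg = readr::col_double()
    )
  )
  usage_log_check(log)
}

#' @rdname read_usage_log
#' @param log A usage-log data frame.
#' @export
write_usage_log <- function(log, path) {
  readr::write_csv(usage_log_check(log), path)
  invisible(path)
}
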