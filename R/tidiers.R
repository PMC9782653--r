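# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' Tidy a UF ledger
#' @param x A `uf_ledger`.
#' @param ... Unused.
#' @return Tibble with one row per uncertainty category.
#' @export
tidy.uf_ledger <- function(x, ...) {
  as_tibble(x)
}

#' One-row ledger summary
#' @param x A `uf_ledger`.
#' @param ... Unused.
#' @export
glance.uf_ledger <- function(x, ...) {
  tibble(
    uf_total = uf_product(x),
    within_cap = uf_product(x) <= 10000
  )
}

#' Tidy a safety limit
#' @param x A `safety_limit`.
#' @param ... Unused.
#' @export
tidy.safety_limit <- function(x, ...) {
  tibble(
    term = c("value_native_units", "value_mg_per_day", "uf_total"),
    value = c(x$value_native_units, x$value_mg_per_day, uf_product(x$ledger)),
    unit = c(x$units, "mg_per_day", "")
  )
}

#' One-row safety-limit summary
#' @param x A `safety_limit`.
#' @param ... Unused.
#' @export
glance.safety_limit <- function(x, ...) {
  tibble(
    value_mg_per_day = x$value_mg_per_day,
    units_native = x$units,
    value_native = x$value_native_units,
    pod_type = x$governing_pod$pod_type,
    endpoint_scope = x$endpoint_scope,
    uf_total = uf_product(x$ledger)
  )
}

#' Tidy a screening result
#' @param x A `screen_result`.
#' @param ... Unused.
#' @export
tidy.screen_result <- function(x, ...) {
  x$reasons
}

#' Tidy a TTC result
#' @param x A `ttc_result`.
#' @param ... Unused.
#' @export
tidy.ttc_result <- function(x, ...) {
  tibble(
    applicable = x$applicable,
    category = x$category,
    limit_ug_per_day = if (x$applicable) x$limit_ug_per_day else NA_real_
  )
}

#' Tidy a risk verdict
#' @param x A `risk_verdict`.
#' @param ... Unused.
#' @export
tidy.risk_verdict <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    exposure_mg_per_day = x$exposure_mg_per_day,
    governing_limit_mg_per_day = x$governing_limit_mg_per_day %||% NA_real_,
    limit_source = x$limit_source %||% NA_character_,
    margin = x$margin %||% NA_real_
  )
}

#' One-row assessment summary
#' @param x An `assessment_report`.
#' @param ... Unused.
#' @export
glance.assessment_report <- function(x, ...) {
  tidy(x$verdict) |>
    mutate(
      substance = x$dossier$name,
      concentration_mg_per_g = x$concentration_mg_per_g,
      max_allowable_concentration_pct = x$max_allowable_concentration_pct %||% NA_real_,
      .before = 1
    )
}

#' Tidy a consumption summary
#' @param x A `consumption_summary`.
#' @param ... Unused.
#' @export
tidy.consumption_summary <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Plot consumption percentiles by timeframe
#'
#' Bar chart of the mean and 50th/90th/95th percentiles for each
#' timeframe of a usage-log summary, mirroring the habits-and-practices
#' table structure.
#'
#' @param object A `consumption_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consumption_summary <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("mean", "p50", "p90", "p95"),
      names_to = "statistic", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~timeframe, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "consumption",
      title = "Consumption summary by timeframe",
      subtitle = sprintf("%d devices", attr(object, "n_devices"))
    )
}

#' Histogram of per-use-day consumption in a usage log
#'
#' @param log A usage-log data frame.
#' @param bins Number of histogram bins.
#' @return A ggplot of positive-consumption days on a log10 x axis.
#' @export
plot_usage_histogram <- function(log, bins = 50) {
  log <- usage_log_check(log)
  df <- filter(log, .data$consumed_mg > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$consumed_mg)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "consumption per use day (mg, log scale)", y = "use days",
      title = "Per-use-day consumption"
    )
}
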