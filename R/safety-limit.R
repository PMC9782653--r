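# Safety-limit derivation: adjust the point of departure to continuous
# exposure and purity, assemble the six-category uncertainty-factor (UF)
# ledger, divide, normalize to mg/day, and select the governing limit
# across candidate PODs. The total UF is capped at 10,000: beyond that the
# database is considered too thin for a numeric first-tier limit and the
# assessment is pushed to the TTC tier.

uf_names <- c(
  "interspecies", "intraspecies", "route_to_route", "loael_to_noael",
  "duration", "database"
)

#' Adjust a point of departure to continuous exposure and purity
#'
#' Study PODs rarely reflect continuous exposure. A NOAEL from dosing five
#' days per week is multiplied by 5/7; an inhalation NOAEC from 6 h/day,
#' 5 d/week exposure is multiplied by 6/24 and 5/7. The value is also
#' scaled by the purity of the test article. The hours-per-day factor
#' applies only to inhalation concentrations (oral doses are daily totals
#' regardless of gavage timing).
#'
#' Regulatory limits are not schedule-adjusted; they are converted through
#' their averaging window by [normalize_limit_to_mg_per_day()].
#'
#' @param pod A one-row POD tibble from [pod_record()].
#' @return The POD with `value` adjusted; other fields preserved.
#' @export
#' @examples
#' p <- pod_record(100, "mg_per_m3", "NOAEC",
#'   route = "inhalation", species = "animal", duration_class = "subchronic",
#'   hours_per_day = 6, days_per_week = 5
#' )
#' adjust_pod(p)$value # 100 * 6/24 * 5/7 = 17.857...
adjust_pod <- function(pod) {
  stopifnot(is.data.frame(pod), nrow(pod) == 1L)
  if (pod$pod_type == "regulatory_limit") {
    abort(
      paste(
        "Regulatory limits are window-converted, not schedule-adjusted;",
        "use normalize_limit_to_mg_per_day() instead."
      ),
      class = "vaportox_bad_pod"
    )
  }
  hours_factor <- if (pod$route == "inhalation") pod$hours_per_day / 24 else 1
  pod$value <- pod$value * hours_factor * (pod$days_per_week / 7) *
    pod$test_article_purity
  attr(pod, "adjusted") <- TRUE
  pod
}

#' Build the uncertainty-factor ledger for a POD
#'
#' Six uncertainty categories are evaluated, each with a default factor and
#' defined reductions:
#'
#' 1. *Interspecies*: 10 for animal studies, 1 for human data.
#' 2. *Intraspecies*: 10 by default; 3 or 1 if the study population was a
#'    moderately or strongly sensitive subpopulation (an explicit dossier
#'    assertion, never automatic).
#' 3. *Route-to-route*: oral-to-inhalation extrapolation combines a
#'    toxicokinetic factor of 2 and a toxicodynamic factor of 3 (total 6);
#'    measured absorption data replace the toxicokinetic component (total
#'    3). Inhalation studies need no extrapolation (1). Dermal PODs are
#'    rejected: no dermal extrapolation factors are defined.
#' 4. *LOAEL-to-NOAEL*: 10 when the POD is a LOAEL/LOAEC.
#' 5. *Duration*: subacute-to-chronic 10, subchronic-to-chronic 3,
#'    chronic/clinical-or-lifetime 1.
#' 6. *Database completeness*: 1 when developmental data exist or the
#'    product is age-gated; otherwise 10, reduced to 3 when the substance's
#'    structural features are not suggestive of developmental toxicity.
#'
#' Categories the source limit already addresses
#' (`uf_categories_already_addressed` on the POD) are forced to 1 with
#' provenance "addressed by source limit".
#'
#' @param pod A one-row POD tibble.
#' @param dossier The `substance_dossier` (supplies developmental-data and
#'   structural-alert fields).
#' @param context The `product_context` (supplies age gating).
#' @param absorption_data_available Measured oral/inhalation absorption data
#'   replace the toxicokinetic half of the route factor.
#' @return A `uf_ledger`: tibble with `category` (1-6), `name`, `value`,
#'   `provenance`.
#' @export
build_uf_ledger <- function(pod, dossier, context,
                            absorption_data_available = FALSE) {
  stopifnot(is.data.frame(pod), nrow(pod) == 1L)
  stopifnot(inherits(context, "product_context"))
  if (pod$route == "dermal") {
    abort(
      "No dermal-to-inhalation extrapolation factors are defined; dermal PODs cannot anchor a first-tier limit.",
      class = "vaportox_bad_pod"
    )
  }

  uf1 <- if (pod$species == "animal") 10 else 1
  p1 <- if (uf1 == 10) "animal-to-human extrapolation" else "human data"

  uf2 <- switch(pod$tested_sensitive_subpopulation,
    none = 10, moderate = 3, strong = 1
  )
  p2 <- if (uf2 == 10) {
    "default intraspecies variability"
  } else {
    sprintf(
      "reduced: study conducted in a %s sensitive subpopulation",
      pod$tested_sensitive_subpopulation
    )
  }

  if (pod$route == "inhalation") {
    uf3 <- 1
    p3 <- "inhalation study; no route extrapolation"
  } else if (absorption_data_available) {
    uf3 <- 3
    p3 <- "oral-to-inhalation: toxicodynamics 3; toxicokinetics replaced by measured absorption"
  } else {
    uf3 <- 6
    p3 <- "oral-to-inhalation: toxicokinetics 2 x toxicodynamics 3"
  }

  uf4 <- if (pod$pod_type %in% c("LOAEL", "LOAEC")) 10 else 1
  p4 <- if (uf4 == 10) "LOAEL-to-NOAEL extrapolation" else "NOAEL/NOAEC basis"

  uf5 <- switch(pod$duration_class,
    subacute = 10, subchronic = 3, chronic = 1, clinical_or_lifetime = 1
  )
  p5 <- switch(pod$duration_class,
    subacute = "subacute-to-chronic extrapolation",
    subchronic = "subchronic-to-chronic extrapolation",
    "chronic or lifetime study"
  )

  if (isTRUE(dossier$developmental_data_available)) {
    uf6 <- 1
    p6 <- "developmental/reproductive data available"
  } else if (isTRUE(context$age_gated)) {
    uf6 <- 1
    p6 <- "age-gated product; developmental database factor waived"
  } else if (!isTRUE(dossier$developmental_structural_alert)) {
    uf6 <- 3
    p6 <- "no developmental data; structural features not suggestive"
  } else {
    uf6 <- 10
    p6 <- "no developmental data for a non-age-gated product"
  }

  ledger <- tibble(
    category = 1:6,
    name = uf_names,
    value = c(uf1, uf2, uf3, uf4, uf5, uf6),
    provenance = c(p1, p2, p3, p4, p5, p6)
  )
  addressed <- pod$uf_categories_already_addressed[[1]]
  if (length(addressed)) {
    ledger$value[ledger$category %in% addressed] <- 1
    ledger$provenance[ledger$category %in% addressed] <- "addressed by source limit"
  }
  structure(ledger, class = c("uf_ledger", class(ledger)))
}

#' Total uncertainty factor of a ledger
#' @param ledger A `uf_ledger`.
#' @return Product of the six factors.
#' @export
uf_product <- function(ledger) {
  prod(ledger$value)
}

#' Compute a safety limit from an adjusted POD and a UF ledger
#'
#' The safety limit is the adjusted POD divided by the product of the six
#' uncertainty factors, in the POD's own units. When the total UF exceeds
#' 10,000 there is likely insufficient information for a numeric
#' first-tier limit and the function refuses with a
#' `vaportox_insufficient_data` error recommending the TTC route.
#'
#' @param adjusted_pod A POD tibble after [adjust_pod()].
#' @param ledger A `uf_ledger` from [build_uf_ledger()].
#' @return A `safety_limit`: value in the POD's native units plus the
#'   ledger and POD provenance; `value_mg_per_day` is filled by
#'   [normalize_limit_to_mg_per_day()].
#' @export
compute_safety_limit <- function(adjusted_pod, ledger) {
  stopifnot(inherits(ledger, "uf_ledger"))
  total <- uf_product(ledger)
  if (total > 10000) {
    abort_insufficient_data(
      sprintf(
        paste(
          "Total uncertainty factor %s exceeds the 10,000 cap: likely",
          "insufficient information for a first-tier limit. Consider the",
          "TTC route or a higher-tier assessment."
        ),
        format(total, big.mark = ",", scientific = FALSE)
      ),
      uf_total = total
    )
  }
  structure(
    list(
      value_native_units = adjusted_pod$value / total,
      units = adjusted_pod$units,
      value_mg_per_day = NA_real_,
      governing_pod = adjusted_pod,
      ledger = ledger,
      endpoint_scope = adjusted_pod$endpoint_scope
    ),
    class = "safety_limit"
  )
}

window_volume <- function(window, assumptions) {
  switch(window,
    stel_15min = assumptions$inhalation_volume_15min_m3,
    twa_8h = assumptions$inhalation_volume_8h_m3,
    continuous_24h = assumptions$inhalation_volume_24h_m3,
    abort(
      "An air concentration (mg/m3) needs an averaging window (stel_15min, twa_8h or continuous_24h) to convert to a daily dose.",
      class = "vaportox_bad_units"
    )
  )
}

#' Normalize a limit or regulatory POD to mg/day
#'
#' Converts between the three supported unit systems using the standard
#' exposure assumptions: body-weight doses (mg/kg bw/day) are multiplied by
#' the 60 kg default body weight; air concentrations (mg/m3) are multiplied
#' by the inhalation volume of their averaging window (0.3 m3 over 15 min,
#' 6.7 m3 over an 8-h workday, 20 m3 over 24 h); mg/day values pass through
#' unchanged. For example, a 135 mg/m3 8-h TWA corresponds to
#' 135 x 6.7 = 904.5 mg inhaled over a workday.
#'
#' @param value Numeric limit or POD value, or a `safety_limit` object (in
#'   which case the converted value is stored in its `value_mg_per_day`
#'   field and the object returned).
#' @param units One of `"mg_per_kg_bw_per_day"`, `"mg_per_m3"`,
#'   `"mg_per_day"`; ignored for `safety_limit` input.
#' @param window Averaging window, required for `"mg_per_m3"`.
#' @param assumptions An [exposure_assumptions()] set.
#' @return mg/day (numeric), or the updated `safety_limit`.
#' @export
#' @examples
#' normalize_limit_to_mg_per_day(135, "mg_per_m3", "twa_8h") # 904.5
#' normalize_limit_to_mg_per_day(0.01, "mg_per_kg_bw_per_day") # 0.6
normalize_limit_to_mg_per_day <- function(value,
                                          units = NULL,
                                          window = "not_applicable",
                                          assumptions = exposure_assumptions()) {
  if (inherits(value, "safety_limit")) {
    lim <- value
    pod <- lim$governing_pod
    win <- if (pod$units == "mg_per_m3") {
      if (pod$regulatory_window != "not_applicable") {
        pod$regulatory_window
      } else {
        # adjust_pod() has normalized a study NOAEC to continuous exposure
        "continuous_24h"
      }
    } else {
      "not_applicable"
    }
    lim$value_mg_per_day <- normalize_limit_to_mg_per_day(
      lim$value_native_units, lim$units, win, assumptions
    )
    return(lim)
  }
  stopifnot(is_scalar_number(value), value >= 0)
  switch(units,
    mg_per_kg_bw_per_day = value * assumptions$body_weight_kg,
    mg_per_m3 = value * window_volume(window, assumptions),
    mg_per_day = value,
    abort(sprintf("Unsupported units '%s'", units), class = "vaportox_bad_units")
  )
}

#' Select the governing limit among candidate safety limits
#'
#' Systemic and local-respiratory endpoints are evaluated as separate
#' tracks. Within a track, a NOAEL-based candidate is only eligible if its
#' (adjusted, mg/day-normalized) POD is lower than every LOAEL-based POD in
#' the track; otherwise it is discarded in favour of the LOAEL-derived
#' candidate, which carries the LOAEL-to-NOAEL factor. The governing limit
#' is then the minimum mg/day value across both tracks (the more sensitive
#' endpoint governs). Every discarded candidate is recorded in the audit
#' attribute.
#'
#' @param candidates List of `safety_limit` objects, all normalized to
#'   mg/day.
#' @param audit Optional audit collector (internal).
#' @return The governing `safety_limit`, with an `"audit"` attribute
#'   listing the decisions.
#' @export
select_governing_limit <- function(candidates, audit = NULL) {
  if (length(candidates) == 0) {
    abort_insufficient_data(
      "No candidate safety limits: no usable PODs. Consider the TTC route."
    )
  }
  stopifnot(all(vapply(candidates, inherits, logical(1), "safety_limit")))
  if (anyNA(vapply(candidates, function(x) x$value_mg_per_day, numeric(1)))) {
    abort("All candidates must be normalized to mg/day before selection.")
  }
  if (is.null(audit)) audit <- new_audit()

  pod_mg_day <- function(cand) {
    pod <- cand$governing_pod
    win <- if (pod$units == "mg_per_m3") {
      if (pod$regulatory_window != "not_applicable") pod$regulatory_window else "continuous_24h"
    } else {
      "not_applicable"
    }
    normalize_limit_to_mg_per_day(pod$value, pod$units, win)
  }

  keep <- rep(TRUE, length(candidates))
  for (scope in unique(vapply(candidates, function(x) x$endpoint_scope, character(1)))) {
    idx <- which(vapply(candidates, function(x) x$endpoint_scope, character(1)) == scope)
    types <- vapply(candidates[idx], function(x) x$governing_pod$pod_type, character(1))
    pods_mgd <- vapply(candidates[idx], pod_mg_day, numeric(1))
    loael_pods <- pods_mgd[types %in% c("LOAEL", "LOAEC")]
    if (length(loael_pods)) {
      for (j in seq_along(idx)) {
        if (types[j] %in% c("NOAEL", "NOAEC") && pods_mgd[j] > min(loael_pods)) {
          keep[idx[j]] <- FALSE
          audit_add(
            audit,
            sprintf(
              "Discarded %s candidate (%s track, POD %.4g mg/day): a lower LOAEL (%.4g mg/day) exists; the LOAEL-derived limit governs.",
              types[j], scope, pods_mgd[j], min(loael_pods)
            )
          )
        }
      }
    }
  }
  surv <- candidates[keep]
  if (length(surv) == 0) {
    abort_insufficient_data(
      paste(
        "Every NOAEL-based candidate sits above a LOAEL whose own limit was",
        "not computable: expert review needed. Consider the TTC route."
      )
    )
  }
  vals <- vapply(surv, function(x) x$value_mg_per_day, numeric(1))
  winner <- surv[[which.min(vals)]]
  audit_add(
    audit,
    sprintf(
      "Governing limit: %.4g mg/day (%s endpoint, %s) selected as the minimum of %d eligible candidate(s).",
      winner$value_mg_per_day, winner$endpoint_scope,
      winner$governing_pod$pod_type, length(surv)
    )
  )
  attr(winner, "audit") <- audit_lines(audit)
  winner
}

#' Derive the governing safety limit for a dossier
#'
#' Runs the full dose-response chain over every POD in the dossier:
#' schedule/purity adjustment (study PODs) or window conversion
#' (regulatory limits), UF ledger assembly, division, mg/day
#' normalization, and governing-limit selection. PODs whose ledger busts
#' the 10,000 UF cap are dropped with an audit line; if none survive, a
#' `vaportox_insufficient_data` error directs the caller to the TTC route.
#'
#' @inheritParams build_uf_ledger
#' @param dossier A `substance_dossier` with at least one POD.
#' @param assumptions An [exposure_assumptions()] set.
#' @param audit Optional audit collector (internal).
#' @return The governing `safety_limit` (mg/day filled), with audit lines.
#' @export
derive_safety_limit <- function(dossier, context,
                                assumptions = exposure_assumptions(),
                                absorption_data_available = FALSE,
                                audit = NULL) {
  validate_dossier(dossier)
  if (is.null(audit)) audit <- new_audit()
  if (nrow(dossier$pods) == 0) {
    abort_insufficient_data(
      "Dossier has no PODs; derive a limit via the TTC route instead."
    )
  }
  candidates <- list()
  for (i in seq_len(nrow(dossier$pods))) {
    pod <- dossier$pods[i, ]
    res <- tryCatch(
      {
        if (pod$pod_type == "regulatory_limit") {
          mgd <- normalize_limit_to_mg_per_day(
            pod$value, pod$units, pod$regulatory_window, assumptions
          )
          audit_add(audit, sprintf(
            "POD %d: regulatory limit %.4g %s (%s window) = %.4g mg/day before UFs.",
            i, pod$value, pod$units, pod$regulatory_window, mgd
          ))
          ledger <- build_uf_ledger(pod, dossier, context, absorption_data_available)
          pod_mgd <- pod
          pod_mgd$value <- mgd
          pod_mgd$units <- "mg_per_day"
          lim <- compute_safety_limit(pod_mgd, ledger)
          normalize_limit_to_mg_per_day(lim, assumptions = assumptions)
        } else {
          adj <- adjust_pod(pod)
          audit_add(audit, sprintf(
            "POD %d: %s %.4g %s adjusted to %.4g (schedule %sx%g/7, purity %g).",
            i, pod$pod_type, pod$value, pod$units, adj$value,
            if (pod$route == "inhalation") sprintf("%g/24 ", pod$hours_per_day) else "",
            pod$days_per_week, pod$test_article_purity
          ))
          ledger <- build_uf_ledger(pod, dossier, context, absorption_data_available)
          audit_add(audit, sprintf(
            "POD %d: UF ledger (%s), total %s.",
            i, paste(ledger$value, collapse = ", "),
            format(uf_product(ledger), big.mark = ",", scientific = FALSE)
          ))
          lim <- compute_safety_limit(adj, ledger)
          normalize_limit_to_mg_per_day(lim, assumptions = assumptions)
        }
      },
      vaportox_insufficient_data = function(e) {
        audit_add(audit, sprintf("POD %d dropped: %s", i, conditionMessage(e)))
        NULL
      },
      vaportox_bad_pod = function(e) {
        audit_add(audit, sprintf("POD %d dropped: %s", i, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) candidates <- c(candidates, list(res))
  }
  if (length(candidates) == 0) {
    abort_insufficient_data(
      paste(
        "No POD yields a computable first-tier limit",
        "(uncertainty cap exceeded or unusable routes).",
        "Consider the TTC route."
      )
    )
  }
  select_governing_limit(candidates, audit)
}

#' @export
print.safety_limit <- function(x, ...) {
  cat("<safety_limit>", signif(x$value_native_units, 3), x$units, "\n")
  if (!is.na(x$value_mg_per_day)) {
    cat("  normalized:", signif(x$value_mg_per_day, 3), "mg/day\n")
  }
  cat(
    "  endpoint:", x$endpoint_scope,
    "| POD:", x$governing_pod$pod_type,
    "| total UF:", uf_product(x$ledger), "\n"
  )
  invisible(x)
}
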