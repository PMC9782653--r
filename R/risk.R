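# Risk characterization: compare the daily additive exposure with the
# governing safety limit, back-calculate the maximum allowable
# concentration, and orchestrate the full first-tier assessment from a
# dossier to an audit-trailed report.

#' Characterize risk from exposure and a safety limit
#'
#' Risk is low when the estimated daily exposure does not exceed the
#' governing limit. Equality is treated as low risk (a "less than"
#' reading would leave the boundary undefined) but emits a boundary
#' warning. When the screen verdict is `exclude`, the verdict is
#' `excluded` regardless of dose. The margin is the limit-to-exposure
#' ratio; it is undefined (NA) at zero exposure.
#'
#' @param exposure An `exposure_estimate` from [daily_exposure()].
#' @param limit_mg_per_day Governing safety limit, mg/day. TTC limits in
#'   ug/day must be converted before this point (done centrally by
#'   [run_assessment()]).
#' @param screen A `screen_result` from [screen_substance()].
#' @param limit_source `"pod_derived"` or `"ttc"`.
#' @return A `risk_verdict`: `verdict` (`excluded`, `low_risk`,
#'   `exceeds_limit`), `exposure_mg_per_day`, `governing_limit_mg_per_day`,
#'   `limit_source`, `margin`, and `guidance`.
#' @export
#' @examples
#' scr <- screen_substance(substance_dossier("x"), product_context())
#' characterize_risk(daily_exposure(5, 100), 0.6, scr)
characterize_risk <- function(exposure, limit_mg_per_day, screen,
                              limit_source = "pod_derived") {
  stopifnot(inherits(screen, "screen_result"))
  exp_mg <- exposure$additive_mg_per_day
  stopifnot(is_scalar_number(exp_mg))

  if (screen$verdict == "exclude") {
    return(structure(
      list(
        verdict = "excluded",
        exposure_mg_per_day = exp_mg,
        governing_limit_mg_per_day = NULL,
        limit_source = NULL,
        margin = NULL,
        screen = screen,
        guidance = paste(
          "Substance is categorically excluded from inhalable products:",
          paste(screen$reasons$rule_id, collapse = ", ")
        )
      ),
      class = "risk_verdict"
    ))
  }
  stopifnot(is_scalar_number(limit_mg_per_day), limit_mg_per_day > 0)
  if (exp_mg == limit_mg_per_day) {
    warn("Exposure equals the safety limit exactly: treated as low risk at the boundary.")
  }
  low <- exp_mg <= limit_mg_per_day
  structure(
    list(
      verdict = if (low) "low_risk" else "exceeds_limit",
      exposure_mg_per_day = exp_mg,
      governing_limit_mg_per_day = limit_mg_per_day,
      limit_source = limit_source,
      margin = if (exp_mg > 0) limit_mg_per_day / exp_mg else NA_real_,
      screen = screen,
      guidance = if (low) {
        "Exposure is at or below the safety limit; toxicological risk is expected to be low."
      } else {
        paste(
          "Exposure exceeds the safety limit. Options: (1) remove the",
          "additive or reduce its concentration, (2) have an experienced",
          "risk assessor conduct a more refined assessment, or (3) generate",
          "the data needed for a full toxicological risk assessment."
        )
      }
    ),
    class = "risk_verdict"
  )
}

#' Maximum allowable concentration of an additive
#'
#' Back-calculates the concentration at which daily exposure equals the
#' safety limit: `limit (mg/day) / consumption (mg/day) x 100`, in % w/w
#' (1% w/w = 10 mg/g). Values above 100% (limit above total product
#' consumption) are capped at 100% with a warning.
#'
#' @param limit_mg_per_day Safety limit, mg/day (>= 0).
#' @param consumption_mg_per_day Daily concentrate consumption, mg/day
#'   (> 0).
#' @return Percent w/w in \[0, 100\].
#' @export
#' @examples
#' max_allowable_concentration(1, 100) # 1% w/w
max_allowable_concentration <- function(limit_mg_per_day, consumption_mg_per_day) {
  stopifnot(is_scalar_number(limit_mg_per_day), limit_mg_per_day >= 0)
  if (!is_scalar_number(consumption_mg_per_day) || consumption_mg_per_day <= 0) {
    abort(
      "consumption_mg_per_day must be a positive number",
      class = "vaportox_validation_error"
    )
  }
  pct <- limit_mg_per_day / consumption_mg_per_day * 100
  if (pct > 100) {
    warn(sprintf(
      "Allowable concentration formula gives %.3g%% w/w; capped at 100%% (the limit exceeds total product consumption).",
      pct
    ))
    pct <- 100
  }
  pct
}

#' Run a complete first-tier assessment
#'
#' Orchestrates the whole pipeline in narrative order: categorical hazard
#' screen; dose-response (POD adjustment, UF ledger, division, mg/day
#' normalization, governing-limit selection) when the dossier has PODs, or
#' TTC routing when it does not (and as fallback when the UF cap refuses a
#' POD-derived limit); daily-exposure calculation at the proposed
#' concentration; risk characterization; and back-calculation of the
#' maximum allowable concentration. Every branch taken is recorded in the
#' report's audit trail. TTC limits (ug/day) are converted to mg/day at a
#' single choke point.
#'
#' When no POD-derived limit is computable and TTC is not applicable, the
#' verdict is `insufficient_data` -- never a silent pass.
#'
#' @param dossier A `substance_dossier`.
#' @param context A `product_context`.
#' @param assumptions An [exposure_assumptions()] set.
#' @param concentration_mg_per_g Proposed additive concentration in the
#'   concentrate, mg/g.
#' @param strict_genotox Passed to [screen_substance()].
#' @param conservative_ttc Passed to [route_ttc()].
#' @return An `assessment_report`: echoes of all inputs, the
#'   `risk_verdict`, the maximum allowable concentration, the audit trail,
#'   and version stamps.
#' @export
#' @examples
#' d <- substance_dossier("geraniol",
#'   native_to_cannabis = TRUE,
#'   gras_or_food_use = TRUE, cramer_class = "1"
#' )
#' run_assessment(d, product_context(), concentration_mg_per_g = 0.5)
run_assessment <- function(dossier, context,
                           assumptions = exposure_assumptions(),
                           concentration_mg_per_g,
                           strict_genotox = FALSE,
                           conservative_ttc = FALSE) {
  validate_dossier(dossier)
  stopifnot(inherits(context, "product_context"))
  audit <- new_audit()

  screen <- screen_substance(dossier, context, strict_genotox = strict_genotox)
  audit_add(audit, sprintf(
    "Screen: %s%s.", screen$verdict,
    if (nrow(screen$reasons)) paste0(" (", paste(screen$reasons$rule_id, collapse = ", "), ")") else ""
  ))

  exposure <- daily_exposure(concentration_mg_per_g, assumptions$daily_consumption_mg)
  audit_add(audit, sprintf(
    "Exposure: %.4g mg/g x %.4g mg/day / 1000 = %.4g mg/day.",
    concentration_mg_per_g, assumptions$daily_consumption_mg,
    exposure$additive_mg_per_day
  ))

  limit <- NULL
  limit_source <- NULL
  ttc <- NULL
  insufficient <- FALSE

  if (screen$verdict != "exclude") {
    if (nrow(dossier$pods) > 0) {
      limit_obj <- tryCatch(
        derive_safety_limit(dossier, context, assumptions, audit = audit),
        vaportox_insufficient_data = function(e) {
          audit_add(audit, sprintf("POD route unavailable: %s", conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(limit_obj)) {
        for (l in attr(limit_obj, "audit")) audit_add(audit, l)
        limit <- limit_obj$value_mg_per_day
        limit_source <- "pod_derived"
      }
    }
    if (is.null(limit)) {
      ttc <- tryCatch(
        route_ttc(dossier, context, conservative = conservative_ttc),
        vaportox_missing_data = function(e) {
          audit_add(audit, sprintf("TTC route blocked: %s", conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(ttc)) {
        for (l in ttc$rationale) audit_add(audit, paste("TTC:", l))
        if (ttc$applicable) {
          limit <- ug_to_mg(ttc$limit_ug_per_day)
          limit_source <- "ttc"
          audit_add(audit, sprintf(
            "TTC limit %.4g ug/day = %.4g mg/day.", ttc$limit_ug_per_day, limit
          ))
        }
      }
      if (is.null(limit)) insufficient <- TRUE
    }
  }

  if (screen$verdict == "exclude") {
    verdict <- characterize_risk(exposure, 1, screen)
    audit_add(audit, "Verdict: excluded by categorical screen; no limit computed.")
    mac <- 0
  } else if (insufficient) {
    verdict <- structure(
      list(
        verdict = "insufficient_data",
        exposure_mg_per_day = exposure$additive_mg_per_day,
        governing_limit_mg_per_day = NULL,
        limit_source = NULL,
        margin = NULL,
        screen = screen,
        guidance = paste(
          "No POD-derived limit is computable and TTC is not applicable",
          "(or blocked on missing classification): a first-tier assessment",
          "cannot conclude. Generate data or escalate to a higher tier."
        )
      ),
      class = "risk_verdict"
    )
    audit_add(audit, "Verdict: insufficient data (no numeric limit available).")
    mac <- NULL
  } else {
    verdict <- characterize_risk(exposure, limit, screen, limit_source)
    mac <- max_allowable_concentration(limit, assumptions$daily_consumption_mg)
    audit_add(audit, sprintf(
      "Risk: exposure %.4g vs limit %.4g mg/day -> %s (margin %s).",
      verdict$exposure_mg_per_day, limit, verdict$verdict,
      if (is.null(verdict$margin) || is.na(verdict$margin)) "undefined" else signif(verdict$margin, 3)
    ))
    audit_add(audit, sprintf("Maximum allowable concentration: %.4g%% w/w.", mac))
    if (screen$verdict == "conditional_cap") {
      if (concentration_mg_per_g > screen$cap_concentration) {
        verdict$verdict <- "exceeds_limit"
        verdict$guidance <- paste(
          "Proposed concentration exceeds the cannabis-native sensitizer",
          "cap; reduce to at most the plant-relative level."
        )
        audit_add(audit, sprintf(
          "Native-sensitizer cap: %.4g mg/g exceeds cap %.4g mg/g -> exceeds_limit.",
          concentration_mg_per_g, screen$cap_concentration
        ))
      } else {
        if (concentration_mg_per_g == screen$cap_concentration) {
          warn("Proposed concentration sits exactly at the native-sensitizer cap.")
        }
        audit_add(audit, sprintf(
          "Native-sensitizer cap: %.4g mg/g is within cap %.4g mg/g.",
          concentration_mg_per_g, screen$cap_concentration
        ))
      }
    }
  }

  structure(
    list(
      dossier = dossier,
      context = context,
      assumptions = assumptions,
      concentration_mg_per_g = concentration_mg_per_g,
      exposure = exposure,
      ttc = ttc,
      verdict = verdict,
      max_allowable_concentration_pct = mac,
      audit = audit_lines(audit),
      versions = list(
        package = as.character(utils::packageVersion("vaportox")),
        ttc_limits = if (!is.null(ttc)) ttc$limits_version else ttc_limits()$version
      )
    ),
    class = "assessment_report"
  )
}

#' Write an assessment report as JSON
#'
#' The JSON report is self-contained: it echoes the dossier, the context,
#' the assumptions and the concentration assessed, so the verdict can be
#' recomputed from the file alone.
#'
#' @param report An `assessment_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "assessment_report"))
  x <- list(
    schema_version = "1.0",
    substance = report$dossier$name,
    dossier = jsonlite::fromJSON(dossier_json_string(report$dossier), simplifyDataFrame = FALSE),
    context = unclass(report$context),
    assumptions = unclass(report$assumptions),
    concentration_mg_per_g = report$concentration_mg_per_g,
    verdict = report$verdict$verdict,
    exposure_mg_per_day = report$verdict$exposure_mg_per_day,
    governing_limit_mg_per_day = report$verdict$governing_limit_mg_per_day,
    limit_source = report$verdict$limit_source,
    margin = report$verdict$margin,
    max_allowable_concentration_pct = report$max_allowable_concentration_pct,
    guidance = report$verdict$guidance,
    audit = report$audit,
    versions = report$versions
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

dossier_json_string <- function(dossier) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_dossier(dossier, tmp, format = "json")
  paste(readLines(tmp, warn = FALSE), collapse = "\n")
}

#' @export
print.risk_verdict <- function(x, ...) {
  cat("<risk_verdict>", x$verdict, "\n")
  cat("  exposure:", signif(x$exposure_mg_per_day, 3), "mg/day\n")
  if (!is.null(x$governing_limit_mg_per_day)) {
    cat(
      "  limit:", signif(x$governing_limit_mg_per_day, 3), "mg/day (",
      x$limit_source, ")\n"
    )
  }
  if (!is.null(x$margin) && !is.na(x$margin)) {
    cat("  margin:", signif(x$margin, 3), "\n")
  }
  cat(" ", x$guidance, "\n")
  invisible(x)
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("== First-tier assessment:", x$dossier$name, "==\n")
  cat(
    "concentration assessed:", signif(x$concentration_mg_per_g, 3), "mg/g at",
    signif(x$assumptions$daily_consumption_mg, 3), "mg/day consumption\n"
  )
  print(x$verdict)
  if (!is.null(x$max_allowable_concentration_pct)) {
    cat(
      "max allowable concentration:",
      signif(x$max_allowable_concentration_pct, 3), "% w/w\n"
    )
  }
  cat("-- audit trail --\n")
  for (l in x$audit) cat("  *", l, "\n")
  invisible(x)
}

#' Exit status for scripted batch screening
#'
#' Maps a verdict to the CLI exit convention: 0 low risk, 2 exceeds limit,
#' 3 excluded, 4 insufficient data.
#'
#' @param report An `assessment_report` or `risk_verdict`.
#' @return Integer status.
#' @export
verdict_status <- function(report) {
  v <- if (inherits(report, "assessment_report")) report$verdict$verdict else report$verdict
  switch(v,
    low_risk = 0L,
    exceeds_limit = 2L,
    excluded = 3L,
    insufficient_data = 4L,
    4L
  )
}
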