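# Threshold-of-toxicological-concern routing for data-poor substances.
# A five-question decision tree assigns a generic ug/day exposure limit by
# chemical category: an applicability gate (classes for which TTC cannot be
# used at all), organophosphates/carbamates, genotoxicants (duration-tiered),
# food-use or cannabis-native substances by Cramer class, and a fallback
# tier by OASIS acute-aquatic mode of action for everything else. Cramer
# class and OASIS MOA are classified with external decision-tree software
# (ToxTree, OECD QSAR Toolbox) and entered in the dossier.

#' TTC limit table
#'
#' Loads the versioned category-to-limit table (ug/day) shipped with the
#' package. Regulators can audit or override the values by pointing `path`
#' at their own copy of the JSON file.
#'
#' @param path Path to a limits JSON file; defaults to the packaged table.
#' @return A list with `version` and a named numeric vector `limits`.
#' @export
ttc_limits <- function(path = system.file("extdata", "ttc_limits.json",
                         package = "vaportox"
                       )) {
  x <- jsonlite::fromJSON(path)
  x$limits <- unlist(x$limits)
  x
}

genotoxic_tier_key <- function(duration) {
  paste0("genotoxic_", duration)
}

#' Route a substance through the TTC decision tree
#'
#' Questions are evaluated strictly in order:
#'
#' 1. *Applicability*: substances in an excluded category (inorganic,
#'    radioactive, nanoparticle, bioaccumulative, protein, polymer,
#'    aflatoxin-like, steroid, dioxin-like polyhalogenated, polycyclic
#'    amine, hydrazine-like, nitroso, alpha-nitro-furyl) cannot use TTC.
#' 2. *Organophosphate/carbamate*: 18 ug/day.
#' 3. *Genotoxicity alert*: duration-tiered limit (1.5 ug/day beyond 10
#'    years to lifetime; 10 for 1-10 years; 20 for 1-12 months; 120 under
#'    a month).
#' 4. *Cannabis-native or GRAS/food use*: by Cramer class (class 1:
#'    865 ug/day; class 2 or 3: 145 ug/day).
#' 5. *Everything else*: by OASIS mode of action (base/surface narcotic:
#'    22.39 ug/day; reactive: 4.286 ug/day).
#'
#' An organophosphate that also carries a genotoxicity alert still receives
#' the question-2 limit (printed order is authoritative) with a warning
#' suggesting expert review. A carcinogen listing without a genotoxicity
#' alert is warned about and does not trigger the genotoxic tier.
#' `conservative = TRUE` instead returns the minimum limit over every
#' branch whose predicate holds, reflecting the advice to run multiple
#' models and keep the more conservative value.
#'
#' @param dossier A `substance_dossier`.
#' @param context A `product_context` (supplies the exposure duration for
#'   the genotoxic tier).
#' @param conservative Return the minimum across all applicable branches
#'   instead of the first matching question.
#' @param limits A limits table from [ttc_limits()].
#' @return A `ttc_result`: `applicable`, `category`, `limit_ug_per_day`
#'   (absent when not applicable), and a `rationale` trail of the
#'   questions answered.
#' @export
#' @examples
#' d <- substance_dossier("geraniol",
#'   native_to_cannabis = TRUE,
#'   gras_or_food_use = TRUE, cramer_class = "1"
#' )
#' route_ttc(d, product_context())
route_ttc <- function(dossier, context, conservative = FALSE,
                      limits = ttc_limits()) {
  validate_dossier(dossier)
  stopifnot(inherits(context, "product_context"))
  lim <- limits$limits
  trail <- character()
  say <- function(...) trail <<- c(trail, paste0(...))

  ttc_result <- function(category, limit_ug) {
    structure(
      list(
        applicable = category != "not_applicable",
        category = category,
        limit_ug_per_day = limit_ug,
        rationale = trail,
        limits_version = limits$version
      ),
      class = "ttc_result"
    )
  }

  # Q1: applicability gate
  if (dossier$ttc_exclusion_category != "none") {
    say(
      "Q1: substance falls in excluded category '",
      dossier$ttc_exclusion_category, "'; TTC cannot be used."
    )
    return(ttc_result("not_applicable", NULL))
  }
  say("Q1: no exclusion category; TTC applicable in principle.")

  if (dossier$carcinogen_classification == "listed" && !dossier$genotoxicity_alert) {
    warn(paste(
      "Carcinogen listing without a genotoxicity alert: the genotoxic TTC",
      "tier is not triggered; expert review recommended."
    ))
    say("Note: carcinogen listed without genotoxicity alert; proceeding past Q3.")
  }

  branches <- list()

  # Q2: organophosphate / carbamate
  if (dossier$is_organophosphate_or_carbamate) {
    say("Q2: organophosphate or carbamate; limit 18 ug/day.")
    if (dossier$genotoxicity_alert) {
      warn(paste(
        "Organophosphate/carbamate with a genotoxicity alert: question",
        "order assigns the 18 ug/day tier; expert review recommended."
      ))
    }
    branches$organophosphate_carbamate <- unname(lim[["organophosphate_carbamate"]])
    if (!conservative) {
      return(ttc_result("organophosphate_carbamate", branches$organophosphate_carbamate))
    }
  } else {
    say("Q2: not an organophosphate or carbamate; move to Q3.")
  }

  # Q3: genotoxicity, duration-tiered
  if (dossier$genotoxicity_alert) {
    key <- genotoxic_tier_key(context$intended_exposure_duration)
    say(
      "Q3: genotoxicity alert; duration '", context$intended_exposure_duration,
      "' gives ", lim[[key]], " ug/day."
    )
    branches$genotoxic_tiered <- unname(lim[[key]])
    if (!conservative) {
      return(ttc_result("genotoxic_tiered", branches$genotoxic_tiered))
    }
  } else {
    say("Q3: no genotoxicity alert; move to Q4.")
  }

  # Q4: cannabis-native or GRAS/food use -> Cramer class
  if (dossier$native_to_cannabis || dossier$gras_or_food_use) {
    if (dossier$cramer_class == "unknown") {
      if (!conservative) {
        abort(
          paste(
            "Cramer class is required at TTC question 4: classify the",
            "substance with ToxTree or the OECD QSAR Toolbox and record",
            "cramer_class in the dossier."
          ),
          class = "vaportox_missing_data"
        )
      }
      say("Q4: cramer_class unknown; branch skipped in conservative mode.")
    } else {
      cat_key <- if (dossier$cramer_class == "1") {
        "cramer_class_1"
      } else {
        "cramer_class_2_or_3"
      }
      say(
        "Q4: cannabis-native or GRAS/food use; Cramer class ",
        dossier$cramer_class, " gives ", lim[[cat_key]], " ug/day."
      )
      branches[[cat_key]] <- unname(lim[[cat_key]])
      if (!conservative) return(ttc_result(cat_key, branches[[cat_key]]))
    }
  } else {
    say("Q4: not cannabis-native and not GRAS/food use; move to Q5.")
  }

  # Q5: fallback by OASIS mode of action
  if (dossier$oasis_moa == "unknown") {
    if (length(branches) == 0 || !conservative) {
      abort(
        paste(
          "OASIS mode of action is required at TTC question 5: profile the",
          "substance with the OECD QSAR Toolbox and record oasis_moa in",
          "the dossier."
        ),
        class = "vaportox_missing_data"
      )
    }
    say("Q5: oasis_moa unknown; branch skipped in conservative mode.")
  } else {
    moa_key <- paste0("oasis_", dossier$oasis_moa)
    moa_cat <- if (dossier$oasis_moa == "base_surface_narcotic") {
      "oasis_base_surface_narcotic"
    } else {
      "oasis_reactive"
    }
    say(
      "Q5: fallback tier; OASIS MOA '", dossier$oasis_moa, "' gives ",
      lim[[moa_key]], " ug/day."
    )
    branches[[moa_cat]] <- unname(lim[[moa_key]])
    if (!conservative) return(ttc_result(moa_cat, branches[[moa_cat]]))
  }

  # conservative mode: minimum over all applicable branches
  vals <- unlist(branches)
  winner <- names(vals)[which.min(vals)]
  say(
    "Conservative mode: minimum of {", toString(signif(vals, 4)),
    "} ug/day across applicable branches."
  )
  winner_cat <- if (winner == "genotoxic_tiered") "genotoxic_tiered" else winner
  ttc_result(winner_cat, unname(min(vals)))
}

#' @export
print.ttc_result <- function(x, ...) {
  cat("<ttc_result>", x$category, "\n")
  if (x$applicable) {
    cat("  limit:", x$limit_ug_per_day, "ug/day\n")
  } else {
    cat("  TTC not applicable\n")
  }
  invisible(x)
}
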