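# Categorical exclusion rules applied before any dose-response work. Some
# toxicant classes are screened out of inhalable products outright:
# respiratory sensitizers not native to cannabis, "Big 8" food-allergen
# sources, phenolic acetates (the vitamin E acetate / EVALI class), and
# supplements/vitamins/HPHCs. Genotoxicants and listed carcinogens are not
# auto-excluded by default: they are routed to the genotoxic TTC tier,
# with a strict mode available to make the listing an exclusion instead.

screen_rules <- c(
  RULE_NON_NATIVE_SENSITIZER = paste(
    "Respiratory sensitizer not naturally occurring in cannabis:",
    "entirely avoided in inhalable products"
  ),
  RULE_NATIVE_SENSITIZER_CAP = paste(
    "Respiratory sensitizer native to the cannabis plant: concentration",
    "capped at the plant level relative to THC"
  ),
  RULE_BIG8_ALLERGEN = "Source of (or contaminated with) a 'Big 8' food allergen",
  RULE_PHENOLIC_ACETATE = "Contains a phenolic acetate moiety (EVALI-implicated class)",
  RULE_SUPPLEMENT_VITAMIN_HPHC = paste(
    "Herbal/dietary supplement, vitamin, mineral, or listed harmful or",
    "potentially harmful constituent"
  ),
  RULE_GENOTOX_TTC_ROUTE = paste(
    "Genotoxicity alert or carcinogen listing: route to the genotoxic TTC",
    "tier (or exclude under strict mode)"
  )
)

#' Screen a substance against the categorical exclusion rules
#'
#' Evaluates every rule (no short-circuiting, so the result lists all
#' triggered rules) and returns one of three verdicts: `"pass"`,
#' `"exclude"`, or `"conditional_cap"` for sensitizers native to the
#' cannabis plant, whose concentration must stay at or below the plant's
#' own level relative to THC (see [native_sensitizer_cap()]).
#'
#' A genotoxicity alert or a carcinogen listing does not exclude by
#' default; it attaches a routing reason directing the assessment to the
#' genotoxic TTC tier. Set `strict_genotox = TRUE` to treat either as an
#' outright exclusion.
#'
#' @param dossier A `substance_dossier`.
#' @param context A `product_context` (supplies the THC concentration for
#'   the native-sensitizer cap).
#' @param strict_genotox Treat genotoxicity/carcinogenicity as exclusion
#'   rather than TTC routing.
#' @return A `screen_result`: list with `verdict`, `reasons` (tibble of
#'   `rule_id`, `message`), and `cap_concentration` (mg additive per g
#'   concentrate, present only for `conditional_cap`).
#' @export
#' @examples
#' d <- substance_dossier("caryophyllene oxide",
#'   is_respiratory_sensitizer = TRUE,
#'   native_to_cannabis = TRUE, plant_ratio_to_thc = 0.001
#' )
#' screen_substance(d, product_context(product_thc_concentration = 850))
screen_substance <- function(dossier, context, strict_genotox = FALSE) {
  validate_dossier(dossier)
  stopifnot(inherits(context, "product_context"))
  fired <- character()
  exclude <- FALSE
  cap <- NULL

  if (dossier$is_respiratory_sensitizer && !dossier$native_to_cannabis) {
    fired <- c(fired, "RULE_NON_NATIVE_SENSITIZER")
    exclude <- TRUE
  }
  if (dossier$is_respiratory_sensitizer && dossier$native_to_cannabis) {
    fired <- c(fired, "RULE_NATIVE_SENSITIZER_CAP")
    cap <- native_sensitizer_cap(
      dossier$plant_ratio_to_thc,
      context$product_thc_concentration
    )
  }
  if (dossier$is_big8_allergen_source) {
    fired <- c(fired, "RULE_BIG8_ALLERGEN")
    exclude <- TRUE
  }
  if (dossier$is_phenolic_acetate) {
    fired <- c(fired, "RULE_PHENOLIC_ACETATE")
    exclude <- TRUE
  }
  if (dossier$is_supplement_vitamin_or_hphc) {
    fired <- c(fired, "RULE_SUPPLEMENT_VITAMIN_HPHC")
    exclude <- TRUE
  }
  if (dossier$genotoxicity_alert || dossier$carcinogen_classification == "listed") {
    fired <- c(fired, "RULE_GENOTOX_TTC_ROUTE")
    if (strict_genotox) exclude <- TRUE
  }

  verdict <- if (exclude) {
    "exclude"
  } else if (!is.null(cap)) {
    "conditional_cap"
  } else {
    "pass"
  }
  structure(
    list(
      verdict = verdict,
      reasons = tibble(
        rule_id = fired,
        message = unname(screen_rules[fired])
      ),
      cap_concentration = if (verdict == "conditional_cap") cap else NULL
    ),
    class = "screen_result"
  )
}

#' Concentration cap for a cannabis-native respiratory sensitizer
#'
#' Sensitizers that occur naturally in the cannabis plant are not excluded
#' outright, but their concentration in the finished concentrate must stay
#' at or below the level the plant itself delivers relative to THC. The cap
#' is the plant's additive-to-THC mass ratio scaled by the product's THC
#' concentration.
#'
#' @param plant_ratio_to_thc Mass of the additive per mass of THC in
#'   cannabis inflorescence (dimensionless, >= 0).
#' @param product_thc_concentration Product THC concentration in mg/g.
#' @return Cap in mg additive per g concentrate.
#' @export
#' @examples
#' native_sensitizer_cap(0.001, 850) # 0.85 mg/g
native_sensitizer_cap <- function(plant_ratio_to_thc, product_thc_concentration) {
  if (is.null(plant_ratio_to_thc) || all(is.na(plant_ratio_to_thc))) {
    abort(
      paste(
        "plant_ratio_to_thc is required to cap a cannabis-native sensitizer:",
        "supply the additive-to-THC mass ratio measured in cannabis inflorescence."
      ),
      class = "vaportox_missing_data"
    )
  }
  stopifnot(
    is_scalar_number(plant_ratio_to_thc), plant_ratio_to_thc >= 0,
    is_scalar_number(product_thc_concentration), product_thc_concentration >= 0
  )
  plant_ratio_to_thc * product_thc_concentration
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> verdict:", x$verdict, "\n")
  if (nrow(x$reasons)) {
    for (i in seq_len(nrow(x$reasons))) {
      cat("  -", x$reasons$rule_id[i], "\n")
    }
  }
  if (!is.null(x$cap_concentration)) {
    cat("  cap:", format(x$cap_concentration), "mg/g\n")
  }
  invisible(x)
}
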