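# Substance-dossier data model: one record per additive, carrying identity,
# hazard flags, TTC routing attributes and zero or more point-of-departure
# (POD) records. The dossier is the single input contract for screening,
# safety-limit derivation and TTC routing; all hazard flags are
# user-asserted (typically from Safety Data Sheets or regulatory lists),
# never predicted from structure.

pod_units_levels <- c("mg_per_kg_bw_per_day", "mg_per_m3", "mg_per_day")
pod_type_levels <- c("NOAEL", "NOAEC", "LOAEL", "LOAEC", "regulatory_limit")
regulatory_window_levels <- c("stel_15min", "twa_8h", "continuous_24h", "not_applicable")
route_levels <- c("oral", "inhalation", "dermal")
species_levels <- c("human", "animal")
sensitive_subpop_levels <- c("none", "moderate", "strong")
duration_class_levels <- c("subacute", "subchronic", "chronic", "clinical_or_lifetime")
endpoint_scope_levels <- c("systemic", "local_respiratory")
carcinogen_levels <- c("none", "listed")
ttc_exclusion_levels <- c(
  "none", "inorganic", "radioactive", "nanoparticle", "bioaccumulative",
  "protein", "polymer", "aflatoxin_like", "steroid",
  "polyhalogenated_dioxin_like", "polycyclic_amine", "hydrazine_like",
  "nitroso", "alpha_nitro_furyl"
)
cramer_levels <- c("1", "2", "3", "unknown")
oasis_levels <- c("base_surface_narcotic", "reactive", "unknown")
evidence_tier_levels <- c(
  "vaporization_cannabis", "vaporization_other", "inhalation_guideline",
  "inhalation_other", "other_route_guideline", "other_route_other"
)
exposure_duration_levels <- c(
  "lt_1_month", "1_to_12_months", "1_to_10_years", "gt_10_years_lifetime"
)

# Hazard flags whose absence is logged as "not asserted" rather than
# silently treated as a clean bill of health.
hazard_flag_fields <- c(
  "is_respiratory_sensitizer", "genotoxicity_alert",
  "is_organophosphate_or_carbamate", "is_phenolic_acetate",
  "is_supplement_vitamin_or_hphc", "is_big8_allergen_source"
)

#' Construct a point-of-departure record
#'
#' A POD record captures one dose or concentration anchoring extrapolation to
#' a safe exposure: a NOAEL/NOAEC, a LOAEL/LOAEC, or a regulatory limit
#' (e.g., an occupational TWA or STEL). LD50/LC50 values are deliberately
#' not representable: they are not appropriate points of departure for risk
#' assessment, so the type enumeration omits them.
#'
#' @param value Positive dose or concentration in `units`.
#' @param units One of `"mg_per_kg_bw_per_day"`, `"mg_per_m3"`,
#'   `"mg_per_day"`.
#' @param pod_type One of `"NOAEL"`, `"NOAEC"`, `"LOAEL"`, `"LOAEC"`,
#'   `"regulatory_limit"`.
#' @param regulatory_window Averaging window for a regulatory limit:
#'   `"stel_15min"`, `"twa_8h"`, `"continuous_24h"`, or `"not_applicable"`
#'   (required default for study-derived PODs).
#' @param route Exposure route in the source study: `"oral"`,
#'   `"inhalation"`, or `"dermal"` (dermal PODs are rejected downstream; no
#'   dermal-to-inhalation extrapolation factors are defined).
#' @param species `"human"` or `"animal"`.
#' @param tested_sensitive_subpopulation Whether the study population was a
#'   sensitive subpopulation: `"none"` (default), `"moderate"`, `"strong"`.
#'   Governs reduction of the intraspecies uncertainty factor.
#' @param duration_class Study duration: `"subacute"` (14-90 days),
#'   `"subchronic"` (90 days-1 year), `"chronic"` (>= 1 year), or
#'   `"clinical_or_lifetime"`.
#' @param hours_per_day,days_per_week Dosing schedule of the source study;
#'   used to adjust the POD to continuous exposure.
#' @param test_article_purity Purity of the tested material as a fraction in
#'   (0, 1]; the POD is scaled by it. Defaults to 1 (no adjustment).
#' @param endpoint_scope `"systemic"` or `"local_respiratory"`; local
#'   respiratory endpoints are tracked separately and never derived by
#'   oral-route extrapolation.
#' @param uf_categories_already_addressed Integer subset of 1:6 naming
#'   uncertainty-factor categories the source limit already accounts for
#'   (relevant for regulatory limits); these are forced to 1 in the ledger.
#' @return A one-row tibble with the POD fields.
#' @export
#' @examples
#' pod_record(100, "mg_per_m3", "NOAEC",
#'   route = "inhalation", species = "animal",
#'   duration_class = "subchronic", hours_per_day = 6, days_per_week = 5
#' )
pod_record <- function(value,
                       units,
                       pod_type,
                       regulatory_window = "not_applicable",
                       route,
                       species,
                       tested_sensitive_subpopulation = "none",
                       duration_class,
                       hours_per_day = 24,
                       days_per_week = 7,
                       test_article_purity = 1,
                       endpoint_scope = "systemic",
                       uf_categories_already_addressed = integer()) {
  pod <- tibble(
    value = as.numeric(value),
    units = as.character(units),
    pod_type = as.character(pod_type),
    regulatory_window = as.character(regulatory_window),
    route = as.character(route),
    species = as.character(species),
    tested_sensitive_subpopulation = as.character(tested_sensitive_subpopulation),
    duration_class = as.character(duration_class),
    hours_per_day = as.numeric(hours_per_day),
    days_per_week = as.numeric(days_per_week),
    test_article_purity = as.numeric(test_article_purity),
    endpoint_scope = as.character(endpoint_scope),
    uf_categories_already_addressed = list(as.integer(uf_categories_already_addressed))
  )
  violations <- validate_pod_tbl(pod)
  if (length(violations)) {
    abort_validation(violations)
  }
  pod
}

empty_pod_tbl <- function() {
  tibble(
    value = numeric(), units = character(), pod_type = character(),
    regulatory_window = character(), route = character(),
    species = character(), tested_sensitive_subpopulation = character(),
    duration_class = character(), hours_per_day = numeric(),
    days_per_week = numeric(), test_article_purity = numeric(),
    endpoint_scope = character(),
    uf_categories_already_addressed = list()
  )
}

validate_pod_tbl <- function(pods) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(all(cond))) v <<- c(v, msg)
  for (i in seq_len(nrow(pods))) {
    p <- pods[i, ]
    tag <- function(msg) sprintf("pods[%d]: %s", i, msg)
    if (!is_scalar_number(p$value) || p$value <= 0) {
      v <- c(v, tag("value must be a positive number"))
    }
    if (!p$units %in% pod_units_levels) {
      v <- c(v, tag(sprintf("units must be one of %s", toString(pod_units_levels))))
    }
    if (!p$pod_type %in% pod_type_levels) {
      v <- c(v, tag(sprintf("pod_type must be one of %s", toString(pod_type_levels))))
    }
    if (!p$regulatory_window %in% regulatory_window_levels) {
      v <- c(v, tag("regulatory_window not recognised"))
    }
    if (p$pod_type != "regulatory_limit" && p$regulatory_window != "not_applicable") {
      v <- c(v, tag("regulatory_window must be not_applicable unless pod_type is regulatory_limit"))
    }
    if (p$pod_type == "regulatory_limit" && !p$units %in% c("mg_per_m3", "mg_per_day")) {
      v <- c(v, tag("regulatory_limit PODs must be in mg_per_m3 or mg_per_day"))
    }
    if (!p$route %in% route_levels) v <- c(v, tag("route not recognised"))
    if (!p$species %in% species_levels) v <- c(v, tag("species not recognised"))
    if (!p$tested_sensitive_subpopulation %in% sensitive_subpop_levels) {
      v <- c(v, tag("tested_sensitive_subpopulation not recognised"))
    }
    if (!p$duration_class %in% duration_class_levels) {
      v <- c(v, tag("duration_class not recognised"))
    }
    if (!is_scalar_number(p$hours_per_day) || p$hours_per_day <= 0 || p$hours_per_day > 24) {
      v <- c(v, tag("hours_per_day must be in (0, 24]"))
    }
    if (!is_scalar_number(p$days_per_week) || p$days_per_week <= 0 || p$days_per_week > 7) {
      v <- c(v, tag("days_per_week must be in (0, 7]"))
    }
    if (!is_scalar_number(p$test_article_purity) ||
      p$test_article_purity <= 0 || p$test_article_purity > 1) {
      v <- c(v, tag("test_article_purity must be in (0, 1]"))
    }
    if (!p$endpoint_scope %in% endpoint_scope_levels) {
      v <- c(v, tag("endpoint_scope not recognised"))
    }
    ufs <- p$uf_categories_already_addressed[[1]]
    if (length(ufs) && !all(ufs %in% 1:6)) {
      v <- c(v, tag("uf_categories_already_addressed must be a subset of 1:6"))
    }
  }
  v
}

#' Construct a substance dossier
#'
#' The dossier is one additive's complete first-tier evidence record:
#' identity, user-asserted hazard flags (from Safety Data Sheets, ECHA/AOEC
#' lookups, or regulatory lists), TTC routing attributes (Cramer class and
#' OASIS mode-of-action are classified externally and entered here), and
#' zero or more POD records. An empty `pods` table routes the assessment to
#' the TTC tier.
#'
#' Hazard flags left unspecified default to `FALSE` but are recorded as
#' "not asserted" in the dossier's provenance attribute, so a clean screen
#' over defaulted flags is distinguishable from one over asserted data.
#'
#' @param name Substance name.
#' @param cas_number CAS registry number (optional).
#' @param purity_fraction Purity of the additive as used, in (0, 1].
#' @param is_respiratory_sensitizer Respiratory sensitizer per SDS/ECHA/AOEC.
#' @param native_to_cannabis Does the substance occur naturally in the
#'   cannabis plant?
#' @param plant_ratio_to_thc Mass of the substance per mass of THC in
#'   cannabis inflorescence (dimensionless); required to cap a native
#'   sensitizer, and only meaningful when `native_to_cannabis` is `TRUE`.
#' @param genotoxicity_alert Structural alert or positive genotoxicity assay.
#' @param carcinogen_classification `"none"` or `"listed"` (IARC, Prop 65,
#'   CMR, ...); see `carcinogen_source_note`.
#' @param carcinogen_source_note Free-text provenance for a listing.
#' @param is_organophosphate_or_carbamate Organophosphate or carbamate class.
#' @param is_phenolic_acetate Contains a phenolic acetate moiety (the vitamin
#'   E acetate / EVALI structural class).
#' @param is_supplement_vitamin_or_hphc Herbal/dietary supplement, vitamin,
#'   mineral, or listed harmful/potentially harmful constituent.
#' @param is_big8_allergen_source Derived from or contaminated with a "Big 8"
#'   food allergen source.
#' @param gras_or_food_use GRAS or established food use (exculpatory flag;
#'   defaults to `FALSE`).
#' @param ttc_exclusion_category TTC applicability gate; `"none"` unless the
#'   substance falls in a category for which TTC cannot be used (inorganic,
#'   radioactive, nanoparticle, bioaccumulative, protein, polymer, ...).
#' @param cramer_class `"1"`, `"2"`, `"3"`, or `"unknown"`; classify with an
#'   external decision-tree tool (e.g., ToxTree).
#' @param oasis_moa OASIS acute-aquatic mode of action:
#'   `"base_surface_narcotic"`, `"reactive"`, or `"unknown"`.
#' @param developmental_data_available Developmental/reproductive toxicity
#'   data exist for the substance.
#' @param developmental_structural_alert Structural features suggestive of
#'   developmental toxicity (conservative default `TRUE`; when `FALSE` the
#'   database uncertainty factor drops from 10 to 3).
#' @param pods A tibble of POD records built with [pod_record()] (rows may
#'   be bound together); may be empty.
#' @param evidence_tier Relevance weighting of the dominant evidence source
#'   (metadata only, not used in computation).
#' @return A `substance_dossier` object (validated).
#' @seealso [read_dossier()], [write_dossier()], [screen_substance()],
#'   [route_ttc()], [derive_safety_limit()]
#' @export
#' @examples
#' substance_dossier("limonene",
#'   native_to_cannabis = TRUE, gras_or_food_use = TRUE, cramer_class = "1"
#' )
substance_dossier <- function(name,
                              cas_number = NA_character_,
                              purity_fraction = 1,
                              is_respiratory_sensitizer = FALSE,
                              native_to_cannabis = FALSE,
                              plant_ratio_to_thc = NULL,
                              genotoxicity_alert = FALSE,
                              carcinogen_classification = "none",
                              carcinogen_source_note = NA_character_,
                              is_organophosphate_or_carbamate = FALSE,
                              is_phenolic_acetate = FALSE,
                              is_supplement_vitamin_or_hphc = FALSE,
                              is_big8_allergen_source = FALSE,
                              gras_or_food_use = FALSE,
                              ttc_exclusion_category = "none",
                              cramer_class = "unknown",
                              oasis_moa = "unknown",
                              developmental_data_available = FALSE,
                              developmental_structural_alert = TRUE,
                              pods = empty_pod_tbl(),
                              evidence_tier = NA_character_) {
  not_asserted <- setdiff(hazard_flag_fields, names(match.call())[-1])
  d <- structure(
    list(
      name = as.character(name),
      cas_number = as.character(cas_number),
      purity_fraction = as.numeric(purity_fraction),
      is_respiratory_sensitizer = is_respiratory_sensitizer,
      native_to_cannabis = native_to_cannabis,
      plant_ratio_to_thc = if (is.null(plant_ratio_to_thc) ||
        all(is.na(plant_ratio_to_thc))) {
        NULL
      } else {
        as.numeric(plant_ratio_to_thc)
      },
      genotoxicity_alert = genotoxicity_alert,
      carcinogen_classification = as.character(carcinogen_classification),
      carcinogen_source_note = as.character(carcinogen_source_note),
      is_organophosphate_or_carbamate = is_organophosphate_or_carbamate,
      is_phenolic_acetate = is_phenolic_acetate,
      is_supplement_vitamin_or_hphc = is_supplement_vitamin_or_hphc,
      is_big8_allergen_source = is_big8_allergen_source,
      gras_or_food_use = gras_or_food_use,
      ttc_exclusion_category = as.character(ttc_exclusion_category),
      cramer_class = as.character(cramer_class),
      oasis_moa = as.character(oasis_moa),
      developmental_data_available = developmental_data_available,
      developmental_structural_alert = developmental_structural_alert,
      pods = as_tibble(pods),
      evidence_tier = as.character(evidence_tier)
    ),
    class = "substance_dossier",
    not_asserted = not_asserted
  )
  validate_dossier(d)
}

#' Validate a substance dossier
#'
#' Checks every field-level invariant and aborts with the full list of
#' violations (class `vaportox_validation_error`), not just the first.
#'
#' @param dossier A `substance_dossier`.
#' @return The dossier, invisibly usable in a pipe (returned visibly for
#'   constructor chaining).
#' @export
validate_dossier <- function(dossier) {
  v <- character()
  d <- dossier
  if (!is.character(d$name) || length(d$name) != 1L || is.na(d$name) || !nzchar(d$name)) {
    v <- c(v, "name must be a non-empty string")
  }
  if (!is_scalar_number(d$purity_fraction) ||
    d$purity_fraction <= 0 || d$purity_fraction > 1) {
    v <- c(v, "purity_fraction must be in (0, 1]")
  }
  for (fl in c(
    hazard_flag_fields, "native_to_cannabis", "gras_or_food_use",
    "developmental_data_available", "developmental_structural_alert"
  )) {
    if (!is_flag(d[[fl]])) v <- c(v, sprintf("%s must be TRUE or FALSE", fl))
  }
  if (!is.null(d$plant_ratio_to_thc)) {
    if (!is_scalar_number(d$plant_ratio_to_thc) || d$plant_ratio_to_thc < 0) {
      v <- c(v, "plant_ratio_to_thc must be a non-negative number")
    }
    if (is_flag(d$native_to_cannabis) && !d$native_to_cannabis) {
      v <- c(v, "plant_ratio_to_thc must be absent when native_to_cannabis is FALSE")
    }
  }
  if (!d$carcinogen_classification %in% carcinogen_levels) {
    v <- c(v, sprintf("carcinogen_classification must be one of %s", toString(carcinogen_levels)))
  }
  if (!d$ttc_exclusion_category %in% ttc_exclusion_levels) {
    v <- c(v, "ttc_exclusion_category not recognised")
  }
  if (!d$cramer_class %in% cramer_levels) {
    v <- c(v, sprintf("cramer_class must be one of %s", toString(cramer_levels)))
  }
  if (!d$oasis_moa %in% oasis_levels) {
    v <- c(v, sprintf("oasis_moa must be one of %s", toString(oasis_levels)))
  }
  if (!is.na(d$evidence_tier) && !d$evidence_tier %in% evidence_tier_levels) {
    v <- c(v, "evidence_tier not recognised")
  }
  if (!is_tibble(d$pods)) {
    v <- c(v, "pods must be a tibble of POD records")
  } else {
    v <- c(v, validate_pod_tbl(d$pods))
  }
  if (length(v)) abort_validation(v)
  dossier
}

#' Construct a product context
#'
#' Describes the finished vaporization product an additive would go into:
#' its THC concentration (which anchors the native-sensitizer concentration
#' cap), whether sale is age-gated (a developmental-toxicity risk
#' mitigation that waives the database uncertainty factor), and the
#' intended consumer exposure duration (which selects the genotoxic TTC
#' tier).
#'
#' @param product_thc_concentration THC concentration of the finished
#'   concentrate in mg/g, in \[0, 1000\].
#' @param age_gated Is the product restricted to adults (state-legal THC
#'   markets)?
#' @param intended_exposure_duration One of `"lt_1_month"`,
#'   `"1_to_12_months"`, `"1_to_10_years"`, `"gt_10_years_lifetime"`.
#' @return A `product_context` object.
#' @export
product_context <- function(product_thc_concentration = 850,
                            age_gated = TRUE,
                            intended_exposure_duration = "gt_10_years_lifetime") {
  if (!is_scalar_number(product_thc_concentration) ||
    product_thc_concentration < 0 || product_thc_concentration > 1000) {
    abort_validation("product_thc_concentration must be in [0, 1000] mg/g")
  }
  if (!is_flag(age_gated)) abort_validation("age_gated must be TRUE or FALSE")
  if (!intended_exposure_duration %in% exposure_duration_levels) {
    abort_validation(sprintf(
      "intended_exposure_duration must be one of %s",
      toString(exposure_duration_levels)
    ))
  }
  structure(
    list(
      product_thc_concentration = product_thc_concentration,
      age_gated = age_gated,
      intended_exposure_duration = intended_exposure_duration
    ),
    class = "product_context"
  )
}

#' @export
print.substance_dossier <- function(x, ...) {
  cat("<substance_dossier>", x$name,
    if (!is.na(x$cas_number)) paste0("(CAS ", x$cas_number, ")") else "", "\n"
  )
  flags <- hazard_flag_fields[vapply(x[hazard_flag_fields], isTRUE, logical(1))]
  cat("  hazard flags:", if (length(flags)) toString(flags) else "none", "\n")
  cat(
    "  TTC attributes: exclusion=", x$ttc_exclusion_category,
    ", cramer=", x$cramer_class, ", oasis=", x$oasis_moa, "\n",
    sep = ""
  )
  cat("  PODs:", nrow(x$pods), "\n")
  na <- attr(x, "not_asserted")
  if (length(na)) cat("  not asserted (defaulted):", toString(na), "\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

dossier_scalar_fields <- c(
  "name", "cas_number", "purity_fraction", "is_respiratory_sensitizer",
  "native_to_cannabis", "genotoxicity_alert", "carcinogen_classification",
  "carcinogen_source_note", "is_organophosphate_or_carbamate",
  "is_phenolic_acetate", "is_supplement_vitamin_or_hphc",
  "is_big8_allergen_source", "gras_or_food_use", "ttc_exclusion_category",
  "cramer_class", "oasis_moa", "developmental_data_available",
  "developmental_structural_alert", "evidence_tier"
)

#' Read a substance dossier from JSON or CSV
#'
#' JSON is the canonical nested form (one object; PODs as an array). The CSV
#' dialect is flat for spreadsheet entry: one row per POD with dossier-level
#' fields repeated, and a single all-`NA` POD block for a dossier with no
#' PODs. Missing optional fields take the documented conservative defaults
#' (`cramer_class = "unknown"`, `oasis_moa = "unknown"`,
#' `developmental_data_available = FALSE`, `test_article_purity = 1`);
#' hazard flags absent from the file are recorded as "not asserted".
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @return A validated `substance_dossier`.
#' @export
read_dossier <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) {
    abort(sprintf("No dossier file at '%s'", path), class = "vaportox_io_error")
  }
  raw <- switch(format,
    json = read_dossier_json(path),
    csv = read_dossier_csv(path)
  )
  raw
}

read_dossier_json <- function(path) {
  x <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) {
      abort(
        sprintf("Failed to parse dossier JSON '%s': %s", path, conditionMessage(e)),
        class = "vaportox_format_error"
      )
    }
  )
  d <- dossier_from_list(x)
  if (!is.null(x$not_asserted)) {
    attr(d, "not_asserted") <- as.character(unlist(x$not_asserted))
  }
  d
}

# Builds a dossier from a plain named list (parsed JSON or a CSV row group),
# applying conservative defaults for absent optionals.
dossier_from_list <- function(x) {
  if (is.null(x$name)) {
    abort("Dossier is missing required field 'name'", class = "vaportox_format_error")
  }
  pods <- x$pods %||% list()
  pod_tbl <- if (length(pods) == 0) {
    empty_pod_tbl()
  } else {
    bind_rows(lapply(pods, function(p) {
      do.call(pod_record, pod_args_with_defaults(p))
    }))
  }
  args <- list(
    name = x$name,
    cas_number = x$cas_number %||% NA_character_,
    purity_fraction = x$purity_fraction %||% 1,
    native_to_cannabis = x$native_to_cannabis %||% FALSE,
    plant_ratio_to_thc = x$plant_ratio_to_thc,
    carcinogen_classification = x$carcinogen_classification %||% "none",
    carcinogen_source_note = x$carcinogen_source_note %||% NA_character_,
    gras_or_food_use = x$gras_or_food_use %||% FALSE,
    ttc_exclusion_category = x$ttc_exclusion_category %||% "none",
    cramer_class = x$cramer_class %||% "unknown",
    oasis_moa = x$oasis_moa %||% "unknown",
    developmental_data_available = x$developmental_data_available %||% FALSE,
    developmental_structural_alert = x$developmental_structural_alert %||% TRUE,
    pods = pod_tbl,
    evidence_tier = x$evidence_tier %||% NA_character_
  )
  asserted_flags <- intersect(hazard_flag_fields, names(x))
  for (fl in asserted_flags) args[[fl]] <- x[[fl]]
  d <- do.call(substance_dossier, args)
  attr(d, "not_asserted") <- setdiff(hazard_flag_fields, asserted_flags)
  d
}

pod_args_with_defaults <- function(p) {
  for (req in c("value", "units", "pod_type", "route", "species", "duration_class")) {
    if (is.null(p[[req]])) {
      abort(
        sprintf("POD record is missing required field '%s'", req),
        class = "vaportox_format_error"
      )
    }
  }
  list(
    value = p$value,
    units = p$units,
    pod_type = p$pod_type,
    regulatory_window = p$regulatory_window %||% "not_applicable",
    route = p$route,
    species = p$species,
    tested_sensitive_subpopulation = p$tested_sensitive_subpopulation %||% "none",
    duration_class = p$duration_class,
    hours_per_day = p$hours_per_day %||% 24,
    days_per_week = p$days_per_week %||% 7,
    test_article_purity = p$test_article_purity %||% 1,
    endpoint_scope = p$endpoint_scope %||% "systemic",
    uf_categories_already_addressed = unlist(p$uf_categories_already_addressed) %||% integer()
  )
}

#' Write a substance dossier to JSON or CSV
#'
#' Inverse of [read_dossier()]: `read_dossier(write_dossier(d, path))`
#' reproduces `d` exactly for both formats.
#'
#' @param dossier A validated `substance_dossier`.
#' @param path Output path; the extension selects the format unless
#'   `format` is given.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dossier <- function(dossier, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  validate_dossier(dossier)
  switch(format,
    json = write_dossier_json(dossier, path),
    csv = write_dossier_csv(dossier, path)
  )
  invisible(path)
}

write_dossier_json <- function(dossier, path) {
  x <- unclass(dossier)
  x$pods <- lapply(seq_len(nrow(dossier$pods)), function(i) {
    p <- as.list(dossier$pods[i, ])
    p$uf_categories_already_addressed <- p$uf_categories_already_addressed[[1]]
    p
  })
  x$not_asserted <- attr(dossier, "not_asserted")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

pod_csv_cols <- c(
  "value", "units", "pod_type", "regulatory_window", "route", "species",
  "tested_sensitive_subpopulation", "duration_class", "hours_per_day",
  "days_per_week", "test_article_purity", "endpoint_scope"
)

write_dossier_csv <- function(dossier, path) {
  scal <- unclass(dossier)[dossier_scalar_fields]
  scal$plant_ratio_to_thc <- dossier$plant_ratio_to_thc %||% NA_real_
  scal$not_asserted <- paste(attr(dossier, "not_asserted"), collapse = ";")
  base <- as_tibble(scal)
  if (nrow(dossier$pods) == 0) {
    out <- base
    for (col in pod_csv_cols) out[[paste0("pod_", col)]] <- NA
    out$pod_uf_categories_already_addressed <- NA_character_
  } else {
    pods <- dossier$pods
    pods$uf_categories_already_addressed <- vapply(
      pods$uf_categories_already_addressed,
      function(u) paste(u, collapse = ";"), character(1)
    )
    names(pods) <- paste0("pod_", names(pods))
    out <- dplyr::cross_join(base, pods)
  }
  readr::write_csv(out, path, na = "")
}

read_dossier_csv <- function(path) {
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(
        sprintf("Failed to parse dossier CSV '%s': %s", path, conditionMessage(e)),
        class = "vaportox_format_error"
      )
    }
  )
  if (!"name" %in% names(out)) {
    abort("Dossier CSV is missing required column 'name'", class = "vaportox_format_error")
  }
  x <- as.list(out[1, intersect(dossier_scalar_fields, names(out))])
  x <- x[!vapply(x, function(e) all(is.na(e)), logical(1))]
  if ("plant_ratio_to_thc" %in% names(out) && !is.na(out$plant_ratio_to_thc[1])) {
    x$plant_ratio_to_thc <- out$plant_ratio_to_thc[1]
  }
  pod_cols <- paste0("pod_", pod_csv_cols)
  has_pods <- all(pod_cols %in% names(out)) && !all(is.na(out$pod_value))
  x$pods <- if (!has_pods) {
    list()
  } else {
    lapply(seq_len(nrow(out)), function(i) {
      p <- as.list(out[i, pod_cols])
      names(p) <- pod_csv_cols
      p <- p[!vapply(p, function(e) all(is.na(e)), logical(1))]
      ufs <- out$pod_uf_categories_already_addressed[i]
      if (!is.na(ufs) && nzchar(ufs)) {
        p$uf_categories_already_addressed <-
          as.integer(strsplit(as.character(ufs), ";")[[1]])
      }
      p
    })
  }
  d <- dossier_from_list(x)
  if ("not_asserted" %in% names(out)) {
    na_str <- out$not_asserted[1]
    attr(d, "not_asserted") <- if (is.na(na_str) || !nzchar(na_str)) {
      character()
    } else {
      strsplit(as.character(na_str), ";")[[1]]
    }
  }
  d
}
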