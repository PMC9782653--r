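# Shared fixtures and independent oracles, all built in code.

# A clean GRAS terpene dossier with no PODs (TTC path).
fixture_gras_dossier <- function(...) {
  substance_dossier(
    "geraniol",
    native_to_cannabis = TRUE,
    gras_or_food_use = TRUE,
    cramer_class = "1",
    ...
  )
}

fixture_oral_noael_pod <- function(value = 18, ...) {
  pod_record(
    value, "mg_per_kg_bw_per_day", "NOAEL",
    route = "oral", species = "animal", duration_class = "subchronic", ...
  )
}

fixture_pod_dossier <- function(pods = fixture_oral_noael_pod(), ...) {
  substance_dossier("test substance", pods = pods, ...)
}

# Independent sort-based quantile oracle (linear interpolation between
# order statistics), written from the definition rather than via quantile().
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Random valid dossier generator for property tests.
random_dossier <- function() {
  n_pods <- sample(0:3, 1)
  pods <- if (n_pods == 0) {
    NULL
  } else {
    do.call(rbind, lapply(seq_len(n_pods), function(i) {
      pod_record(
        value = runif(1, 0.1, 500),
        units = sample(c("mg_per_kg_bw_per_day", "mg_per_m3", "mg_per_day"), 1),
        pod_type = sample(c("NOAEL", "NOAEC", "LOAEL", "LOAEC"), 1),
        route = sample(c("oral", "inhalation"), 1),
        species = sample(c("human", "animal"), 1),
        tested_sensitive_subpopulation = sample(c("none", "moderate", "strong"), 1),
        duration_class = sample(
          c("subacute", "subchronic", "chronic", "clinical_or_lifetime"), 1
        ),
        hours_per_day = runif(1, 1, 24),
        days_per_week = runif(1, 1, 7),
        test_article_purity = runif(1, 0.5, 1),
        endpoint_scope = sample(c("systemic", "local_respiratory"), 1),
        uf_categories_already_addressed = sample(1:6, sample(0:2, 1))
      )
    }))
  }
  native <- sample(c(TRUE, FALSE), 1)
  args <- list(
    name = paste0("substance-", sample.int(1e6, 1)),
    cas_number = if (runif(1) < 0.5) "123-45-6" else NA_character_,
    purity_fraction = runif(1, 0.5, 1),
    is_respiratory_sensitizer = sample(c(TRUE, FALSE), 1),
    native_to_cannabis = native,
    genotoxicity_alert = sample(c(TRUE, FALSE), 1),
    carcinogen_classification = sample(c("none", "listed"), 1),
    is_organophosphate_or_carbamate = sample(c(TRUE, FALSE), 1),
    is_phenolic_acetate = sample(c(TRUE, FALSE), 1),
    is_supplement_vitamin_or_hphc = sample(c(TRUE, FALSE), 1),
    is_big8_allergen_source = sample(c(TRUE, FALSE), 1),
    gras_or_food_use = sample(c(TRUE, FALSE), 1),
    ttc_exclusion_category = sample(c("none", "inorganic", "protein"), 1),
    cramer_class = sample(c("1", "2", "3", "unknown"), 1),
    oasis_moa = sample(c("base_surface_narcotic", "reactive", "unknown"), 1),
    developmental_data_available = sample(c(TRUE, FALSE), 1),
    developmental_structural_alert = sample(c(TRUE, FALSE), 1),
    evidence_tier = sample(c("vaporization_cannabis", "inhalation_guideline"), 1)
  )
  if (native && runif(1) < 0.8) args$plant_ratio_to_thc <- runif(1, 0, 0.05)
  if (!is.null(pods)) args$pods <- pods
  do.call(substance_dossier, args)
}

expect_dossier_equal <- function(a, b) {
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
  expect_setequal(attr(a, "not_asserted"), attr(b, "not_asserted"))
}
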