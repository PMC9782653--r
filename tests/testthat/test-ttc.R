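ctx_life <- product_context(intended_exposure_duration = "gt_10_years_lifetime")

test_that("the applicability gate returns not-applicable for every excluded category", {
  for (cat in c(
    "inorganic", "radioactive", "nanoparticle", "bioaccumulative", "protein",
    "polymer", "aflatoxin_like", "steroid", "polyhalogenated_dioxin_like",
    "polycyclic_amine", "hydrazine_like", "nitroso", "alpha_nitro_furyl"
  )) {
    r <- route_ttc(
      substance_dossier("x", ttc_exclusion_category = cat), ctx_life
    )
    expect_false(r$applicable)
    expect_equal(r$category, "not_applicable")
    expect_null(r$limit_ug_per_day)
  }
})

test_that("each decision-tree branch returns its fixed limit", {
  expect_equal(
    route_ttc(
      substance_dossier("op", is_organophosphate_or_carbamate = TRUE), ctx_life
    )$limit_ug_per_day, 18
  )
  tiers <- c(
    gt_10_years_lifetime = 1.5, `1_to_10_years` = 10,
    `1_to_12_months` = 20, lt_1_month = 120
  )
  for (dur in names(tiers)) {
    r <- route_ttc(
      substance_dossier("gx", genotoxicity_alert = TRUE),
      product_context(intended_exposure_duration = dur)
    )
    expect_equal(r$category, "genotoxic_tiered")
    expect_equal(r$limit_ug_per_day, unname(tiers[dur]))
  }
  expect_equal(
    route_ttc(
      substance_dossier("c1", gras_or_food_use = TRUE, cramer_class = "1"),
      ctx_life
    )$limit_ug_per_day, 865
  )
  for (cc in c("2", "3")) {
    expect_equal(
      route_ttc(
        substance_dossier("c23", native_to_cannabis = TRUE, cramer_class = cc),
        ctx_life
      )$limit_ug_per_day, 145
    )
  }
  expect_equal(
    route_ttc(
      substance_dossier("nar", oasis_moa = "base_surface_narcotic"), ctx_life
    )$limit_ug_per_day, 22.39
  )
  expect_equal(
    route_ttc(
      substance_dossier("rx", oasis_moa = "reactive"), ctx_life
    )$limit_ug_per_day, 4.286
  )
})

test_that("question order is total and earlier questions shadow later ones", {
  # adding GRAS status to an organophosphate does not change its limit
  r <- route_ttc(
    substance_dossier("opg",
      is_organophosphate_or_carbamate = TRUE,
      gras_or_food_use = TRUE, cramer_class = "1"
    ),
    ctx_life
  )
  expect_equal(r$category, "organophosphate_carbamate")
  expect_equal(r$limit_ug_per_day, 18)

  # an organophosphate with a genotoxicity alert keeps the Q2 limit, warned
  expect_warning(
    r2 <- route_ttc(
      substance_dossier("opx",
        is_organophosphate_or_carbamate = TRUE, genotoxicity_alert = TRUE
      ),
      ctx_life
    ),
    "expert review"
  )
  expect_equal(r2$limit_ug_per_day, 18)

  # a genotoxicant that is also GRAS gets the genotoxic tier, not Cramer
  r3 <- route_ttc(
    substance_dossier("gg",
      genotoxicity_alert = TRUE, gras_or_food_use = TRUE, cramer_class = "1"
    ),
    ctx_life
  )
  expect_equal(r3$category, "genotoxic_tiered")
})

test_that("genotoxic tier limits decrease strictly with exposure duration", {
  durations <- c("lt_1_month", "1_to_12_months", "1_to_10_years", "gt_10_years_lifetime")
  lims <- vapply(durations, function(dur) {
    route_ttc(
      substance_dossier("gx", genotoxicity_alert = TRUE),
      product_context(intended_exposure_duration = dur)
    )$limit_ug_per_day
  }, numeric(1))
  expect_true(all(diff(lims) < 0))
})

test_that("every returned limit belongs to the fixed table value set", {
  value_set <- c(18, 1.5, 10, 20, 120, 865, 145, 22.39, 4.286)
  withr::local_seed(303)
  for (i in 1:40) {
    d <- random_dossier()
    r <- tryCatch(
      suppressWarnings(route_ttc(d, ctx_life)),
      vaportox_missing_data = function(e) NULL
    )
    if (!is.null(r) && r$applicable) {
      expect_true(r$limit_ug_per_day %in% value_set)
    }
  }
})

test_that("unknown classifications block the branch with an instructive error", {
  expect_error(
    route_ttc(
      substance_dossier("uc", gras_or_food_use = TRUE, cramer_class = "unknown"),
      ctx_life
    ),
    regexp = "ToxTree", class = "vaportox_missing_data"
  )
  expect_error(
    route_ttc(substance_dossier("um", oasis_moa = "unknown"), ctx_life),
    regexp = "QSAR Toolbox", class = "vaportox_missing_data"
  )
})

test_that("a carcinogen listing without a genotoxicity alert warns and proceeds", {
  expect_warning(
    r <- route_ttc(
      substance_dossier("carc",
        carcinogen_classification = "listed",
        gras_or_food_use = TRUE, cramer_class = "1"
      ),
      ctx_life
    ),
    "expert review"
  )
  expect_equal(r$limit_ug_per_day, 865)
})

test_that("conservative mode takes the minimum across applicable branches", {
  # GRAS Cramer-1 (865) but reactive OASIS (4.286): conservative picks 4.286
  r <- route_ttc(
    substance_dossier("cons",
      gras_or_food_use = TRUE, cramer_class = "1", oasis_moa = "reactive"
    ),
    ctx_life,
    conservative = TRUE
  )
  expect_equal(r$limit_ug_per_day, 4.286)
  # printed-tree default would have stopped at Cramer
  r0 <- route_ttc(
    substance_dossier("cons",
      gras_or_food_use = TRUE, cramer_class = "1", oasis_moa = "reactive"
    ),
    ctx_life
  )
  expect_equal(r0$limit_ug_per_day, 865)
})
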