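ctx <- product_context()
pass_screen <- screen_substance(substance_dossier("clean"), ctx)

test_that("risk characterization compares exposure to the limit with margin", {
  v <- characterize_risk(daily_exposure(5, 100), 0.6, pass_screen)
  expect_equal(v$verdict, "low_risk")
  expect_equal(v$exposure_mg_per_day, 0.5)
  expect_equal(v$margin, 1.2)

  v2 <- characterize_risk(daily_exposure(20, 100), 0.6, pass_screen)
  expect_equal(v2$verdict, "exceeds_limit")
  expect_match(v2$guidance, "reduce its concentration")

  # zero exposure: low risk, margin undefined
  v3 <- characterize_risk(daily_exposure(0, 100), 0.6, pass_screen)
  expect_equal(v3$verdict, "low_risk")
  expect_true(is.na(v3$margin))
})

test_that("the verdict boundary is at equality, warned, and flips for any upward step", {
  expect_warning(
    v <- characterize_risk(daily_exposure(6, 100), 0.6, pass_screen),
    "boundary"
  )
  expect_equal(v$verdict, "low_risk")
  for (eps in c(1e-9, 1e-6, 0.01)) {
    vv <- characterize_risk(daily_exposure(6 * (1 + eps), 100), 0.6, pass_screen)
    expect_equal(vv$verdict, "exceeds_limit")
  }
})

test_that("an exclude screen verdict dominates any dose", {
  excl <- screen_substance(
    substance_dossier("vea", is_phenolic_acetate = TRUE), ctx
  )
  v <- characterize_risk(daily_exposure(0, 100), 100, excl)
  expect_equal(v$verdict, "excluded")
  expect_null(v$governing_limit_mg_per_day)
})

test_that("maximum allowable concentration implements the back-calculation", {
  expect_equal(max_allowable_concentration(1, 100), 1)
  expect_equal(max_allowable_concentration(0.0006, 100), 0.0006)
  expect_equal(max_allowable_concentration(0, 100), 0)
  expect_warning(pct <- max_allowable_concentration(500, 100), "capped")
  expect_equal(pct, 100)
  expect_error(max_allowable_concentration(1, 0), class = "vaportox_validation_error")
})

test_that("exposure at the max allowable concentration reproduces the limit", {
  withr::local_seed(47)
  for (i in 1:20) {
    use <- runif(1, 10, 500)
    lim <- runif(1, 0, use) # limits at or below total consumption
    conc_mg_g <- max_allowable_concentration(lim, use) * 10 # % w/w -> mg/g
    expect_equal(
      daily_exposure(conc_mg_g, use)$additive_mg_per_day, lim,
      tolerance = 1e-12
    )
  }
})

test_that("a full assessment with a human chronic inhalation POD is POD-derived", {
  pod <- pod_record(5, "mg_per_m3", "NOAEC",
    route = "inhalation", species = "human", duration_class = "chronic"
  )
  d <- substance_dossier("inh", pods = pod)
  rep <- run_assessment(d, ctx, concentration_mg_per_g = 0.5)
  expect_equal(rep$verdict$limit_source, "pod_derived")
  # 5 mg/m3 continuous x 20 m3 / UF 10 = 10 mg/day
  expect_equal(rep$verdict$governing_limit_mg_per_day, 10)
  expect_equal(rep$verdict$verdict, "low_risk")
  expect_equal(rep$max_allowable_concentration_pct, 10)
  expect_true(length(rep$audit) > 3)
})

test_that("an excluded substance yields an excluded report with no limit", {
  d <- substance_dossier("vea", is_phenolic_acetate = TRUE)
  rep <- run_assessment(d, ctx, concentration_mg_per_g = 10)
  expect_equal(rep$verdict$verdict, "excluded")
  expect_null(rep$verdict$governing_limit_mg_per_day)
  expect_equal(rep$max_allowable_concentration_pct, 0)
  expect_equal(verdict_status(rep), 3L)
})

test_that("a POD-free GRAS Cramer-1 substance routes through TTC", {
  d <- fixture_gras_dossier()
  rep <- run_assessment(d, ctx, concentration_mg_per_g = 0.5)
  expect_equal(rep$verdict$limit_source, "ttc")
  # 0.05 mg/day = 50 ug/day vs 865 ug/day
  expect_equal(rep$verdict$exposure_mg_per_day, 0.05)
  expect_equal(rep$verdict$governing_limit_mg_per_day, 0.865)
  expect_equal(rep$verdict$verdict, "low_risk")
})

test_that("UF-cap failures fall back to TTC, and no route at all is insufficient data", {
  worst_pod <- pod_record(5, "mg_per_kg_bw_per_day", "LOAEL",
    route = "oral", species = "animal", duration_class = "subacute"
  )
  ctx_open <- product_context(age_gated = FALSE)
  d_fallback <- substance_dossier("fb",
    pods = worst_pod, gras_or_food_use = TRUE, cramer_class = "2"
  )
  rep <- run_assessment(d_fallback, ctx_open, concentration_mg_per_g = 0.1)
  expect_equal(rep$verdict$limit_source, "ttc")
  expect_equal(rep$verdict$governing_limit_mg_per_day, 0.145)
  expect_true(any(grepl("10,000", rep$audit)))

  d_nothing <- substance_dossier("stuck", ttc_exclusion_category = "inorganic")
  rep2 <- run_assessment(d_nothing, ctx, concentration_mg_per_g = 0.1)
  expect_equal(rep2$verdict$verdict, "insufficient_data")
  expect_equal(verdict_status(rep2), 4L)
})

test_that("a native sensitizer above its plant-relative cap exceeds the limit", {
  d <- substance_dossier("ns",
    is_respiratory_sensitizer = TRUE, native_to_cannabis = TRUE,
    plant_ratio_to_thc = 0.001, gras_or_food_use = TRUE, cramer_class = "1"
  )
  over <- run_assessment(d, ctx, concentration_mg_per_g = 2) # cap is 0.85
  expect_equal(over$verdict$verdict, "exceeds_limit")
  under <- run_assessment(d, ctx, concentration_mg_per_g = 0.1)
  expect_equal(under$verdict$verdict, "low_risk")
})

test_that("reports serialize to self-contained JSON that recomputes the same verdict", {
  d <- fixture_gras_dossier()
  rep <- run_assessment(d, ctx, concentration_mg_per_g = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  expect_equal(x$verdict, "low_risk")
  expect_equal(x$exposure_mg_per_day, 0.05)
  # re-run from the report's own echoes
  d2 <- x$dossier
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(d2, path2, auto_unbox = TRUE, null = "null")
  rerun <- run_assessment(
    read_dossier(path2),
    do.call(product_context, x$context),
    do.call(exposure_assumptions, x$assumptions),
    x$concentration_mg_per_g
  )
  expect_equal(rerun$verdict$verdict, x$verdict)
  expect_equal(rerun$verdict$governing_limit_mg_per_day, x$governing_limit_mg_per_day)
})

test_that("tidiers expose the verdict and ledger as tibbles", {
  pod <- fixture_oral_noael_pod()
  d <- fixture_pod_dossier(pods = pod)
  led <- build_uf_ledger(pod, d, ctx)
  expect_named(tidy(led), c("category", "name", "value", "provenance"))
  expect_true(glance(led)$within_cap)
  rep <- run_assessment(fixture_gras_dossier(), ctx, concentration_mg_per_g = 0.5)
  g <- glance(rep)
  expect_equal(g$verdict, "low_risk")
  expect_equal(g$substance, "geraniol")
})

test_that("the CLI front-end assesses, simulates and summarizes", {
  dossier_path <- withr::local_tempfile(fileext = ".json")
  write_dossier(fixture_gras_dossier(), dossier_path)
  out_path <- withr::local_tempfile(fileext = ".json")
  capture.output(status <- vaportox_cli(c(
    "assess", "--dossier", dossier_path, "--concentration", "0.5",
    "--out", out_path
  )))
  expect_equal(status, 0L)
  expect_true(file.exists(out_path))

  log_path <- withr::local_tempfile(fileext = ".csv")
  expect_equal(
    suppressMessages(vaportox_cli(c(
      "simulate", "--devices", "5", "--seed", "3", "--out", log_path
    ))), 0L
  )
  sum_path <- withr::local_tempfile(fileext = ".csv")
  capture.output(
    status2 <- vaportox_cli(c("summarize-usage", "--log", log_path, "--out", sum_path))
  )
  expect_equal(status2, 0L)
  expect_equal(nrow(readr::read_csv(sum_path, show_col_types = FALSE)), 6L)

  capture.output(status3 <- vaportox_cli("nonsense"))
  expect_equal(status3, 64L)
  expect_equal(
    suppressMessages(vaportox_cli(c("assess", "--concentration", "1"))), 64L
  )
})
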