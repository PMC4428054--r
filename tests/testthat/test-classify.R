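test_that("the DC < IC25 rule reproduces all five published-style fixtures", {
  # five screening fixtures (DC, IC25 on embryonic cells, censoring) and
  # the expected calls
  fixtures <- data.frame(
    compound = c("Thalidomide", "RA", "D-penicillamine", "VPA",
                 "Penicillin G"),
    dc = c(30, 0.36, 200, 0.1, 1000),
    ic25 = c(1000, 2000, 278, 0.13, 787),
    censored = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    unit = c("uM", "ng/ml", "ug/ml", "mM", "ug/ml"),
    expected = c("teratogenic", "teratogenic", "teratogenic", "teratogenic",
                 "non-teratogenic"))
  for (i in seq_len(nrow(fixtures))) {
    rep <- callTeratogenicity(fixtures$dc[i], fixtures$ic25[i],
                              unit = fixtures$unit[i],
                              ic25Censored = fixtures$censored[i],
                              compound = fixtures$compound[i])
    expect_equal(rep@call, fixtures$expected[i], label = fixtures$compound[i])
  }
})

test_that("rule edge cases: no DC, equality boundary, unit mismatch", {
  expect_equal(callTeratogenicity(NA_real_, 100, "uM")@call,
               "non-teratogenic")
  # strict inequality: DC equal to the IC25 bound is non-teratogenic
  expect_equal(callTeratogenicity(100, 100, "uM")@call, "non-teratogenic")
  expect_equal(callTeratogenicity(99.9, 100, "uM")@call, "teratogenic")
  expect_error(callTeratogenicity(30, 1000, unit = "uM", ic25Unit = "ug/ml"),
               "unit mismatch")
})

test_that("reports round-trip through JSON losslessly", {
  rep <- callTeratogenicity(30, 1000, "uM", ic25Censored = TRUE,
                            compound = "Thalidomide",
                            ic25Adult = 500, ic25AdultCensored = FALSE)
  path <- tempfile(fileext = ".json")
  writeReport(rep, path)
  back <- readReport(path)
  expect_identical(back@compound, rep@compound)
  expect_identical(back@dc, rep@dc)
  expect_identical(back@ic25Embryonic, rep@ic25Embryonic)
  expect_identical(back@ic25EmbryonicCensored, rep@ic25EmbryonicCensored)
  expect_identical(back@ic25Adult, rep@ic25Adult)
  expect_identical(back@call, rep@call)

  # undefined DC serializes as the token "none", never infinity
  repNone <- callTeratogenicity(NA_real_, 1000, "uM")
  writeReport(repNone, path)
  raw <- jsonlite::read_json(path)
  expect_identical(raw$dc, "none")
  expect_true(is.na(readReport(path)@dc))
})

test_that("end-to-end pipeline discriminates the three scenario archetypes", {
  geo <- coarseGeometry()
  design <- fourGroupDesign()  # 0, 1, 10, 100 uM
  runScenario <- function(groups, ic50, seed) {
    m <- disruptionModel(disruptionByGroup = groups)
    cs <- generateDoseSeries(geo, model = m, nPerGroup = 10, noiseSd = 5,
                             seed = seed)
    vt <- generateViabilityData(
      viabilityDesign(cMax = 1000, ic50 = ic50, hill = 1, noiseSd = 0.05),
      seed = seed + 1)
    runPipeline(cs, design, vt, minArea = COARSE_MIN_AREA)
  }
  seeds <- 1:8

  # teratogen: disruption from the low dose, cytotoxicity far above it
  callsT <- vapply(seeds, function(s)
    runScenario(c(control = 0, low = 0.4, medium = 0.7, high = 1.0),
                ic50 = 2000, seed = 100 + s)$report@call, character(1))
  expect_gte(sum(callsT == "teratogenic"), 7)

  # inert: no disruption anywhere
  callsI <- vapply(seeds, function(s)
    runScenario(c(control = 0, low = 0, medium = 0, high = 0),
                ic50 = 2000, seed = 200 + s)$report@call, character(1))
  expect_gte(sum(callsI == "non-teratogenic"), 7)

  # cytotoxic-only: disruption appears only at doses above the IC25
  # (IC25 = 5 uM < medium dose 10 uM where disruption starts)
  callsC <- vapply(seeds, function(s)
    runScenario(c(control = 0, low = 0, medium = 0.6, high = 0.9),
                ic50 = 15, seed = 300 + s)$report@call, character(1))
  expect_gte(sum(callsC == "non-teratogenic"), 7)
})

test_that("pipeline errors carry their stage label", {
  cs <- generateDoseSeries(coarseGeometry(), nPerGroup = 2, noiseSd = 5,
                           seed = 1)
  vt <- data.frame(concentration = c(0, 1, 5, 25), viability = 1)
  expect_error(
    runPipeline(cs, fourGroupDesign(), vt, minArea = COARSE_MIN_AREA),
    "\\[cytotoxicity\\]")
})

test_that("pipeline persists auditable intermediates", {
  cs <- generateDoseSeries(coarseGeometry(), nPerGroup = 3, noiseSd = 5,
                           seed = 17)
  vt <- generateViabilityData(viabilityDesign(cMax = 1000, ic50 = 2000),
                              seed = 18)
  outDir <- tempfile()
  res <- runPipeline(cs, fourGroupDesign(), vt, minArea = COARSE_MIN_AREA,
                     outDir = outDir)
  expect_true(all(file.exists(file.path(outDir,
    c("features.csv", "clusters.csv", "readouts.csv", "linkage.nwk",
      "stats.json", "report.json")))))
  back <- readReport(file.path(outDir, "report.json"))
  expect_identical(back@call, res$report@call)
  unlink(outDir, recursive = TRUE)
})
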