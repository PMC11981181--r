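# Synthetic cohort generator: determinism, range conservation,
# construction guarantees, and spec validation.

test_that("cohort generation conserves counts and labels", {
  sim <- generateCohort(cohortSpec(n_high = 3, n_low = 5, seed = 7))
  expect_equal(nrow(sim$cohort), 8)
  expect_equal(length(sim$recordings), 8 * 8)  # 4 shapes x 2 phases
  expect_equal(sum(sim$cohort$group == "high"), 3)
  expect_true(all(sim$cohort$age_years >= 4.5 & sim$cohort$age_years <= 5.5))

  lowonly <- generateCohort(cohortSpec(n_high = 0, n_low = 2, seed = 1))
  expect_true(all(lowonly$cohort$group == "low"))
})

test_that("identical spec and seed reproduce identical output", {
  a <- generateCohort(cohortSpec(n_high = 2, n_low = 3, seed = 123))
  b <- generateCohort(cohortSpec(n_high = 2, n_low = 3, seed = 123))
  expect_identical(a$cohort, b$cohort)
  expect_identical(lapply(a$recordings, recordingSamples),
                   lapply(b$recordings, recordingSamples))
  c <- generateCohort(cohortSpec(n_high = 2, n_low = 3, seed = 124))
  expect_false(identical(a$cohort$srs2_score, c$cohort$srs2_score))
})

test_that("generated channels respect their documented ranges", {
  sim <- generateCohort(cohortSpec(n_high = 2, n_low = 2, seed = 5))
  for (rec in sim$recordings) {
    s <- recordingSamples(rec)
    expect_true(all(s$x >= 0 & s$x <= 1))
    expect_true(all(s$y >= 0 & s$y <= 1))
    expect_true(all(s$pressure >= 0 & s$pressure <= 1))
    expect_true(all(s$azimuth >= 0 & s$azimuth < 360))
    expect_true(all(s$tilt >= 0 & s$tilt <= 90))
    expect_true(all(is.na(s$gaze_x) | abs(s$gaze_x) <= 90))
    expect_true(all(diff(s$t) > 0))
  }
})

test_that("srs2 scores are consistent with the sex-specific cutoff rule", {
  sim <- generateCohort(cohortSpec(n_high = 15, n_low = 30, seed = 9))
  expect_identical(assignGroup(sim$cohort$sex, sim$cohort$srs2_score),
                   sim$cohort$group)
})

test_that("invalid cohort specs are rejected with the field named", {
  expect_error(cohortSpec(n_high = -1), "n_high")
  expect_error(cohortSpec(n_high = 1, n_low = 0), "n_high")
  expect_error(cohortSpec(srs_low_sd = 0), "srs_low_sd")
  expect_error(cohortSpec(gaze_coupling_high = 1.2), "gaze_coupling_high")
  expect_error(cohortSpec(effect_map = c(NotAFeature = 1)), "effect_map")
})

test_that("noise-free drawings reproduce the programmed constants", {
  prof <- constant_profile(speed = 0.12, pressure = 0.5)
  rec <- generateDrawing(line_template(0.6), prof, seed = 3)
  seg <- segmentActiveDrawing(rec)
  expect_equal(nrow(seg), 1)
  kin <- kinematicsFeatures(rec, seg)
  expect_equal(unname(kin["Mdrawingspeed"]), 0.12, tolerance = 1e-10)
  expect_equal(unname(kin["SDdrawingspeed"]), 0)
  pres <- pressureFeatures(rec, seg)
  expect_equal(unname(pres["Mpenpressure"]), 0.5)
  expect_equal(unname(pres["SDpenpressure"]), 0)
  expect_equal(unname(pres["Mpenpressurechange"]), 0)
})

test_that("a 3-stroke triangle yields exactly 3 active segments", {
  tpl <- shapeTemplates("equilateral_triangle")
  rec <- generateDrawing(tpl, drawingProfile(), seed = 11)
  expect_equal(nrow(segmentActiveDrawing(rec)), 3)
})

test_that("gaze coupling is realized exactly over active samples", {
  tpl <- shapeTemplates("square")
  rec <- generateDrawing(tpl, drawingProfile(), seed = 21)
  for (cpl in c(-1, -0.4, 0, 0.6, 1)) {
    g <- generateGaze(rec, cpl, seed = 22)
    s <- recordingSamples(g)
    act <- s$pressure > 0
    expect_gt(sum(act), 200)
    expect_equal(cor(s$gaze_x[act], s$x[act]), cpl, tolerance = 1e-9)
    expect_equal(cor(s$gaze_y[act], s$y[act]), cpl, tolerance = 1e-9)
    expect_true(all(abs(s$gaze_x) <= 90))
  }
  expect_error(generateGaze(make_recording(rep(0, 20)), 0.5), "empty drawing")
})

test_that("d = 2 on mean pressure separates extracted features strongly", {
  # scaled-down realization check: 50 + 50 participants, a few seeds
  for (seed in c(101, 202, 303)) {
    spec <- cohortSpec(n_high = 50, n_low = 50,
                       effect_map = c(Mpenpressure = 2),
                       gaze_coupling_high = 0.6, gaze_coupling_low = 0.6,
                       seed = seed)
    sim <- generateCohort(spec)
    sheet <- extractFeatureSheet(sim$recordings, sim$cohort, "square")
    tt <- t.test(Mpenpressure ~ group, data = sheet)
    expect_gt(abs(tt$statistic), 5)
  }
})

test_that("null effect map yields calibrated group t statistics", {
  # d = 0 everywhere, equal coupling: two-sample t statistics on the
  # extracted features behave like null draws (|t| <= 3 for ~95%)
  stats <- c()
  for (seed in 1:10) {
    spec <- cohortSpec(n_high = 20, n_low = 20,
                       effect_map = setNames(rep(0, 12), featureNames16()[1:12]),
                       gaze_coupling_high = 0.6, gaze_coupling_low = 0.6,
                       seed = 5000 + seed)
    sim <- generateCohort(spec)
    sheet <- extractFeatureSheet(sim$recordings, sim$cohort,
                                 "inverted_triangle")
    for (f in featureNames16()) {
      tt <- t.test(sheet[[f]][sheet$group == "high"],
                   sheet[[f]][sheet$group == "low"])
      stats <- c(stats, tt$statistic)
    }
  }
  expect_gte(mean(abs(stats) <= 3), 0.93)
})
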