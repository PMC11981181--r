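# The sixteen features: worked arithmetic examples, circular statistics,
# gaze coupling conventions, and brute-force oracle equivalence.

test_that("pressure features match direct arithmetic", {
  rec <- make_recording(c(0.2, 0.4, 0.6))
  f <- pressureFeatures(rec, segmentActiveDrawing(rec, min_len = 2))
  expect_equal(unname(f), c(0.4, 0.2, 0.2), tolerance = 1e-12)

  # two segments: no change pair crosses the pen-up gap
  rec2 <- make_recording(c(0.2, 0.4, 0, 0, 0.8, 0.6))
  f2 <- pressureFeatures(rec2, segmentActiveDrawing(rec2, min_len = 2))
  expect_equal(unname(f2["Mpenpressure"]), 0.5)
  expect_equal(unname(f2["Mpenpressurechange"]), 0.2, tolerance = 1e-12)

  expect_error(pressureFeatures(make_recording(c(0.5, 0, 0, 0))),
               "insufficient data")
})

test_that("kinematic features match direct arithmetic", {
  # constant 0.01 units per frame at 30 Hz -> 0.3 units/s
  n <- 31
  rec <- make_recording(rep(0.5, n), x = 0.05 + 0.01 * (0:(n - 1)))
  f <- kinematicsFeatures(rec)
  expect_equal(unname(f["Mdrawingspeed"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(f["SDdrawingspeed"]), 0, tolerance = 1e-10)

  # speeds 1, 2, 3 units/s -> mean |dv| = 1
  dt <- 1 / 30
  xs <- cumsum(c(0.1, 1 * dt, 2 * dt, 3 * dt))
  rec2 <- make_recording(rep(0.5, 4), x = xs)
  f2 <- kinematicsFeatures(rec2)
  expect_equal(unname(f2["Mdrawingspeed"]), 2, tolerance = 1e-12)
  expect_equal(unname(f2["Mdrawingacceleration"]), 1, tolerance = 1e-12)

  # stationary pen-down
  rec3 <- make_recording(rep(0.5, 10), x = rep(0.3, 10))
  expect_equal(unname(kinematicsFeatures(rec3)), c(0, 0, 0))
})

test_that("orientation features use circular statistics", {
  rec <- make_recording(c(0.5, 0.5), azimuth = c(350, 10))
  f <- poseFeatures(rec, segmentActiveDrawing(rec, min_len = 2))
  expect_equal(unname(f["Mpenorientation"]) %% 360, 0, tolerance = 1e-9)
  expect_equal(unname(f["Mpenorientationchange"]), 20, tolerance = 1e-9)

  rec2 <- make_recording(rep(0.5, 5), azimuth = 270, tilt = 45)
  f2 <- poseFeatures(rec2)
  expect_equal(unname(f2["Mpenorientation"]), 270, tolerance = 1e-9)
  expect_equal(unname(f2["SDpenorientation"]), 0, tolerance = 1e-9)
  expect_equal(unname(f2["Mpentilt"]), 45)
  expect_equal(unname(f2["SDpentilt"]), 0)
  expect_equal(unname(f2["Mpentiltchange"]), 0)

  # linear fallback treats angles arithmetically
  f3 <- poseFeatures(rec, segmentActiveDrawing(rec, min_len = 2),
                     featureConfig(orientation_stats = "linear", min_len = 2))
  expect_equal(unname(f3["Mpenorientation"]), 180)
  expect_equal(unname(f3["Mpenorientationchange"]), 340)
})

test_that("gaze coupling follows the correlation conventions", {
  n <- 40
  x <- seq(0.1, 0.9, length.out = n)
  # exact affine dependence: +1 and -1
  rec <- make_recording(rep(0.5, n), x = x, gaze_x = 2 * x - 1,
                        gaze_y = -x)
  cc <- gazeCoupling(rec)
  expect_equal(unname(cc["horizontal"]), 1, tolerance = 1e-12)
  # vertical reference is constant y -> invalid, imputed 0
  expect_equal(unname(cc["vertical"]), 0)
  expect_false(attr(cc, "valid")["vertical"])

  rec2 <- make_recording(rep(0.5, n), x = x, y = x, gaze_y = -x)
  cc2 <- gazeCoupling(rec2)
  expect_equal(unname(cc2["vertical"]), -1, tolerance = 1e-12)

  # constant gaze -> zero variance -> invalid
  rec3 <- make_recording(rep(0.5, n), x = x, gaze_x = 5)
  cc3 <- gazeCoupling(rec3)
  expect_false(attr(cc3, "valid")["horizontal"])

  # fewer than 10 valid pairs -> invalid
  g <- c(runif(5), rep(NA, n - 5))
  rec4 <- make_recording(rep(0.5, n), x = x, gaze_x = g)
  expect_false(attr(gazeCoupling(rec4), "valid")["horizontal"])
})

test_that("extractFeatures assembles all 16 with validity flags", {
  pair <- random_recording_pair(1)
  fv <- extractFeatures(pair$demo, pair$drawing)
  expect_identical(names(fv), featureNames16())
  expect_true(all(attr(fv, "valid")))
  expect_true(all(fv[c("SDpenpressure", "SDdrawingspeed", "SDpentilt",
                       "SDpenorientation")] >= 0))
  expect_true(all(abs(fv[13:16]) <= 1))

  # all gaze missing: 12 pen features valid, 4 correlations invalid
  s <- recordingSamples(pair$drawing); s$gaze_x <- NA; s$gaze_y <- NA
  drawing2 <- DrawingRecording("T001", "square", "drawing", s)
  sd2 <- recordingSamples(pair$demo); sd2$gaze_x <- NA; sd2$gaze_y <- NA
  demo2 <- DrawingRecording("T001", "square", "demo", sd2)
  fv2 <- extractFeatures(demo2, drawing2)
  expect_identical(unname(attr(fv2, "valid")),
                   c(rep(TRUE, 12), rep(FALSE, 4)))
  expect_equal(unname(fv2[13:16]), rep(0, 4))

  expect_error(extractFeatures(NULL, make_recording(rep(0, 10))),
               "no active drawing")
})

test_that("every feature matches a brute-force recomputation to 1e-10", {
  for (seed in 1:8) {
    pair <- random_recording_pair(seed)
    fv <- extractFeatures(pair$demo, pair$drawing)
    expect_equal(as.numeric(fv),
                 as.numeric(oracle_features(pair$demo, pair$drawing)),
                 tolerance = 1e-10)
  }
})

test_that("sampling-rate halving leaves smooth-path statistics stable", {
  # a smooth drawing sampled at 30 Hz vs the same path at 15 Hz
  prof <- drawingProfile(speed_rough = 0.05, pressure_rough = 0.05,
                         tilt_rough = 0.05, azimuth_rough = 0.05,
                         pressure_sd = 0.02, tilt_sd = 1, azimuth_sd = 2,
                         speed_cv = 0.05)
  rec30 <- generateDrawing(line_template(0.7), prof, seed = 12)
  s <- recordingSamples(rec30)
  rec15 <- DrawingRecording("T001", "square", "drawing",
                            s[seq(1, nrow(s), by = 2), ])
  for (feat in c("Mpenpressure", "Mpentilt", "Mpenorientation")) {
    v30 <- extractFeatures(NULL, rec30)[feat]
    v15 <- extractFeatures(NULL, rec15)[feat]
    expect_equal(unname(v15), unname(v30), tolerance = 0.02)
  }
  # constant-velocity speed is frame-rate invariant
  recc <- generateDrawing(line_template(0.6), constant_profile(0.12), seed = 1)
  sc <- recordingSamples(recc)
  recc15 <- DrawingRecording("T001", "square", "drawing",
                             sc[seq(1, nrow(sc), by = 2), ])
  expect_equal(unname(kinematicsFeatures(recc15)["Mdrawingspeed"]), 0.12,
               tolerance = 1e-10)
})

test_that("feature sets assemble into a SummarizedExperiment container", {
  sim <- generateCohort(cohortSpec(n_high = 2, n_low = 3, seed = 41))
  sheets <- lapply(setNames(shapeIds(), shapeIds()), function(sh)
    extractFeatureSheet(sim$recordings, sim$cohort, sh))
  fs <- buildFeatureSet(sheets, sim$cohort)
  expect_s4_class(fs, "DrawingFeatureSet")
  expect_equal(dim(fs), c(64L, 5L))
  x <- featureMatrix(fs, "sun")
  expect_identical(colnames(x), featureNames16())
  expect_equal(unname(x[, "Mpenpressure"]),
               sheets$sun$Mpenpressure)
  xa <- featureMatrix(fs, "all")
  expect_equal(ncol(xa), 64L)
})
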