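# CSV ingestion, schema/range validation, round trips, segmentation.

test_that("recording round trip through CSV is lossless", {
  tpl <- shapeTemplates("inverted_triangle")
  rec <- generateGaze(generateDrawing(tpl, drawingProfile(), seed = 2),
                      0.5, seed = 3)
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  back <- readRecording(path)
  expect_equal(recordingSamples(back), recordingSamples(rec),
               tolerance = 1e-12)
  expect_identical(back@shapeId, rec@shapeId)
  expect_identical(recordingPhase(back), "drawing")
})

test_that("header aliases are resolved through the dialect map", {
  rec <- make_recording(c(0.5, 0.5, 0.5, 0.5))
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  d <- read.csv(path)
  names(d)[names(d) == "t"] <- "time"
  names(d)[names(d) == "x"] <- "pen_x"
  names(d)[names(d) == "pressure"] <- "p"
  write.csv(d, path, row.names = FALSE, na = "")
  back <- readRecording(path)
  expect_equal(recordingSamples(back)$pressure, rep(0.5, 4))
})

test_that("schema and range violations are reported precisely", {
  rec <- make_recording(runif(20, 0.2, 0.8))
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  d <- read.csv(path)

  d2 <- d; d2$pressure <- NULL
  write.csv(d2, path, row.names = FALSE)
  expect_error(readRecording(path), "pressure")

  d3 <- d; d3$pressure[17] <- 1.2
  write.csv(d3, path, row.names = FALSE)
  expect_error(readRecording(path), "17")

  d4 <- d; d4$t[5] <- d4$t[4]          # non-monotone time
  write.csv(d4, path, row.names = FALSE)
  expect_error(readRecording(path), "time")
})

test_that("blank gaze values load as missing", {
  rec <- make_recording(runif(30, 0.2, 0.8), gaze_x = 10, gaze_y = -5)
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  d <- read.csv(path)
  d$gaze_x[1:3] <- NA
  write.csv(d, path, row.names = FALSE, na = "")
  back <- readRecording(path)
  expect_equal(sum(is.na(recordingSamples(back)$gaze_x)), 3)
  expect_equal(recordingSamples(back)$gaze_x[4], 10)
})

test_that("feature sheets round trip and validate their schema", {
  sim <- generateCohort(cohortSpec(n_high = 2, n_low = 3, seed = 31))
  sheet <- extractFeatureSheet(sim$recordings, sim$cohort, "sun")
  path <- tempfile(fileext = ".csv")
  writeFeatureSheet(sheet, path)
  back <- readFeatureSheet(path)
  for (f in featureNames16())
    expect_equal(back[[f]], sheet[[f]], tolerance = 1e-12)
  expect_identical(as.character(back$group), as.character(sheet$group))

  d <- read.csv(path)
  d$Mpenpressure <- NULL
  write.csv(d, path, row.names = FALSE)
  expect_error(readFeatureSheet(path), "Mpenpressure")
})

test_that("feature sheets accept spelling-variant headers", {
  sim <- generateCohort(cohortSpec(n_high = 2, n_low = 2, seed = 32))
  sheet <- extractFeatureSheet(sim$recordings, sim$cohort, "square")
  names(sheet)[names(sheet) == "Corrdemoeyevertical"] <- "Corrdemoeyevartical"
  names(sheet)[names(sheet) == "Corrdrawingeyevertical"] <- "Corrdrawingeyevartical"
  path <- tempfile(fileext = ".csv")
  writeFeatureSheet(sheet, path)
  back <- readFeatureSheet(path)
  expect_true(all(featureNames16() %in% names(back)))
})

test_that("segmentation finds maximal runs by definition", {
  rec <- make_recording(c(0, 0, 0.4, 0.5, 0, 0, 0.3, 0.2, 0))
  seg <- segmentActiveDrawing(rec, pressure_threshold = 0, min_len = 2)
  expect_equal(seg$start, c(3, 7))
  expect_equal(seg$end, c(4, 8))

  expect_equal(nrow(segmentActiveDrawing(make_recording(rep(0, 10)))), 0)

  seg1 <- segmentActiveDrawing(make_recording(rep(0.5, 100)))
  expect_equal(seg1, data.frame(start = 1L, end = 100L))

  expect_error(segmentActiveDrawing(
    make_recording(rep(0, 5), phase = "demo")), "drawing")
})

test_that("segments are disjoint, ordered, maximal and cover all
           qualifying samples", {
  for (seed in 1:20) {
    set.seed(seed)
    pr <- ifelse(runif(200) < 0.6, runif(200, 0.05, 1), 0)
    rec <- make_recording(pr)
    min_len <- sample(1:4, 1)
    seg <- segmentActiveDrawing(rec, 0, min_len)
    covered <- unlist(lapply(seq_len(nrow(seg)),
                             function(i) seg$start[i]:seg$end[i]))
    # disjoint and ordered
    expect_true(all(diff(covered) >= 1))
    # all covered samples are active, and boundaries are maximal
    expect_true(all(pr[covered] > 0))
    expect_true(all(pr[pmax(seg$start - 1, 1)][seg$start > 1] == 0))
    expect_true(all(pr[pmin(seg$end + 1, 200)][seg$end < 200] == 0))
    # every active run of length >= min_len is covered
    r <- rle(pr > 0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    want <- unlist(mapply(function(s, e, v, l) if (v && l >= min_len) s:e,
                          starts, ends, r$values, r$lengths))
    expect_identical(sort(covered), as.integer(sort(want)))
  }
})
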