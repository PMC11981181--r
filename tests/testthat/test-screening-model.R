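# Linear-SVM screening: LOOCV, metrics, probability calibration, and
# the joint feature/cost search.

test_that("LOOCV is exact on hand-separable 1-D data", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  cv <- loocvConfusion(x, c("low", "low", "high", "high"), cost = 1)
  expect_equal(unname(cvCounts(cv)), c(2L, 0L, 2L, 0L))
  expect_equal(unname(cvMetrics(cv)), c(1, 1, 1))
})

test_that("a near-single-class cohort yields a degenerate-fold warning
           but a defined result", {
  set.seed(4)
  x <- matrix(rnorm(10), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(
    cv <- loocvConfusion(x, c("high", rep("low", 4)), cost = 1),
    "degenerate")
  expect_s4_class(cv, "CVResult")
  expect_equal(sum(cvCounts(cv)), 5)
})

test_that("confusion metrics match their defining formulas", {
  expect_equal(unname(confusionMetrics(c(tp = 18, fn = 2, tn = 113, fp = 0))),
               c(131 / 133, 0.9, 1), tolerance = 1e-12)
  expect_equal(unname(confusionMetrics(c(tp = 20, fn = 0, tn = 113, fp = 0))),
               c(1, 1, 1))
  expect_equal(unname(confusionMetrics(c(tp = 0, fn = 20, tn = 0, fp = 113))),
               c(0, 0, 0))
  expect_warning(m <- confusionMetrics(c(tp = 0, fn = 0, tn = 5, fp = 1)),
                 "sensitivity undefined")
  expect_true(is.na(m["sensitivity"]))
  expect_equal(unname(m["specificity"]), 5 / 6)
})

test_that("LOOCV is deterministic and scale invariant under
           standardization", {
  set.seed(9)
  x <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- rep(c("high", "low"), c(10, 30))
  cv1 <- loocvConfusion(x, y, cost = 0.01)
  cv2 <- loocvConfusion(x, y, cost = 0.01)
  expect_identical(cvPredictions(cv1), cvPredictions(cv2))
  expect_identical(cvCounts(cv1), cvCounts(cv2))

  xs <- x; xs[, "b"] <- xs[, "b"] * 1000
  cv3 <- loocvConfusion(xs, y, cost = 0.01)
  expect_identical(cvCounts(cv3), cvCounts(cv1))
  expect_identical(cvPredictions(cv3)$predicted, cvPredictions(cv1)$predicted)

  # metrics identity with the confusion counts
  k <- cvCounts(cv1)
  expect_equal(unname(cvMetrics(cv1)),
               unname(confusionMetrics(k)))
})

test_that("calibrated probabilities are monotone in the decision value", {
  set.seed(10)
  x <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  x[1:10, 1] <- x[1:10, 1] + 2.5
  y <- rep(c("high", "low"), c(10, 20))
  m <- fitScreeningModel(x, y, cost = 1)
  f <- decisionValues(m, x)
  p <- predictProbability(m, x)
  expect_true(all(p > 0 & p < 1))
  expect_identical(order(f), order(p))

  # two points on opposite margins: probabilities symmetric about 0.5
  xm <- matrix(c(-1, 1), ncol = 1, dimnames = list(NULL, "f"))
  ms <- fitScreeningModel(xm, c("low", "high"), cost = 1,
                          standardize = FALSE)
  ps <- predictProbability(ms, xm)
  expect_equal(sum(ps), 1, tolerance = 1e-6)
  expect_equal(predictProbability(ms, matrix(0, dimnames = list(NULL, "f"))),
               0.5, tolerance = 1e-6)

  expect_error(fitScreeningModel(xm, c("low", "low")), "single class")
})

test_that("pure-noise LOOCV accuracy stays near the majority rate", {
  accs <- sapply(1:3, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(133 * 4), 133, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
    y <- rep(c("high", "low"), c(20, 113))
    cvMetrics(loocvConfusion(x, y, cost = 0.001,
                             probabilities = FALSE))["accuracy"]
  })
  expect_true(all(abs(accs - 113 / 133) <= 0.10))
})

test_that("the search selects the single candidate when only one exists", {
  set.seed(2)
  x <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "only"))
  x[1:10] <- x[1:10] + 3
  y <- rep(c("high", "low"), c(10, 20))
  sel <- selectModel(x, y)
  expect_identical(sel$features, "only")
  expect_true(sel$cost %in% 10^(-3:1))
})

test_that("greedy search latches onto planted informative features", {
  # at this size a noise feature can stand in for one planted feature
  # once accuracy saturates; full containment is checked at larger n in
  # the calibration suite
  pm <- planted_matrix(12, 28, d = c(Mpenpressure = 3, SDpentilt = 3),
                       seed = 5)
  sel <- selectModel(pm$x, pm$labels)
  expect_true(any(c("Mpenpressure", "SDpentilt") %in% sel$features))
  expect_gte(cvMetrics(sel$cv)["accuracy"], 0.95)
})

test_that("exhaustive search bounds the greedy search on 5 candidates", {
  pm <- planted_matrix(8, 16, d = c(Mpenpressure = 2.5), seed = 8)
  cand <- featureNames16()[1:5]
  g <- selectModel(pm$x[, cand], pm$labels, search = "greedy")
  e <- selectModel(pm$x[, cand], pm$labels, search = "exhaustive")
  score <- function(sel) sum(cvPredictions(sel$cv)$predicted ==
                               cvPredictions(sel$cv)$label)
  expect_gte(score(e), score(g))
})

test_that("nested LOOCV reports a defined accuracy and subset sizes", {
  pm <- planted_matrix(6, 14, d = c(Mpenpressure = 3), seed = 3)
  nested <- nestedLoocvAccuracy(pm$x[, featureNames16()[1:4]], pm$labels)
  expect_true(nested$accuracy >= 0 && nested$accuracy <= 1)
  expect_equal(length(nested$subset_sizes), 20)
  expect_equal(nested$majority_rate, 14 / 20)
})
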