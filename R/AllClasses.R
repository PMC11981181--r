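#' @import methods
#' @importFrom stats cor sd rnorm runif optim pchisq pt predict
#' @importFrom utils read.csv write.csv modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' Canonical names of the sixteen drawing features
#'
#' The per-shape feature vector holds three pen-pressure statistics, three
#' pen-tip kinematic statistics, six pen-barrel pose statistics (tilt and
#' orientation), and four gaze-coupling correlations (demonstration and
#' drawing phases, horizontal and vertical).
#'
#' @return Character vector of length 16, in canonical order.
#' @export
featureNames16 <- function() {
  c("Mpenpressure", "SDpenpressure", "Mpenpressurechange",
    "Mdrawingspeed", "SDdrawingspeed", "Mdrawingacceleration",
    "Mpentilt", "SDpentilt", "Mpentiltchange",
    "Mpenorientation", "SDpenorientation", "Mpenorientationchange",
    "Corrdemoeyehorizontal", "Corrdemoeyevertical",
    "Corrdrawingeyehorizontal", "Corrdrawingeyevertical")
}

#' Shape identifiers of the drawing battery
#'
#' The four shapes of the task, in presentation order of increasing
#' complexity.
#'
#' @return Character vector of the four shape ids.
#' @export
shapeIds <- function() {
  c("equilateral_triangle", "inverted_triangle", "square", "sun")
}

.PEN_FEATURES <- function() featureNames16()[1:12]
.CORR_FEATURES <- function() featureNames16()[13:16]

#' DrawingRecording: one synchronized stylus + gaze time series
#'
#' Holds the 30 Hz multichannel recording for one participant, one shape
#' and one phase (demonstration or drawing). Channels: time (s), pen-tip
#' x/y (relative screen coordinates in \[0,1\]), pressure (\[0,1\]; 0 means
#' pen lifted), azimuth (degrees \[0,360)), tilt (degrees \[0,90\]), gaze
#' rotation about the vertical and horizontal axes (degrees \[-90,90\],
#' `NA` allowed), and, for the demonstration phase, the advancing-line tip
#' position `line_x`/`line_y`.
#'
#' @slot participantId single participant identifier.
#' @slot shapeId one of [shapeIds()].
#' @slot phase `"demo"` or `"drawing"`.
#' @slot samples data.frame with columns `t, x, y, pressure, azimuth,
#'   tilt, gaze_x, gaze_y` and, for demo phase, `line_x, line_y`.
#'
#' @export
setClass("DrawingRecording",
  representation(
    participantId = "character",
    shapeId = "character",
    phase = "character",
    samples = "data.frame"
  )
)

.check_range <- function(v, lo, hi, name, allow_na = FALSE) {
  bad <- if (allow_na) which(!is.na(v) & (v < lo | v > hi)) else
    which(is.na(v) | v < lo | v > hi)
  if (length(bad)) {
    sprintf("column '%s' out of range [%g,%g] at row(s) %s", name, lo, hi,
            paste(utils::head(bad, 5), collapse = ", "))
  } else NULL
}

setValidity("DrawingRecording", function(object) {
  msgs <- character()
  if (length(object@participantId) != 1L)
    msgs <- c(msgs, "participantId must be a single string")
  if (!(object@phase %in% c("demo", "drawing")))
    msgs <- c(msgs, "phase must be 'demo' or 'drawing'")
  if (!(object@shapeId %in% shapeIds()))
    msgs <- c(msgs, sprintf("unknown shapeId '%s'", object@shapeId))
  s <- object@samples
  need <- c("t", "x", "y", "pressure", "azimuth", "tilt", "gaze_x", "gaze_y")
  miss <- setdiff(need, names(s))
  if (length(miss))
    return(sprintf("missing sample column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(s) > 1 && any(diff(s$t) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  msgs <- c(msgs,
    .check_range(s$x, 0, 1, "x"),
    .check_range(s$y, 0, 1, "y"),
    .check_range(s$pressure, 0, 1, "pressure"),
    .check_range(s$tilt, 0, 90, "tilt"),
    .check_range(s$gaze_x, -90, 90, "gaze_x", allow_na = TRUE),
    .check_range(s$gaze_y, -90, 90, "gaze_y", allow_na = TRUE))
  if (any(is.na(s$azimuth) | s$azimuth < 0 | s$azimuth >= 360))
    msgs <- c(msgs, "column 'azimuth' out of range [0,360)")
  if (object@phase == "demo") {
    if (!all(c("line_x", "line_y") %in% names(s)))
      msgs <- c(msgs, "demo phase requires line_x/line_y columns")
    else
      msgs <- c(msgs, .check_range(s$line_x, 0, 1, "line_x"),
                .check_range(s$line_y, 0, 1, "line_y"))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a DrawingRecording
#'
#' @param participantId single participant identifier.
#' @param shapeId one of [shapeIds()].
#' @param phase `"demo"` or `"drawing"`.
#' @param samples data.frame of channel samples (see
#'   [DrawingRecording-class]).
#' @return A validated `DrawingRecording`.
#' @export
DrawingRecording <- function(participantId, shapeId, phase, samples) {
  new("DrawingRecording", participantId = as.character(participantId),
      shapeId = shapeId, phase = phase,
      samples = as.data.frame(samples))
}

#' @describeIn DrawingRecording-class number of samples
#' @param x a `DrawingRecording`
#' @export
setMethod("length", "DrawingRecording", function(x) nrow(x@samples))

setMethod("show", "DrawingRecording", function(object) {
  cat(sprintf("DrawingRecording: participant %s, %s, %s phase\n",
              object@participantId, object@shapeId, object@phase))
  s <- object@samples
  cat(sprintf("  %d samples spanning %.2f s; %d pen-down (pressure > 0)\n",
              nrow(s), if (nrow(s)) diff(range(s$t)) else 0,
              sum(s$pressure > 0)))
  cat(sprintf("  gaze present on %d samples\n", sum(!is.na(s$gaze_x))))
})

#' @rdname recordingSamples
#' @export
setGeneric("recordingSamples", function(x) standardGeneric("recordingSamples"))

#' Extract the sample table of a recording
#'
#' @param x a `DrawingRecording`
#' @return data.frame of time samples.
#' @export
setMethod("recordingSamples", "DrawingRecording", function(x) x@samples)

#' @rdname recordingPhase
#' @export
setGeneric("recordingPhase", function(x) standardGeneric("recordingPhase"))

#' Phase of a recording (demo or drawing)
#'
#' @param x a `DrawingRecording`
#' @return `"demo"` or `"drawing"`.
#' @export
setMethod("recordingPhase", "DrawingRecording", function(x) x@phase)

#' DrawingFeatureSet: per-shape feature matrices with cohort metadata
#'
#' Extends `SummarizedExperiment`. Rows are shape-suffixed features (16
#' features x 4 shapes = 64 when all shapes are present); columns are
#' participants. `rowData` carries `feature` and `shape`; `colData`
#' carries the cohort table (`sex`, `age_years`, `srs2_score`, `group`).
#' The assay `"features"` holds the feature values; the assay `"valid"`
#' flags whether each value was computable from the recording (invalid
#' gaze correlations are imputed with 0 and flagged `FALSE`).
#'
#' @export
setClass("DrawingFeatureSet", contains = "SummarizedExperiment")

setValidity("DrawingFeatureSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("feature", "shape") %in% names(rd)))
    return("rowData must contain 'feature' and 'shape'")
  if (!all(rd$feature %in% featureNames16()))
    return("rowData$feature contains unknown feature names")
  if (!all(rd$shape %in% shapeIds()))
    return("rowData$shape contains unknown shape ids")
  if (!("features" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'features' is required")
  TRUE
})

#' ScreeningModel: a fitted linear screening classifier
#'
#' A linear soft-margin SVM fitted on standardized features, together
#' with its Platt sigmoid calibration. The decision function is
#' `f(x) = w . z(x) + b` where `z` standardizes with the stored training
#' center/scale; `f > 0` predicts the high-trait class.
#'
#' @slot features character, the selected feature names (row order of the
#'   training matrix).
#' @slot cost numeric, soft-margin cost parameter.
#' @slot weights numeric, linear weights on standardized features.
#' @slot bias numeric(1), intercept of the decision function.
#' @slot center,scale numeric, training standardization parameters.
#' @slot plattA,plattB numeric(1), sigmoid calibration
#'   `P(high|f) = 1/(1+exp(A f + B))`.
#' @slot levels character(2), class labels `c(positive, negative)`.
#'
#' @export
setClass("ScreeningModel",
  representation(
    features = "character", cost = "numeric",
    weights = "numeric", bias = "numeric",
    center = "numeric", scale = "numeric",
    plattA = "numeric", plattB = "numeric",
    levels = "character"
  )
)

setValidity("ScreeningModel", function(object) {
  if (length(object@features) < 1L) return("empty feature set")
  if (object@cost <= 0) return("cost must be > 0")
  if (length(object@weights) != length(object@features))
    return("weights/features length mismatch")
  TRUE
})

setMethod("show", "ScreeningModel", function(object) {
  cat("ScreeningModel (linear SVM)\n")
  cat(sprintf("  cost: %g; positive class: %s\n", object@cost,
              object@levels[1]))
  cat(sprintf("  %d feature(s): %s\n", length(object@features),
              paste(object@features, collapse = " + ")))
})

#' CVResult: leave-one-out cross-validation outcome
#'
#' Confusion counts over the held-out predictions (positive class =
#' high-trait group), the derived accuracy, sensitivity and specificity,
#' and the per-participant predicted label and calibrated probability of
#' the high-trait class.
#'
#' @slot counts named integer `tp, fn, tn, fp`.
#' @slot accuracy,sensitivity,specificity proportions in \[0,1\].
#' @slot predictions data.frame with `participant_id`, `label`,
#'   `predicted`, `probability` (NA when probabilities were not requested).
#'
#' @export
setClass("CVResult",
  representation(
    counts = "integer",
    accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
    predictions = "data.frame"
  )
)

setValidity("CVResult", function(object) {
  if (!identical(sort(names(object@counts)), c("fn", "fp", "tn", "tp")))
    return("counts must be named tp, fn, tn, fp")
  if (any(object@counts < 0L)) return("negative confusion counts")
  TRUE
})

setMethod("show", "CVResult", function(object) {
  k <- object@counts
  cat("Leave-one-out cross-validation result\n")
  cat(sprintf("  tp=%d fn=%d tn=%d fp=%d\n", k["tp"], k["fn"], k["tn"],
              k["fp"]))
  cat(sprintf("  accuracy=%.3f sensitivity=%.3f specificity=%.3f\n",
              object@accuracy, object@sensitivity, object@specificity))
})

#' @rdname cvMetrics
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' Accuracy, sensitivity and specificity of a CVResult
#'
#' @param x a `CVResult`
#' @return named numeric vector `accuracy, sensitivity, specificity`.
#' @export
setMethod("cvMetrics", "CVResult", function(x) {
  c(accuracy = x@accuracy, sensitivity = x@sensitivity,
    specificity = x@specificity)
})

#' @rdname cvCounts
#' @export
setGeneric("cvCounts", function(x) standardGeneric("cvCounts"))

#' Confusion counts of a CVResult
#'
#' @param x a `CVResult`
#' @return named integer vector `tp, fn, tn, fp`.
#' @export
setMethod("cvCounts", "CVResult", function(x) x@counts[c("tp", "fn", "tn", "fp")])

#' @rdname cvPredictions
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' Per-participant held-out predictions of a CVResult
#'
#' @param x a `CVResult`
#' @return data.frame with participant_id, label, predicted, probability.
#' @export
setMethod("cvPredictions", "CVResult", function(x) x@predictions)

#' ShapMatrix: exact Shapley attributions of a linear model
#'
#' Per-participant, per-feature additive contributions to the decision
#' function, plus the base value (expected decision value over the
#' background cohort). For a linear model the Shapley value has the
#' closed form `phi_ij = w_j (x_ij - mean_j(background))`, so local
#' accuracy `base + sum_j phi_ij = f(x_i)` holds exactly.
#'
#' @slot values numeric matrix, participants x features.
#' @slot baseValue numeric(1).
#'
#' @export
setClass("ShapMatrix",
  representation(values = "matrix", baseValue = "numeric")
)

setMethod("show", "ShapMatrix", function(object) {
  cat(sprintf("ShapMatrix: %d participants x %d features; base value %.4f\n",
              nrow(object@values), ncol(object@values), object@baseValue))
  imp <- sort(colMeans(abs(object@values)), decreasing = TRUE)
  top <- utils::head(imp, 3)
  cat("  top mean |contribution|:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
})

#' @rdname shapValues
#' @export
setGeneric("shapValues", function(x) standardGeneric("shapValues"))

#' Attribution matrix of a ShapMatrix
#'
#' @param x a `ShapMatrix`
#' @return numeric matrix (participants x features).
#' @export
setMethod("shapValues", "ShapMatrix", function(x) x@values)

#' @rdname shapBaseValue
#' @export
setGeneric("shapBaseValue", function(x) standardGeneric("shapBaseValue"))

#' Base (expected) decision value of a ShapMatrix
#'
#' @param x a `ShapMatrix`
#' @return numeric(1).
#' @export
setMethod("shapBaseValue", "ShapMatrix", function(x) x@baseValue)
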