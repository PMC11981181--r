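# Extraction of the sixteen per-shape drawing features: pressure,
# pen-tip kinematics, pen-barrel pose (tilt linear, orientation
# circular), and gaze-pen / gaze-line coupling correlations.

#' Feature-extraction configuration
#'
#' @param pressure_threshold contact threshold for segmentation.
#' @param min_len minimum segment length (samples).
#' @param change `"absolute"` (default) or `"signed"`: whether the
#'   mean-change features average |x_{t+1} - x_t| or the signed
#'   difference. Signed means telescope to ~0, so absolute is the
#'   informative default.
#' @param per_second divide change features by the sampling interval
#'   (default `FALSE`: change is per sample).
#' @param orientation_stats `"circular"` (default) or `"linear"`:
#'   circular mean/SD and wrapped differences for azimuth, or naive
#'   arithmetic on \[0,360).
#' @param min_corr_pairs minimum time-aligned non-missing pairs for the
#'   gaze-coupling correlations (default 10).
#' @param corr_impute value substituted for an invalid correlation
#'   feature (default 0: no linear coupling); the validity flag records
#'   the imputation.
#' @return Named list of options.
#' @export
featureConfig <- function(pressure_threshold = 0, min_len = 3L,
                          change = c("absolute", "signed"),
                          per_second = FALSE,
                          orientation_stats = c("circular", "linear"),
                          min_corr_pairs = 10L, corr_impute = 0) {
  list(pressure_threshold = pressure_threshold, min_len = as.integer(min_len),
       change = match.arg(change), per_second = per_second,
       orientation_stats = match.arg(orientation_stats),
       min_corr_pairs = as.integer(min_corr_pairs),
       corr_impute = corr_impute)
}

# per-segment sample tables
.segment_list <- function(recording, segments) {
  lapply(seq_len(nrow(segments)), function(i)
    recording@samples[segments$start[i]:segments$end[i], , drop = FALSE])
}

.mean_change <- function(xs, diff_fun, cfg) {
  # xs: list of per-segment vectors; no difference crosses a boundary
  d <- unlist(lapply(xs, function(v) if (length(v) >= 2) diff_fun(v) else numeric(0)))
  if (!length(d)) return(NA_real_)
  if (cfg$change == "absolute") mean(abs(d)) else mean(d)
}

#' Pen-pressure features of a segmented recording
#'
#' Mean and sample SD (n-1 divisor) of pressure over all active samples
#' pooled across segments, and the mean change in pressure: the average
#' absolute per-sample first difference |p_{t+1} - p_t| over consecutive
#' within-segment pairs (no pair spans a pen-up gap).
#'
#' @param recording a drawing-phase `DrawingRecording`.
#' @param segments segmentation as from [segmentActiveDrawing()];
#'   computed with `cfg` defaults when omitted.
#' @param cfg a [featureConfig()].
#' @return Named numeric: `Mpenpressure, SDpenpressure,
#'   Mpenpressurechange`.
#' @export
pressureFeatures <- function(recording, segments = NULL,
                             cfg = featureConfig()) {
  if (is.null(segments))
    segments <- segmentActiveDrawing(recording, cfg$pressure_threshold,
                                     cfg$min_len)
  segs <- .segment_list(recording, segments)
  p <- unlist(lapply(segs, `[[`, "pressure"))
  if (length(p) < 2) stop("insufficient data: need >= 2 active samples")
  ch <- .mean_change(lapply(segs, `[[`, "pressure"), diff, cfg)
  if (cfg$per_second) ch <- ch * .SAMPLE_RATE
  c(Mpenpressure = mean(p), SDpenpressure = stats::sd(p),
    Mpenpressurechange = ch)
}

# per-pair speeds within one segment: Euclidean step length / actual dt
.segment_speeds <- function(seg) {
  if (nrow(seg) < 2) return(numeric(0))
  sqrt(diff(seg$x)^2 + diff(seg$y)^2) / diff(seg$t)
}

#' Pen-tip kinematic features of a segmented recording
#'
#' Drawing speed is the length of line drawn per unit time between
#' consecutive pen-down samples (screen units/s), computed within
#' segments only. `Mdrawingspeed`/`SDdrawingspeed` are the mean and
#' sample SD of the per-pair speeds; `Mdrawingacceleration` is the mean
#' absolute change in speed between consecutive speed pairs.
#'
#' @inheritParams pressureFeatures
#' @return Named numeric: `Mdrawingspeed, SDdrawingspeed,
#'   Mdrawingacceleration`.
#' @export
kinematicsFeatures <- function(recording, segments = NULL,
                               cfg = featureConfig()) {
  if (is.null(segments))
    segments <- segmentActiveDrawing(recording, cfg$pressure_threshold,
                                     cfg$min_len)
  segs <- .segment_list(recording, segments)
  vlist <- lapply(segs, .segment_speeds)
  v <- unlist(vlist)
  if (length(v) < 2 || !any(vapply(segs, nrow, 1L) >= 3))
    stop("insufficient data: need >= 3 active samples in some segment")
  acc <- .mean_change(vlist, diff, cfg)
  if (isTRUE(cfg$per_second)) acc <- acc * .SAMPLE_RATE
  c(Mdrawingspeed = mean(v), SDdrawingspeed = stats::sd(v),
    Mdrawingacceleration = acc)
}

.circ_mean_deg <- function(a) {
  r <- a * pi / 180
  out <- (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
  if (out >= 360) out <- 0   # guard the floating-point wrap at 360
  out
}

.circ_sd_deg <- function(a) {
  r <- a * pi / 180
  R <- min(sqrt(mean(sin(r))^2 + mean(cos(r))^2), 1)
  sqrt(max(-2 * log(R), 0)) * 180 / pi
}

# angular differences wrapped to [-180, 180]
.wrap_diff <- function(a) {
  (diff(a) + 180) %% 360 - 180
}

#' Pen-barrel pose features of a segmented recording
#'
#' Tilt (altitude, 0-90 degrees) is treated linearly: mean, sample SD and
#' mean absolute per-sample change. Orientation (azimuth, 0-360 degrees)
#' is circular by default: mean direction, circular SD in degrees
#' (sqrt(-2 log R)), and mean absolute angular difference wrapped to
#' \[0,180\]. Set `orientation_stats = "linear"` in the config for naive
#' arithmetic on the raw angles.
#'
#' @inheritParams pressureFeatures
#' @return Named numeric: `Mpentilt, SDpentilt, Mpentiltchange,
#'   Mpenorientation, SDpenorientation, Mpenorientationchange`.
#' @export
poseFeatures <- function(recording, segments = NULL, cfg = featureConfig()) {
  if (is.null(segments))
    segments <- segmentActiveDrawing(recording, cfg$pressure_threshold,
                                     cfg$min_len)
  segs <- .segment_list(recording, segments)
  tilt <- unlist(lapply(segs, `[[`, "tilt"))
  az <- unlist(lapply(segs, `[[`, "azimuth"))
  if (length(tilt) < 2) stop("insufficient data: need >= 2 active samples")
  tch <- .mean_change(lapply(segs, `[[`, "tilt"), diff, cfg)
  if (cfg$orientation_stats == "circular") {
    m_az <- .circ_mean_deg(az)
    sd_az <- .circ_sd_deg(az)
    och <- .mean_change(lapply(segs, `[[`, "azimuth"), .wrap_diff, cfg)
  } else {
    m_az <- mean(az)
    sd_az <- stats::sd(az)
    och <- .mean_change(lapply(segs, `[[`, "azimuth"), diff, cfg)
  }
  if (cfg$per_second) {
    tch <- tch * .SAMPLE_RATE
    och <- och * .SAMPLE_RATE
  }
  c(Mpentilt = mean(tilt), SDpentilt = stats::sd(tilt), Mpentiltchange = tch,
    Mpenorientation = m_az, SDpenorientation = sd_az,
    Mpenorientationchange = och)
}

#' Gaze-coupling correlations of one phase
#'
#' Product-moment correlation between the gaze-rotation channels and the
#' reference trajectory: the advancing line (`line_x`/`line_y`, all
#' frames) for a demo-phase recording, the pen tip restricted to active
#' (pen-down) samples for a drawing-phase recording. Pairs with missing
#' gaze are dropped pairwise. With fewer than `min_corr_pairs` valid
#' pairs or zero variance in either signal the feature is invalid and
#' imputed with `cfg$corr_impute`.
#'
#' @inheritParams pressureFeatures
#' @return Named numeric of length 2 (`horizontal`, `vertical`) with
#'   attribute `"valid"` (logical length 2).
#' @export
gazeCoupling <- function(recording, segments = NULL, cfg = featureConfig()) {
  s <- recording@samples
  if (recording@phase == "demo") {
    ref_x <- s$line_x; ref_y <- s$line_y
    gx <- s$gaze_x; gy <- s$gaze_y
  } else {
    if (is.null(segments))
      segments <- segmentActiveDrawing(recording, cfg$pressure_threshold,
                                       cfg$min_len)
    idx <- unlist(lapply(seq_len(nrow(segments)), function(i)
      segments$start[i]:segments$end[i]))
    ref_x <- s$x[idx]; ref_y <- s$y[idx]
    gx <- s$gaze_x[idx]; gy <- s$gaze_y[idx]
  }
  one <- function(g, ref) {
    ok <- !is.na(g) & !is.na(ref)
    if (sum(ok) < cfg$min_corr_pairs ||
        stats::sd(g[ok]) == 0 || stats::sd(ref[ok]) == 0)
      return(c(NA_real_, FALSE))
    c(stats::cor(g[ok], ref[ok]), TRUE)
  }
  h <- one(gx, ref_x); v <- one(gy, ref_y)
  out <- c(horizontal = h[1], vertical = v[1])
  valid <- c(horizontal = as.logical(h[2]), vertical = as.logical(v[2]))
  out[!valid] <- cfg$corr_impute
  attr(out, "valid") <- valid
  out
}

#' Extract the 16-feature vector for one participant x shape
#'
#' Combines the pressure, kinematic and pose features of the drawing
#' phase with the gaze-coupling correlations of both phases. Invalid
#' correlation features (too few gaze samples or a flat signal) are
#' imputed with `cfg$corr_impute` and flagged in the `"valid"` attribute.
#'
#' @param demo demo-phase `DrawingRecording` (or `NULL`: demo
#'   correlations flagged invalid).
#' @param drawing drawing-phase `DrawingRecording`.
#' @param cfg a [featureConfig()].
#' @return Named numeric of length 16 in [featureNames16()] order, with
#'   attribute `"valid"`.
#' @export
extractFeatures <- function(demo, drawing, cfg = featureConfig()) {
  stopifnot(is(drawing, "DrawingRecording"))
  segments <- segmentActiveDrawing(drawing, cfg$pressure_threshold,
                                   cfg$min_len)
  if (nrow(segments) == 0)
    stop(sprintf("no active drawing (participant %s, shape %s)",
                 drawing@participantId, drawing@shapeId))
  out <- c(pressureFeatures(drawing, segments, cfg),
           kinematicsFeatures(drawing, segments, cfg),
           poseFeatures(drawing, segments, cfg))
  valid <- rep(TRUE, 12)
  if (!is.null(demo)) {
    dc <- gazeCoupling(demo, cfg = cfg)
    demo_corr <- as.numeric(dc)
    demo_valid <- attr(dc, "valid")
  } else {
    demo_corr <- c(cfg$corr_impute, cfg$corr_impute)
    demo_valid <- c(FALSE, FALSE)
  }
  wc <- gazeCoupling(drawing, segments, cfg)
  out <- c(out,
           Corrdemoeyehorizontal = demo_corr[1],
           Corrdemoeyevertical = demo_corr[2],
           Corrdrawingeyehorizontal = as.numeric(wc)[1],
           Corrdrawingeyevertical = as.numeric(wc)[2])
  valid <- c(valid, demo_valid, attr(wc, "valid"))
  names(valid) <- featureNames16()
  out <- out[featureNames16()]
  attr(out, "valid") <- valid
  out
}

#' Extract a per-shape feature sheet from a set of recordings
#'
#' @param recordings list of `DrawingRecording` (both phases), e.g. from
#'   [generateCohort()].
#' @param cohort cohort data.frame with `participant_id` and `group`.
#' @param shape single shape id.
#' @param cfg a [featureConfig()].
#' @return data.frame: `participant_id`, `group`, the 16 features.
#' @export
extractFeatureSheet <- function(recordings, cohort, shape,
                                cfg = featureConfig()) {
  stopifnot(shape %in% shapeIds())
  rows <- lapply(cohort$participant_id, function(pid) {
    demo <- recordings[[sprintf("%s_%s_demo", pid, shape)]]
    draw <- recordings[[sprintf("%s_%s_drawing", pid, shape)]]
    if (is.null(draw))
      stop(sprintf("missing drawing recording for %s / %s", pid, shape))
    fv <- extractFeatures(demo, draw, cfg)
    as.data.frame(as.list(fv))
  })
  out <- do.call(rbind, rows)
  data.frame(participant_id = cohort$participant_id,
             group = factor(cohort$group, levels = c("high", "low")),
             out, stringsAsFactors = FALSE)
}

#' Assemble per-shape sheets into a DrawingFeatureSet
#'
#' Stacks the per-shape feature sheets into one shape-suffixed feature
#' matrix (features x participants) inside a `SummarizedExperiment`
#' subclass, with the cohort table as `colData`. Row names are
#' `<feature>_<shape>`.
#'
#' @param sheets named list of per-shape feature sheets (names = shape
#'   ids), as from [extractFeatureSheet()].
#' @param cohort cohort data.frame (participant_id, sex, age_years,
#'   srs2_score, group); optional columns are carried through.
#' @return A [DrawingFeatureSet-class].
#' @export
buildFeatureSet <- function(sheets, cohort) {
  stopifnot(length(sheets) >= 1, !is.null(names(sheets)))
  pids <- sheets[[1]]$participant_id
  mats <- lapply(names(sheets), function(sh) {
    s <- sheets[[sh]]
    stopifnot(identical(s$participant_id, pids))
    m <- t(as.matrix(s[, featureNames16()]))
    rownames(m) <- paste(featureNames16(), sh, sep = "_")
    m
  })
  mat <- do.call(rbind, mats)
  colnames(mat) <- pids
  rd <- S4Vectors::DataFrame(
    feature = rep(featureNames16(), length(sheets)),
    shape = rep(names(sheets), each = 16L))
  cd_src <- if (!is.null(cohort)) cohort[match(pids, cohort$participant_id), ]
            else data.frame(participant_id = pids,
                            group = sheets[[1]]$group)
  cd <- S4Vectors::DataFrame(cd_src, row.names = pids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), rowData = rd, colData = cd)
  methods::new("DrawingFeatureSet", se)
}

#' Feature matrix for one shape (or all shapes) from a DrawingFeatureSet
#'
#' @param fs a `DrawingFeatureSet`.
#' @param shape a shape id, or `"all"` for the full shape-suffixed
#'   matrix.
#' @return Numeric matrix, participants x features.
#' @export
featureMatrix <- function(fs, shape = "all") {
  rd <- SummarizedExperiment::rowData(fs)
  keep <- if (identical(shape, "all")) seq_len(nrow(fs)) else
    which(rd$shape == shape)
  if (!length(keep)) stop(sprintf("no features for shape '%s'", shape))
  m <- t(SummarizedExperiment::assay(fs, "features")[keep, , drop = FALSE])
  if (!identical(shape, "all"))
    colnames(m) <- rd$feature[keep]
  m
}
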