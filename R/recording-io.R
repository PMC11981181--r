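# CSV ingestion of stylus recordings and feature sheets, plus the
# stroke segmentation that defines "active drawing".

.RECORDING_COLS <- c("participant_id", "shape", "phase", "t", "x", "y",
                     "pressure", "azimuth", "tilt", "gaze_x", "gaze_y",
                     "line_x", "line_y")

#' Default column-alias dialect for recording CSVs
#'
#' Maps the canonical recording column names to accepted aliases, so
#' exports with differing headers (e.g. `time`, `pen_x`, `px`) can be
#' ingested without editing the file. Extend or override entries via the
#' `dialect` argument of [readRecording()].
#'
#' @return Named list: canonical name -> character vector of aliases.
#' @export
recordingDialect <- function() {
  list(
    participant_id = c("participant_id", "participant", "id", "subject"),
    shape = c("shape", "shape_id"),
    phase = c("phase",  "stage"),
    t = c("t", "time", "timestamp", "time_s"),
    x = c("x", "pen_x", "px"),
    y = c("y", "pen_y", "py"),
    pressure = c("pressure", "pen_pressure", "p"),
    azimuth = c("azimuth", "orientation", "pen_orientation"),
    tilt = c("tilt", "altitude", "pen_tilt"),
    gaze_x = c("gaze_x", "eye_x", "gaze_rotation_x"),
    gaze_y = c("gaze_y", "eye_y", "gaze_rotation_y"),
    line_x = c("line_x", "demo_line_x"),
    line_y = c("line_y", "demo_line_y")
  )
}

.resolve_columns <- function(header, dialect, mandatory) {
  lh <- tolower(header)
  out <- vapply(names(dialect), function(canon) {
    hit <- which(lh %in% tolower(dialect[[canon]]))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  miss <- mandatory[is.na(out[mandatory])]
  if (length(miss))
    stop(sprintf("schema error: missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  out
}

#' Read a drawing recording from CSV
#'
#' Expects one recording (one participant x shape x phase) per file, in
#' the canonical schema `participant_id, shape, phase, t, x, y, pressure,
#' azimuth, tilt, gaze_x, gaze_y, line_x, line_y` (empty string = missing
#' gaze). Header names are resolved through the alias `dialect`. Range
#' violations are reported with their row numbers; blank gaze values load
#' as `NA` and are dropped pairwise by the correlation features.
#'
#' @param path CSV file path.
#' @param dialect alias map, see [recordingDialect()].
#' @return A validated `DrawingRecording`.
#' @export
readRecording <- function(path, dialect = recordingDialect()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("participant_id", "shape", "phase", "t", "x", "y",
                 "pressure", "azimuth", "tilt")
  idx <- .resolve_columns(names(raw), dialect, mandatory)
  get_col <- function(canon, default = NA_real_) {
    if (is.na(idx[canon])) return(rep(default, nrow(raw)))
    v <- raw[[idx[canon]]]
    if (is.character(v)) v[v == ""] <- NA
    suppressWarnings(as.numeric(v))
  }
  phase <- as.character(raw[[idx["phase"]]][1])
  samples <- data.frame(
    t = get_col("t"), x = get_col("x"), y = get_col("y"),
    pressure = get_col("pressure"), azimuth = get_col("azimuth"),
    tilt = get_col("tilt"), gaze_x = get_col("gaze_x"),
    gaze_y = get_col("gaze_y"))
  if (phase == "demo") {
    samples$line_x <- get_col("line_x")
    samples$line_y <- get_col("line_y")
  }
  if (any(diff(samples$t) <= 0))
    stop(sprintf("data error in %s: time not strictly increasing at row %d",
                 path, which(diff(samples$t) <= 0)[1] + 1L))
  .report_range_errors(samples, path)
  DrawingRecording(as.character(raw[[idx["participant_id"]]][1]),
                   as.character(raw[[idx["shape"]]][1]), phase, samples)
}

.report_range_errors <- function(s, path) {
  checks <- list(
    c("x", 0, 1), c("y", 0, 1), c("pressure", 0, 1),
    c("tilt", 0, 90))
  for (ck in checks) {
    v <- s[[ck[1]]]
    bad <- which(is.na(v) | v < as.numeric(ck[2]) | v > as.numeric(ck[3]))
    if (length(bad))
      stop(sprintf("range error in %s: column '%s' outside [%s,%s] at row %s",
                   path, ck[1], ck[2], ck[3],
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  bad <- which(is.na(s$azimuth) | s$azimuth < 0 | s$azimuth >= 360)
  if (length(bad))
    stop(sprintf("range error in %s: column 'azimuth' outside [0,360) at row %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  for (g in c("gaze_x", "gaze_y")) {
    v <- s[[g]]
    bad <- which(!is.na(v) & (v < -90 | v > 90))
    if (length(bad))
      stop(sprintf("range error in %s: column '%s' outside [-90,90] at row %s",
                   path, g, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a drawing recording to CSV
#'
#' Inverse of [readRecording()]; missing gaze is written as an empty
#' string.
#'
#' @param recording a `DrawingRecording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  s <- recording@samples
  out <- data.frame(
    participant_id = recording@participantId,
    shape = recording@shapeId,
    phase = recording@phase,
    s[, intersect(.RECORDING_COLS, names(s))],
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-shape feature sheet
#'
#' Expects columns `participant_id`, `group` and the 16 feature names of
#' [featureNames16()] (matched case-insensitively through `aliases`).
#' Group labels are binarized to `high`/`low`.
#'
#' @param path CSV path.
#' @param aliases optional named list mapping canonical feature names to
#'   accepted aliases (e.g. to absorb spelling variants such as
#'   `Corrdemoeyevartical`).
#' @return data.frame with `participant_id`, `group` (factor high/low)
#'   and the 16 features in canonical order.
#' @export
readFeatureSheet <- function(path, aliases = featureSheetAliases()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  lh <- tolower(names(raw))
  find_col <- function(canon) {
    cand <- tolower(c(canon, aliases[[canon]]))
    hit <- which(lh %in% cand)
    if (!length(hit)) NA_integer_ else hit[1]
  }
  feat_idx <- vapply(featureNames16(), find_col, integer(1))
  if (any(is.na(feat_idx)))
    stop(sprintf("schema error: feature sheet missing column(s): %s (expected the 16 names %s)",
                 paste(featureNames16()[is.na(feat_idx)], collapse = ", "),
                 paste(featureNames16(), collapse = ", ")), call. = FALSE)
  grp_idx <- find_col("group")
  if (is.na(grp_idx)) stop("schema error: feature sheet missing 'group' column")
  pid_idx <- find_col("participant_id")
  out <- as.data.frame(lapply(raw[feat_idx], as.numeric))
  names(out) <- featureNames16()
  grp <- tolower(as.character(raw[[grp_idx]]))
  grp[grp %in% c("1", "true", "asd", "positive")] <- "high"
  grp[grp %in% c("0", "false", "td", "negative")] <- "low"
  if (!all(grp %in% c("high", "low")))
    stop("schema error: group labels not binarizable to high/low")
  data.frame(
    participant_id = if (is.na(pid_idx)) sprintf("P%03d", seq_len(nrow(raw)))
                     else as.character(raw[[pid_idx]]),
    group = factor(grp, levels = c("high", "low")),
    out, stringsAsFactors = FALSE)
}

#' Aliases accepted for feature-sheet columns
#'
#' @return Named list: canonical column -> aliases.
#' @export
featureSheetAliases <- function() {
  list(
    participant_id = c("participant", "id", "subject"),
    group = c("label", "class", "trait_group"),
    Corrdemoeyevertical = c("Corrdemoeyevartical"),
    Corrdrawingeyevertical = c("Corrdrawingeyevartical"),
    Mdrawingspeed = c("Drawingspeed", "Mdrawingspeed")
  )
}

#' Write a feature sheet to CSV
#'
#' @param features data.frame as returned by [readFeatureSheet()] or
#'   [extractFeatureSheet()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureSheet <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Segment a recording into active drawing strokes
#'
#' An active drawing segment is a maximal run of consecutive samples with
#' pen pressure above `pressure_threshold`, kept only if at least
#' `min_len` samples long. All pen features are computed within such
#' segments; no differencing crosses a segment boundary.
#'
#' @param recording a `DrawingRecording` with phase `"drawing"`.
#' @param pressure_threshold contact threshold (default 0: any positive
#'   pressure counts as contact).
#' @param min_len minimum run length in samples (default 3, i.e. 0.1 s at
#'   30 Hz).
#' @return data.frame with `start`, `end` (inclusive 1-based sample
#'   indices), in temporal order; zero rows if no run qualifies.
#' @examples
#' tpl <- shapeTemplates("equilateral_triangle")
#' prof <- drawingProfile()
#' rec <- generateDrawing(tpl, prof, seed = 7)
#' segmentActiveDrawing(rec)  # three strokes -> three segments
#' @export
segmentActiveDrawing <- function(recording, pressure_threshold = 0,
                                 min_len = 3L) {
  stopifnot(is(recording, "DrawingRecording"))
  if (recording@phase != "drawing")
    stop("segmentation applies to drawing-phase recordings")
  active <- recording@samples$pressure > pressure_threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Default latent drawing profile
#'
#' The base (population-average) latent parameters used by the synthetic
#' generator: pressure mean/SD/roughness, speed (screen units/s), speed
#' coefficient of variation and roughness, tilt and azimuth mean/SD/
#' roughness. Useful for constructing single recordings in examples and
#' tests.
#'
#' @param ... named overrides of individual parameters.
#' @return Named list of latent parameters.
#' @export
drawingProfile <- function(...) {
  prof <- as.list(stats::setNames(.PROFILE_PARAMS$base, .PROFILE_PARAMS$param))
  over <- list(...)
  bad <- setdiff(names(over), names(prof))
  if (length(bad))
    stop(sprintf("unknown profile parameter(s): %s", paste(bad, collapse = ", ")))
  utils::modifyList(prof, over)
}
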