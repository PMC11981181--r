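# Synthetic cohort generator: drawing sessions (stylus + gaze) and SRS-2
# metadata with controllable group effect sizes, so the downstream
# pipeline can be exercised and calibrated without clinical recordings.

.SAMPLE_RATE <- 30

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# derived substream seed, kept below 2^31
.substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629) + 1L
}

# latent drawing-profile parameters: base value, between-subject SD, and
# clamp range. Each of the 12 pen features maps onto one parameter, so a
# standardized shift d on a feature is applied as base + bsd * d.
.PROFILE_PARAMS <- data.frame(
  param = c("pressure_mean", "pressure_sd", "pressure_rough",
            "speed", "speed_cv", "speed_rough",
            "tilt_mean", "tilt_sd", "tilt_rough",
            "azimuth_mean", "azimuth_sd", "azimuth_rough"),
  feature = c("Mpenpressure", "SDpenpressure", "Mpenpressurechange",
              "Mdrawingspeed", "SDdrawingspeed", "Mdrawingacceleration",
              "Mpentilt", "SDpentilt", "Mpentiltchange",
              "Mpenorientation", "SDpenorientation", "Mpenorientationchange"),
  base = c(0.45, 0.07, 0.5, 0.10, 0.25, 0.5, 55, 4, 0.5, 200, 8, 0.5),
  bsd  = c(0.06, 0.02, 0.12, 0.02, 0.06, 0.12, 6, 1.2, 0.12, 18, 2.5, 0.12),
  lo   = c(0.10, 0.005, 0.05, 0.02, 0.03, 0.05, 10, 0.2, 0.05, -Inf, 0.3, 0.05),
  hi   = c(0.90, 0.20, 1.40, 0.40, 0.80, 1.40, 85, 15, 1.40, Inf, 40, 1.40),
  stringsAsFactors = FALSE
)

#' Default per-feature standardized group shifts
#'
#' The generator's default effect map: the standardized shift (Cohen's d,
#' in units of the between-subject SD of the corresponding latent
#' parameter) applied to the high-trait group for each of the twelve pen
#' features. The defaults encode the direction and rough magnitude of
#' group differences reported in the handwriting literature and implied
#' by the near-separable classification the screening models achieve:
#' heavier and more variable pressure, slower but more variable and
#' jerkier pen-tip movement, and less stable pen pose in the high-trait
#' group. Gaze coupling is controlled separately (see [cohortSpec()]).
#'
#' @return Named numeric vector over the 12 pen features.
#' @export
defaultEffectMap <- function() {
  c(Mpenpressure = 1.0, SDpenpressure = 1.2, Mpenpressurechange = 1.2,
    Mdrawingspeed = -1.0, SDdrawingspeed = 1.0, Mdrawingacceleration = 1.2,
    Mpentilt = 0.6, SDpentilt = 1.2, Mpentiltchange = 1.0,
    Mpenorientation = 0.4, SDpenorientation = 1.0,
    Mpenorientationchange = 1.2)
}

#' Specification of a synthetic cohort
#'
#' Bundles and validates the parameters of the synthetic cohort: group
#' sizes, sex ratio, the SRS-2 score distributions of the two trait
#' groups (T-score scale; defaults follow the observed cohort, high group
#' 68.15 +/- 23.68 with n = 20 and low group 32.06 +/- 11.26 with
#' n = 113), per-feature standardized effect sizes on the pen features,
#' and the target gaze-pen coupling correlations of the two groups.
#'
#' @param n_high,n_low group sizes (n_high + n_low >= 2).
#' @param sex_ratio proportion of boys (default 70/133 as observed).
#' @param srs_high_mean,srs_high_sd,srs_low_mean,srs_low_sd SRS-2 T-score
#'   distribution parameters per group.
#' @param effect_map named numeric vector of standardized shifts (d) for
#'   a subset of the 12 pen features; see [defaultEffectMap()].
#' @param gaze_coupling_high,gaze_coupling_low target gaze-pen
#'   correlation per group, in \[-1,1\].
#' @param coupling_sd between-participant SD of the coupling value.
#' @param seed integer random-stream identifier.
#' @return A validated `CohortSpec` (list).
#' @export
cohortSpec <- function(n_high = 20, n_low = 113, sex_ratio = 70 / 133,
                       srs_high_mean = 68.15, srs_high_sd = 23.68,
                       srs_low_mean = 32.06, srs_low_sd = 11.26,
                       effect_map = defaultEffectMap(),
                       gaze_coupling_high = 0.45, gaze_coupling_low = 0.75,
                       coupling_sd = 0.12, seed = 1L) {
  spec <- list(n_high = n_high, n_low = n_low, sex_ratio = sex_ratio,
               srs_high_mean = srs_high_mean, srs_high_sd = srs_high_sd,
               srs_low_mean = srs_low_mean, srs_low_sd = srs_low_sd,
               effect_map = effect_map,
               gaze_coupling_high = gaze_coupling_high,
               gaze_coupling_low = gaze_coupling_low,
               coupling_sd = coupling_sd, seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  validateCohortSpec(spec)
  spec
}

#' Validate a CohortSpec
#'
#' @param spec a `CohortSpec` as returned by [cohortSpec()].
#' @return `spec`, invisibly; errors name the offending field.
#' @export
validateCohortSpec <- function(spec) {
  stop_field <- function(field, why)
    stop(sprintf("invalid CohortSpec: field '%s' %s", field, why),
         call. = FALSE)
  if (spec$n_high < 0) stop_field("n_high", "must be >= 0")
  if (spec$n_low < 0) stop_field("n_low", "must be >= 0")
  if (spec$n_high + spec$n_low < 2)
    stop_field("n_high", "n_high + n_low must be >= 2")
  if (spec$sex_ratio < 0 || spec$sex_ratio > 1)
    stop_field("sex_ratio", "must be in [0,1]")
  for (f in c("srs_high_sd", "srs_low_sd", "coupling_sd"))
    if (spec[[f]] <= 0) stop_field(f, "must be > 0")
  for (f in c("gaze_coupling_high", "gaze_coupling_low"))
    if (abs(spec[[f]]) > 1) stop_field(f, "must be in [-1,1]")
  if (length(spec$effect_map)) {
    if (is.null(names(spec$effect_map)) ||
        !all(names(spec$effect_map) %in% .PROFILE_PARAMS$feature))
      stop_field("effect_map",
                 "must be named with pen feature names (first 12 of featureNames16())")
  }
  invisible(spec)
}

# draw one participant's latent drawing profile
.draw_profile <- function(group, effect_map) {
  p <- .PROFILE_PARAMS
  d <- rep(0, nrow(p))
  if (length(effect_map)) {
    idx <- match(names(effect_map), p$feature)
    d[idx] <- effect_map
  }
  shift <- if (group == "high") d else rep(0, nrow(p))
  val <- p$base + p$bsd * (stats::rnorm(nrow(p)) + shift)
  val <- pmin(pmax(val, p$lo), p$hi)
  prof <- as.list(val)
  names(prof) <- p$param
  prof$azimuth_mean <- prof$azimuth_mean %% 360
  prof
}

# AR(1) series with standard-normal marginal; lag-1 correlation derived
# from the roughness parameter r via rho = 1 - r^2/2, so that the mean
# absolute first difference is proportional to r.
.ar1 <- function(n, rough) {
  rho <- max(min(1 - rough^2 / 2, 0.999), -0.999)
  z <- stats::rnorm(n)
  e <- numeric(n)
  if (n == 0) return(e)
  e[1] <- z[1]
  if (n > 1) for (i in 2:n) e[i] <- rho * e[i - 1] + sqrt(1 - rho^2) * z[i]
  e
}

#' Generate one synthetic drawing recording
#'
#' Traces each stroke polyline of the template at 30 Hz with per-sample
#' speed, pressure, tilt and azimuth drawn from the participant's latent
#' profile (autocorrelated within-stroke noise). Strokes are separated by
#' pen-up gaps of 0.2-0.5 s during which pressure is exactly 0, so that
#' stroke segmentation is exercised downstream. Gaze channels are left
#' `NA`; fill them with [generateGaze()].
#'
#' @param template a shape template (see [shapeTemplates()]).
#' @param profile named list of latent parameters: `pressure_mean`,
#'   `pressure_sd`, `pressure_rough`, `speed` (screen units/s),
#'   `speed_cv`, `speed_rough`, `tilt_mean`, `tilt_sd`, `tilt_rough`
#'   (degrees), `azimuth_mean`, `azimuth_sd`, `azimuth_rough` (degrees).
#' @param seed integer seed.
#' @param participant_id identifier stored on the recording.
#' @return A `DrawingRecording` with phase `"drawing"`.
#' @export
generateDrawing <- function(template, profile, seed = 1L,
                            participant_id = "sim") {
  .validate_template(template)
  .with_seed(seed, {
    dt <- 1 / .SAMPLE_RATE
    rows <- list()
    last_xy <- NULL
    for (si in seq_along(template$strokes)) {
      stroke <- template$strokes[[si]]
      L <- .polyline_length(stroke)
      n_max <- ceiling(2 * L / (profile$speed * dt)) + 20L
      v <- profile$speed *
        pmax(1 + profile$speed_cv * .ar1(n_max, profile$speed_rough), 0.05)
      cum <- cumsum(v * dt)
      keep <- cum <= L + 1e-12
      v <- v[keep]
      n <- length(v) + 1L  # include the stroke start point
      s <- c(0, cum[keep])
      xy <- .polyline_point(stroke, s)
      pressure <- pmin(pmax(
        profile$pressure_mean +
          profile$pressure_sd * .ar1(n, profile$pressure_rough), 0.01), 1)
      tilt <- pmin(pmax(
        profile$tilt_mean + profile$tilt_sd * .ar1(n, profile$tilt_rough),
        0), 90)
      azimuth <- (profile$azimuth_mean +
                    profile$azimuth_sd * .ar1(n, profile$azimuth_rough)) %% 360
      rows[[length(rows) + 1L]] <- data.frame(
        x = xy[, 1], y = xy[, 2], pressure = pressure,
        azimuth = azimuth, tilt = tilt)
      # pen-up gap before the next stroke: pressure 0, pen gliding over
      if (si < length(template$strokes)) {
        gap_n <- max(round(stats::runif(1, 0.2, 0.5) / dt), 1L)
        nxt <- template$strokes[[si + 1L]][1, ]
        frac <- seq_len(gap_n) / (gap_n + 1)
        gx <- xy[n, 1] + frac * (nxt[1] - xy[n, 1])
        gy <- xy[n, 2] + frac * (nxt[2] - xy[n, 2])
        rows[[length(rows) + 1L]] <- data.frame(
          x = gx, y = gy, pressure = 0,
          azimuth = azimuth[n], tilt = tilt[n])
      }
    }
    samples <- do.call(rbind, rows)
    samples <- cbind(t = (seq_len(nrow(samples)) - 1L) * dt, samples)
    samples$gaze_x <- NA_real_
    samples$gaze_y <- NA_real_
    DrawingRecording(participant_id, template$shape_id, "drawing", samples)
  })
}

#' Generate a synthetic demonstration recording
#'
#' The advancing line traces the template at constant speed over the
#' demonstration duration; `line_x`/`line_y` hold the line-tip position.
#' The participant is watching, so pressure is 0 throughout and the pen
#' pose channels are held at the profile means.
#'
#' @inheritParams generateDrawing
#' @return A `DrawingRecording` with phase `"demo"`.
#' @export
generateDemo <- function(template, profile, seed = 1L,
                         participant_id = "sim") {
  .validate_template(template)
  .with_seed(seed, {
    dt <- 1 / .SAMPLE_RATE
    n <- round(template$demo_duration / dt)
    lens <- vapply(template$strokes, .polyline_length, numeric(1))
    total <- sum(lens)
    s_all <- seq(0, total, length.out = n)
    bounds <- c(0, cumsum(lens))
    stroke_of <- findInterval(s_all, bounds, rightmost.closed = TRUE)
    stroke_of <- pmin(stroke_of, length(lens))
    pts <- matrix(0, n, 2)
    for (si in unique(stroke_of)) {
      idx <- stroke_of == si
      pts[idx, ] <- .polyline_point(template$strokes[[si]],
                                    s_all[idx] - bounds[si])
    }
    samples <- data.frame(
      t = (seq_len(n) - 1L) * dt,
      x = pts[, 1], y = pts[, 2], pressure = 0,
      azimuth = profile$azimuth_mean %% 360, tilt = profile$tilt_mean,
      gaze_x = NA_real_, gaze_y = NA_real_,
      line_x = pts[, 1], line_y = pts[, 2])
    DrawingRecording(participant_id, template$shape_id, "demo", samples)
  })
}

# standardized vector orthogonalization used by the exact-correlation
# construction: returns unit-norm centered vector orthogonal to u
.orthonormal_noise <- function(u, n) {
  e <- stats::rnorm(n)
  e <- e - mean(e)
  e <- e - sum(e * u) * u
  nrm <- sqrt(sum(e^2))
  if (nrm < 1e-12) return(NULL)
  e / nrm
}

# build a gaze signal whose sample correlation with ref equals coupling
# exactly (over the given samples); amplitude in degrees
.coupled_signal <- function(ref, coupling, amp = 12) {
  n <- length(ref)
  u <- ref - mean(ref)
  nrm <- sqrt(sum(u^2))
  if (nrm < 1e-12) {           # flat reference: pure noise, r undefined
    return(amp * stats::rnorm(n))
  }
  u <- u / nrm
  if (abs(coupling) >= 1) {
    g <- coupling * u
  } else {
    ep <- .orthonormal_noise(u, n)
    if (is.null(ep)) return(amp * coupling * u * sqrt(n - 1))
    g <- coupling * u + sqrt(1 - coupling^2) * ep
  }
  amp * sqrt(n - 1) * g        # unit sample SD before amplitude scaling
}

#' Fill the gaze channels of a recording with pen-coupled eye rotation
#'
#' Constructs horizontal and vertical gaze-rotation signals as linear
#' functions of the reference trajectory plus orthogonalized noise,
#' calibrated so that the sample correlation with the reference equals
#' `coupling` exactly over the correlation support: pen-down samples for
#' a drawing-phase recording, the advancing line over all frames for a
#' demo-phase recording. Remaining samples (pen-up frames of the drawing
#' phase) are filled with the same linear map plus independent noise.
#' Values are clamped to \[-90, 90\] degrees.
#'
#' @param recording a `DrawingRecording`.
#' @param coupling target gaze-pen correlation in \[-1,1\]; length 1
#'   (both axes) or 2 (horizontal, vertical).
#' @param seed integer seed.
#' @param amplitude gaze excursion scale in degrees (sample SD of the
#'   generated signal over the correlation support).
#' @return The recording with `gaze_x`/`gaze_y` filled.
#' @export
generateGaze <- function(recording, coupling, seed = 1L, amplitude = 12) {
  stopifnot(is(recording, "DrawingRecording"))
  if (any(abs(coupling) > 1)) stop("coupling must be in [-1,1]")
  coupling <- rep_len(coupling, 2L)
  s <- recording@samples
  if (recording@phase == "drawing") {
    act <- which(s$pressure > 0)
    if (!length(act)) stop("empty drawing: no active samples")
    ref_x <- s$x[act]; ref_y <- s$y[act]
  } else {
    act <- seq_len(nrow(s))
    ref_x <- s$line_x; ref_y <- s$line_y
  }
  .with_seed(seed, {
    gx <- .coupled_signal(ref_x, coupling[1], amplitude)
    gy <- .coupled_signal(ref_y, coupling[2], amplitude)
    s$gaze_x <- NA_real_; s$gaze_y <- NA_real_
    s$gaze_x[act] <- pmin(pmax(gx, -90), 90)
    s$gaze_y[act] <- pmin(pmax(gy, -90), 90)
    rest <- setdiff(seq_len(nrow(s)), act)
    if (length(rest)) {      # pen-up frames: same linear map + noise
      sdr <- stats::sd(ref_x)
      mx <- if (is.na(sdr) || sdr == 0) 0 else
        coupling[1] * amplitude * (s$x[rest] - mean(ref_x)) / sdr
      sdy <- stats::sd(ref_y)
      my <- if (is.na(sdy) || sdy == 0) 0 else
        coupling[2] * amplitude * (s$y[rest] - mean(ref_y)) / sdy
      nzx <- amplitude * sqrt(max(1 - coupling[1]^2, 0))
      nzy <- amplitude * sqrt(max(1 - coupling[2]^2, 0))
      s$gaze_x[rest] <- pmin(pmax(mx + nzx * stats::rnorm(length(rest)), -90), 90)
      s$gaze_y[rest] <- pmin(pmax(my + nzy * stats::rnorm(length(rest)), -90), 90)
    }
    methods::initialize(recording, samples = s)
  })
}

# SRS-2 scores: the low group is truncated normal on [0, cutoff]; the
# high group is cutoff + shifted gamma matched to the requested
# mean/SD offset, reproducing the right skew of the observed
# distribution while guaranteeing consistency with the cutoff rule.
.draw_srs2 <- function(group, sex, spec) {
  cut <- srs2Cutoff(sex)
  if (group == "low") {
    repeat {
      v <- stats::rnorm(1, spec$srs_low_mean, spec$srs_low_sd)
      if (v >= 0 && v <= cut) return(round(v))
    }
  } else {
    off_mean <- max(spec$srs_high_mean - cut, 1)
    shape <- (off_mean / spec$srs_high_sd)^2
    rate <- shape / off_mean
    round(cut + 0.5 + stats::rgamma(1, shape = shape, rate = rate))
  }
}

#' Generate a synthetic cohort of drawing sessions
#'
#' Draws per-participant metadata (sex, age ~ Normal(5.05, 0.17)
#' truncated to \[4.5, 5.5\] years, SRS-2 score from the group's
#' distribution) and latent drawing profiles with the group shifts of
#' `spec$effect_map`, then generates 4 shapes x 2 phases (demo, drawing)
#' recordings per participant with gaze channels coupled to the pen or
#' advancing line at the participant's coupling value. Identical
#' spec + seed reproduces identical output.
#'
#' @param spec a [cohortSpec()].
#' @return A list with `cohort` (data.frame: participant_id, sex,
#'   age_years, srs2_score, group) and `recordings` (list of
#'   `DrawingRecording`, named `<participant>_<shape>_<phase>`).
#' @export
generateCohort <- function(spec = cohortSpec()) {
  validateCohortSpec(spec)
  n <- spec$n_high + spec$n_low
  templates <- shapeTemplates()
  .with_seed(spec$seed, {
    group <- rep(c("high", "low"), c(spec$n_high, spec$n_low))
    sex <- ifelse(stats::runif(n) < spec$sex_ratio, "M", "F")
    age <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        a <- stats::rnorm(1, 5.05, 0.17)
        if (a >= 4.5 && a <= 5.5) { age[i] <- a; break }
      }
    }
    srs2 <- vapply(seq_len(n),
                   function(i) .draw_srs2(group[i], sex[i], spec),
                   numeric(1))
    cohort <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      sex = sex, age_years = age, srs2_score = srs2, group = group,
      stringsAsFactors = FALSE)
    coupling_target <- ifelse(group == "high", spec$gaze_coupling_high,
                              spec$gaze_coupling_low)
    coupling <- pmin(pmax(
      coupling_target + spec$coupling_sd * stats::rnorm(n), -0.95), 0.95)
    profiles <- lapply(group, .draw_profile, effect_map = spec$effect_map)
    cohort
    list(cohort = cohort, coupling = coupling, profiles = profiles)
  }) -> drawn

  recordings <- vector("list", n * 8L)
  nm <- character(n * 8L)
  k <- 0L
  for (i in seq_len(n)) {
    pid <- drawn$cohort$participant_id[i]
    for (sh in shapeIds()) {
      # per-recording jitter keeps shapes from sharing one exact coupling
      cj <- pmin(pmax(drawn$coupling[i] +
        0.08 * .with_seed(.substream(spec$seed, i * 101L + match(sh, shapeIds())),
                          stats::rnorm(2)), -0.99), 0.99)
      demo <- generateDemo(templates[[sh]], drawn$profiles[[i]],
                           seed = .substream(spec$seed, i * 1009L + 2L * match(sh, shapeIds())),
                           participant_id = pid)
      demo <- generateGaze(demo, cj[1],
                           seed = .substream(spec$seed, i * 2003L + match(sh, shapeIds())))
      draw <- generateDrawing(templates[[sh]], drawn$profiles[[i]],
                              seed = .substream(spec$seed, i * 3001L + match(sh, shapeIds())),
                              participant_id = pid)
      draw <- generateGaze(draw, cj[2],
                           seed = .substream(spec$seed, i * 4001L + match(sh, shapeIds())))
      for (rec in list(demo, draw)) {
        k <- k + 1L
        recordings[[k]] <- rec
        nm[k] <- sprintf("%s_%s_%s", pid, sh, rec@phase)
      }
    }
  }
  names(recordings) <- nm
  list(cohort = drawn$cohort, recordings = recordings)
}
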