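# In-code fixtures shared across the suite.

# a drawing-phase recording built directly from channel vectors
make_recording <- function(pressure, x = NULL, y = NULL, tilt = 45,
                           azimuth = 180, gaze_x = NA_real_,
                           gaze_y = NA_real_, dt = 1 / 30,
                           phase = "drawing", line_x = NULL, line_y = NULL,
                           shape = "square") {
  n <- length(pressure)
  if (is.null(x)) x <- seq(0.1, 0.9, length.out = n)
  if (is.null(y)) y <- rep(0.5, n)
  s <- data.frame(
    t = (seq_len(n) - 1) * dt, x = x, y = y, pressure = pressure,
    azimuth = rep_len(azimuth, n), tilt = rep_len(tilt, n),
    gaze_x = rep_len(gaze_x, n), gaze_y = rep_len(gaze_y, n))
  if (phase == "demo") {
    s$line_x <- if (is.null(line_x)) x else line_x
    s$line_y <- if (is.null(line_y)) y else line_y
  }
  DrawingRecording("T001", shape, phase, s)
}

# single-stroke straight-line template from (0.1, 0.5) of given length
line_template <- function(len = 0.6) {
  list(shape_id = "square",
       strokes = list(rbind(c(0.1, 0.5), c(0.1 + len, 0.5))),
       demo_duration = 10)
}

# noise-free latent profile: constant speed/pressure/pose
constant_profile <- function(speed = 0.1, pressure = 0.5, tilt = 45,
                             azimuth = 180) {
  drawingProfile(speed = speed, speed_cv = 0, speed_rough = 0.05,
                 pressure_mean = pressure, pressure_sd = 0,
                 pressure_rough = 0.05,
                 tilt_mean = tilt, tilt_sd = 0, tilt_rough = 0.05,
                 azimuth_mean = azimuth, azimuth_sd = 0,
                 azimuth_rough = 0.05)
}

# random feature matrix with planted group shifts (feature-level
# generation for model-search tests)
planted_matrix <- function(n_high, n_low, d = c(), seed = 1) {
  set.seed(seed)
  n <- n_high + n_low
  x <- matrix(rnorm(n * 16), n, 16, dimnames = list(NULL, featureNames16()))
  for (f in names(d))
    x[seq_len(n_high), f] <- x[seq_len(n_high), f] + d[[f]]
  list(x = x, labels = rep(c("high", "low"), c(n_high, n_low)))
}
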