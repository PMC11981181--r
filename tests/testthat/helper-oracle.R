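# Brute-force reference implementations of the sixteen features,
# written as plain loops straight from the definitions, kept independent
# of the package's extraction code.

oracle_features <- function(demo, drawing, threshold = 0, min_len = 3) {
  s <- recordingSamples(drawing)
  # maximal pressure runs by scanning
  segs <- list(); start <- NA
  for (i in seq_len(nrow(s) + 1)) {
    active <- i <= nrow(s) && s$pressure[i] > threshold
    if (active && is.na(start)) start <- i
    if (!active && !is.na(start)) {
      if (i - start >= min_len) segs[[length(segs) + 1]] <- start:(i - 1)
      start <- NA
    }
  }
  pool <- function(col) unlist(lapply(segs, function(ix) s[[col]][ix]))
  sample_sd <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  p <- pool("pressure")

  pch <- c()
  for (ix in segs) for (j in seq_along(ix)[-1])
    pch <- c(pch, abs(s$pressure[ix[j]] - s$pressure[ix[j - 1]]))

  v <- c(); acc <- c()
  for (ix in segs) {
    vs <- c()
    for (j in seq_along(ix)[-1]) {
      d <- sqrt((s$x[ix[j]] - s$x[ix[j - 1]])^2 +
                (s$y[ix[j]] - s$y[ix[j - 1]])^2)
      vs <- c(vs, d / (s$t[ix[j]] - s$t[ix[j - 1]]))
    }
    if (length(vs) > 1)
      for (j in seq_along(vs)[-1]) acc <- c(acc, abs(vs[j] - vs[j - 1]))
    v <- c(v, vs)
  }

  tch <- c()
  for (ix in segs) for (j in seq_along(ix)[-1])
    tch <- c(tch, abs(s$tilt[ix[j]] - s$tilt[ix[j - 1]]))

  az <- pool("azimuth")
  rad <- az * pi / 180
  S <- mean(sin(rad)); C <- mean(cos(rad))
  m_az <- (atan2(S, C) * 180 / pi) %% 360
  if (m_az >= 360) m_az <- 0
  R <- min(sqrt(S^2 + C^2), 1)
  sd_az <- sqrt(max(-2 * log(R), 0)) * 180 / pi
  och <- c()
  for (ix in segs) for (j in seq_along(ix)[-1]) {
    d <- s$azimuth[ix[j]] - s$azimuth[ix[j - 1]]
    d <- (d + 180) %% 360 - 180
    och <- c(och, abs(d))
  }

  corr2 <- function(g, ref) {
    ok <- !is.na(g) & !is.na(ref)
    if (sum(ok) < 10 || sample_sd(g[ok]) == 0 || sample_sd(ref[ok]) == 0)
      return(0)
    g <- g[ok]; ref <- ref[ok]
    sum((g - mean(g)) * (ref - mean(ref))) /
      sqrt(sum((g - mean(g))^2) * sum((ref - mean(ref))^2))
  }
  ds <- recordingSamples(demo)
  act <- unlist(segs)
  c(Mpenpressure = mean(p), SDpenpressure = sample_sd(p),
    Mpenpressurechange = mean(pch),
    Mdrawingspeed = mean(v), SDdrawingspeed = sample_sd(v),
    Mdrawingacceleration = mean(acc),
    Mpentilt = mean(pool("tilt")), SDpentilt = sample_sd(pool("tilt")),
    Mpentiltchange = mean(tch),
    Mpenorientation = m_az, SDpenorientation = sd_az,
    Mpenorientationchange = mean(och),
    Corrdemoeyehorizontal = corr2(ds$gaze_x, ds$line_x),
    Corrdemoeyevertical = corr2(ds$gaze_y, ds$line_y),
    Corrdrawingeyehorizontal = corr2(s$gaze_x[act], s$x[act]),
    Corrdrawingeyevertical = corr2(s$gaze_y[act], s$y[act]))
}

# random multi-segment recording pair for oracle-equivalence checks
random_recording_pair <- function(seed, n_segments = 3, seg_len = 50) {
  set.seed(seed)
  pr <- c(); gap <- function() rep(0, sample(3:8, 1))
  for (k in seq_len(n_segments)) {
    pr <- c(pr, runif(seg_len, 0.05, 0.95))
    if (k < n_segments) pr <- c(pr, gap())
  }
  n <- length(pr)
  drawing <- make_recording(
    pressure = pr,
    x = runif(n), y = runif(n),
    tilt = runif(n, 0, 90), azimuth = runif(n, 0, 360),
    gaze_x = runif(n, -60, 60), gaze_y = runif(n, -60, 60))
  nd <- 80
  demo <- make_recording(
    pressure = rep(0, nd), x = runif(nd), y = runif(nd),
    gaze_x = runif(nd, -60, 60), gaze_y = runif(nd, -60, 60),
    phase = "demo", line_x = runif(nd), line_y = runif(nd))
  list(demo = demo, drawing = drawing)
}
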