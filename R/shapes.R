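#' Shape templates of the drawing battery
#'
#' Returns the stroke templates used both to drive the synthetic drawing
#' generator and to lay out the demonstration line. Each template gives
#' the ordered stroke polylines (vertex sequences in \[0,1\]^2 screen
#' coordinates, drawn in stroke order) and the duration of the
#' demonstration video: about 16 s for the equilateral triangle, 14 s for
#' the inverted triangle, 15 s for the square and 23 s for the sun. The
#' sun is rendered as a 36-gon circle followed by eight ray strokes.
#'
#' @param shape optional single shape id; default returns all four.
#' @return A named list of templates, each a list with `shape_id`,
#'   `strokes` (list of 2-column matrices) and `demo_duration` (seconds).
#' @examples
#' tpl <- shapeTemplates("square")
#' length(tpl$strokes)  # 4 sides, drawn as separate strokes
#' @export
shapeTemplates <- function(shape = NULL) {
  tri <- list(
    shape_id = "equilateral_triangle",
    strokes = list(
      rbind(c(0.50, 0.80), c(0.20, 0.28)),
      rbind(c(0.20, 0.28), c(0.80, 0.28)),
      rbind(c(0.80, 0.28), c(0.50, 0.80))
    ),
    demo_duration = 16
  )
  inv <- list(
    shape_id = "inverted_triangle",
    strokes = list(
      rbind(c(0.20, 0.72), c(0.80, 0.72)),
      rbind(c(0.80, 0.72), c(0.50, 0.20)),
      rbind(c(0.50, 0.20), c(0.20, 0.72))
    ),
    demo_duration = 14
  )
  sq <- list(
    shape_id = "square",
    strokes = list(
      rbind(c(0.25, 0.75), c(0.75, 0.75)),
      rbind(c(0.75, 0.75), c(0.75, 0.25)),
      rbind(c(0.75, 0.25), c(0.25, 0.25)),
      rbind(c(0.25, 0.25), c(0.25, 0.75))
    ),
    demo_duration = 15
  )
  th <- seq(0, 2 * pi, length.out = 37)
  circle <- cbind(0.5 + 0.16 * cos(th), 0.55 + 0.16 * sin(th))
  rays <- lapply(seq(0, 2 * pi, length.out = 9)[1:8], function(a) {
    rbind(c(0.5 + 0.20 * cos(a), 0.55 + 0.20 * sin(a)),
          c(0.5 + 0.30 * cos(a), 0.55 + 0.30 * sin(a)))
  })
  sun <- list(
    shape_id = "sun",
    strokes = c(list(circle), rays),
    demo_duration = 23
  )
  all <- list(equilateral_triangle = tri, inverted_triangle = inv,
              square = sq, sun = sun)
  if (is.null(shape)) return(all)
  if (!shape %in% names(all))
    stop(sprintf("unknown shape '%s'", shape))
  all[[shape]]
}

.validate_template <- function(template) {
  if (is.null(template$strokes) || length(template$strokes) < 1L)
    stop("template must have at least one stroke")
  for (s in template$strokes) {
    if (any(s < 0 | s > 1)) stop("template coordinates must lie in [0,1]")
    if (nrow(s) < 2L) stop("each stroke needs at least two vertices")
  }
  if (is.null(template$demo_duration) || template$demo_duration <= 0)
    stop("demo_duration must be > 0")
  invisible(template)
}

.polyline_length <- function(m) {
  sum(sqrt(rowSums(diff(m)^2)))
}

# position along a polyline at arc lengths s (vectorized)
.polyline_point <- function(m, s) {
  seg <- sqrt(rowSums(diff(m)^2))
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  x <- stats::approx(cum, m[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, m[, 2], xout = s, ties = "ordered")$y
  cbind(x, y)
}
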