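#' Closed planar contours in pixel coordinates
#'
#' A contour is the boundary polygon of a fiber wall or lumen: an ordered
#' sequence of (x, y) vertices in pixel coordinates, implicitly closed (the
#' last vertex connects back to the first; the closing vertex is not
#' repeated). Coordinates follow the image convention: x rightward, y
#' downward, 0-based. On ingest the vertex order is normalized to
#' counter-clockwise in that frame.
#'
#' @param x A two-column numeric matrix (or data frame) of (x, y) vertices.
#' @param check_simple Also verify the polygon does not self-intersect
#'   (quadratic cost; off by default for segmentation output, which is simple
#'   by construction).
#' @return A numeric matrix of class `contour` with columns `x`, `y`.
#' @examples
#' sq <- as_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' polygon_area(sq, calibration_scale(um_per_px = 1))
#' @export
as_contour <- function(x, check_simple = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (!is.matrix(x) || ncol(x) != 2 || !is.numeric(x)) {
    abort("a contour is a two-column numeric matrix of (x, y) vertices")
  }
  if (anyNA(x) || any(!is.finite(x))) abort("contour vertices must be finite")
  # drop an explicitly repeated closing vertex
  n <- nrow(x)
  if (n >= 2 && all(x[1, ] == x[n, ])) x <- x[-n, , drop = FALSE]
  if (nrow(x) < 3) abort("a contour needs at least 3 distinct vertices")
  sa <- shoelace_signed(x)
  if (abs(sa) < .Machine$double.eps * 16 * max(1, max(abs(x)))^2) {
    abort("degenerate contour: collinear vertices enclose zero area")
  }
  # image frame (y down): visually counter-clockwise traversal has negative
  # standard shoelace sign, so normalize to signed area < 0
  if (sa > 0) x <- x[nrow(x):1, , drop = FALSE]
  if (check_simple && !is_simple_polygon(x)) {
    abort("contour is self-intersecting")
  }
  colnames(x) <- c("x", "y")
  class(x) <- c("contour", class(x))
  x
}

# standard shoelace (positive for counter-clockwise in a y-up frame)
shoelace_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

is_simple_polygon <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n] # edge n closes onto edge 1
    if (!length(js)) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                           b[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- function(o, a, bx, by) (a[1] - o[1]) * (by - o[2]) - (a[2] - o[2]) * (bx - o[1])
  d1 <- d(p1, p2, q1[, 1], q1[, 2])
  d2 <- d(p1, p2, q2[, 1], q2[, 2])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Polygon area of a contour, in square micrometres
#'
#' Shoelace area of the closed polygon times the square of the calibration
#' factor.
#'
#' @param contour A [as_contour()] polygon (pixel coordinates).
#' @param scale A [calibration_scale()] or a bare um-per-px factor. Defaults
#'   to 1 (area returned in px^2).
#' @return Strictly positive area in um^2.
#' @export
polygon_area <- function(contour, scale = 1) {
  contour <- as_contour(contour)
  s <- as_scale_factor(scale)
  abs(shoelace_signed(contour)) * s^2
}

#' Polygon perimeter of a contour, in micrometres
#'
#' Sum of consecutive edge lengths, including the closing edge, times the
#' calibration factor.
#'
#' @inheritParams polygon_area
#' @return Strictly positive perimeter in um.
#' @export
polygon_perimeter <- function(contour, scale = 1) {
  contour <- as_contour(contour)
  s <- as_scale_factor(scale)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - unclass(contour))^2))) * s
}

#' Axis-aligned bounding extents of a contour
#'
#' Height is the extent along y (image rows), width the extent along x.
#'
#' @inheritParams polygon_area
#' @return Named numeric vector `c(height = , width = )` in um.
#' @export
bounding_dims <- function(contour, scale = 1) {
  contour <- as_contour(contour)
  s <- as_scale_factor(scale)
  c(height = diff(range(contour[, 2])) * s,
    width  = diff(range(contour[, 1])) * s)
}

#' Isoperimetric circularity of a closed shape
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle, smaller for any other
#' shape. Dimensionless, so the units of area and perimeter only need to be
#' consistent.
#'
#' @param area Enclosed area (> 0).
#' @param perimeter Boundary length (> 0).
#' @return Circularity in (0, 1] (up to discretization tolerance for
#'   rasterized boundaries).
#' @examples
#' circularity(pi, 2 * pi)      # circle: 1
#' circularity(1, 4)            # unit square: pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    abort("`area` and `perimeter` must be positive and finite")
  }
  4 * pi * area / perimeter^2
}

#' Full shape measurements of one contour
#'
#' Area, perimeter, circularity, height and width of a single closed contour,
#' calibrated to micrometres. This is the per-mask measurement recorded for
#' each lumen and each outer fiber boundary.
#'
#' @inheritParams polygon_area
#' @return A one-row tibble with columns `area`, `perimeter`, `circularity`,
#'   `height`, `width`.
#' @export
measure_contour <- function(contour, scale = 1) {
  a <- polygon_area(contour, scale)
  p <- polygon_perimeter(contour, scale)
  bd <- bounding_dims(contour, scale)
  tibble(area = a, perimeter = p, circularity = circularity(a, p),
         height = bd[["height"]], width = bd[["width"]])
}

# regular polygon helper used by the simulator and tests
regular_polygon <- function(n, r = 1, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  as_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}
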