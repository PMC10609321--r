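COTTON_DENSITY <- 1.52      # g/cm^3, cellulose density of the cotton wall
STANDARD_THETA <- 0.577     # degree of thickening of a standard-maturity fiber

canonical_names <- c(
  "Name", "Lumen Area", "Lumen Perimeter", "Lumen Circularity",
  "Lumen Height", "Lumen Width", "Outer Area", "Outer True Area",
  "Outer Perimeter", "Outer Circularity", "Outer Height", "Outer Width",
  "Outer/Lumen", "Line"
)

derived_names <- c("Theta", "Fiber Fineness", "Maturity Ratio",
                   "Standard Fineness")

#' Column order of the canonical per-fiber measurement table
#'
#' Fourteen columns, one row per fiber: identity, the five lumen shape
#' measures, the six outer measures (outer area includes the lumen; outer
#' true area is wall material only), the wall-to-lumen area ratio, and the
#' cotton line. All areas in um^2 and lengths in um after calibration.
#'
#' @param derived Also append the four derived maturity-metric column names.
#' @return Character vector of column names.
#' @export
canonical_columns <- function(derived = FALSE) {
  if (derived) c(canonical_names, derived_names) else canonical_names
}

#' Degree of cell-wall thickening (theta)
#'
#' `theta = 4 * pi * A_true / P_outer^2`, where `A_true` is the wall
#' cross-sectional area (outer minus lumen) and `P_outer` the outer
#' perimeter. Dimensionless; approaches 1 for a fully thickened circular
#' fiber with a vanishing lumen.
#'
#' @param outer_true_area Wall cross-sectional area, um^2.
#' @param outer_perimeter Outer boundary length, um.
#' @export
theta <- function(outer_true_area, outer_perimeter) {
  if (any(outer_true_area <= 0) || any(outer_perimeter <= 0)) {
    abort("`outer_true_area` and `outer_perimeter` must be positive")
  }
  4 * pi * outer_true_area / outer_perimeter^2
}

#' Fiber fineness (linear density, millitex)
#'
#' Wall cross-sectional area times the density of cotton cell-wall material
#' (1.52 g/cm^3); um^2 * g/cm^3 equals millitex.
#'
#' @param outer_true_area Wall cross-sectional area, um^2.
#' @param density Cotton wall density, g/cm^3.
#' @export
fineness <- function(outer_true_area, density = COTTON_DENSITY) {
  if (any(outer_true_area <= 0)) abort("`outer_true_area` must be positive")
  density * outer_true_area
}

#' Maturity ratio
#'
#' Theta normalized against the 0.577 thickening of a reference
#' standard-maturity fiber: `M = theta / 0.577`.
#'
#' @param theta Degree of cell-wall thickening.
#' @param standard Thickening of the standard-maturity reference fiber.
#' @export
maturity_ratio <- function(theta, standard = STANDARD_THETA) {
  if (any(theta <= 0)) abort("`theta` must be positive")
  theta / standard
}

#' Standard fineness (millitex)
#'
#' Fineness adjusted to standard maturity: `SF = 0.577 * F / theta`, so that
#' fibers differing only in wall thickening report the same standard
#' fineness.
#'
#' @param fineness Fiber fineness, millitex.
#' @param theta Degree of cell-wall thickening.
#' @param standard Thickening of the standard-maturity reference fiber.
#' @export
standard_fineness <- function(fineness, theta, standard = STANDARD_THETA) {
  if (any(fineness <= 0) || any(theta <= 0)) {
    abort("`fineness` and `theta` must be positive")
  }
  standard * fineness / theta
}

#' Shape measures of a single mask
#'
#' Convenience constructor for the five per-mask measurements when they are
#' known directly (e.g. from a manual measurement log) rather than computed
#' from a contour.
#'
#' @param area,perimeter,height,width Calibrated measures (um^2 / um), all
#'   positive.
#' @param circularity Dimensionless; computed from area and perimeter when
#'   omitted.
#' @return One-row tibble with columns `area`, `perimeter`, `circularity`,
#'   `height`, `width`.
#' @export
shape_measures <- function(area, perimeter, circularity = NULL,
                           height = NA_real_, width = NA_real_) {
  if (area <= 0 || perimeter <= 0) abort("area and perimeter must be positive")
  if (is.null(circularity)) circularity <- 4 * pi * area / perimeter^2
  tibble(area = area, perimeter = perimeter, circularity = circularity,
         height = height, width = width)
}

#' Assemble one canonical table row from lumen and outer measures
#'
#' Computes the wall area (`Outer True Area = Outer Area - Lumen Area`) and
#' the `Outer/Lumen` ratio (wall area over lumen area), and lays the fiber
#' out as one row of the canonical 14-column table.
#'
#' @param name Fiber identifier (image id plus position letter).
#' @param lumen,outer [shape_measures()] rows (or equivalently named lists);
#'   outer area includes the lumen.
#' @param line Cotton line label.
#' @return One-row canonical tibble; see [canonical_columns()].
#' @export
fiber_record <- function(name, lumen, outer, line = NA_character_) {
  lumen <- as.list(lumen); outer <- as.list(outer)
  if (outer$area <= lumen$area) {
    abort("lumen exceeds fiber: outer area must be larger than lumen area")
  }
  if (outer$perimeter <= 0) abort("outer perimeter must be positive")
  true_area <- outer$area - lumen$area
  out <- tibble(
    name, lumen$area, lumen$perimeter, lumen$circularity,
    lumen$height, lumen$width, outer$area, true_area, outer$perimeter,
    outer$circularity, outer$height, outer$width, true_area / lumen$area,
    line
  )
  names(out) <- canonical_names
  out
}

#' Derive the maturity metrics for every fiber of a canonical table
#'
#' Appends the four derived columns to a canonical measurement table:
#' `Theta` (degree of cell-wall thickening, `4*pi*A_true/P_outer^2`),
#' `Fiber Fineness` (`1.52 * A_true`, millitex), `Maturity Ratio`
#' (`Theta/0.577`) and `Standard Fineness` (`0.577 * Fineness / Theta`).
#' Full precision is kept; rounding to two decimals happens only at report
#' time ([write_canonical_table()] with `digits = 2`).
#'
#' @param data A canonical table ([canonical_columns()]); extra columns are
#'   passed through.
#' @param density Cotton wall density, g/cm^3.
#' @param standard Thickening of the standard-maturity reference fiber.
#' @return `data` with the four derived columns appended.
#' @examples
#' rec <- fiber_record("ex_A",
#'   lumen = shape_measures(area = 14, perimeter = 30),
#'   outer = shape_measures(area = 116.58, perimeter = 48.07),
#'   line = "2888")
#' derive_fiber_metrics(rec)
#' @export
derive_fiber_metrics <- function(data, density = COTTON_DENSITY,
                                 standard = STANDARD_THETA) {
  missing <- setdiff(c("Outer Area", "Lumen Area", "Outer True Area",
                       "Outer Perimeter"), names(data))
  if (length(missing)) {
    abort(paste("not a canonical measurement table; missing:",
                paste(missing, collapse = ", ")))
  }
  a_true <- data[["Outer True Area"]]
  if (any(abs(a_true - (data[["Outer Area"]] - data[["Lumen Area"]])) >
          1e-8 * pmax(1, data[["Outer Area"]]))) {
    abort("`Outer True Area` must equal `Outer Area` - `Lumen Area`")
  }
  th <- theta(a_true, data[["Outer Perimeter"]])
  fin <- fineness(a_true, density)
  out <- as_tibble(data)
  out[["Theta"]] <- th
  out[["Fiber Fineness"]] <- fin
  out[["Maturity Ratio"]] <- maturity_ratio(th, standard)
  out[["Standard Fineness"]] <- standard_fineness(fin, th, standard)
  out
}
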