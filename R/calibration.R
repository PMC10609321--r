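#' Pixel-to-micrometre calibration from a reference distance
#'
#' Micrographs carry a reference distance (a scale bar or stage graticule) of
#' known physical length. Measuring that reference in pixels fixes the
#' conversion factor `um_per_px = reference_length_um / reference_length_px`;
#' areas convert with the square of the factor, lengths linearly.
#'
#' @param reference_length_um Physical length of the reference distance, in
#'   micrometres. May be omitted when `um_per_px` is given directly.
#' @param reference_length_px The same reference measured on the image, in
#'   pixels.
#' @param um_per_px Conversion factor given directly; mutually redundant with
#'   the two reference lengths (if all are supplied they must agree).
#'
#' @return An object of class `calibration_scale`: a list with fields
#'   `reference_length_um`, `reference_length_px` and `um_per_px`.
#' @examples
#' calibration_scale(reference_length_um = 50, reference_length_px = 500)
#' calibration_scale(um_per_px = 0.1)
#' @export
calibration_scale <- function(reference_length_um = NULL,
                              reference_length_px = NULL,
                              um_per_px = NULL) {
  if (is.null(um_per_px)) {
    if (is.null(reference_length_um) || is.null(reference_length_px)) {
      abort("supply either `um_per_px` or both reference lengths")
    }
    um_per_px <- reference_length_um / reference_length_px
  } else if (is.null(reference_length_um)) {
    reference_length_um <- um_per_px
    reference_length_px <- 1
  }
  vals <- c(reference_length_um, reference_length_px, um_per_px)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("calibration lengths must be strictly positive and finite")
  }
  if (abs(um_per_px - reference_length_um / reference_length_px) >
      1e-9 * um_per_px) {
    abort("`um_per_px` disagrees with reference_length_um / reference_length_px")
  }
  structure(
    list(reference_length_um = reference_length_um,
         reference_length_px = reference_length_px,
         um_per_px = um_per_px),
    class = "calibration_scale"
  )
}

#' @export
print.calibration_scale <- function(x, ...) {
  cat(sprintf("<calibration_scale> %g um / %g px = %g um/px\n",
              x$reference_length_um, x$reference_length_px, x$um_per_px))
  invisible(x)
}

as_scale_factor <- function(scale) {
  if (inherits(scale, "calibration_scale")) return(scale$um_per_px)
  if (is.numeric(scale) && length(scale) == 1 && is.finite(scale) && scale > 0) {
    return(scale)
  }
  abort("`scale` must be a calibration_scale or a positive um-per-px number")
}
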