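#' Detect fiber candidates in a micrograph
#'
#' Detection stage: binarize, extract connected components with their
#' lumens, assign reading-order letters.
#'
#' @param image Image matrix/array (see [binarize()]).
#' @param method,threshold Binarization settings ([binarize()]).
#' @param min_area_px,min_hole_px Component/hole size floors
#'   ([extract_candidates()]).
#' @return List with `candidates` (lettered tibble) and `mask`.
#' @export
segment_image <- function(image, method = c("otsu", "fixed"),
                          threshold = NULL, min_area_px = 500,
                          min_hole_px = 25) {
  mask <- binarize(image, method = method, threshold = threshold)
  candidates <- assign_letters(
    extract_candidates(mask, min_area_px = min_area_px,
                       min_hole_px = min_hole_px))
  list(candidates = candidates, mask = mask)
}

#' Full measurement pipeline for one micrograph
#'
#' Detection (binarize, component/lumen extraction, lettering),
#' measurement (calibrated shape measures per candidate), classification
#' (quality scoring and partition), and assembly of the canonical 14-column
#' table with derived maturity metrics for the good fibers. Fiber names are
#' `image_id` plus the position letter.
#'
#' @inheritParams segment_image
#' @param scale A [calibration_scale()] or um-per-px factor.
#' @param image_id Image identifier (line_capsule_slide_image convention).
#' @param line Cotton line label for the `Line` column.
#' @param rules A [quality_rules()] set.
#' @param scorer Quality scorer satisfying the [score_candidates()]
#'   contract.
#' @return Object of class `fiber_measurements`: list with `table`
#'   (canonical + derived tibble of good fibers), `candidates` (all scored
#'   candidates), `rejected` (audit tibble), `mask`, `scale`, `image_id`.
#' @export
measure_image <- function(image, scale, image_id = "image",
                          line = NA_character_, rules = quality_rules(),
                          method = c("otsu", "fixed"), threshold = NULL,
                          min_area_px = 500, min_hole_px = 25,
                          scorer = score_candidates) {
  seg <- segment_image(image, method = method, threshold = threshold,
                       min_area_px = min_area_px, min_hole_px = min_hole_px)
  measured <- measure_candidates(seg$candidates, scale)
  part <- filter_scene(measured, rules, scorer = scorer)
  good <- part$good
  tab <- good[good$has_lumen, , drop = FALSE]
  table <- if (nrow(tab)) {
    recs <- purrr::map(seq_len(nrow(tab)), function(i) {
      fiber_record(
        paste0(image_id, "_", tab$letter[i]),
        lumen = tibble(area = tab$lumen_area[i],
                       perimeter = tab$lumen_perimeter[i],
                       circularity = tab$lumen_circularity[i],
                       height = tab$lumen_height[i],
                       width = tab$lumen_width[i]),
        outer = tibble(area = tab$outer_area[i],
                       perimeter = tab$outer_perimeter[i],
                       circularity = tab$outer_circularity[i],
                       height = tab$outer_height[i],
                       width = tab$outer_width[i]),
        line = line
      )
    })
    derive_fiber_metrics(dplyr::bind_rows(recs))
  } else {
    derive_fiber_metrics(fiber_record(
      "x", shape_measures(1, 4), shape_measures(10, 12), line = "x"))[0, ]
  }
  structure(
    list(table = table, candidates = dplyr::bind_rows(part$good,
                                                      part$rejected),
         good = part$good, rejected = part$rejected, mask = seg$mask,
         scale = scale, image_id = image_id),
    class = "fiber_measurements"
  )
}

#' Run the measurement pipeline on a synthetic scene
#'
#' @param scene A [simulate_scene()] result.
#' @param ... Passed on to [measure_image()].
#' @return A `fiber_measurements` object.
#' @export
measure_scene <- function(scene, ...) {
  stopifnot(inherits(scene, "fiber_scene"))
  measure_image(scene$image, scene$scale, image_id = scene$image_id,
                line = scene$line, ...)
}

#' @export
print.fiber_measurements <- function(x, ...) {
  cat(sprintf("<fiber_measurements> %s: %d candidates, %d good, %d rejected\n",
              x$image_id, nrow(x$candidates), nrow(x$good),
              nrow(x$rejected)))
  invisible(x)
}

#' @export
tidy.fiber_measurements <- function(x, ...) x$table

#' @export
glance.fiber_measurements <- function(x, ...) {
  tibble(image_id = x$image_id, n_candidates = nrow(x$candidates),
         n_good = nrow(x$good), n_rejected = nrow(x$rejected),
         mean_theta = mean(x$table[["Theta"]]),
         mean_fineness = mean(x$table[["Fiber Fineness"]]))
}

#' @describeIn measure_image Segmentation overlay: mask raster with every
#'   candidate's outer contour, colored by quality verdict.
#' @param object A `fiber_measurements` object.
#' @param ... Unused.
#' @export
autoplot.fiber_measurements <- function(object, ...) {
  img <- object$mask
  raster_df <- tibble(
    x = rep(seq_len(ncol(img)) - 1, each = nrow(img)),
    y = rep(seq_len(nrow(img)) - 1, times = ncol(img)),
    value = as.vector(img * 1)
  )
  cont <- object$candidates |>
    dplyr::mutate(verdict = ifelse(.data$good, "good", "rejected"),
                  pts = purrr::map(.data$outer,
                                   ~ as_tibble(unclass(.x)))) |>
    dplyr::select("letter", "verdict", "pts") |>
    tidyr::unnest("pts")
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = raster_df,
                         ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "grey70",
                                 guide = "none") +
    ggplot2::geom_path(data = cont,
                       ggplot2::aes(.data$x, .data$y, group = .data$letter,
                                    color = .data$verdict),
                       linewidth = 0.4) +
    ggplot2::scale_color_manual(values = c(good = "#2e7d32",
                                           rejected = "#c62828")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
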