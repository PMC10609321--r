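#' Population parameters for synthetic fiber cross-sections
#'
#' Describes the distribution a scene's fibers are drawn from. A mature dry
#' cotton cross-section is kidney shaped: a flattened ellipse with a single
#' concave dent, enclosing a lumen. The generator controls the wall
#' cross-sectional area (log-normal, since fiber sizes are right-skewed),
#' the ellipse aspect, the dent depth, and the wall thickness; defaults are
#' set so rendered outer circularity averages about 0.55 and wall areas sit
#' in the 100-160 um^2 range typical of mature upland cotton.
#'
#' @param mean_true_area_um2 Population mean wall (outer true) area, um^2.
#' @param cv_true_area Coefficient of variation of wall area.
#' @param aspect_mean,aspect_sd Base-ellipse aspect ratio b/a (truncated to
#'   `[0.1, 0.95]`).
#' @param dent_mean,dent_sd Kidney dent depth as a fraction of local radius
#'   (truncated to `[0, 0.8]`).
#' @param wall_fraction_mean,wall_fraction_sd Lumen inset: the lumen contour
#'   is the outer contour scaled toward its center by `1 - wall_fraction`
#'   (truncated to `[0.3, 0.92]`).
#' @param tilt_sd Standard deviation (radians) of the half-normal axis
#'   deviation of properly embedded fibers; sectioning at tilt t inflates
#'   apparent area by 1/cos(t).
#' @return List of class `fiber_population`.
#' @export
fiber_population <- function(mean_true_area_um2 = 130, cv_true_area = 0.25,
                             aspect_mean = 0.22, aspect_sd = 0.05,
                             dent_mean = 0.60, dent_sd = 0.10,
                             wall_fraction_mean = 0.69,
                             wall_fraction_sd = 0.04,
                             tilt_sd = 0.05) {
  if (mean_true_area_um2 <= 0 || cv_true_area <= 0) {
    abort("area parameters must be positive")
  }
  if (aspect_mean <= 0 || aspect_mean > 1 || dent_mean < 0 || dent_mean >= 1 ||
      wall_fraction_mean <= 0 || wall_fraction_mean >= 1) {
    abort("infeasible population ranges")
  }
  structure(
    list(mean_true_area_um2 = mean_true_area_um2, cv_true_area = cv_true_area,
         aspect_mean = aspect_mean, aspect_sd = aspect_sd,
         dent_mean = dent_mean, dent_sd = dent_sd,
         wall_fraction_mean = wall_fraction_mean,
         wall_fraction_sd = wall_fraction_sd, tilt_sd = tilt_sd),
    class = "fiber_population"
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Draw fiber shape parameters from a population
#'
#' All randomness flows through R's global generator, so a single
#' `set.seed()` makes every downstream scene bit-exact.
#'
#' @param n Number of fibers to draw.
#' @param population A [fiber_population()].
#' @return Tibble of shape parameters, one row per fiber: `true_area_um2`,
#'   `aspect`, `dent_depth`, `wall_thickness_fraction`, `rotation`,
#'   `tilt_angle`.
#' @export
sample_fiber_shape <- function(n = 1, population = fiber_population()) {
  p <- population
  sdlog <- sqrt(log(1 + p$cv_true_area^2))
  meanlog <- log(p$mean_true_area_um2) - sdlog^2 / 2
  tibble(
    true_area_um2 = stats::rlnorm(n, meanlog, sdlog),
    aspect = rtrunc_norm(n, p$aspect_mean, p$aspect_sd, 0.1, 0.95),
    dent_depth = rtrunc_norm(n, p$dent_mean, p$dent_sd, 0, 0.8),
    wall_thickness_fraction = rtrunc_norm(n, p$wall_fraction_mean,
                                          p$wall_fraction_sd, 0.3, 0.92),
    rotation = stats::runif(n, 0, 2 * pi),
    tilt_angle = abs(stats::rnorm(n, 0, p$tilt_sd))
  )
}

#' Exact outer and lumen contours of one kidney-shaped fiber
#'
#' Base ellipse `(cos phi, aspect * sin phi)` with a radial multiplier
#' `1 - dent_depth * ((1 + cos phi)/2)^4` (a single smooth concave dent
#' centered on one side); the lumen is the same shape scaled toward the center by
#' `1 - wall_thickness_fraction`, so it is strictly inside the wall. The
#' whole shape is scaled so the enclosed wall area equals `true_area_um2`
#' exactly (up to polygon discretization), then rotated, tilted and
#' translated.
#'
#' @param true_area_um2 Target wall area, um^2.
#' @param aspect,dent_depth,wall_thickness_fraction,rotation,tilt_angle
#'   Shape parameters (see [fiber_population()]).
#' @param center Fiber center, um.
#' @param n_vertices Polygon resolution.
#' @return List with `outer` and `lumen` contours in um coordinates.
#' @export
kidney_fiber <- function(true_area_um2, aspect = 0.22, dent_depth = 0.60,
                         wall_thickness_fraction = 0.69, rotation = 0,
                         tilt_angle = 0, center = c(0, 0),
                         n_vertices = 160) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  mult <- 1 - dent_depth * ((1 + cos(phi)) / 2)^4
  outer0 <- cbind(mult * cos(phi), mult * aspect * sin(phi))
  inset <- 1 - wall_thickness_fraction
  a_true0 <- abs(shoelace_signed(outer0)) * (1 - inset^2)
  sc <- sqrt(true_area_um2 / a_true0)
  outer <- outer0 * sc
  lumen <- outer * inset
  rot <- matrix(c(cos(rotation), sin(rotation),
                  -sin(rotation), cos(rotation)), 2, 2)
  place <- function(p) {
    p <- p %*% t(rot)
    p <- cbind(p[, 1] + center[1], p[, 2] + center[2])
    as_contour(p)
  }
  outer <- place(outer)
  lumen <- place(lumen)
  if (tilt_angle > 0) {
    ctr <- colMeans(outer)
    outer <- tilt_transform(outer, tilt_angle, center = ctr)
    lumen <- tilt_transform(lumen, tilt_angle, center = ctr)
  }
  list(outer = outer, lumen = lumen)
}

#' Oblique-sectioning distortion of a contour
#'
#' A fiber whose axis deviates from the section normal by `tilt_angle`
#' presents a cross-section stretched by `1/cos(tilt_angle)` along the
#' projection direction, so its apparent area is inflated by exactly that
#' factor. Used by the simulator to create oblique "bad" fibers and to
#' reason about the error such fibers would introduce.
#'
#' @param contour A contour.
#' @param tilt_angle Axis deviation, radians, in `[0, pi/2)`.
#' @param direction Angle of the stretch direction in the image plane.
#' @param center Point held fixed; defaults to the vertex centroid.
#' @return The stretched contour; its area is the input area times
#'   `1/cos(tilt_angle)` to machine precision.
#' @export
tilt_transform <- function(contour, tilt_angle, direction = pi / 2,
                           center = NULL) {
  if (tilt_angle < 0 || tilt_angle >= pi / 2) {
    abort("`tilt_angle` must lie in [0, pi/2)")
  }
  contour <- as_contour(contour)
  if (tilt_angle == 0) return(contour)
  f <- 1 / cos(tilt_angle)
  u <- c(cos(direction), sin(direction))
  if (is.null(center)) center <- colMeans(contour)
  d <- sweep(unclass(contour), 2, center)
  proj <- drop(d %*% u)
  as_contour(sweep(d + (f - 1) * outer(proj, u), 2, center, `+`))
}

rasterize_fiber <- function(wall, outer, lumen) {
  # paint wall pixels (inside outer, outside lumen) into the logical matrix
  xr <- range(outer[, 1]); yr <- range(outer[, 2])
  xs <- max(0, floor(xr[1])):min(ncol(wall) - 1, ceiling(xr[2]))
  ys <- max(0, floor(yr[1])):min(nrow(wall) - 1, ceiling(yr[2]))
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  close_poly <- function(p) rbind(unclass(p), unclass(p)[1, ])
  inside <- mgcv::in.out(close_poly(outer), grid)
  inside[inside] <- !mgcv::in.out(close_poly(lumen),
                                  grid[inside, , drop = FALSE])
  hit <- grid[inside, , drop = FALSE]
  wall[cbind(hit[, 2] + 1, hit[, 1] + 1)] <- TRUE
  wall
}

#' Render a synthetic micrograph scene with exact ground truth
#'
#' Emulates a resin-section micrograph: 40-60 kidney-shaped cross-sections
#' per field, bright walls on a dark background with dark lumens, Gaussian
#' sensor noise, and optionally a few faint section-crease streaks. Fibers
#' are placed by rejection sampling so they do not overlap. A configurable
#' fraction are rendered as defective: "folded" fibers (collapsed,
#' low-circularity outline) and "oblique" fibers (tilted axis, area inflated
#' by 1/cos tilt). The returned truth table holds every fiber's exact
#' polygon metrics, computed from the generating contours by the same
#' morphometry code the pipeline uses on segmented contours.
#'
#' @param n_fibers Number of fibers in the field.
#' @param population A [fiber_population()].
#' @param scale A [calibration_scale()]; default 0.1 um/px puts fibers at
#'   roughly 150-250 px across.
#' @param prop_folded,prop_oblique Expected fractions of defective fibers.
#' @param image_size `c(height, width)` in px; sized automatically from the
#'   fiber radii when `NULL`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param n_creases Number of faint streak artifacts.
#' @param wall_intensity,background_intensity Rendering intensities.
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the same seed reproduces the scene bit-exactly.
#' @param image_id Scene identifier used in fiber names
#'   (line_capsule_slide_image convention in real data).
#' @param line Line label written to the truth table.
#' @param max_attempts Placement attempts per fiber before giving up.
#' @return Object of class `fiber_scene`: list with `image` (matrix in
#'   `[0, 1]`), `wall_mask` (noise-free logical wall mask), `truth` (tibble:
#'   shape parameters, contours in px, `quality` label, and exact canonical
#'   + derived metrics), `scale`, `image_id`, `seed`.
#' @export
simulate_scene <- function(n_fibers = 50, population = fiber_population(),
                           scale = calibration_scale(um_per_px = 0.1),
                           prop_folded = 0.05, prop_oblique = 0.05,
                           image_size = NULL, noise_sd = 0.03,
                           n_creases = 1, wall_intensity = 0.8,
                           background_intensity = 0.12, seed = NULL,
                           image_id = "sim_1_1_1", line = "simline",
                           max_attempts = 200) {
  if (!is.null(seed)) set.seed(seed)
  s <- as_scale_factor(scale)
  shp <- sample_fiber_shape(n_fibers, population)
  quality <- sample(c("good", "folded", "oblique"), n_fibers, replace = TRUE,
                    prob = c(1 - prop_folded - prop_oblique,
                             prop_folded, prop_oblique))
  folded <- quality == "folded"
  oblique <- quality == "oblique"
  # folded: collapsed outline, below the default circularity floor
  shp$aspect[folded] <- stats::runif(sum(folded), 0.06, 0.10)
  shp$dent_depth[folded] <- stats::runif(sum(folded), 0.70, 0.80)
  # oblique: strong axis deviation, area inflated past the area ceiling
  shp$tilt_angle[oblique] <- stats::runif(sum(oblique), 76, 82) * pi / 180

  # build each fiber at the origin; exact bounding radii drive the packing
  fibers0 <- purrr::map(seq_len(n_fibers), function(i) {
    kidney_fiber(
      true_area_um2 = shp$true_area_um2[i], aspect = shp$aspect[i],
      dent_depth = shp$dent_depth[i],
      wall_thickness_fraction = shp$wall_thickness_fraction[i],
      rotation = shp$rotation[i], tilt_angle = shp$tilt_angle[i]
    )
  })
  r_px <- purrr::map_dbl(fibers0, function(fb) {
    max(sqrt(rowSums(unclass(fb$outer)^2)))
  }) / s
  if (is.null(image_size)) {
    side <- ceiling(sqrt(n_fibers) * 2.6 * mean(r_px) + 2 * max(r_px))
    image_size <- c(side, side)
  }
  h <- image_size[1]; w <- image_size[2]

  centers <- matrix(NA_real_, n_fibers, 2)
  margin <- 4
  for (i in seq_len(n_fibers)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cx <- stats::runif(1, r_px[i] + margin, w - 1 - r_px[i] - margin)
      cy <- stats::runif(1, r_px[i] + margin, h - 1 - r_px[i] - margin)
      if (i == 1 || all(sqrt((centers[seq_len(i - 1), 1] - cx)^2 +
                             (centers[seq_len(i - 1), 2] - cy)^2) >
                        r_px[seq_len(i - 1)] + r_px[i] + margin)) {
        centers[i, ] <- c(cx, cy)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(paste("could not place", n_fibers, "fibers without overlap;",
                  "use fewer or smaller fibers or a larger image"))
    }
  }

  wall <- matrix(FALSE, h, w)
  fibers <- vector("list", n_fibers)
  for (i in seq_len(n_fibers)) {
    # px-space contours for rendering and ground truth
    fb_px <- purrr::map(fibers0[[i]], function(p) {
      as_contour(sweep(unclass(p) / s, 2, centers[i, ], `+`))
    })
    wall <- rasterize_fiber(wall, fb_px$outer, fb_px$lumen)
    fibers[[i]] <- fb_px
  }

  img <- matrix(background_intensity, h, w)
  img[wall] <- wall_intensity
  if (n_creases > 0) {
    for (ci in seq_len(n_creases)) {
      x0 <- stats::runif(1, 0, w); ang <- stats::runif(1, -0.3, 0.3)
      cols <- pmin(pmax(round(x0 + tan(ang) * seq_len(h)), 1), w)
      img[cbind(seq_len(h), cols)] <- img[cbind(seq_len(h), cols)] - 0.06
    }
  }
  img <- img + stats::rnorm(h * w, 0, noise_sd)
  img <- pmin(pmax(img, 0), 1)

  truth <- dplyr::bind_cols(
    tibble(
      name = paste0(image_id, "_", seq_len(n_fibers)),
      quality = quality,
      center_x_px = centers[, 1], center_y_px = centers[, 2],
      outer_contour = purrr::map(fibers, "outer"),
      lumen_contour = purrr::map(fibers, "lumen")
    ),
    shp
  )
  metrics <- purrr::map2_dfr(
    truth$outer_contour, truth$lumen_contour,
    function(o, l) {
      dplyr::bind_rows(fiber_record(
        "x", measure_contour(l, s), measure_contour(o, s), line = line))
    })
  metrics$Name <- truth$name
  truth <- dplyr::bind_cols(truth, metrics[setdiff(names(metrics), "Name")])

  structure(
    list(image = img, wall_mask = wall, truth = truth,
         scale = calibration_scale(um_per_px = s),
         image_id = image_id, line = line, seed = seed),
    class = "fiber_scene"
  )
}

#' Exact canonical table of a synthetic scene
#'
#' The ground-truth counterpart of the pipeline's output: one canonical row
#' per generated fiber, computed from the exact generating polygons, with
#' derived metrics appended and the quality label in a `Quality` column —
#' same schema as [measure_image()]'s table so the two can be diffed
#' directly.
#'
#' @param scene A [simulate_scene()] result.
#' @param good_only Keep only fibers generated as good.
#' @return Canonical + derived tibble with an extra `Quality` column.
#' @export
ground_truth_table <- function(scene, good_only = FALSE) {
  stopifnot(inherits(scene, "fiber_scene"))
  tr <- scene$truth
  if (good_only) tr <- tr[tr$quality == "good", , drop = FALSE]
  tab <- dplyr::bind_cols(tibble(Name = tr$name),
                          tr[setdiff(canonical_names, "Name")])
  tab <- derive_fiber_metrics(tab)
  tab$Quality <- tr$quality
  tab
}

#' @export
print.fiber_scene <- function(x, ...) {
  cat(sprintf("<fiber_scene> %s: %d x %d px, %d fibers (%s), %g um/px\n",
              x$image_id, nrow(x$image), ncol(x$image), nrow(x$truth),
              paste(names(table(x$truth$quality)),
                    table(x$truth$quality), collapse = " ", sep = ":"),
              x$scale$um_per_px))
  invisible(x)
}

#' @describeIn simulate_scene Rendered scene with ground-truth contours
#'   overlaid, colored by quality label.
#' @param object A `fiber_scene`.
#' @param ... Unused.
#' @export
autoplot.fiber_scene <- function(object, ...) {
  img <- object$image
  raster_df <- tibble(
    x = rep(seq_len(ncol(img)) - 1, each = nrow(img)),
    y = rep(seq_len(nrow(img)) - 1, times = ncol(img)),
    value = as.vector(img)
  )
  cont <- object$truth |>
    dplyr::mutate(pts = purrr::map(.data$outer_contour, ~ as_tibble(unclass(.x)))) |>
    dplyr::select("name", "quality", "pts") |>
    tidyr::unnest("pts")
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = raster_df,
                         ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_path(data = cont,
                       ggplot2::aes(.data$x, .data$y, group = .data$name,
                                    color = .data$quality), linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
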