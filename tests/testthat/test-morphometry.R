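test_that("polygon area and perimeter are exact on squares and scale correctly", {
  sq <- as_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  s1 <- calibration_scale(um_per_px = 1)
  s2 <- calibration_scale(um_per_px = 2)
  expect_equal(polygon_area(sq, s1), 1)
  expect_equal(polygon_area(sq, s2), 4)  # areas scale quadratically
  expect_equal(polygon_perimeter(sq, s1), 4)
  expect_equal(polygon_perimeter(sq, s2), 8)
  expect_equal(bounding_dims(sq, s1), c(height = 1, width = 1))
})

test_that("calibration scale derives um_per_px from the reference distance", {
  cs <- calibration_scale(reference_length_um = 50, reference_length_px = 500)
  expect_equal(cs$um_per_px, 0.1)
  expect_error(calibration_scale(reference_length_um = -1,
                                 reference_length_px = 10), "positive")
  expect_error(calibration_scale(), "supply")
})

test_that("area matches a pixel-rasterization oracle within 1% on large polygons", {
  set.seed(7)
  for (rep in 1:5) {
    poly <- random_star_polygon(12, 150, 280, center = c(300, 300))
    expect_equal(polygon_area(poly), raster_area_px(poly),
                 tolerance = 0.01)
  }
  # convex case >= 200 px across
  disk <- regular_polygon(64, 180, c(250, 250))
  expect_equal(polygon_area(disk), raster_area_px(disk), tolerance = 0.01)
  expect_equal(polygon_perimeter(disk), loop_perimeter(disk),
               tolerance = 1e-12)
})

test_that("perimeter of a fine regular polygon approaches the circle limit", {
  p360 <- regular_polygon(360, 100)
  expect_equal(polygon_perimeter(p360), 2 * pi * 100, tolerance = 1e-4)
  set.seed(42)
  poly <- random_star_polygon(17, 10, 90)
  expect_equal(polygon_perimeter(poly), loop_perimeter(poly),
               tolerance = 1e-12)
})

test_that("bounding dims follow a coordinate scan on rotated shapes", {
  rect <- as_contour(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))
  expect_equal(bounding_dims(rect), c(height = 1, width = 2))
  set.seed(3)
  poly <- random_star_polygon(20, 5, 60)
  a <- 0.83
  rot <- as_contour(unclass(poly) %*%
                      matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2))
  expect_equal(
    unname(bounding_dims(rot)),
    c(diff(range(rot[, 2])), diff(range(rot[, 1])))
  )
})

test_that("contour ingest validates and normalizes orientation", {
  expect_error(as_contour(cbind(c(0, 1), c(0, 1))), "at least 3")
  expect_error(as_contour(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
  cw <- cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))
  ccw <- as_contour(cw)
  expect_equal(polygon_area(ccw), 1)
  # normalization is idempotent and direction-independent
  expect_equal(unclass(as_contour(cw[4:1, ])), unclass(ccw),
               ignore_attr = TRUE)
  expect_true(is_simple_contour <- !inherits(try(
    as_contour(cw, check_simple = TRUE), silent = TRUE), "try-error"))
  bow <- cbind(c(0, 4, 1, 3), c(0, 0, 2, 2)) # self-crossing hourglass
  expect_error(as_contour(bow, check_simple = TRUE), "self-intersect")
})

test_that("circularity is 1 for circles, pi/4 for squares, and matches printed line means", {
  expect_equal(circularity(pi, 2 * pi), 1)
  expect_equal(circularity(1, 4), pi / 4)
  # outer shell of line Alpha: total outer area over outer perimeter
  expect_equal(round(circularity(115.49 + 13.59, 55.45), 2), 0.53)
  expect_error(circularity(-1, 4), "positive")
})

test_that("derived metrics reproduce the reference-line worked example", {
  rec <- fiber_record(
    "2888_A",
    lumen = shape_measures(area = 14, perimeter = 21),
    outer = shape_measures(area = 102.58 + 14, perimeter = 48.07),
    line = "2888"
  )
  out <- derive_fiber_metrics(rec)
  expect_equal(out[["Outer True Area"]], 102.58)
  expect_equal(round(out[["Theta"]], 2), 0.56)
  expect_equal(round(out[["Fiber Fineness"]], 2), 155.92)
  expect_equal(round(out[["Maturity Ratio"]], 2), 0.97)
  expect_equal(round(maturity_ratio(0.93), 2), 1.61)
})

test_that("metric identities hold to machine precision on random tables", {
  set.seed(11)
  n <- 50
  lum_a <- runif(n, 5, 25)
  out_a <- lum_a + runif(n, 50, 200)
  out_p <- runif(n, 40, 70)
  recs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    fiber_record(paste0("f", i),
                 lumen = shape_measures(lum_a[i], sqrt(4 * pi * lum_a[i])),
                 outer = shape_measures(out_a[i], out_p[i]),
                 line = "L")
  }))
  tab <- derive_fiber_metrics(recs)
  # conservation: outer = true + lumen, exactly
  expect_identical(tab[["Outer Area"]],
                   tab[["Outer True Area"]] + tab[["Lumen Area"]])
  # F linear in A_true with slope exactly 1.52
  expect_equal(tab[["Fiber Fineness"]], 1.52 * tab[["Outer True Area"]])
  # SF * theta = 0.577 * F and M * 0.577 = theta
  expect_equal(tab[["Standard Fineness"]] * tab[["Theta"]],
               0.577 * tab[["Fiber Fineness"]])
  expect_equal(tab[["Maturity Ratio"]] * 0.577, tab[["Theta"]])
})

test_that("theta and circularity are scale-invariant; theta tends to 1 for a full disc", {
  set.seed(5)
  poly <- random_star_polygon(30, 20, 80)
  for (f in c(0.37, 3.7)) {
    scaled <- as_contour(unclass(poly) * f)
    expect_equal(
      circularity(polygon_area(poly), polygon_perimeter(poly)),
      circularity(polygon_area(scaled), polygon_perimeter(scaled))
    )
  }
  # isoperimetric limit: wall of a disc with a vanishing lumen
  disc <- regular_polygon(720, 100)
  a <- polygon_area(disc); p <- polygon_perimeter(disc)
  expect_equal(theta(a - 1e-9, p), 1, tolerance = 1e-4)
})

test_that("degenerate metric inputs raise errors", {
  expect_error(
    fiber_record("x", shape_measures(10, 12), shape_measures(8, 11)),
    "lumen exceeds fiber"
  )
  expect_error(theta(-1, 10), "positive")
  expect_error(standard_fineness(100, 0), "positive")
  bad <- fiber_record("x", shape_measures(1, 4), shape_measures(10, 12))
  bad[["Outer True Area"]] <- 5 # break conservation
  expect_error(derive_fiber_metrics(bad), "must equal")
})
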