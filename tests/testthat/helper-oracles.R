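# Independent oracles and shared fixtures for the suite.

# pixel-center counting oracle for polygon area (crossing test, no shoelace)
raster_area_px <- function(contour, step = 1) {
  p <- unclass(contour)
  xr <- range(p[, 1]); yr <- range(p[, 2])
  xs <- seq(floor(xr[1]), ceiling(xr[2]), by = step)
  ys <- seq(floor(yr[1]), ceiling(yr[2]), by = step)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  sum(mgcv::in.out(rbind(p, p[1, ]), grid)) * step^2
}

# brute-force perimeter: explicit pairwise distances around the ring
loop_perimeter <- function(contour) {
  p <- unclass(contour)
  n <- nrow(p)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    total <- total + sqrt(sum((p[j, ] - p[i, ])^2))
  }
  total
}

# a random simple (star-shaped) polygon around the origin
random_star_polygon <- function(n = 12, r_min = 50, r_max = 250,
                                center = c(0, 0)) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_min, r_max)
  as_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# binary mask of one annulus, pixel-true (distance test, not polygons)
annulus_mask <- function(nrow, ncol, cx, cy, r_out, r_in) {
  xs <- matrix(rep(0:(ncol - 1), each = nrow), nrow, ncol)
  ys <- matrix(rep(0:(nrow - 1), times = ncol), nrow, ncol)
  d2 <- (xs - cx)^2 + (ys - cy)^2
  d2 <= r_out^2 & d2 > r_in^2
}

# one shared mid-size defect-free scene, built once per test run
shared_clean_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scene(n_fibers = 16, prop_folded = 0,
                               prop_oblique = 0, n_creases = 1,
                               seed = 101, image_id = "shared_1_1_1",
                               line = "shared")
    }
    cache
  }
})

# match measured candidates to truth fibers by bounding-box center
match_truth <- function(candidates, scene) {
  ctr <- cbind(candidates$x + candidates$w / 2,
               candidates$y + candidates$h / 2)
  apply(ctr, 1, function(p) {
    which.min((scene$truth$center_x_px - p[1])^2 +
              (scene$truth$center_y_px - p[2])^2)
  })
}

# brute-force maximal cliques of the non-significance graph (letters oracle)
maximal_nonsig_cliques <- function(groups, sig_lookup) {
  k <- length(groups)
  compatible <- function(set) {
    if (length(set) < 2) return(TRUE)
    prs <- utils::combn(set, 2)
    all(!vapply(seq_len(ncol(prs)), function(j) {
      sig_lookup(prs[1, j], prs[2, j])
    }, logical(1)))
  }
  subsets <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(groups, m, simplify = FALSE)
  }), recursive = FALSE)
  cliques <- Filter(compatible, subsets)
  Filter(function(cl) {
    !any(vapply(cliques, function(other) {
      length(other) > length(cl) && all(cl %in% other)
    }, logical(1)))
  }, cliques)
}
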