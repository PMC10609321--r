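#' Rule set for good/bad fiber classification
#'
#' The classification stage decides which detected cross-sections are
#' measurable fibers. Real micrographs contain folded fibers (collapsed,
#' low-circularity outlines), obliquely sectioned fibers (inflated apparent
#' area: a tilt of angle t multiplies area by 1/cos t), touching pairs,
#' clipped fibers at the image border, and debris. The defaults bracket the
#' per-line ranges typical of mature upland cotton (outer circularity around
#' 0.5-0.6, wall areas of roughly 100-160 um^2) widened by about 50%; every
#' bound is configurable.
#'
#' @param min_area_um2,max_area_um2 Accepted outer (whole-fiber) area range,
#'   um^2.
#' @param min_outer_circularity,max_outer_circularity Accepted outer
#'   circularity range.
#' @param require_lumen Reject candidates with no detectable lumen.
#' @param max_defect_holes Maximum number of extra (non-lumen) holes.
#' @param reject_border Reject candidates touching the image border (a
#'   clipped fiber cannot be measured).
#' @param max_theta Upper cap on the degree of cell-wall thickening.
#' @return A list of class `quality_rules`.
#' @export
quality_rules <- function(min_area_um2 = 20, max_area_um2 = 400,
                          min_outer_circularity = 0.30,
                          max_outer_circularity = 0.85,
                          require_lumen = TRUE, max_defect_holes = 2,
                          reject_border = TRUE, max_theta = 1.0) {
  if (min_area_um2 >= max_area_um2) {
    abort("`min_area_um2` must be below `max_area_um2`")
  }
  if (min_outer_circularity >= max_outer_circularity) {
    abort("`min_outer_circularity` must be below `max_outer_circularity`")
  }
  structure(
    list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
         min_outer_circularity = min_outer_circularity,
         max_outer_circularity = max_outer_circularity,
         require_lumen = require_lumen, max_defect_holes = max_defect_holes,
         reject_border = reject_border, max_theta = max_theta),
    class = "quality_rules"
  )
}

#' Score measured candidates against a quality rule set
#'
#' Evaluates every rule on every candidate. A candidate is good iff no rule
#' fails; the score is the fraction of rules passed, so partially plausible
#' candidates can be ranked in the audit output. Verdicts are a pure function
#' of (candidate, measures, rules) — no hidden state, no randomness — and
#' this function is the reference implementation of the pluggable scorer
#' contract: any function with the same signature and return columns can
#' replace it in [filter_scene()], e.g. to host a learned classifier.
#'
#' @param measured Measured candidate tibble from [measure_candidates()].
#' @param rules A [quality_rules()] set.
#' @return `measured` with columns `good` (logical), `reasons` (list of
#'   failed rule identifiers) and `score` in `[0, 1]`.
#' @export
score_candidates <- function(measured, rules = quality_rules()) {
  stopifnot(inherits(rules, "quality_rules"))
  n <- nrow(measured)
  checks <- list(
    area_min = measured$outer_area >= rules$min_area_um2,
    area_max = measured$outer_area <= rules$max_area_um2,
    circularity_min = measured$outer_circularity >= rules$min_outer_circularity,
    circularity_max = measured$outer_circularity <= rules$max_outer_circularity,
    lumen = if (rules$require_lumen) measured$has_lumen else rep(TRUE, n),
    defect_holes = measured$n_defect_holes <= rules$max_defect_holes,
    border = if (rules$reject_border) !measured$touches_border else rep(TRUE, n),
    theta = {
      ok <- rep(TRUE, n)
      with_lumen <- measured$has_lumen &
        measured$outer_area > measured$lumen_area
      th <- theta(
        pmax(measured$outer_area[with_lumen] - measured$lumen_area[with_lumen],
             .Machine$double.eps),
        measured$outer_perimeter[with_lumen]
      )
      ok[with_lumen] <- th <= rules$max_theta
      ok
    }
  )
  pass <- do.call(cbind, checks)
  measured$good <- apply(pass, 1, all)
  measured$reasons <- apply(pass, 1, function(p) names(checks)[!p],
                            simplify = FALSE)
  if (n == 0) measured$reasons <- list()
  measured$score <- if (n) rowMeans(pass) else numeric()
  measured
}

#' Partition a measured scene into good fibers and a rejection audit
#'
#' Applies a scorer (the rule engine by default) and splits the candidates.
#' Letters are preserved, never re-assigned, so fiber identities remain
#' traceable between the two outputs. Filtering is idempotent: re-filtering
#' the good subset returns it unchanged.
#'
#' @param measured Measured candidate tibble ([measure_candidates()]).
#' @param rules A [quality_rules()] set, passed to the scorer.
#' @param scorer A function `(measured, rules) -> measured + good/reasons/
#'   score` satisfying the [score_candidates()] contract.
#' @return List with `good` (scored tibble of accepted candidates) and
#'   `rejected` (audit tibble: letter, box, measures, score and a
#'   comma-separated `reasons` string).
#' @export
filter_scene <- function(measured, rules = quality_rules(),
                         scorer = score_candidates) {
  scored <- scorer(measured, rules)
  list(good = scored[scored$good, , drop = FALSE],
       rejected = scored[!scored$good, , drop = FALSE])
}

#' Write the rejected-fiber audit as CSV
#'
#' @param rejected The `rejected` element of [filter_scene()].
#' @param path Output CSV path.
#' @export
write_rejection_audit <- function(rejected, path) {
  flat <- dplyr::select(rejected, -dplyr::any_of(c("outer", "holes")))
  if (is.list(flat$reasons)) {
    flat$reasons <- purrr::map_chr(flat$reasons, paste, collapse = ",")
  }
  readr::write_csv(flat, path)
  invisible(path)
}
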