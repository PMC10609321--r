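---
title: "Cross-section morphometry of cotton fibers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-section morphometry of cotton fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibersect)
```

## The measurement model

A mature cotton fiber is a single dried cell: a cellulose secondary wall
enclosing a hollow lumen. In cross-section the wall appears as a closed
ring — roughly kidney-shaped once the fiber has dried — and everything a
breeder wants to know about maturity and fineness is a function of two
nested closed contours: the outer wall boundary and the lumen boundary.

From calibrated areas (µm²) and perimeters (µm), with
$A_\text{true} = A_\text{outer} - A_\text{lumen}$ the wall material's
cross-sectional area, the package computes per fiber:

* **Degree of cell-wall thickening**
  $\theta = 4\pi A_\text{true} / P_\text{outer}^2$. Dimensionless; a
  lumen-less circular fiber approaches 1 (isoperimetric limit), a thin-walled
  or collapsed fiber is far below it.
* **Fiber fineness** $F = \rho\, A_\text{true}$ with
  $\rho = 1.52\ \text{g/cm}^3$, the density of the cellulose wall. The
  product of an area in µm² and a density in g/cm³ is a linear density;
  numerically µm²·g/cm³ is the millitex.
* **Maturity ratio** $M = \theta / 0.577$, thickening relative to a
  reference standard-maturity fiber.
* **Standard fineness** $SF = 0.577\, F / \theta$, fineness adjusted to
  standard maturity so lines differing only in thickening compare on size.

Two formula choices deserve a note. First, one textual description of
fineness in the source literature reads as lumen area times density, but
every published value in the reference tables equals the *wall* area times
1.52 (e.g. 102.58 µm² × 1.52 = 155.92 millitex), and a lumen-based fineness
would be physically wrong (the lumen is empty space). The package therefore
defines $F = 1.52\,A_\text{true}$. Second, the maturity ratio is nowhere
given explicitly as a formula; all published values satisfy
$M = \theta/0.577$ to printed precision (0.56/0.577 = 0.97, 0.93/0.577 =
1.61), which is also the standard definition in fiber metrology, so that is
what is implemented.

$\theta$ uses the wall area but the **outer circularity** column uses the
total enclosed area ($4\pi A_\text{outer}/P_\text{outer}^2$); the two are
deliberately distinct quantities and both are reported.

Published line-level tables in this area are not always internally
consistent: in one reference panel the line-level $\theta$ (~0.9) cannot be
reproduced from the same table's printed mean areas and perimeters (~0.5).
Plugging means into a nonlinear ratio does not commute with averaging the
per-fiber ratio. `fibersect` computes $\theta$ per fiber and defines
line-level $\theta$ as the mean of per-fiber values, never as $\theta$ of
the means; full precision is kept internally and rounding to two decimals
happens only at report time (`write_canonical_table(digits = 2)`).

## Geometry and calibration

Contours are polygons in pixel coordinates (x rightward, y downward,
0-based), normalized counter-clockwise on ingest. Areas are shoelace sums,
perimeters edge-length sums including the closing edge; a
`calibration_scale` built from a reference distance converts lengths by
`um_per_px` and areas by its square. Degenerate (collinear) rings are
rejected at construction.

## Segmentation

Detection is classical: luminance collapse, Otsu (or fixed) thresholding of
the bright resin-embedded wall against the dark background, connected
components, and hole extraction inside each filled component. Contours are
traced by marching squares at the 0.5 level (`grDevices::contourLines`),
giving sub-pixel polygon boundaries, then smoothed with a 5-vertex circular
moving average. The smoothing matters for one number only: a raw level
contour tracks the pixel staircase and overestimates the perimeter of a
smooth boundary by about 5% (pixel-edge counting would be worse, up to
4/π), which would bias $\theta$ down by ~10%. With the window applied,
perimeters of shapes ≥ 200 px across are accurate to ~0.3% and enclosed
areas move by < 0.1%.

Numerical/edge choices, all configurable:

* components under 500 px² are dropped as debris;
* enclosed holes under 25 px² are filled as speckle noise, not lumens;
* when a component encloses several holes, the largest is the lumen (a
  fiber has one lumen); the rest count as defect holes against its quality
  score;
* components touching the image border are kept but flagged — a clipped
  fiber cannot be measured, so the default rules reject it;
* touching fibers are not split (no watershed); merged blobs fail the
  quality rules instead, mirroring how such fibers are excluded manually.

Letters follow reading order: candidates whose box-center y differ by less
than half the median box height form one row band; bands run top to bottom
and fibers left to right within a band, with ties broken by y then size.
This makes lettering deterministic and invariant to input order; beyond 26
candidates labels continue AA, AB, ...

## Quality filtering

The good/bad decision is a rule set over the measured shape: outer area
within [20, 400] µm², outer circularity within [0.30, 0.85], a lumen
required, at most 2 defect holes, no border contact, $\theta \le 1$. The
area and circularity windows bracket the published per-line ranges of
mature upland cotton (wall areas ~100–160 µm², outer circularity
~0.51–0.58) widened by roughly 50%, since the source workflow delegated
this decision to a trained network and published no explicit criteria; the
defaults make no claim of equivalence with that network's annotations. Every
verdict lists the rules that failed and a score (fraction passed), and the
scorer is a contract — any function with the same signature can replace the
rule engine, e.g. to host a learned classifier — so the pipeline depends
only on the interface.

## Statistics

The inferential battery mirrors standard practice for line comparisons:
per-line summaries, equal-variance one-way ANOVA, unadjusted pairwise
Student's t, and the Tukey–Kramer HSD

$$q_{ij} = \frac{|\bar y_i - \bar y_j|}{\sqrt{\tfrac{\text{MSE}}{2}
\left(\tfrac{1}{n_i} + \tfrac{1}{n_j}\right)}},$$

with MSE pooled on $N - k$ degrees of freedom and tail probabilities from
the studentized range distribution (`ptukey`); with equal $n$ this is
exactly the classical Tukey HSD, which the tests verify against
`TukeyHSD()`. Connecting letters are produced by insert-and-absorb: start
with one class holding all lines, split every class containing a
significant pair, absorb subset classes, and label classes in order of
their best-ranked member. The resulting display satisfies, exactly and by
construction, "two lines share a letter iff their difference is not
significant"; the test suite checks this against a brute-force enumeration
of maximal non-significant cliques for every significance pattern on up to
five groups. Report rows are sorted by descending mean. α defaults to 0.05
(the convention the published letter tables presumably used, though it is
not stated there) and is configurable.

Before inference, per-line outlier trimming is available: the default is
an IQR rule (inverse-ECDF quartiles, k = 1.5, no trimming when the IQR is
zero), replacing the visual histogram-based culling used in manual
workflows with a deterministic, reported equivalent; a z-score rule
(k = 3) is the alternative. Removed rows are always returned, never
silently dropped.

## The synthetic-scene generator

The simulator exists so that segmentation, filtering and statistics are
testable end to end with exact ground truth. It emulates a resin-section
field: 40–60 kidney-shaped cross-sections per image (default 50), bright
walls on a dark background, Gaussian sensor noise (sd 0.03 in [0,1]
intensity units), and occasional faint section-crease streaks.

The shape model is a base ellipse $(\cos\varphi,\ b\sin\varphi)$ with a
radial multiplier $1 - d\,((1+\cos\varphi)/2)^4$ — a single smooth concave
dent that gives two-parameter control of the kidney concavity. The lumen is
the outer contour scaled toward its center by (1 − wall fraction), which
guarantees a strictly interior hole. Each fiber is scaled so its wall area
equals the drawn target exactly, then rotated, tilted and placed without
overlap by rejection sampling.

Defaults (all configurable through `fiber_population()`): wall area
log-normal with mean 130 µm² and CV 0.25 (published line means span
~105–160 µm²); aspect 0.22 ± 0.05; dent depth 0.60 ± 0.10; wall fraction
0.69 ± 0.04 (lumen ≈ 10% of the outer area, matching lumen areas of
12–15 µm²); small axis tilts (half-normal, sd 0.05 rad) for good fibers.
The aspect/dent defaults were calibrated once so that mean outer
circularity over draws is ≈ 0.55, the center of the published per-line
range, which puts per-fiber $\theta$ near 0.5, consistent with the
per-fiber reference table. Defect fibers take parameters that realize their
defining failure mode under the default rules: "folded" fibers use aspect
0.06–0.10 with deep dents (outer circularity ≤ ~0.27, below the 0.30
floor); "oblique" fibers tilt 76–82°, and since sectioning at tilt $t$
stretches the cross-section by exactly $1/\cos t$ along one direction
(area × $1/\cos t$, implemented and tested to machine precision in
`tilt_transform`), their apparent outer areas land beyond the 400 µm²
ceiling for essentially all draws.

The default scale is 0.1 µm/px, putting fibers at roughly 150–250 px
across — large enough that polygon measurements on segmented contours are
accurate to well under 1%, small enough that a 25–50 fiber field renders in
seconds. All randomness flows through R's global generator, so one seed
reproduces a scene bit-exactly.

What the simulator does *not* emulate: optical point-spread blur, SEM
charging, partial focus in thick sections, wall-thickness variation around
the ring, touching or overlapping fibers, and staining variability. Tests
passing on synthetic scenes therefore demonstrate the correctness of the
geometry, bookkeeping and statistics under realistic shape and noise
conditions — not robustness to every artifact of real micrographs.

## Problem sizes used in the checks

The end-to-end recovery check simulates five lines with distinct wall-area
means (105–160 µm²), 100 fibers per line rendered as four 25-fiber fields,
and requires line means of $A_\text{true}$, $\theta$ and $F$ from the full
pipeline to land within 3% of the generating values; the per-line CV is
0.10 in that scenario so the 3% window spans ≈ 3 standard errors of a
100-fiber mean. Power of the letter display is checked by 100 replicates of
a five-line design (n = 100/line) with one line shifted a full standard
deviation: the shifted line must separate from all others in ≥ 95% of
replicates. ANOVA size is verified on 1000 null replicates (5 × 20). These
sizes keep the whole suite to a few minutes while leaving the Monte-Carlo
margins comfortable.

## Known limitations

* No watershed separation of touching fibers; dense fields lose merged
  pairs to the quality filter rather than recovering them.
* The rule-based classifier is a transparent stand-in for the original
  learned good/bad model; its defaults are bracketing heuristics, not a
  reproduction of that model's annotations (which are unpublished).
* Letter displays are deterministic and exhaustively verified to satisfy
  the sharing contract on every significance pattern up to five groups, but
  they are not guaranteed to use the absolute minimum number of letters in
  adversarial patterns on more groups.
* Line-level $\theta$ is the mean of per-fiber $\theta$; comparing it
  against values computed from line-mean areas and perimeters will
  disagree, by design (see above).
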