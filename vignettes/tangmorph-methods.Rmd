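---
title: "Outline morphometrics of tanged tools: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics of tanged tools: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tangmorph)
```

## The scientific question

Tanged (stemmed) stone tools pose a functional puzzle: their silhouette
resembles a projectile point, but projectiles and hand-held cutting or
scraping tools leave different *resharpening* signatures. A tool kept in
its haft and repeatedly resharpened loses length from the tip while the
tang — the part buried in the haft — stays fixed; if one lateral edge is
preferred, the outline also grows increasingly asymmetric as the tool
shrinks. tangmorph implements the outline-morphometric machinery needed to
read those signatures from closed 2-D silhouettes: elliptical Fourier
parametrization with a specific standardization dialect, a
principal-component shape space with extreme-shape reconstruction and
external-sample projection, and the classical statistics (Welch
comparisons, size regressions of shape scores, major-axis allometry,
score spread by length quantile) that connect shape to reduction.

Because the original museum photographs behind published analyses of this
kind are generally not available, the package ships a first-class
synthetic generator: parametric tanged-tool silhouettes with known
elongation, tip pointedness, side-to-side asymmetry and tang fraction,
plus a staged resharpening simulator. Every pipeline stage is tested
against this ground truth.

## Elliptical Fourier analysis

A closed outline is a pair of periodic coordinate functions
$x(t), y(t)$, expanded as

$$x(t) = A_0 + \sum_{n=1}^{H} a_n \cos nt + b_n \sin nt,\qquad
  y(t) = C_0 + \sum_{n=1}^{H} c_n \cos nt + d_n \sin nt,$$

four real coefficients per harmonic. `efa_forward()` evaluates the
coefficient integrals *exactly* on the piecewise-linear contour
(Kuhl–Giardina segment integrals), not by an FFT of sampled points, so
polygons are represented exactly and the result does not depend on
sampling phase.

**Parametrization.** The coefficients of a curve depend on how it is
parametrized. tangmorph assigns each vertex an equal parameter increment.
Two consequences follow. First, after `resample_outlines()` (equal
arc-length spacing, the pipeline default) this coincides with the
classical chord-length parametrization used throughout the morphometric
literature. Second, an ellipse traced at uniform parameter is *exactly*
one harmonic — the natural calibration case — whereas under forced
chord-length parametrization an ellipse leaks power into higher harmonics
(its first-harmonic amplitude for a 2:1 ellipse would be 1.83, not 2).
The uniform convention keeps the ellipse examples exact, makes
`efa_inverse()` followed by `efa_forward()` an identity in the
dense-sampling limit (quadratic convergence; about 1e-9 coefficient error
at $2^{17}$ points), and changes nothing for pipeline data.

**Standardization dialect.** `efa_standardize()` applies, in coefficient
space:

1. *Translation*: offsets $A_0, C_0$ set to zero.
2. *Size*: all coefficients divided by the square root of the source
   outline's area, so the reconstructed outline has unit area. Area — not
   the semi-major axis — is the size measure.
3. *Rotation*: the whole coefficient set is rotated so the best-fitting
   (first-harmonic) ellipse's major axis lies along $+x$. The
   coefficients are *not* divided by the semi-major axis length, so
   elongation (the first-harmonic axis ratio) survives as a shape
   variable — deliberately, since elongation along the reduction axis is
   part of the signal.
4. *Start point*: the parametric start is moved to the major-axis end at
   larger $x$, making coefficient vectors comparable across specimens.

The 180° ambiguity of an ellipse axis is resolved by the **minimal
in-plane rotation** (never more than a quarter turn). An earlier design
re-detected the tang on the reconstructed outline and put it left; that
detector necessarily confuses a pointed tip (which is narrower than the
stem) with the tang and silently flipped pointed specimens, reversing the
sign of their asymmetry coefficients. Orientation is therefore the job of
`orient_outlines()` *before* the transform — an oriented outline is a
precondition — and the standardization only preserves it. The
standardized coefficients are then invariant to input translation, scale,
and rotation up to a quarter turn beyond the ellipse tilt (tested at 36°).

A degenerate first harmonic (a circle, semi-axes equal within 1e-9) has
no defined orientation; rotation is skipped with a warning rather than
injecting an arbitrary angle.

**Truncation.** Harmonic $n$ carries power
$(a_n^2+b_n^2+c_n^2+d_n^2)/2$. `choose_harmonics()` returns the smallest
$H$ at which every specimen's cumulative power fraction reaches the
threshold (default 0.99). Eleven harmonics — 44 coefficients — is the
conventional choice for tanged-tool outlines. One subtlety: the cumulative
fraction at the last *available* harmonic is 1 by construction, so a
threshold reached only there is indistinguishable from an unreachable one
and raises an error asking for spectra at larger $H$.

## Shape space

`fit_shape_pca()` performs PCA on the covariance (not correlation) matrix
of the standardized coefficients — they share units, and the near-constant
columns pinned by the normalization ($b_1, c_1 \approx 0$) contribute
nothing but keep the vector invertible back to an outline. Eigenvector
signs are fixed (largest-magnitude loading positive) for reproducibility.
`extreme_shapes()` reconstructs the outline at mean $\pm$ the extreme
observed score along a component — the visual key for reading a component
as "asymmetry" or "elongation". `project_shapes()` places an external
sample into an existing space without refitting, which is how a
known-projectile population is compared against a tool population.

**Confidence ellipses.** Published cluster summaries of this kind do not
state whether they are data ellipses or standard-error ellipses of the
mean. tangmorph defaults to the *data ellipse* (2×2 score covariance
scaled by the $\chi^2_2$ quantile): clusters of hundreds of specimens
drawn with broadly overlapping ellipses are only possible with data
ellipses, standard-error ellipses being roughly $\sqrt{n}$ times smaller.
`confidence_ellipse(type = "mean")` exposes the other reading.
`ellipse_overlap()` classifies two ellipses as disjoint, overlapping, or
nested by polygonal approximation at 256 vertices.

## Classical morphometry

* `measure_tang_tip()` — the tang/tip boundary is rarely defined
  operationally in the literature. tangmorph detects it as the largest
  positive jump of the smoothed width profile $w(x)$ (the shoulder above
  the tang notches) within the left 60 % of the length, requiring the
  jump to exceed 15 % of the maximum width; a monotone profile (plain
  ellipse) is an explicit detection error, and an explicit per-specimen
  hint always wins. On the generator's parameter space the detector
  recovers the true tang fraction within 0.03 without hints.
* `welch_test()` — the unequal-variance two-sample statistic with
  Welch–Satterthwaite degrees of freedom. (Published wording sometimes
  says "equal variance" while reporting fractional df; fractional df
  only arise from the unequal-variance form, which is what is
  implemented.)
* `major_axis()` — model-II regression: the slope of the first principal
  axis of the bivariate covariance, appropriate when both variables (log
  tip and log tang length) carry error. The isometry test is a seeded
  percentile bootstrap over specimens: a closed-form test exists, but the
  published quantity is a confidence interval with no stated method, and
  the bootstrap is distribution-light and exactly reproducible. The slope
  is invariant to the logarithm base and to axis swapping (reciprocal).
  Both orientations are exposed; the default regresses log tang length on
  log tip length, as the published analysis is worded. No
  multiple-testing correction is applied anywhere, matching the
  single-comparison reporting style of the source analyses.
* `spread_by_length()` — median, IQR and retouched fraction of a score
  within length classes, either quantile bins (equal counts) or
  equal-width segments; the descriptive device for "short tools are more
  often extremely asymmetric". It is deliberately descriptive — a formal
  variance test can be run on its output but is not part of the summary.
* `cumulative_type_curve()` — cumulative percentages over ascending
  integer type codes, with the optional re-classification of
  endscraper-tip codes 30–31 as transverse scrapers 22–23.

## The synthetic stated world

`generate_tool()` builds a silhouette from a half-width profile: a
rounded-trapezoid tang of length $f \cdot L$, a notch of fixed depth
(25 % of the tang half-width, not a free parameter — keeping the truth
vector identifiable), a smooth cubic blend to the blade, and a blade that
tapers to the tip as a superellipse $h \propto (1-u^q)^{1/q}$: $q$ small
is pointed, $q$ large is blunt and endscraper-like. Asymmetry $s$ scales
the upper edge by $1+s$ and the lower by $1-s$. Gaussian jitter
(sd = 1 % of the blade half-width by default) is added to the half-width
profile and *shared by the two edges*: this keeps a symmetric tool exactly
mirror-symmetric and makes the $\pm s$ pair exact mirror images under the
same seed, so symmetry invariants can be tested to machine precision.
Independent per-edge noise would be marginally more realistic but would
turn every exact symmetry test into a statistical one.

`simulate_reduction()` implements the four classic trajectories: per step
the tip length shrinks by a fixed fraction (default 10 %) with the tang's
absolute length held fixed; `edge_left`/`edge_right` drift the asymmetry
by 0.07 per step, `rounding` inflates the taper exponent, and
`symmetric_point` changes neither. Tang-length noise exists only at
lineage creation — tang length "varies randomly" across specimens but is
constant within a lineage, which is precisely what makes the
retouched-vs-unretouched tang comparison null.

**Default calibration.** No quantitative reduction rates are published,
so the defaults were fixed once against the *qualitative published
structure* of this tool class: a shape space whose leading components
separate side-to-side asymmetry and elongation cleanly (published
variance shares ≈ 48 % asymmetry, 31 % elongation, 5 % tang/roundness),
retouched tips clearly shorter at $p < 0.01$ with tangs indistinguishable,
and asymmetry spreading out in the shortest length quartile. That
calibration drove two choices. First, asymmetry drift per step (0.07) is
large relative to the creation spread (sd 0.12, truncated at ±0.2), so
reduction — not initial blank shape — dominates extreme asymmetry.
Second, the nuisance spreads (pointedness sdlog 0.2, tang fraction
0.24–0.32, half-width sds 1.5–2 on means of 14 and 22) are tight enough
that asymmetry and elongation each align with a single principal
component at $|r| \ge 0.9$; with much wider pointedness variation, the
direction of the asymmetry response in coefficient space rotates with tip
shape and no linear component can track the generating parameter. The
creation tang fraction stays below 0.35 so that five reduction steps at
10 % keep the realized fraction inside its (0.1, 0.5) bound.

What the generator does *not* emulate: flaking scars and edge serration
(the jitter is smooth-profile noise), raw-material constraints, 3-D form,
and any correlation between blank size and shape at creation. A green
test therefore establishes that the *pipeline* recovers what it claims
from outlines with these properties — not that real assemblages are this
clean.

The arrowhead-like comparison population
(`generate_projectile_population()`) is drawn elongated (narrow blade,
length/width ≈ 4.7 vs ≈ 1.9 for tools), nearly symmetric (asymmetry sd
0.02) and unreduced, mirroring a hafted-projectile reference sample:
projected into a tool shape space it shows a fraction of the reference
variance along the asymmetry component.

## Numerical choices

* **Resampling** is equal arc-length spacing relaxed to a fixed point
  (iterated re-spacing, tolerance 1e-12, at most 512 passes), making
  `resample_outlines()` idempotent to 1e-9 — without relaxation,
  resampling an already-resampled outline shifts points by ~1e-4 of the
  scale. The perimeter is preserved well within 0.1 %.
* **Mask tracing** uses marching squares at the 0.5 level with linear
  interpolation (sub-pixel), 8-connected component labelling, outer
  contour only; holes are discarded because specimens are silhouettes.
  Raster rows are flipped so y increases upward.
* **Default density** is 512 points per outline: at 11 harmonics the
  discretization error of the segment-exact integrals is ~1e-5 of the
  coefficient scale, two orders below the jitter floor of real
  digitization.
* **Degenerate inputs** error loudly and specifically: fewer than 8
  distinct points, zero signed area, zero perimeter, all-zero power
  spectra, collinear score clouds, zero-variance coefficient matrices.
* **Ties**: quantile binning with tied lengths raises an error naming the
  empty bin rather than silently merging classes; the auto-orientation
  detector declares a tie below 1 % relative width difference and asks
  for a hint.

## Known limitations

* The tang/tip boundary detector assumes a shoulder; heavily reduced
  pieces whose tang fraction approaches the blade can defeat it (supply
  hints from an expert table in that case).
* Auto-orientation cannot distinguish a narrow stem from a pointed tip —
  by construction of the width heuristic. Conventionally digitized
  (tang-left) material should use `tang_side = "asis"`.
* The published per-component variance percentages of real assemblages
  are properties of museum samples whose photographs are not deposited;
  they guide the generator's calibration but are not reproduction
  targets.
* Projection assumes the external sample was digitized, resampled and
  standardized identically to the reference; the column/normalization
  check enforces the mechanics but cannot audit digitization practice.
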