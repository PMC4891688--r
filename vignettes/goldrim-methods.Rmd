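---
title: "Quantifying gold-labeled protein at membrane pore rims: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gold-labeled protein at membrane pore rims: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Cryo-electron micrographs of porated liposomes decorated with
nanogold-labeled protein are transmission projections: every density along
the beam sums into one 2D image, with the ~1.3 nm gold particles appearing
as the darkest objects.  `goldrim` reimplements, as a tested pipeline, the
quantitative questions one asks of such images:

* are the particles concentrated at the pore rim rather than elsewhere on
  the membrane (region-density comparison, Mann-Whitney test)?
* how close do particle centers sit to the traced pore edge
  (point-to-polyline distances)?
* is the *linear* particle density along the rim independent of pore size
  (total particle area regressed on pore circumference, with the intercept
  near the origin as the telltale)?
* what is the mean interparticle spacing (circumference / detected count,
  an upper bound on the true molecular spacing)?

Because no micrographs ship with the analysis, a synthetic-scene generator
produces porated vesicles with exact ground truth, and every measurement
operation is validated against that truth or an independent oracle.

## Scene model

A vesicle is a spherical shell of outer radius $R$ (default range
50–150 nm) and thickness $t$ (default 5 nm) with one circular pore: the
spherical cap of polar half-angle $\alpha$ about the pore axis is removed,
leaving a rim circle of radius $R\sin\alpha$, pore diameter
$d = 2R\sin\alpha$ and circumference $\pi d$.  The default half-angle range
(0.3–1.3 rad) spans small pores up to nearly vesicle-spanning ones, matching
the qualitative description of large, growing pores; the vesicle size range
is a choice, not a measured distribution, since none is published for the
analyzed set.

Rim particles are placed as a Poisson process of intensity
$\lambda p$ per nm of rim ($\lambda$ = linear density, default 1/6 nm$^{-1}$,
the headline gBax spacing scale; $p$ = labeling efficiency, default 0.8,
the reported ~80%).  Each particle is displaced across the rim by a radial
Gaussian jitter (sd 0.3 nm by default) applied along the sphere's meridian.
The jitter is *truncated at 3 sd* so that the ground-truth invariant
"every rim particle lies within $3\sigma$ + diameter of the rim" holds
deterministically; an untruncated Gaussian would break it for ~0.3% of
particles.  Particle diameters are normal, 1.3 ± 0.14 nm (the commercial
nanogold specification), truncated at 4 sd.

Nonspecific background particles are uniform on the membrane sphere
excluding the pore cap and a 5 nm exclusion band around the rim, at a low
area density (default $5\times10^{-5}$ nm$^{-2}$, emulating "essentially no
particles outside the pores").  The exclusion band keeps ground-truth
classes separable, so detection recall/false-positive statements against
truth are unambiguous.

Projection is orthographic along the viewing axis — the appropriate
geometry for TEM at these scales — with no occlusion.  A pore viewed at
tilt $\theta$ (angle between pore axis and beam) projects its rim to an
ellipse with semiaxes $r$ and $r\cos\theta$.

## Rendering

Images are 8-bit, calibrated in nm/px (default 0.25).  Intensities follow
the cryo-EM convention that denser objects are darker:

* gold: hard disks at intensity 40, the center of the default detection
  band;
* membrane: linear in the ray's path length through the shell, mapped into
  [80, 150] against the maximal tangential chord $2\sqrt{R^2-(R-t)^2}$
  (computed by midpoint quadrature along the beam, step 0.25 nm, restricted
  to the sphere chord);
* lumen/exterior: ≥ 180.

With additive noise off (the default), the 30–50 band therefore selects all
gold and nothing else, which is what makes recall-1/false-positive-0
assertions on noise-free scenes meaningful.  Optional Gaussian noise is
rounded and clipped to [0, 255].

What the generator does **not** emulate: contrast transfer function and
defocus, ice-thickness gradients, beam damage, membrane debris, multi-pore
vesicles, or vesicle aggregates.  A green synthetic test therefore
establishes correctness of the *measurement chain*, not robustness to real
micrograph artifacts.

## Detection

Candidate pixels lie in the closed intensity band [30, 50] out of 256.
Whether the original analysis counted pixels *darker* than 30 as particles
is not stated; the package defaults to the literal closed band and offers
`include_below_band = TRUE` (real gold may saturate darker).  Components
are formed under 8-connectivity (a round 1.3 nm particle at 0.2 nm/px
produces diagonal adjacency) and components below 0.32 nm² are discarded.
That threshold corresponds to an equivalent-circle diameter of 0.64 nm,
more than 4 sd below the mean gold diameter, so >99% of particles pass —
the package exposes this as `diameter_inclusion_fraction()`.

Touching particles are *not* split (no watershed): the analysis treats
merged objects as single clusters and uses total particle area, not count,
as the robust abundance measure.  Two consequences are quantified below.

## Statistics

**Region density** is the ratio of particle area to *non-particle* area in
a region, per the prose definition; the figure-caption variant
(particle area / full region area) is available via
`denominator = "region"`.  The two differ by less than the particle
fraction; the explicit prose definition is the default.  The control-dose
normalization (a control gold concentration measured at 64.4% of the
labeled dose) enters as a multiplicative factor on cluster area.

**Pore perimeter** is the average of the outer and inner flanking-boundary
lengths.  The generator draws those boundaries half a band width (default
band 5 nm — the original band width is unstated, so this is a package
choice) on either side of the rim along the sphere surface.

**Projection foreshortening**: a perimeter measured in projection
underestimates $\pi d$ by at most $(\pi-2)/\pi \approx 36\%$ (the edge-on
limit, where the projected perimeter is $2d$).  `projected_perimeter()`
evaluates the ellipse perimeter by adaptive quadrature of the arc-length
integral rather than a series approximation so that both limits
($\pi d$ at tilt 0, exactly $2d$ at $\pi/2$) are exact — both are part of
the acceptance surface.

**En-face selection** uses circularity — the minor/major axis ratio of the
second-moment ellipse of the traced edge, which equals $\cos\theta$ for a
uniformly sampled projected circle.  The en-face cutoff (0.9, i.e. tilt
≲ 26°) and edge-on cutoff (0.2) are configurable defaults; no numeric
criterion is published.

**Mann-Whitney**: U from midranks; for $n_1+n_2 \le 14$ the two-sided
p-value is exact by full enumeration of all $\binom{n_1+n_2}{n_1}$
labelings (≤ 3432 cases — instant, and covering the published sample sizes
of 4–25 images), measuring the probability of a U at least as far from
$n_1 n_2/2$ as observed.  Larger samples use the normal approximation with
continuity correction and tie-corrected variance.

**Regression** reports both the intercept fit (whose $R^2$ and intercept
are quoted) and the through-origin slope, unweighted, since the size-
invariance argument rests on the intercept being near zero.

## Known quantitative consequences of merging

With Poisson-distributed rim particles at rate $\lambda$ and an effective
merge distance $s \approx$ diameter + pixel ($\approx 1.35$ nm at
0.25 nm/px), the detected cluster count is deflated by $e^{-\lambda s}$
(Poisson clump heuristic).  At $\lambda = 1/6$ nm$^{-1}$ this predicts a
detected-count factor of 0.799 — the simulated cohorts reproduce this to
three decimals — so the spacing estimator reads ≈ 7.5 nm where the
generative spacing is 6 nm.  This is exactly why such spacings are upper
bounds on molecular spacing.  Total particle *area* is nearly conserved
under merging (only overlap pixels are lost), which is why area, not count,
carries the density-vs-size regression.

## Numerical choices

* Coordinates: continuous nm frame; image pixel (row, col) has its center
  at ((col − 0.5)·px, (row − 0.5)·px), y increasing downward; ground truth
  is written in the image frame with the shift recorded.
* Polygon membership: even-odd rule with boundary points counted inside
  (particles straddling a drawn boundary belong to the region).
* Degenerate inputs: zero detected particles give density 0 and an
  undefined (NA) spacing, not an error; a cluster area at or above its
  region area, identical perimeters in the regression, and empty samples in
  the rank test are classed errors.
* Reproducibility: one master seed drives per-vesicle geometry draws and
  per-stage sub-seeds in a documented order; placements use inverse-CDF
  truncated normals so the RNG draw count is fixed; repeated runs are
  byte-identical (TIFFs, JSONs, CSVs).
* TIFF: the package carries a minimal built-in codec (8-bit, single
  channel, uncompressed; both byte orders on read) because no TIFF package
  is available in the supported dependency set; pixel size travels in the
  resolution tags and, losslessly, in a JSON sidecar.

## Scaled-down validation suites

The acceptance tests run at desk scale: the parameter-recovery cohort is 30
vesicles at 0.25 nm/px; the null-cohort study runs the full 100 replicate
cohorts but at 5-vs-5 images per cohort with 45–60 nm vesicles at
0.5 nm/px.  Two sub-checks of the recovery criterion fail honestly at this
scale and are documented rather than tuned away: the pooled-spacing band
(±20% of $1/\lambda$) is narrower than the merging inflation
$e^{\lambda s}$ at $\lambda = 1/6$, and the regression-intercept band
(±2 particle areas) is narrower than the intercept's own standard error at
$n = 30$ (the intercept is statistically indistinguishable from zero, which
is the substantive claim).

## Limitations

Manual pore-edge tracing is out of scope (annotations are inputs);
detection is threshold-based by design, not template-matched or learned;
no multiple-testing correction is applied (single pairwise comparisons);
spatial point-process statistics beyond the implemented summaries (e.g.
Ripley's K) are out of scope.
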