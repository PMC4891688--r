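# goldrim

Quantification of nanogold-labeled protein density along membrane pore rims
in cryo-EM projection images — plus a synthetic-scene generator with exact
ground truth to validate every step of the measurement chain.

## The problem

When a pore-forming protein (the motivating case is Bax permeabilizing
liposomal membranes) is tagged with ~1.3 nm gold and imaged by
cryo-electron microscopy, the micrographs are 2D transmission projections
in which gold is the darkest feature.  The quantitative questions are:

* **Where is the protein?**  Particle density (particle area : non-particle
  area) inside pore regions vs elsewhere on the membrane, compared with an
  exact Mann-Whitney rank test.
* **How close to the edge?**  Shortest distances from particle centers to
  the traced pore edge; the fraction within 1 nm.
* **Does the rim density depend on pore size?**  Total particle area per
  pore regressed on pore circumference (the average of the outer and inner
  flanking-boundary lengths).  Constant linear density λ means a line
  through the origin with slope λ · (mean particle area).
* **How tightly packed?**  Interparticle spacing = circumference / detected
  particle count — an upper bound on molecular spacing, since unlabeled
  molecules and merged clusters deflate the count.
* **How wrong can a projected perimeter be?**  A circle of diameter d
  projects to an ellipse of perimeter between πd (en face) and 2d
  (edge-on), so the worst-case fractional error is (π − 2)/π ≈ 36%.

Detection mirrors the published procedure: pixels in the intensity band
30–50 (out of 256) are grouped into 8-connected components and components
smaller than 0.32 nm² are discarded — a threshold more than 4 standard
deviations below the mean gold diameter (1.3 ± 0.14 nm), so it admits
>99% of particles.

Because the original micrographs are not deposited, the package includes a
first-class simulator: spherical vesicles (radius 50–200 nm) with one
circular pore, rim particles placed as a Poisson process at fixed linear
density with sub-nm radial jitter, sparse nonspecific background particles,
arbitrary 3D orientation, orthographic projection, and calibrated 8-bit
rendering with full ground truth.

## Worked example

```r
library(goldrim)

cfg <- run_config(seed = 1, n_vesicles = 8, radius_range = c(50, 120),
                  pixel_size = 0.3, out_dir = "readme_run")
run_simulate(cfg)                        # TIFFs + ground truth + manifest
run_measure("readme_run", "readme_out", cfg)  # densities/pores/distances/tests CSVs
run_report("readme_out")
```

```
pores analyzed: 8
pooled interparticle spacing: 8.71 nm
area vs circumference: slope 0.1739 nm^2/nm, intercept -0.965 nm^2, R^2 0.851 (through origin: 0.1715)
mean pore density: 0.05278 (n = 8)
mean non_pore density: 0.00041 (n = 8)
pore_vs_nonpore_density: U = 64, p = 0.0009391 (normal_approx, n1 = 8, n2 = 8)
```

Reading this: the pore-region density is two orders of magnitude above the
non-pore density (U at its maximum, p < 0.001); particle area grows
linearly with circumference through an intercept near zero (constant linear
density); the pooled spacing of 8.7 nm sits above the generative 1/λ·p =
7.5 nm because touching particles merge into single clusters — the upper-
bound behavior the estimator is known for.

The analytic helpers print the two headline numbers directly:

```r
perimeter_error_bound()                      # 0.3634  (~36%)
equivalent_circle_diameter(0.32)             # 0.638 nm
diameter_inclusion_fraction(1.3, 0.14, 0.32) # 0.9999989 (> 99%)
mann_whitney(c(0.061, 0.054, 0.072, 0.049), c(0.002, 0.004, 0.001))
# U = 12, p = 0.05714 (exact)
```

A command-line interface wraps the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/goldrim.R", package = "goldrim"))')
Rscript "$CLI" simulate --out runs/demo --seed 4 --n 10 --pixel-size 0.3
Rscript "$CLI" measure  --in runs/demo --out runs/demo --band 30:50 --min-area 0.32
Rscript "$CLI" report   --in runs/demo
```

## Layout

* `R/`, `src/` — scene model, renderer (Rcpp), detection, ROI geometry,
  rim statistics, pipeline/CLI, minimal 8-bit TIFF codec.
* `vignettes/goldrim-methods.Rmd` — the model, parameter meanings and
  defaults, numerical choices, and what a green synthetic test does and
  does not establish.
* `tests/testthat/` — unit, property and oracle tests;
  `test-acceptance.R` holds the acceptance criteria.
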