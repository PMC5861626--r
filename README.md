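# bridgeflow

Hemodynamics of cerebral bridging veins (BVs) entering the superior
sagittal sinus (SSS), as a reproducible R pipeline. Cerebral venous
thrombosis clusters at these junctions; the hemodynamic explanation is
that wide veins entering the sinus at shallow angles -- which open
*against* the sinus stream -- carve out a near-stagnant pocket at the
dural entrance where the wall shear stress (WSS) collapses far below the
venous norm of 0.1-0.6 Pa, disabling shear-dependent anticoagulation.

The package provides, end to end:

* **Cohort statistics** (`read_cohort`, `summarize_cohort`, `pooled_mean`,
  `anova_oneway`): the anatomical table of vein diameters and entry
  angles, mean ± SD (min-max), with classic one-way ANOVA comparisons.
* **Synthetic cohorts** (`generate_cohort`, `solve_truncnorm_params`):
  moment-matched truncated-normal sampling that reproduces the published
  per-group moments and hard ranges (anterior n = 62: 2.0 ± 0.9 mm,
  93 ± 34°; posterior n = 75: 3.0 ± 1.1 mm, 43 ± 25°), deterministic
  under a fixed seed.
* **Parametric junction geometry** (`build_geometry`, `rasterize`,
  `wall_arclength`): a planar SSS channel with one straight vein, six
  labelled wall segments (SSU, SSD, SSO-U, SSO-D, BVU, BVD) with arc
  length anchored at the dural entrance, rasterized to a solver grid.
* **Steady flow** (`solve_steady`): a D2Q9 lattice Boltzmann solver
  (TRT collision, halfway bounce-back walls, non-equilibrium-extrapolation
  inlets/outlet) under venous conditions -- blood at 1050 kg/m³ and
  4.24e-3 Pa·s, 15 cm/s into the sinus, 10 cm/s into the vein, zero
  gauge pressure at the outlet.
* **WSS analysis** (`wall_shear_profile`, `stable_value`, `min_wss`,
  `average_wss`, `extent_below`): tau = mu |du/dn| along each wall,
  plateau ("stable") values, minima and their distance to the entrance.
* **Sweep findings** (`run_sweep`, `demarcation_threshold`,
  `classify_angle_groups`, `compare_anterior_posterior`, `ratio_percent`,
  `predilection_extent`): per-vein models, the demarcation threshold on
  sorted minima (maximal adjacent ratio, geometric-mean placement), the
  angle-group and anterior/posterior tables, and the ratio/extent
  findings.

A thin command line lives at `inst/exec/bridgeflow`
(`generate-cohort`, `run-sweep`, `analyze`, `report`); the methods are
documented in `vignettes/junction-hemodynamics.Rmd`.

## Worked example

One posterior-type vein (3 mm, 43°) against the sinus stream:

```r
library(bridgeflow)

cfg  <- run_config(L_up = 12, L_down = 30, L_bv = 20, spacing = 0.25,
                   solver = solver_config(tolerance = 2e-4, u_lat_max = 0.05,
                                          max_iterations = 250000L))
mod  <- run_model(d_bv = 3, alpha = 43, cfg)
round(mod$min[c("SSD", "BVU")], 4)
#>    SSD    BVU
#> 0.0048 0.0104
round(mod$position[c("SSD", "BVU")], 2)
#> SSD BVU
#>   8   2
round(mod$stable[c("SSD", "BVU")], 3)
#>   SSD   BVU
#> 0.483 0.656
```

Both walls that border the junction pocket -- the downstream sinus wall
(SSD) and the upstream vein wall (BVU) -- are depressed by roughly two
orders of magnitude below their plateaus, with the vein-wall minimum a
couple of millimetres up the vein: the predilection site the analysis
identifies. Steep entries (beyond about 105°) lift both minima back
toward their plateaus, and thin veins (at or below 1.2 mm) are excluded
from the grouped tables, following the threshold analysis this pipeline
reproduces (a caveat of the planar model: it overstates the influence of
thin veins, which leave a 3-D sinus essentially undisturbed -- see the
vignette's limitations).

(Numbers above are from the desk-scale configuration shown; absolute Pa
values depend on the planar idealisation and the assumed sinus caliber,
so the package reproduces the published analysis at the level of
structure -- trends, orderings, thresholds, ratios -- not absolute
magnitudes.)

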