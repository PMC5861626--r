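---
title: "Wall shear stress at bridging vein-sinus junctions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall shear stress at bridging vein-sinus junctions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cerebral venous thrombosis concentrates where bridging veins (BVs) drain
into the superior sagittal sinus (SSS). The hemodynamic hypothesis is that
particular junction morphologies -- wide veins entering at shallow angles --
depress the wall shear stress (WSS) near the dural entrance far below the
venous norm (0.1-0.6 Pa), disabling the shear-dependent anticoagulant
response of the endothelium. `bridgeflow` rebuilds that analysis as a
reproducible pipeline: a synthetic anatomical cohort, a parametric junction
model, a lattice Boltzmann flow solver, WSS profiling along labelled walls,
and the threshold/grouping analysis that identifies the thrombosis-prone
morphologies (diameter above about 1.2 mm, entry angle below about 65
degrees).

## Synthetic cohort

The measured anatomy is summarised by per-group moments and ranges: 62
anterior veins (diameter 2.0 +/- 0.9 mm on 0.6-5.2; entry angle 93 +/- 34
degrees on 40-170) and 75 posterior veins (3.0 +/- 1.1 mm on 0.8-5.8;
43 +/- 25 degrees on 10-90). `generate_cohort()` draws from truncated
normal distributions whose latent parameters are solved by moment matching
(`solve_truncnorm_params()`), so the *truncated* distribution -- not the
latent one -- reproduces the printed mean and SD. Sampling is by inverse
CDF, which gives exact support (no clipping, no rejection) and bit-for-bit
reproducibility under a fixed seed. Diameter and angle are independent by
default; a Gaussian-copula `correlation` knob exists because posterior
veins are jointly larger and shallower.

One published cell is mathematically unreachable: a truncated normal is
log-concave, and any log-concave distribution on an interval of width $w$
has SD at most $w/\sqrt{12}$ (the uniform limit). For the posterior entry
angle, $80/\sqrt{12} = 23.09 < 25$ degrees. The generator therefore warns
and uses the nearest attainable member of the family: the mean (43 degrees)
is matched exactly, the SD saturates near the bound (about 22.5 degrees).
Every other Table cell is feasible and matched to 1e-8.

The generator emulates the *marginal* anatomy only: it ignores the
clustering of veins within the six cadavers, any diameter-angle dependence,
and measurement error. Tests passing on synthetic cohorts therefore
validate the pipeline's statistics, not the anatomy itself.

## Junction geometry

`build_geometry()` models the junction in the plane: the SSS is a straight
channel of width `d_ss` along the x-axis (flow in +x), the vein a straight
channel of width `d_bv` whose centerline pierces the upper sinus wall at
the dural entrance (the coordinate origin for all reported positions). Six
wall segments are labelled: `SSU`/`SSD` (upper sinus wall upstream /
downstream of the vein mouth), `SSO_U`/`SSO_D` (opposite sinus wall, split
at the foot of the perpendicular from the entrance), `BVU`/`BVD` (vein
walls through the upstream and downstream junction corners). Arc length
`s` is zero at each wall's junction anchor; reported positions are `|s|`.

**Angle convention.** Bridging veins open *against* the sinus stream: the
entry angle is measured so that an acute angle means the vein tube leans
downstream and discharges an opposing jet. This choice is load-bearing.
Under the opposite convention (acute = co-flowing discharge) the simulated
junctions show no WSS deficit at shallow angles at all -- merging co-flowing
streams are smooth -- whereas the opposing-jet orientation produces the
documented phenomenology: a recirculating dead-water pocket in the acute
wedge between `SSD` and the vein mouth, a deeply depressed `SSD` minimum a
few millimetres downstream, and a near-stagnant zone on `BVU` one to three
millimetres up the vein wall. The orientation is recorded in the geometry
export metadata.

Dimensions the source anatomy does not constrain are explicit assumptions,
surfaced in `run_config()`: sinus width 8 mm (literature-typical SSS
caliber), sinus length 30 mm upstream and 60 mm downstream of the entrance
(downstream minima are reported out to 50 mm), vein length 20 mm (vein-wall
minima out to 13.5 mm). Absolute WSS magnitudes in Pa depend on these
choices and on the planar idealisation, which is why the package treats
magnitudes as internally consistent model outputs and reproduces the
published analysis only at the level of structure: trends, orderings,
thresholds, ratios.

`rasterize()` classifies a uniform grid (cell centers, half-open cells)
into fluid, solid, labelled wall, inlet and outlet cells. The default
spacing rule is `d_bv / 10` capped at 0.25 mm; the hard precondition is at
least 8 cells across the vein. Grid-aligned walls are resolved exactly when
`d_ss` is a multiple of the spacing; the oblique vein walls become
staircases, which matters for WSS extraction (below).

## Flow solver

`solve_steady()` marches the D2Q9 lattice Boltzmann equation to steady
state: two-relaxation-time (TRT) collision, halfway bounce-back walls,
velocity inlets and a zero-gauge-pressure outlet implemented by
non-equilibrium extrapolation anchored to an interior neighbour cell.
Blood is Newtonian (density 1050 kg/m^3, viscosity 4.24e-3 Pa s); inlet
means are 0.15 m/s (sinus) and 0.10 m/s (vein), plug profiles by default.
The intracranial ambient pressure (1333 Pa) is an additive constant in
incompressible rigid-wall flow and is carried as metadata only.

Numerical choices worth knowing:

* **Lattice scaling.** The solver prefers a relaxation time of 0.55
  (diffusive scaling, Mach shrinking linearly under refinement) but caps
  the lattice velocity at `u_lat_max`. At venous Reynolds numbers
  (about 300 in the sinus) on desk-scale grids the cap binds and tau falls
  to about 0.51-0.53.
* **Collision.** At those tau values BGK is fragile and the textbook
  magic-parameter TRT (Lambda = 1/4) under-relaxes the odd moments into
  instability; the default keeps the odd-moment rate fixed at 1.0, which
  is stable and accurate across the sweep. BGK remains available
  (`scheme = "lbm_bgk"`).
* **Grid-convergence verification.** Near tau = 1/2 the non-hydrodynamic
  (ghost) boundary modes decay over many cells and flatten the observed
  convergence of near-wall quantities, so the refinement study runs where
  the scheme is clean: a gentle channel flow (mean 0.01 m/s, Re about 20)
  at fixed tau = 0.7 over 16, 24 and 32 cells across, where the
  Poiseuille wall-shear error falls monotonically at better than second
  order. The venous-velocity accuracy statement (within 2 percent of
  6 mu U / h at 32 cells) is checked separately at the study conditions.
* **Start-up.** Inlet velocities ramp linearly over the first 2000 steps;
  an impulsive start excites a pressure transient that destabilises the
  acute-angle junctions.
* **Convergence.** The residual is the relative L2 change of the velocity
  field per 1000 steps; the default tolerance is 1e-6. Acute junctions
  sustain a weak corner oscillation that floors the residual near 1e-4 to
  1e-5; sweep configurations therefore use a tolerance of 2e-4 with the
  lattice Mach capped at 0.05, which the validation suite shows is ample
  for minima and plateau statistics.
* **Validation.** Plane Poiseuille flow (32 cells across) reproduces the
  closed-form wall shear 6 mu U / h within 2 percent; global mass balance
  closes within 0.5 percent on converged junction runs; the right-angle
  junction is mirror-symmetric; wall shear scales linearly in viscosity
  and in velocity at low Reynolds number.

## WSS extraction and analysis

`wall_shear_profile()` evaluates tau = mu |du_t/dn| at wall points one
grid cell apart, by a one-sided quadratic through the no-slip wall value
and two fluid samples -- at h/2 and 3h/2 on grid-aligned walls (these sit
exactly on cell-center rows, so a parabolic profile is differentiated
without truncation error), at h and 2h with fluid-cell-restricted bilinear
interpolation on staircase walls, followed by a five-point running mean
there to suppress staircase noise.

`stable_value()` estimates each wall's plateau as the median after
excluding two vessel widths from the wall's own inlet and 1.5 mouth spans
(`d_bv / sin(alpha)`) from the entrance. The median is robust to residual
junction tails; the exclusion sizes are configurable, and a window that
comes up empty (physically plateau-free geometries, e.g. a 5.8 mm vein at
10 degrees whose mouth span exceeds the vein length) raises a named error
that `run_sweep()` records as `NA`. `min_wss()` deliberately keeps the
junction region -- that is where the minima live -- and reports the global
minimum with ties broken toward the entrance. `extent_below()` measures
the contiguous sub-threshold interval around the minimum;
`predilection_extent()` doubles the farthest minimum position, the
minimum sitting near the centre of its depressed region.

`demarcation_threshold()` operationalises "the most drastic change of the
curve" on sorted per-model minima as the adjacent pair with the maximal
*ratio* (the minima span three orders of magnitude, so differences are
dominated by the top of the range), placing the threshold at the pair's
geometric mean and refusing to report one when no adjacent ratio reaches 2.
The published analogue of this threshold is 0.017 Pa; reproducing that
number quantitatively would require the original 3-D geometry, but the
detector itself is exact, scale-equivariant, and validated on constructed
sets. Angle groups are left-closed bins [10, 65), [65, 105), [105, 170]
so that a vein entering at exactly 65 degrees counts as steep, and models
with diameter at or below 1.2 mm are excluded from the grouped tables, both
following the published grouping; group comparisons use classic
equal-variance one-way ANOVA with no multiple-testing correction, as in the
source analysis.

## Desk-scale study conditions

The test and acceptance runs use a 12-model reference grid (diameters 1.0,
2.0, 3.0, 4.5 mm crossed with angles 43, 90, 135 degrees), shortened
vessels (12 mm upstream, 30 mm downstream, 20 mm vein), spacing
`min(d_bv / 8, 0.25)` mm, and the sweep solver settings above; the full
cohort at default resolution is a configuration flag away but takes hours
rather than minutes. On this grid the structural core of the published
result reproduces: every junction minimum sits strictly below its wall's
plateau; the vein-wall (`BVU`) minimum rises monotonically with the entry
angle at the posterior mean diameter, spanning the same two orders of
magnitude as the published angle groups; and the deep `SSD`/`BVU`
depression appears only for opposing (acute to right-angle) entries,
vanishing at obtuse ones. Two finer-grained orderings do **not** hold in
the planar model and the corresponding acceptance expectations fail by
design rather than being weakened: at a 43-degree entry the minima stop
falling with vein diameter because the dead zone saturates (a 1 mm slot
obstructs the full depth of a 2-D channel, where a 1 mm round vein
leaves a 3-D sinus essentially undisturbed -- the published
diameter trend lives in exactly that thin-vein regime), and the `SSD`
minimum at 43 versus 90 degrees lands within noise of itself, much as
the corresponding published cells differ by less than their own SDs.

## Known limitations

* Planar (2-D) junctions: recirculation lengths and absolute Pa values
  differ from 3-D circular-vessel junctions; only structure is claimed.
* Steady flow; no pulsatility, wall compliance, or non-Newtonian rheology.
* The acute-corner staircase limits WSS accuracy on the vein walls to the
  smoothing scale (about one mouth-span resolution element near the
  corner).
* The synthetic cohort reproduces marginal moments, not the joint or
  per-cadaver structure of the source data.
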