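---
title: "Quantifying fungal macro-morphology and relating it to productivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fungal macro-morphology and relating it to productivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungalmorph)
```

## The problem

Filamentous fungi in submerged culture grow anywhere between dense spherical
pellets and dispersed mycelium, and product secretion depends strongly on
where a cultivation sits on that continuum. `fungalmorph` implements a
desk-scale version of the full analysis chain used to study this dependence:
image-based macro-morphology quantification, a laser-diffraction germination
assay, and cultivation-performance metrics, joined by an exponential
correlation between morphology and specific productivity. Because no public
instrument data accompany this kind of experiment, the package ships a
synthetic-data module whose outputs carry exact ground truth; every claim the
test suite makes is a claim about recovery of known quantities.

## Image analysis and the Morphology number

Images are reduced to 8-bit grayscale (Rec. 601 luminance for color input)
and binarised at the Otsu threshold — the gray level maximising the
between-class variance over all 256 candidates, ties broken toward the lowest
level. On a histogram with an empty valley between the two classes every
level in the gap maximises the criterion; the returned threshold is then the
lowest tied level, and the resulting mask is identical for any choice in the
gap. Particles are 8-connected components (the ImageJ convention), filtered
at `min_area = 50` px² with border-touching particles excluded by default;
interior holes are filled before measuring, so particles are treated as
silhouettes.

Per-particle geometry:

* **area** — pixel count (times the square of the µm-per-px scale);
* **perimeter** — Moore boundary chain code with Kulpa length weights
  (0.948 per straight, 1.340 per diagonal step). Raw chain-code counting
  overestimates smooth perimeters by several percent; the Kulpa weights
  bring a radius-100 px disc to within 0.5% of 2πr. A single-pixel particle
  is assigned perimeter 4 and aspect ratio 1 by convention.
* **convex area** — area of the convex hull of the boundary-pixel *corner*
  points. Using corners (not centers) guarantees `convex_area >= area` for
  any mask, so solidity never exceeds 1 except through the explicit cap.
* **maximal diameter D** — the maximal Feret diameter, computed as the
  largest pairwise distance over hull vertices. We read "maximal diameter of
  the pellet" literally as the Feret diameter; the moment-ellipse major axis
  is available instead via `diameter = "ellipse"`.
* **major/minor axes** — from the ellipse with the same normalised second
  central moments as the pixel set, adding 1/12 per-pixel variance; the full
  axes are `4*sqrt(eigenvalues)`.

The descriptors are circularity `4*pi*A/P^2`, solidity `A/convex_area` and
aspect ratio `major/minor`, and the composite Morphology number is

$$MN = \frac{2\sqrt{A\,S}}{\sqrt{\pi}\,D\,E}.$$

This form is the unique simple dimensionless combination of the four
quantities that satisfies the two boundary anchors — a perfect circle
(`A = pi r^2, S = 1, D = 2r, E = 1`) gives exactly 1, and a shrinking
rectangle (a "line") gives MN ∝ w^{3/2} → 0 — together with the required
monotonicities (increasing in A and S, decreasing in D and E). Digitisation
can push circularity, solidity or MN slightly above 1 on coarse rasters;
capped values are reported alongside the raw ones (`*_raw` columns). On
rasterised discs the raw geometric measurements are within 1% of the closed
forms from r = 100 px; the composite MN reaches 1% around r = 200 px, mostly
because the staircase boundary of a digitised disc genuinely is not convex
(solidity ≈ 0.99).

A sample with no measurable particles (dispersed mycelium) raises
`mycelial_flag` instead of producing numbers: the descriptors are particle
descriptors and deliberately do not attempt to characterise mycelial
morphology (fractal approaches would be needed there).

## The synthetic particle generator

`shape_spec()` spans the morphological continuum: discs, ellipses, rough
pellets, clumps, mycelium. Rough boundaries are harmonic perturbations
`r(θ) = r₀(1 + Σₖ aₖ cos(kθ + φₖ))`, k = 2..`roughness_order`, with random
amplitudes scaled so `Σ|aₖ| = roughness_amplitude < 0.5`; this keeps the
boundary star-shaped (exact rasterisation by a polar inside test) and yields
a generating polygon from which ground truth is computed exactly: shoelace
area, hull of the polygon vertices, polygon second moments for the moment
ellipse. For discs and ellipses the closed forms are used directly. Mycelium
is a seeded correlated random walk painted at 1 px width; only its projected
area is well defined, and all other descriptors are `NA` by design.

## The germination simulator and detectors

The simulated instrument reports, every 285 s, a volumetric particle-size
distribution on 100 logarithmic bins from 0.5 to 3,000 µm. Per-spore
germination times follow a Gaussian truncated at zero (`lag_mean_min`,
`lag_sd_min`); the sharp sigmoidal population curves seen in such experiments
are reproduced by this choice, and `lag_sd = 0` gives step germination.
Spore diameters have mean 3 µm with a 10% CV (the inoculum width is a free
parameter of the generator; nothing downstream is sensitive to it).

A germinating particle passes through three states:

1. **Ungerminated spore** — recorded at its own diameter.
2. **Germ tube** — length grows at `tube_growth_rate_um_min` (default
   30 µm/min); at each snapshot the instrument records the *length* with
   probability `orientation_prob` and the spore-sized *width* otherwise.
   This is the orientation ambiguity of laser diffraction: it cannot
   distinguish a narrow elongated particle from a large spherical one, so
   fluid dynamics decide which side is seen. The default rate is an
   *effective* recorded-size growth rate standing in for tube elongation plus
   the immediate aggregation of germinated spores; it is chosen so that an
   emerging tube crosses the instrument's detection scale within one sampling
   interval, consistent with the observation that a germ tube influences the
   measured diameter essentially instantly.
3. **Aggregate** — once the tube reaches `aggregation_length_um` (100 µm) the
   particle joins the aggregate population, whose common diameter ramps
   deterministically from spore size to `pellet_diameter_um` (1,000 µm) as
   `d = spore + (pellet − spore) · min(F/0.9, 1)`, with `F` the germinated
   fraction. The ramp completes exactly when 90% of spores have germinated —
   the conventional definition of germination completion.

The collective ramp is the one deliberate modelling idealisation. Volume
distributions weight particles by d³, so if each particle grew to pellet size
independently, the very first germinator would dominate both the median and
the Sauter mean almost immediately and both statistics would jump together —
contradicting the observed behaviour in which the SMD rises later and more
slowly than the median. Tying the aggregate diameter to the germinated
fraction reproduces the real phenomenology (median jumps at onset because of
recorded tube lengths; SMD follows the population ramp and plateaus at
completion) while keeping the completion time analytically known. Ground
truth attached to each series records the earliest germination event and the
empirical 90th-percentile germination time.

Per snapshot, `median_diameter()` interpolates the cumulative volume linearly
in log-diameter, assigning each bin center the cumulative volume below the
bin plus half its own (so a monodisperse snapshot returns its bin exactly and
two equal bins return their geometric midpoint), and
`sauter_mean_diameter()` computes `Σv / Σ(v/d)`, identical to the
number-weighted `Σnd³/Σnd²`.

Detection conventions (the published definitions are visual; these
thresholds are explicit, configurable stand-ins, all echoed in
`detection_params`):

* **onset / lag phase** — first time the median exceeds `jump_factor = 10`
  times the baseline (median of the first `baseline_window = 5` snapshots)
  for `persistence = 2` consecutive snapshots. Persistence, not smoothing,
  absorbs the orientation flicker, preserving the raw signal. With
  `lag_sd = 0` the detected onset is within one sampling interval of the true
  germination time; with `lag_sd > 0` it sits a constant ~2σ above the *first*
  germination event, because a 10× median jump requires a detectable
  germinated cohort — a calibration-type offset that cancels in comparisons
  across conditions (detected vs true lag regresses with slope 1).
* **plateau / completion** — plateau value is the median SMD over the final
  5% of snapshots; the series must have stabilised there (total change over
  the final segment below `plateau_tolerance = 5%` of the plateau value,
  otherwise "series ended before plateau"); the plateau time is the first
  sustained time the SMD reaches 95% of the plateau value. On simulated
  scenarios this lands within two sampling intervals of the true
  90%-germination time.
* **germination time** — `Δt = plateau_time − onset_time`; time zero is
  inoculation, which coincides with the first snapshot.

## Cultivation performance

The generator uses logistic growth
`x(t) = x_max / (1 + (x_max/x0 − 1)e^{−μt})` — chosen over pure exponential so
the biomass-dry-weight integral saturates as in 72 h batch cultivations —
with activity proportional to the *analytic* BDWI (closed-form logistic
integral) times multiplicative Gaussian noise. The analysis side computes the
BDWI by the cumulative trapezoid and the specific productivity as the OLS
slope of activity over BDWI with a free intercept (a through-origin option
exists; the free intercept is the default because the linearity is only
approximate in practice). Units need no conversion factor: activity in U/mL
over BDWI in g·h/L is numerically U/mg/h, since 1 g/L = 1 mg/mL. Because the
regressor is the trapezoidal BDWI while the generator used the exact
integral, noiseless recovery is exact only up to discretisation (relative
error ~10⁻⁴ at 200 samples). `mu_max()` is the maximum sliding-window
(default 4 points) log-linear slope of ln(BDW) — exact on noiseless
exponential data, within 5% of the logistic's intrinsic rate when sampling
covers early growth.

`fit_exponential()` fits `y = a·e^{bx}` by Levenberg–Marquardt nonlinear
least squares on the original scale, initialised from the log-linear
regression (whose estimates are also retained). R² is reported on the
original scale, the nonlinear-fitting convention; the log-scale R² is kept
alongside because the choice is not canonical. Constant y degrades gracefully
to `b = 0, a = mean(y)`; nonpositive y or constant x are errors.

## The osmolality panel

`generate_osmolality_panel()` interpolates scenario parameters linearly
between published anchor values: biomass 4 → 0.2 g/L and specific
productivity 0.5 → 9 U/mg/h over 0.4 → 4.9 osmol/kg, maximal growth rate
0.16 → 0.02 h⁻¹ over 0.4 → 4.5 osmol/kg, with particles becoming smaller,
rougher and more elongated, germination lags lengthening (150 → 500 min over
0.35 → 3.6 osmol/kg, a qualitative emulation — the source figures are not
tabulated numerically), and purely mycelial growth beyond 4.2 osmol/kg. The
anchor lines are evaluated (not clamped) across the allowed 0.2–5.0 osmol/kg
range so panel parameters stay strictly monotone. `run_osmolality_study()`
chains everything and fits the morphology–productivity correlation; on every
seeded panel the fitted exponent is negative — smaller Morphology number,
higher specific productivity — which is the central qualitative relationship
this analysis exists to expose.

```{r example, eval = FALSE}
st <- run_osmolality_study(osmolalities = c(0.4, 1.4, 2.4, 3.4),
                           n_replicates = 1, n_particles = 4,
                           image_size = 192, seed = 1)
st$fit          # negative exponent b
st$germination  # lag phase increasing with osmolality
```

## Problem sizes, tolerances, limitations

The shipped tests run the generators at deliberately modest sizes — 2,000
spores per germination series, panels of four to six osmolality levels with a
handful of 160–224 px particle images per cultivation, twenty seeds for
recovery checks — which suffices for the stated tolerances (1–2% digitisation
bounds on descriptors, 3% slope recovery at 5% noise, two-interval agreement
for detection) while keeping the suite fast; all sizes scale up linearly if
finer checks are wanted.

What passing tests do and do not show: the synthetic generator emulates the
*structure* of the real data (binary particle silhouettes, binned volumetric
size distributions with orientation ambiguity, near-linear activity–BDWI
relationships) but not its nuisance processes — uneven illumination,
touching/overlapping particles, bubbles in the measuring cell, assay
interference at high salinity, biological replicate variability. Recovery on
synthetic data therefore validates the estimators and detectors, not the
wet-lab workflow. Mycelial morphologies are flagged, not quantified. The
Otsu implementation assumes a particle/background gray-level contrast; the
detectors assume the series actually spans germination (both fail loudly, by
design, otherwise).
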