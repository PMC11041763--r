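---
title: "Methods: microscale oxygen and colony dynamics in model marine-snow particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microscale oxygen and colony dynamics in model marine-snow particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrescope)
```

## The system and the measurement problem

Millimeter-scale sinking organic particles ("marine snow") host dense
heterotrophic activity. When facultative denitrifiers colonize a particle,
their respiration can locally exhaust oxygen even while the surrounding
seawater stays fully oxygenated, switching colonies to nitrate and nitrite
respiration. The experimental model this package analyzes is a hydrogel disk
(radius 1.5 mm, thickness 700 µm, sandwiched between impermeable plates, so
the geometry is effectively two-dimensional) seeded with diatoms as the
carbon source, bacteria, and oxygen-sensitive nanosensor particles. Seawater
flows past at an imposed sinking speed and the particle is imaged hourly for
roughly two weeks: a pseudo-darkfield brightfield channel, a nanosensor
fluorescence channel, and (in separate experiments) transcriptional-reporter
channels for nitrate (NarK-GFP) and nitrite (NirS-dsRed) reduction.

`aggrescope` implements the image-computation chain from those stacks to the
quantities of scientific interest: per-colony oxygen and area trajectories,
diauxic lag statistics, oxygen-exposure area fractions, radial biomass and
expression profiles, and depth-translated bulk chemistry. Because the
original stacks are not required (and microscopes are not reproducible at
desk scale), a synthetic-scene generator with complete ground truth stands in
for the instrument, which makes every stage verifiable.

## Nanosensor calibration and inversion

The nanosensor is a quenching sensor: fluorescence is maximal under anoxia
and falls as oxygen rises, following Stern–Volmer,

$$F(C) = \frac{F_0}{1 + K_{sv} C},$$

so the *image* brightens as oxygen is consumed. Nanoparticle loading is
spatially heterogeneous, so each particle carries its own pair of endmember
frames: one fully anoxic (fluorescence saturated, \(F = F_0\)) and one
air-equilibrated (\(C = C_{sat}\)). The particle is divided into annuli of
distance-from-edge and the median endmember fluorescence per annulus anchors
a per-zone inversion

$$K_{sv} = \frac{F_{anoxic}/F_{air} - 1}{C_{sat}}, \qquad
  C = \frac{F_{anoxic}/F - 1}{K_{sv}},$$

clipped to \([0, C_{sat}]\). Choices worth stating:

* **Inversion law.** Two-point Stern–Volmer, not linear interpolation
  between endmembers; linear interpolation is the degenerate
  \(K_{sv} C \ll 1\) limit and does not match quenching physics. The choice
  is recorded in the model's metadata (`inversion` field).
* **Zones.** 20 equal-width annuli by default. The zoning exists to absorb
  radial heterogeneity in nanoparticle loading; 20 zones keep hundreds to
  thousands of pixels per zone at the imaging scales used here, so the
  medians are stable. Each particle's own endmembers are used (the type also
  accepts endmembers from an inert upstream particle; whichever is supplied
  is what the model records).
* **Degenerate zones.** A zone where the anoxic median does not exceed the
  air median cannot be inverted; it is flagged (`ok = FALSE`, `Ksv = NA`)
  and never silently interpolated. If every zone fails the calibration
  errors out.
* **Oxygen categories.** Concentrations are classed with strict
  upper bounds exactly as conventionally printed: hypoxic (< 40), microoxic
  (< 10), suboxic (< 5), nanoxic (< 1 µmol L⁻¹); a value exactly at a
  boundary belongs to the milder class (40 µmol L⁻¹ is oxic).
* **Photobleaching.** Endmembers are acquired at the end of the experiment
  (after chloramphenicol arrest) and treated as time-invariant; no bleaching
  correction is applied by default because none is warranted without
  repeated endmembers.

## Particle geometry

The particle is detected once, on the first frame: contrast stretch
(1st–99th percentile by default), Gaussian blur with a large kernel
(σ = 20 px), Otsu global threshold, largest connected component, hole fill.
The heavy blur erases internal structure (diatoms, colonies) so the
threshold sees a single bright disk; for a symmetric intensity step the
mid-level crossing preserves the edge position, and the residual inward
bias from boundary curvature is of order σ²/2R (≈ 1–2 px at the scales
here), within the ±2 px the tests require. Distance-to-edge is the exact
Euclidean distance to the nearest boundary pixel of the mask (the distance
transform of the contour's complement), so a contour pixel is at distance 0
and the center of a disk is ~one radius from the edge. All radial
statistics downstream are expressed in this coordinate. Coordinates are
1-based (x, y) pixel centers, the native R matrix convention; the pixel
pitch in µm converts to physical units and is carried in every output.

## Diatom exclusion and colony segmentation

Diatom chains autofluoresce (chlorophyll) and must not contaminate sensor or
reporter statistics. They are removed by shape: bright objects inside the
particle are segmented (Otsu on intensity, connected components) and the
*elongation shape factor* — the square root of the ratio of the second
central moments about the principal axes — separates chains (ESF ≈ axis
ratio, ≫ 1) from near-circular microcolonies (ESF ≈ 1). The threshold
defaults to 2.0: rendered diatoms have axis ratio ≥ 3 and digital disks stay
within a few percent of 1, so the margin is wide on both sides. Objects with
a vanishing minor moment (collinear pixels) get an `Inf` sentinel and are
flagged rather than scored.

Colonies are then found per frame: Sobel gradient magnitude restricted to
the particle interior (a 6 px rim margin excludes the particle's own edge),
Otsu binarization of the gradient, dilation (disk, radius 2 px), flood fill,
connected components. Candidates overlapping the diatom mask are discarded.
Two deliberate refinements:

* **Intensity refinement (default on).** The dilate-and-fill region
  systematically overstates colony area by a perimeter band of the dilation
  radius plus the gradient kernel's support. Each surviving candidate is
  therefore refined to the bright pixels it contains (pooled Otsu over
  candidate pixels), which removes that bias; on noiseless synthetic scenes
  the recovered areas equal the rasterized ground truth exactly. With
  refinement off the raw dilated regions are returned, and their area
  inflation is visible in the tests.
* **Speckle floor.** Components below 10 px² are dropped; at the default
  scales that is far below the smallest rendered colony.

## Backtracking

Colonies only appear and grow, so the final frame is the most
information-rich anchor. Tracking therefore runs backward: each colony in
frame *t* is matched to at most one colony in frame *t − 1* by maximal pixel
overlap, greedily in descending overlap with deterministic tie-breaks
(larger area, then lower label id). Matching is injective: when two later
colonies overlap one earlier colony — a split, viewed forward — the larger
overlap claims the ancestor and the loser's backtrack terminates, flagged
`split_orphan` in the QC table. Shared ancestry is never assigned. A track
with no overlap candidate may fall back to the nearest unclaimed centroid
within 20 µm, and tolerates up to 2 missing frames (transient segmentation
dropouts); both limits are configurable and recorded. Earlier colonies no
later track claims start their own track (a colony that dies, viewed
forward), so every observation belongs to exactly one track and the
bookkeeping is conservative by construction. The merge policy is exposed as
`resolve_overlap_conflicts()` so its determinism can be tested directly;
nothing in the source experiments constrains it, so it is declared, not
inferred.

## Growth phases and lag statistics

Colony area trajectories are diauxic: exponential growth on labile carbon,
a lag while the regulatory machinery switches to denitrification, a second
exponential, and eventually stationary phase. `fit_growth_phases()` fits
log-area versus time with piecewise-linear least squares — exact dynamic
programming over segment boundaries (O(n²) segment costs via prefix sums),
up to 3 changepoints, minimum 4 points per segment, model order chosen by
BIC. Segments are then labeled: the first is `exp1` (slope `mu1`); the lag
is the longest interior low-slope segment (slope < 10% of `mu1`) *that is
followed by another above-threshold segment* — a diauxic lag sits between
two growth phases, and without that condition a stationary tail would
masquerade as the lag; if no low-slope segment has a successor the longest
interior one is taken (a track may end mid-lag). Areas at or below the
detection floor enter as missing values, never as log(0). Tracks shorter
than 12 frames are flagged and excluded from population statistics. Lag
durations are reported in hours and in depth-translated meters, as mean ±
sd and median (the dual convention for skewed lag distributions), and the
broken-versus-intact comparison uses Welch's *t* — a routine supporting
statistic, not part of the pipeline's novelty.

Depth translation itself is linear and explicit: depth = speed × t/24, with
the imposed 4.8 m d⁻¹ as default — 100 h is 20 m, 200 h is 40 m. No
compaction or acceleration is modelled.

## Radial statistics

* **Biomass profiles** bin each track's final observation by
  distance-from-edge: cumulative area, mean colony size, and count per bin;
  binning conserves total area exactly and empty bins are missing, not zero.
* **Colony position densities** are Gaussian KDEs of distance-to-edge with
  the kernel *reflected at zero*: without reflection the density is biased
  low exactly where the biology concentrates (the edge). The result is
  renormalized numerically to integrate to 1 within 10⁻⁶.
* **Expression profiles** subtract the median intensity outside the
  particle as background, exclude diatom pixels, and bin by
  distance-from-edge. The per-bin statistic is the *mean* pixel intensity
  of the annulus — the radial line-profile equivalent — rather than the
  annulus total, so the annulus-area factor (2π(R − d)) does not drag the
  peak toward the edge. Two numerical details matter: background-subtracted
  noise is *not* clipped per pixel (rectified noise would put a uniform
  positive floor under every annulus and pull the weighted mean toward the
  particle center — an effect of tens of µm at realistic noise); instead
  noise cancels within each annulus mean, and annuli statistically
  indistinguishable from background (mean below 2σ_bg/√n) are zeroed.
  Peak location is reported as the density-weighted mean, sd, *and* median,
  because skewed profiles make them differ; count-style weighting (annulus
  totals) is available behind the `weighting` flag.
* **Chemistry profiles** map sampled bulk series (DOC, nitrate, nitrite)
  onto depth with the same linear translation and average replicates where
  a replicate column is present; a non-monotone time axis is an error.

## The oxygen solver

Within a frame the oxygen field is quasi-steady — colony-scale
equilibration takes seconds, the imaging cadence is an hour — so each frame
solves

$$D \nabla^2 C = q(x), \qquad C = C_b \text{ outside the particle},$$

with \(q\) the volumetric uptake on colony pixels. The Laplacian is the
five-point stencil; where the geometry carries an analytic disk radius
(synthetic scenes) the stencil is boundary-fitted (Shortley–Weller arm
shortening), restoring second-order accuracy at the curved Dirichlet
boundary — on the uniform-consumption disk, whose exact solution
\(C(r) = C_b - q(R^2 - r^2)/4D\) is quadratic, the discretization is exact
to rounding. The linear system is solved by sparse direct LU
(factorized once per geometry and reused across frames and iterations),
with the residual checked explicitly rather than trusted. Anoxia is handled
as a linear complementarity problem: \(C \ge 0\), uptake cannot exceed
supply where \(C = 0\), solved by primal active-set (policy) iteration,
which terminates finitely for an M-matrix; failure to stabilize within the
iteration cap is an explicit error, never a silent clip. A relaxation
sweep (Jacobi/Gauss–Seidel) would solve the same equations but needs
O(N²) sweeps on fine grids and complicates the anoxia logic; the direct
factorization is both faster and easier to verify against the closed form.

## What the generator emulates — and what it does not

`scene_config()` + `render_scene()` produce the full observable record:
brightfield frames (bright rim, static elongated diatoms, growing disk
colonies on a uniform interior), sensor frames
\(F = F_0(x)/(1 + K_{sv} C) + \varepsilon\), both endmember frames, and
ground truth (label maps, areas, true oxygen fields, the diatom mask, lag
windows). Generator defaults state the study conditions: particle radius
1500 µm, 1 h frames, ≥ 312 frames (13 days), sinking at 4.8 m d⁻¹, and the
broken-diatom chemistry anchor of 28.0 mg L⁻¹ C initial DOC versus
14 mg L⁻¹ for intact diatoms, with nanomolar nitrite excursions (an early
pulse for broken, a deeper peak for intact) and nitrate starting at the
10 µmol L⁻¹ amendment. Values neither measured nor printed anywhere had to
be chosen once, as plausible for the system, and are documented here rather
than revisited:

* pixel pitch 10 µm by default (a 150 px particle radius keeps default
  scenes tractable; tests use 15–20 µm);
* air-saturation 250 µmol L⁻¹ — a config value, not a claim about the
  experiment's seawater, which is why `o2_saturation_umol_L` must be
  supplied to the calibration explicitly;
* Stern–Volmer \(K_{sv}\) = 0.012 L µmol⁻¹, giving a 4× fluorescence
  contrast between anoxia and saturation, typical of optode nanosensors;
* colony uptake 5 µmol L⁻¹ s⁻¹ per colony pixel, set by the scaling
  argument that a few-percent colony cover should draw the particle down
  by tens of µmol L⁻¹ (q_eff R²/4D);
* diauxic defaults µ₁ = 0.05 h⁻¹, lag onset 48 h, lag 48 h,
  µ₂ = 0.03 h⁻¹, initial area 80 µm², stationary cap 2 × 10⁴ µm²;
* fluorescence noise sd 1% of \(F_0\), plus a 10% radial gradient in
  \(F_0\) to emulate heterogeneous nanoparticle loading (this is what makes
  the zoned calibration non-trivial);
* the track-population generator draws lag durations Normal(48 h, 20.5 h)
  — i.e. 9.6 ± 4.1 m of sinking at 4.8 m d⁻¹ — truncated below at 8 h,
  roughly the shortest lag the changepoint fit can resolve at hourly
  sampling.

Deliberate non-realism, hence limits on what passing tests show about real
data: colonies are perfect disks placed with enough clearance that they
never merge, touch diatoms, or reach the rim; diatoms are static ellipses
with no chlorophyll bleed into the *sensor* channel (bleed-through is
exercised in the expression tests instead); noise is additive Gaussian, not
shot-limited; the particle is a perfect disk; there is no photobleaching,
drift, or focus variation. Exact-recovery results (areas, lineages) are
statements about the pipeline's internal consistency under these clean
conditions, not about microscope data. The 2-D geometry itself is faithful
to the experiment (disks between impermeable plates), but 3-D particles,
flow-field hydrodynamics and carbon-explicit metabolism are out of scope.

## Problem sizes

The test suite renders scenes of 100 px particle radius and 2–10 frames,
solves oxygen on grids up to 256², fits 60–200 synthetic tracks of 200
hourly frames, and evaluates 20 noise seeds per expression ring; these
sizes make every stage's check rerun in seconds while leaving the
estimators' biases measurable. The same sizes are used by
`scripts/acceptance.R`.

## Known limitations

* The Shortley–Weller boundary fitting needs an analytic radius; general
  masks fall back to imposing the Dirichlet value at the first outside
  pixel (first-order at the boundary).
* The tracker's greedy matching is not globally optimal; with the
  generator's non-merging colonies it is exact, but heavily overlapping
  real colonies would need an assignment solver.
* The lag definition (slope below 10% of µ₁) is operational and
  configurable; no operational definition is canonical for these data.
* Calibration assumes co-registered, time-invariant endmembers; drift or
  bleaching between experiment and calibration would bias oxygen low.
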