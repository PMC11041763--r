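# aggrescope

Image-computation pipeline for time-lapse microscopy of model marine-snow
particles colonized by facultatively denitrifying bacteria — and a
ground-truthed synthetic-scene generator that stands in for the microscope.

## The problem

Sinking organic particles ("marine snow") are millimeter-scale hotspots of
microbial activity in an otherwise oxygenated ocean. As bacterial
microcolonies grow on the carbon leaking from the diatoms embedded in a
particle, their respiration can locally exhaust oxygen and switch the cells
to denitrification — even a few hundred µm from fully oxic seawater. The
laboratory model for this is a hydrogel disk (1.5 mm radius) seeded with
diatoms, bacteria and oxygen-sensitive nanosensor particles, held in a
millifluidic flow cell where seawater passes at an imposed sinking speed
(4.8 m d⁻¹) while the particle is imaged hourly for ~13 days.

Extracting science from those stacks requires a chain of image computations,
all provided here for anyone analyzing comparable particle/biofilm
time-lapse data:

* **Oxygen from fluorescence.** The nanosensor is quenched by oxygen
  (fluorescence *rises* as O₂ falls). Each particle carries two endmember
  frames — fully anoxic and air-equilibrated — and a radially zoned
  Stern–Volmer inversion converts fluorescence to concentration:
  `Ksv = (F_anoxic/F_air − 1)/C_sat`, `C = (F_anoxic/F − 1)/Ksv`.
* **Geometry.** Particle edge detection (blur σ = 20 px → Otsu → largest
  component → fill) and an exact Euclidean distance-to-edge transform, the
  coordinate for all radial statistics.
* **Diatom exclusion.** Elongated diatom chains are removed by the
  elongation shape factor `sqrt(λ_major/λ_minor)` of each object's second
  central moments (disk ≈ 1, chain ≫ 1) before any fluorescence statistic.
* **Colony segmentation and backtracking.** Sobel edge → Otsu → dilate →
  flood-fill segmentation per frame, then backward tracking from the
  information-rich final frame by maximal pixel overlap, with a
  deterministic, injective merge policy (split losers are flagged, never
  given shared ancestry).
* **Dynamics.** Piecewise-linear (BIC-penalized changepoint) decomposition
  of log-area trajectories into exponential → lag → second exponential →
  stationary phases; oxygen-exposure area fractions below the standard
  thresholds (hypoxic < 40, microoxic < 10, suboxic < 5, nanoxic < 1
  µmol L⁻¹); linear depth translation (100 h → 20 m at 4.8 m d⁻¹).
* **Spatial statistics.** Radial biomass profiles, boundary-reflected
  colony position densities, NarK/NirS radial expression profiles with
  peak statistics, and depth-translated bulk chemistry (DOC, nitrate,
  nitrite) profiles.
* **Synthetic scenes.** `scene_config()`/`render_scene()` produce
  brightfield + sensor stacks, endmember frames and complete ground truth
  (label maps, true oxygen fields from a quasi-steady reaction–diffusion
  solve `D∇²C = q` with anoxia handled as a complementarity problem, true
  areas, lag windows), so every stage above is testable without microscope
  data.

## Worked example

```r
library(aggrescope)

cfg <- scene_config(pixel_size_um = 15, n_frames = 8, n_colonies = 5,
                    n_diatoms = 4, noise_sd = 0, rng_seed = 42,
                    growth_law = diauxic_growth(mu1 = 0.06, lag_start_h = 100,
                                                lag_duration_h = 0, mu2 = 0,
                                                area0_um2 = 5000))
scene <- render_scene(cfg)

detect_particle(scene$brightfield[, , 1], pixel_size_um = 15)
#> Particle geometry
#>   image: 240 x 240 px (15 um/px)
#>   center: (120.5, 120.5) px
#>   equivalent radius: 1474.4 um (98.3 px)
#>   area: 30354 px

fit_calibration(scene$calib_anoxic, scene$calib_air, scene$geometry,
                n_zones = 20, o2_saturation = 250)
#> Stern-Volmer two-endmember calibration
#>   zones: 20 annuli over [0, 1476] um from the edge
#>   saturation: 250 umol/L
#>   Ksv: 0.012 - 0.012 L/umol (0 zones flagged)
```

The detected radius is within 2 px of the configured 1500 µm, and the
recovered quenching constant equals the generator's `Ksv = 0.012 L/µmol`
in every zone (the scene is noiseless). Segmenting and backtracking:

```r
cal    <- fit_calibration(scene$calib_anoxic, scene$calib_air, scene$geometry,
                          n_zones = 20, o2_saturation = 250)
frames <- segment_stack(scene, cal)
tracks <- backtrack(frames)
tracks
#> 5 colony track(s); lengths 8-8; 0 split-orphan(s)

head(as.data.frame(tracks)[, c("track_id", "frame_index", "area_um2",
                               "distance_to_edge_um", "median_o2_umol_L",
                               "o2_category")], 4)
#>  track_id frame_index area_um2 distance_to_edge_um median_o2_umol_L o2_category
#>         1           1     4725            432.9261         247.0091        oxic
#>         1           2     4725            432.9261         246.9744        oxic
#>         1           3     5175            432.9261         246.6922        oxic
#>         1           4     5625            432.9261         246.4585        oxic
```

All five colonies are tracked through all eight frames with their areas,
positions and median oxygen. Growth-phase decomposition on a simulated
diauxic population (lags drawn Normal(48 h, 20.5 h), i.e. 9.6 ± 4.1 m of
sinking at 4.8 m d⁻¹):

```r
pop <- simulate_colony_tracks(n_tracks = 50, seed = 1)
fit_growth_phases(pop[[3]])
#> Growth phases:
#>       phase t_start_h t_end_h slope_per_h depth_start_m depth_end_m
#>        exp1         0      43    0.049365           0.0         8.6
#>         lag        44      72    0.001153           8.8        14.4
#>        exp2        73     186    0.029814          14.6        37.2
#>  stationary       187     199    0.004786          37.4        39.8
#>   lag: starts 44.0 h, lasts 28.0 h (5.60 m of sinking)

ls <- lag_statistics(pop)
sprintf("population lag: %.1f +/- %.1f m (median %.1f m), n = %d",
        ls$mean_m, ls$sd_m, ls$median_m, ls$n_fitted)
#> "population lag: 10.1 +/- 2.9 m (median 10.0 m), n = 50"
```

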