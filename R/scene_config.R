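#' Diauxic colony growth law
#'
#' Colonies on diatom-fueled particles show a characteristic diauxie: an
#' initial exponential expansion on labile carbon under aerobic respiration,
#' an intermediate lag while the regulatory machinery switches to nitrate
#' respiration, and a second exponential phase once denitrification enzymes
#' are in place. Cross-sectional area follows
#' \deqn{A(t) = A_0 e^{\mu_1 \min(t, t_1)} e^{\mu_2 \max(0, t - t_1 - \ell)}}
#' capped at `area_max_um2` (stationary phase), with `t1 = lag_start_h` and
#' `l = lag_duration_h`.
#'
#' Defaults describe a colony nucleating at ~80 µm² that grows at
#' 0.05 h⁻¹, pauses for two days starting two days in (the oxygen-driven
#' diauxic switch), and resumes at a slightly lower anaerobic rate.
#'
#' @param mu1 first exponential growth rate, 1/h.
#' @param lag_start_h onset of the lag, h.
#' @param lag_duration_h lag length, h.
#' @param mu2 second exponential growth rate, 1/h.
#' @param area0_um2 initial colony area, µm².
#' @param area_max_um2 stationary-phase cap, µm².
#' @return object of class `diauxic_growth`.
#' @export
diauxic_growth <- function(mu1 = 0.05, lag_start_h = 48, lag_duration_h = 48,
                           mu2 = 0.03, area0_um2 = 80,
                           area_max_um2 = 2e4) {
  check_scalar(mu1, "mu1", nonneg = TRUE)
  check_scalar(mu2, "mu2", nonneg = TRUE)
  check_scalar(lag_start_h, "lag_start_h", nonneg = TRUE)
  check_scalar(lag_duration_h, "lag_duration_h", nonneg = TRUE)
  check_scalar(area0_um2, "area0_um2", positive = TRUE)
  if (!identical(area_max_um2, Inf))
    check_scalar(area_max_um2, "area_max_um2", positive = TRUE)
  structure(list(mu1 = mu1, lag_start_h = lag_start_h,
                 lag_duration_h = lag_duration_h, mu2 = mu2,
                 area0_um2 = area0_um2, area_max_um2 = area_max_um2),
            class = "diauxic_growth")
}

#' Colony area under the diauxic law
#'
#' @param growth a [diauxic_growth()] object.
#' @param t_h time(s) in hours.
#' @return area(s) in µm².
#' @export
colony_area_at <- function(growth, t_h) {
  stopifnot(inherits(growth, "diauxic_growth"))
  if (any(t_h < 0)) stop("t_h must be >= 0", call. = FALSE)
  t1 <- growth$lag_start_h
  t2 <- t1 + growth$lag_duration_h
  a <- growth$area0_um2 *
    exp(growth$mu1 * pmin(t_h, t1)) *
    exp(growth$mu2 * pmax(0, t_h - t2))
  pmin(a, growth$area_max_um2)
}

#' Synthetic-scene configuration
#'
#' Describes one model marine-snow particle experiment: a hydrogel disk of
#' nominal radius 1.5 mm imaged hourly for at least 13 days while "sinking"
#' at 4.8 m d⁻¹, seeded with elongated diatoms and near-circular bacterial
#' microcolonies that consume oxygen, with an oxygen-quenched nanosensor
#' (fluorescence rises as oxygen falls) distributed through the gel.
#'
#' @param particle_radius_um particle radius, µm.
#' @param pixel_size_um pixel pitch, µm (10 µm by default keeps the default
#'   scene at a tractable 150 px radius).
#' @param frame_interval_h imaging interval, h.
#' @param n_frames number of time points (default 312 = 13 days at 1 h).
#' @param sinking_speed_m_per_d imposed sinking speed, m d⁻¹.
#' @param n_colonies colonies nucleated at frame 1.
#' @param colony_seed_positions `"random"` or a 2-column matrix of (r, theta)
#'   polar positions (r in µm from the particle center).
#' @param growth_law a [diauxic_growth()] object.
#' @param n_diatoms static elongated diatoms rendered in brightfield.
#' @param diatom_axis_ratio major/minor semi-axis ratio (> 1).
#' @param o2_saturation_umol_L air-equilibrated bulk oxygen, µmol L⁻¹. No
#'   universal default is claimed; 250 is a plausible surface-seawater value
#'   and is only the generator's choice.
#' @param stern_volmer_Ksv quenching constant, L µmol⁻¹.
#' @param consumption_q volumetric colony oxygen consumption, µmol L⁻¹ s⁻¹.
#' @param diffusivity_um2_s oxygen diffusivity, µm² s⁻¹.
#' @param noise_sd additive Gaussian noise on fluorescence, in units of the
#'   unquenched intensity F0 (= 1); default 1% of F0.
#' @param f0_gradient relative radial gradient of unquenched nanosensor
#'   brightness, emulating heterogeneous nanoparticle loading (this is what
#'   makes the radially zoned calibration worthwhile).
#' @param rng_seed integer seed; a fixed seed makes the rendered scene
#'   bit-identical across runs.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(particle_radius_um = 1500,
                         pixel_size_um = 10,
                         frame_interval_h = 1,
                         n_frames = 312,
                         sinking_speed_m_per_d = 4.8,
                         n_colonies = 30,
                         colony_seed_positions = "random",
                         growth_law = diauxic_growth(),
                         n_diatoms = 40,
                         diatom_axis_ratio = 4,
                         o2_saturation_umol_L = 250,
                         stern_volmer_Ksv = 0.012,
                         consumption_q = 2,
                         diffusivity_um2_s = 1900,
                         noise_sd = 0.01,
                         f0_gradient = 0.1,
                         rng_seed = 1L) {
  check_scalar(particle_radius_um, "particle_radius_um", positive = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(frame_interval_h, "frame_interval_h", positive = TRUE)
  check_scalar(n_frames, "n_frames", positive = TRUE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  check_scalar(sinking_speed_m_per_d, "sinking_speed_m_per_d", positive = TRUE)
  check_scalar(n_colonies, "n_colonies", nonneg = TRUE)
  check_scalar(n_diatoms, "n_diatoms", nonneg = TRUE)
  check_scalar(diatom_axis_ratio, "diatom_axis_ratio", positive = TRUE)
  if (diatom_axis_ratio <= 1)
    stop("diatom_axis_ratio must be > 1", call. = FALSE)
  check_scalar(o2_saturation_umol_L, "o2_saturation_umol_L", positive = TRUE)
  check_scalar(stern_volmer_Ksv, "stern_volmer_Ksv", positive = TRUE)
  check_scalar(consumption_q, "consumption_q", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot(inherits(growth_law, "diauxic_growth"))
  if (!identical(colony_seed_positions, "random")) {
    colony_seed_positions <- as.matrix(colony_seed_positions)
    if (ncol(colony_seed_positions) != 2 ||
        nrow(colony_seed_positions) != n_colonies)
      stop("colony_seed_positions must be 'random' or an n_colonies x 2 (r, theta) matrix",
           call. = FALSE)
  }
  structure(list(
    particle_radius_um = particle_radius_um, pixel_size_um = pixel_size_um,
    frame_interval_h = frame_interval_h, n_frames = as.integer(n_frames),
    sinking_speed_m_per_d = sinking_speed_m_per_d,
    n_colonies = as.integer(n_colonies),
    colony_seed_positions = colony_seed_positions,
    growth_law = growth_law, n_diatoms = as.integer(n_diatoms),
    diatom_axis_ratio = diatom_axis_ratio,
    o2_saturation_umol_L = o2_saturation_umol_L,
    stern_volmer_Ksv = stern_volmer_Ksv, consumption_q = consumption_q,
    diffusivity_um2_s = diffusivity_um2_s,
    noise_sd = noise_sd, f0_gradient = f0_gradient,
    rng_seed = as.integer(rng_seed)
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic particle scene\n")
  cat(sprintf("  particle: radius %g um, %g um/px (%d px)\n",
              x$particle_radius_um, x$pixel_size_um,
              round(x$particle_radius_um / x$pixel_size_um)))
  cat(sprintf("  frames: %d at %g h (%.1f d), sinking %g m/d\n",
              x$n_frames, x$frame_interval_h,
              x$n_frames * x$frame_interval_h / 24, x$sinking_speed_m_per_d))
  cat(sprintf("  biology: %d colonies (mu1 %.3g, lag %g h, mu2 %.3g), %d diatoms (axis ratio %g)\n",
              x$n_colonies, x$growth_law$mu1, x$growth_law$lag_duration_h,
              x$growth_law$mu2, x$n_diatoms, x$diatom_axis_ratio))
  cat(sprintf("  sensor: Ksv %g L/umol, saturation %g umol/L, noise sd %g\n",
              x$stern_volmer_Ksv, x$o2_saturation_umol_L, x$noise_sd))
  invisible(x)
}

#' Read a scene configuration from YAML
#'
#' Scalar fields map one-to-one onto [scene_config()] arguments; growth-law
#' parameters live under a `growth_law:` block.
#'
#' @param path YAML file path.
#' @return a `scene_config` object.
#' @export
read_scene_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$growth_law)) y$growth_law <- do.call(diauxic_growth, y$growth_law)
  do.call(scene_config, y)
}
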