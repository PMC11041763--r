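# Scene rendering: brightfield + sensor channels with full ground truth.
#
# Intensity palette (arbitrary units in [0, 1]):
#   background 0.05, particle interior 0.30, particle rim 0.55,
#   colonies 0.70, diatoms 0.90.
# The pseudo-darkfield look (particle brighter than background, objects
# brighter still) is what the detection and segmentation stages assume.

RENDER_LEVELS <- c(bg = 0.05, interior = 0.30, rim = 0.55,
                   colony = 0.70, diatom = 0.90)

#' Render a ground-truthed synthetic particle scene
#'
#' Produces the full observable record of one synthetic experiment: a
#' brightfield stack (particle rim, static elongated diatoms, growing disk
#' colonies), an oxygen-nanosensor fluorescence stack in which fluorescence
#' rises as oxygen falls (`F = F0 / (1 + Ksv C)` plus additive noise), the
#' two calibration endmember frames (fully anoxic: `C = 0`; air-equilibrated:
#' `C =` saturation), and the ground truth needed to verify every
#' downstream stage (label maps, true areas, true oxygen fields, diatom
#' mask, lag windows).
#'
#' Oxygen is solved quasi-steadily each frame ([simulate_oxygen_field()]),
#' with every colony pixel consuming at `config$consumption_q`. Colonies are
#' placed (uniformly over the particle area, or at the configured polar
#' positions) so that their final extents stay separated and clear of the
#' rim and of diatoms; placement that cannot satisfy these constraints, or
#' explicit positions outside the particle, is an error.
#'
#' @param config a [scene_config()] object.
#' @param diatom_length_um major-axis length of a rendered diatom.
#' @param rim_width_px width of the bright particle rim.
#' @param store_o2 keep the per-frame true oxygen fields (memory-hungry for
#'   long stacks).
#' @return object of class `particle_scene`: list with `brightfield`,
#'   `sensor` (x, y, frame arrays), `calib_anoxic`, `calib_air` (matrices),
#'   `geometry` ([particle_geometry]), `config`, `time_h`, and `truth`
#'   (list: `labels` array, `areas_px2`, `areas_um2`, `analytic_areas_um2`
#'   (colony x frame matrices), `centers` (colony x 2, px), `diatom_mask`,
#'   `o2` array if `store_o2`, `lag_start_h`, `lag_duration_h`).
#' @export
render_scene <- function(config, diatom_length_um = 160, rim_width_px = 2,
                         store_o2 = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$rng_seed)

  px <- config$pixel_size_um
  R_px <- config$particle_radius_um / px
  margin <- 8
  size <- ceiling(2 * R_px + 2 * (margin + 12))
  geometry <- disk_geometry(size, R_px, px)
  center <- geometry$center
  mask <- geometry$mask
  nT <- config$n_frames
  time_h <- (seq_len(nT) - 1) * config$frame_interval_h

  gl <- config$growth_law
  analytic_areas <- vapply(time_h, function(t)
    colony_area_at(gl, t), numeric(1))
  final_r_px <- sqrt(max(analytic_areas) / pi) / px

  # --- colony placement ------------------------------------------------------
  nC <- config$n_colonies
  rim_clear <- margin + rim_width_px
  sep <- 2 * final_r_px + 10
  if (nC > 0) {
    if (identical(config$colony_seed_positions, "random")) {
      centers <- place_disks(nC, center, R_px - rim_clear - final_r_px, sep)
    } else {
      pos <- config$colony_seed_positions
      r_px <- pos[, 1] / px
      if (any(r_px + final_r_px > R_px - rim_clear))
        stop("colony placement outside particle (or too close to the rim)",
             call. = FALSE)
      centers <- cbind(center[1] + r_px * cos(pos[, 2]),
                       center[2] + r_px * sin(pos[, 2]))
    }
  } else centers <- matrix(numeric(0), 0, 2)

  # --- diatom placement (static ellipses, clear of colonies and rim) --------
  nD <- config$n_diatoms
  a_px <- (diatom_length_um / 2) / px
  b_px <- max(a_px / config$diatom_axis_ratio, 1.2)
  diatom_mask <- matrix(0, size, size)
  if (nD > 0) {
    placed <- 0; attempts <- 0
    xs <- matrix(seq_len(size), size, size); ys <- t(xs)
    while (placed < nD && attempts < 20000) {
      attempts <- attempts + 1
      rr <- sqrt(runif(1)) * (R_px - rim_clear - a_px)
      th <- runif(1, 0, 2 * pi)
      cx <- center[1] + rr * cos(th); cy <- center[2] + rr * sin(th)
      if (nrow(centers) > 0 &&
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) <
            a_px + final_r_px + 12) next
      ang <- runif(1, 0, pi)
      dx <- xs - cx; dy <- ys - cy
      u <- dx * cos(ang) + dy * sin(ang); v <- -dx * sin(ang) + dy * cos(ang)
      ell <- (u / a_px)^2 + (v / b_px)^2 <= 1
      if (any(ell & diatom_mask > 0)) next
      diatom_mask[ell] <- 1
      placed <- placed + 1
    }
    if (placed < nD)
      stop("could not place all diatoms without overlap", call. = FALSE)
  }

  # --- static brightfield backdrop ------------------------------------------
  lv <- RENDER_LEVELS
  rim <- dilate_binary(mask_contour(mask), rim_width_px) * mask
  backdrop <- matrix(lv["bg"], size, size)
  backdrop[mask == 1] <- lv["interior"]
  backdrop[rim == 1] <- lv["rim"]
  backdrop[diatom_mask == 1] <- lv["diatom"]

  solver <- oxygen_solver(geometry, config$diffusivity_um2_s)
  d_center <- sqrt((matrix(seq_len(size), size, size) - center[1])^2 +
                     (t(matrix(seq_len(size), size, size)) - center[2])^2)
  f0 <- 1 + config$f0_gradient * (d_center / R_px - 0.5)
  sat <- config$o2_saturation_umol_L
  Ksv <- config$stern_volmer_Ksv

  brightfield <- array(0, c(size, size, nT))
  sensor <- array(0, c(size, size, nT))
  labels_arr <- array(0L, c(size, size, nT))
  o2_arr <- if (store_o2) array(NA_real_, c(size, size, nT)) else NULL
  areas_px2 <- matrix(0, max(nC, 1), nT)[seq_len(nC), , drop = FALSE]
  areas_um2 <- areas_px2
  xs <- matrix(seq_len(size), size, size); ys <- t(xs)

  sensor_frame <- function(C) {
    f <- matrix(0.02, size, size)
    inb <- mask == 1
    f[inb] <- f0[inb] / (1 + Ksv * C[inb])
    if (config$noise_sd > 0)
      f <- f + matrix(rnorm(size * size, 0, config$noise_sd), size, size)
    f
  }

  for (t in seq_len(nT)) {
    labs <- matrix(0L, size, size)
    r_t <- sqrt(colony_area_at(gl, time_h[t]) / pi) / px
    for (k in seq_len(nC)) {
      disk <- (xs - centers[k, 1])^2 + (ys - centers[k, 2])^2 <= r_t^2
      labs[disk] <- k
      areas_px2[k, t] <- sum(disk)
      areas_um2[k, t] <- sum(disk) * px^2
    }
    bf <- backdrop
    bf[labs > 0] <- lv["colony"]
    if (config$noise_sd > 0)
      bf <- bf + matrix(rnorm(size * size, 0, config$noise_sd), size, size)

    sinks <- sink_field_from_labels(labs, config$consumption_q)
    C <- simulate_oxygen_field(geometry, sinks, boundary = sat,
                               diffusivity_um2_s = config$diffusivity_um2_s,
                               solver = solver)
    brightfield[, , t] <- bf
    sensor[, , t] <- sensor_frame(C)
    labels_arr[, , t] <- labs
    if (store_o2) o2_arr[, , t] <- C
  }

  calib_anoxic <- sensor_frame(matrix(0, size, size))
  calib_air <- sensor_frame(matrix(sat, size, size))

  structure(list(
    brightfield = brightfield, sensor = sensor,
    calib_anoxic = calib_anoxic, calib_air = calib_air,
    geometry = geometry, config = config, time_h = time_h,
    truth = list(
      labels = labels_arr, areas_px2 = areas_px2, areas_um2 = areas_um2,
      analytic_areas_um2 = outer(rep(1, max(nC, 1)), vapply(
        time_h, function(t) colony_area_at(gl, t), numeric(1)))[seq_len(nC), , drop = FALSE],
      centers = centers, diatom_mask = diatom_mask,
      o2 = o2_arr, f0 = f0,
      lag_start_h = gl$lag_start_h, lag_duration_h = gl$lag_duration_h
    )
  ), class = "particle_scene")
}

#' @noRd
place_disks <- function(n, center, r_max, min_sep, max_attempts = 20000) {
  if (r_max <= 0) stop("particle too small for the requested colonies", call. = FALSE)
  pts <- matrix(NA_real_, n, 2)
  placed <- 0; attempts <- 0
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1
    rr <- sqrt(runif(1)) * r_max
    th <- runif(1, 0, 2 * pi)
    p <- center + rr * c(cos(th), sin(th))
    if (placed == 0 ||
        min(sqrt((pts[seq_len(placed), 1] - p[1])^2 +
                   (pts[seq_len(placed), 2] - p[2])^2)) >= min_sep) {
      placed <- placed + 1
      pts[placed, ] <- p
    }
  }
  if (placed < n)
    stop("could not place all colonies with the required separation", call. = FALSE)
  pts
}

#' @noRd
dilate_binary <- function(mask, radius) {
  if (radius < 1) return(mask)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask), brush))
}

#' Render a radial gene-expression ring
#'
#' Emulates a transcriptional-reporter channel (NarK-GFP or NirS-dsRed)
#' whose intensity is Gaussian in distance from the particle edge:
#' `I(d) = amplitude * exp(-(d - peak_um)^2 / (2 sd_um^2))` inside the
#' particle, a faint uniform background outside, plus additive noise.
#'
#' @param geometry a [particle_geometry] object.
#' @param peak_um ring center, µm from the particle edge.
#' @param sd_um ring width (Gaussian sd), µm.
#' @param amplitude peak intensity.
#' @param background intensity outside the particle.
#' @param noise_sd additive Gaussian noise sd.
#' @return intensity matrix.
#' @export
render_expression_ring <- function(geometry, peak_um, sd_um, amplitude = 1,
                                   background = 0.02, noise_sd = 0) {
  stopifnot(inherits(geometry, "particle_geometry"))
  check_scalar(peak_um, "peak_um", nonneg = TRUE)
  check_scalar(sd_um, "sd_um", positive = TRUE)
  d <- geometry$distance_to_edge_um
  img <- matrix(background, nrow(d), ncol(d))
  inb <- geometry$mask == 1
  img[inb] <- background + amplitude * exp(-(d[inb] - peak_um)^2 / (2 * sd_um^2))
  if (noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img), ncol(img))
  img
}

#' Write a rendered scene to disk
#'
#' Multi-page TIFF per channel (brightfield, sensor, labels), single-page
#' TIFFs for the calibration endmembers, and a JSON sidecar with the scalar
#' ground truth (areas, centers, lag windows, configuration).
#'
#' @param scene a `particle_scene` from [render_scene()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "particle_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(arr, name, scale = 1) {
    img <- EBImage::Image(pmin(pmax(arr / scale, 0), 1))
    EBImage::writeImage(img, file.path(dir, name), type = "tiff")
  }
  wr(scene$brightfield, "brightfield.tif")
  wr(scene$sensor, "sensor.tif", scale = 2)
  wr(scene$truth$labels, "labels.tif",
     scale = max(1, max(scene$truth$labels)))
  wr(scene$calib_anoxic, "calib_anoxic.tif", scale = 2)
  wr(scene$calib_air, "calib_air.tif", scale = 2)
  truth <- scene$truth
  jsonlite::write_json(list(
    config = unclass(scene$config)[setdiff(names(scene$config), "growth_law")],
    growth_law = unclass(scene$config$growth_law),
    time_h = scene$time_h,
    areas_um2 = truth$areas_um2,
    centers_px = truth$centers,
    lag_start_h = truth$lag_start_h,
    lag_duration_h = truth$lag_duration_h
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
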