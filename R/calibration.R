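#' Radially zoned two-endmember nanosensor calibration
#'
#' The oxygen nanosensor is a quenching sensor: fluorescence is maximal
#' under full anoxia (`F_anoxic = F0`) and quenched by oxygen following
#' Stern-Volmer, `F = F0 / (1 + Ksv C)`. Because nanoparticle loading is
#' spatially heterogeneous, each particle carries its own calibration, and
#' the particle is divided into annular zones of distance-from-edge; the
#' median fluorescence of each zone in the two endmember frames (anoxic and
#' air-equilibrated) anchors a per-zone inversion:
#' \deqn{K_{sv} = (F_{anoxic}/F_{air} - 1) / C_{sat}.}
#'
#' @param anoxic_frame sensor image under full anoxia (`C = 0` everywhere).
#' @param air_frame sensor image at air equilibration (`C =` saturation).
#' @param geometry a [particle_geometry] object co-registered with the
#'   frames.
#' @param n_zones number of equal-width distance-from-edge annuli.
#' @param o2_saturation air-equilibrated oxygen concentration, µmol L⁻¹
#'   (supplied by the user for their seawater; no correction is applied).
#' @return object of class `calibration_model`: `zone_edges_um` (length
#'   `n_zones + 1`, from 0 at the edge to the maximal distance), per-zone
#'   `F_anoxic`, `F_air`, `Ksv`, `ok` (FALSE for zones with degenerate
#'   endmembers, whose `Ksv` is `NA` — flagged, never interpolated), and
#'   `o2_saturation`.
#' @export
fit_calibration <- function(anoxic_frame, air_frame, geometry, n_zones = 20,
                            o2_saturation) {
  anoxic_frame <- as_matrix_image(anoxic_frame, "anoxic_frame")
  air_frame <- as_matrix_image(air_frame, "air_frame")
  stopifnot(inherits(geometry, "particle_geometry"))
  check_scalar(o2_saturation, "o2_saturation", positive = TRUE)
  if (n_zones < 1) stop("n_zones must be >= 1", call. = FALSE)
  if (!all(dim(anoxic_frame) == dim(geometry$mask)) ||
      !all(dim(air_frame) == dim(geometry$mask)))
    stop("calibration frames must match the geometry dimensions", call. = FALSE)

  d <- geometry$distance_to_edge_um
  inside <- geometry$mask == 1
  d_max <- max(d[inside])
  edges <- seq(0, d_max, length.out = n_zones + 1)
  zone <- zone_index(d, edges)

  F_anoxic <- F_air <- rep(NA_real_, n_zones)
  for (z in seq_len(n_zones)) {
    sel <- inside & !is.na(zone) & zone == z
    if (!any(sel))
      stop(sprintf("calibration zone %d contains no pixels; reduce n_zones", z),
           call. = FALSE)
    F_anoxic[z] <- median(anoxic_frame[sel])
    F_air[z] <- median(air_frame[sel])
  }
  ok <- F_anoxic > F_air & F_air > 0
  if (!any(ok))
    stop("calibration failed in every zone: anoxic endmember must exceed the air endmember",
         call. = FALSE)
  if (!all(ok))
    warning(sprintf("calibration failed in %d of %d zones (flagged, not interpolated)",
                    sum(!ok), n_zones))
  Ksv <- ifelse(ok, (F_anoxic / F_air - 1) / o2_saturation, NA_real_)

  structure(list(zone_edges_um = edges, F_anoxic = F_anoxic, F_air = F_air,
                 Ksv = Ksv, ok = ok, o2_saturation = o2_saturation,
                 inversion = "stern-volmer two-point"),
            class = "calibration_model")
}

#' @noRd
zone_index <- function(d, edges) {
  z <- findInterval(d, edges, rightmost.closed = TRUE)
  n <- length(edges) - 1
  z[!is.na(z) & z < 1] <- 1L
  z[!is.na(z) & z > n] <- n
  z
}

#' @export
print.calibration_model <- function(x, ...) {
  n <- length(x$Ksv)
  cat("Stern-Volmer two-endmember calibration\n")
  cat(sprintf("  zones: %d annuli over [0, %.0f] um from the edge\n",
              n, max(x$zone_edges_um)))
  cat(sprintf("  saturation: %g umol/L\n", x$o2_saturation))
  cat(sprintf("  Ksv: %.4g - %.4g L/umol (%d zone%s flagged)\n",
              min(x$Ksv, na.rm = TRUE), max(x$Ksv, na.rm = TRUE),
              sum(!x$ok), if (sum(!x$ok) == 1) "" else "s"))
  invisible(x)
}

#' Convert a sensor frame to an oxygen concentration field
#'
#' Inverts the per-zone Stern-Volmer relation pixel by pixel:
#' `C = (F_anoxic / F - 1) / Ksv`, using the calibration zone of each
#' pixel's distance to the edge; clipped to `[0, saturation]`. Pixels
#' outside the particle are `NA`; non-positive fluorescence pixels are
#' masked (`NA`) and counted in the `"masked_pixels"` attribute.
#'
#' @param frame sensor fluorescence image.
#' @param model a `calibration_model` from [fit_calibration()].
#' @param geometry a [particle_geometry] object.
#' @return oxygen concentration matrix (µmol L⁻¹).
#' @export
fluorescence_to_oxygen <- function(frame, model, geometry) {
  frame <- as_matrix_image(frame, "frame")
  stopifnot(inherits(model, "calibration_model"),
            inherits(geometry, "particle_geometry"))
  inside <- geometry$mask == 1
  zone <- zone_index(geometry$distance_to_edge_um, model$zone_edges_um)
  C <- matrix(NA_real_, nrow(frame), ncol(frame))
  bad <- inside & frame <= 0
  n_bad <- sum(bad)
  use <- inside & !bad & !is.na(zone)
  z <- zone[use]
  C[use] <- (model$F_anoxic[z] / frame[use] - 1) / model$Ksv[z]
  C[use] <- pmin(pmax(C[use], 0), model$o2_saturation)
  if (n_bad > 0)
    message(sprintf("fluorescence_to_oxygen: masked %d non-positive pixel(s)", n_bad))
  attr(C, "masked_pixels") <- n_bad
  C
}

#' Classify an oxygen concentration into the standard categories
#'
#' Strictly-below thresholds: nanoxic (< 1), suboxic (< 5), microoxic
#' (< 10), hypoxic (< 40), otherwise oxic (all µmol L⁻¹). The most extreme
#' applicable category is returned; the boundaries are exclusive, so exactly
#' 40 µmol L⁻¹ is oxic.
#'
#' @param c oxygen concentration(s), µmol L⁻¹; must be non-negative.
#' @return factor with ordered levels
#'   `nanoxic < suboxic < microoxic < hypoxic < oxic`.
#' @export
classify_oxygen <- function(c) {
  if (any(is.na(c))) stop("oxygen concentrations must not be NA", call. = FALSE)
  if (any(c < 0)) stop("oxygen concentrations must be >= 0", call. = FALSE)
  lv <- c("nanoxic", "suboxic", "microoxic", "hypoxic", "oxic")
  idx <- findInterval(c, c(1, 5, 10, 40)) + 1L
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Serialize a calibration model to JSON
#' @param model a `calibration_model`.
#' @param path file path.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
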