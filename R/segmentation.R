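#' Elongation shape factor of a binary object
#'
#' The square root of the ratio of the object's second central moments
#' around its principal axes: 1 for a disk, ~= the axis ratio for an
#' ellipse, and large for diatom chains. Degenerate objects (all pixels
#' collinear, so the minor moment vanishes) return `Inf`.
#'
#' @param object_mask binary matrix (or logical) marking the object pixels.
#' @return the shape factor, a scalar >= 1 (or `Inf`).
#' @export
elongation_shape_factor <- function(object_mask) {
  object_mask <- as_matrix_image(object_mask * 1, "object_mask")
  idx <- which(object_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("object mask is empty", call. = FALSE)
  if (nrow(idx) == 1) return(Inf)
  S <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx) # population moments
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Mask diatoms by shape
#'
#' Diatom chains are strongly elongated where microcolonies are
#' near-circular, so bright objects inside the particle are segmented
#' (Otsu on brightfield intensity, connected components) and those with an
#' elongation shape factor at or above the threshold are returned as the
#' diatom mask. The mask is subsequently used to invalidate diatom pixels
#' in the sensor and expression channels, where chlorophyll
#' autofluorescence would contaminate the signal.
#'
#' @param brightfield brightfield image.
#' @param geometry a [particle_geometry] object.
#' @param esf_threshold objects with ESF >= this are classified as diatoms;
#'   `Inf` yields an empty mask.
#' @param rim_margin_px pixels within this distance of the particle edge are
#'   not considered (the bright rim is not an object).
#' @return binary matrix (1 = diatom pixel); possibly empty.
#' @export
mask_diatoms <- function(brightfield, geometry, esf_threshold = 2,
                         rim_margin_px = 6) {
  brightfield <- as_matrix_image(brightfield, "brightfield")
  stopifnot(inherits(geometry, "particle_geometry"))
  region <- interior_region(geometry, rim_margin_px)
  out <- matrix(0, nrow(brightfield), ncol(brightfield))
  if (!any(region) || is.infinite(esf_threshold)) return(out)

  vals <- brightfield[region]
  thr <- otsu_threshold(vals)
  bin <- matrix(0, nrow(brightfield), ncol(brightfield))
  bin[region] <- (brightfield[region] > thr) * 1
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
  n <- max(labels)
  if (n == 0) return(out)
  for (k in seq_len(n)) {
    obj <- labels == k
    if (elongation_shape_factor(obj * 1) >= esf_threshold) out[obj] <- 1
  }
  out
}

#' @noRd
interior_region <- function(geometry, rim_margin_px) {
  d <- geometry$distance_to_edge_um
  !is.na(d) & d > rim_margin_px * geometry$pixel_size_um
}

# Otsu on a numeric vector (256-bin histogram over the value range)
#' @noRd
otsu_threshold <- function(x, n_bins = 256) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  xn <- (x - r[1]) / diff(r)
  thr <- EBImage::otsu(EBImage::Image(matrix(xn, nrow = 1)), range = c(0, 1),
                       levels = n_bins)
  r[1] + thr * diff(r)
}

#' Sobel gradient magnitude
#' @noRd
sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), kx))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), t(kx)))
  sqrt(gx^2 + gy^2)
}

#' Segment microcolonies in one frame
#'
#' Edge filter (Sobel magnitude) restricted to the particle interior, Otsu
#' binarization of the gradient, dilation, flood fill, and connected
#' components give candidate colony regions; candidates overlapping the
#' diatom mask (or mostly outside the particle) are discarded. By default
#' each surviving candidate is then refined to the bright pixels it
#' contains (pooled Otsu on brightfield intensity inside the candidates),
#' which removes the systematic area inflation the dilation step would
#' otherwise introduce. Every colony is reported with its area, centroid,
#' distance to the particle edge, and the median oxygen over its pixels.
#'
#' @param brightfield brightfield image.
#' @param geometry a [particle_geometry] object.
#' @param diatom_mask optional binary diatom mask from [mask_diatoms()].
#' @param o2_field optional co-registered oxygen field (µmol L⁻¹); when
#'   absent the oxygen columns are `NA`.
#' @param frame_index,time_h bookkeeping stamped into the observations.
#' @param dilate_radius radius (px) of the disk structuring element.
#' @param min_area_px candidates smaller than this are dropped (speckle
#'   suppression).
#' @param rim_margin_px interior margin excluded from edge detection (the
#'   particle rim is itself a strong edge).
#' @param refine_intensity refine candidate regions to their bright pixels
#'   (recommended; `FALSE` gives the raw dilated-and-filled regions).
#' @return list with `observations` (one row per colony: `frame_index`,
#'   `time_h`, `label`, `area_um2`, `centroid_x`, `centroid_y`,
#'   `distance_to_edge_um`, `median_o2_umol_L`, `o2_category`) and `labels`
#'   (integer label matrix).
#' @export
segment_colonies <- function(brightfield, geometry, diatom_mask = NULL,
                             o2_field = NULL, frame_index = 1L, time_h = 0,
                             dilate_radius = 2, min_area_px = 10,
                             rim_margin_px = 6, refine_intensity = TRUE) {
  brightfield <- as_matrix_image(brightfield, "brightfield")
  stopifnot(inherits(geometry, "particle_geometry"))
  dims <- dim(brightfield)
  if (is.null(diatom_mask)) diatom_mask <- matrix(0, dims[1], dims[2])

  region <- interior_region(geometry, rim_margin_px)
  grad <- sobel_magnitude(brightfield)
  grad[!region] <- 0

  empty <- list(observations = empty_observations(), labels = matrix(0L, dims[1], dims[2]))
  if (max(grad) <= 0) return(empty)
  thr <- otsu_threshold(grad[region])
  band <- (grad > thr) * 1
  if (!any(band == 1)) return(empty)

  cand <- dilate_binary(band, dilate_radius)
  cand <- EBImage::imageData(EBImage::fillHull(EBImage::Image(cand)))
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand)))

  keep <- matrix(FALSE, dims[1], dims[2])
  for (k in seq_len(max(labels))) {
    obj <- labels == k
    if (any(obj & diatom_mask > 0)) next     # chlorophyll interference
    if (mean(geometry$mask[obj]) < 0.5) next # rim artifact / outside
    keep[obj] <- TRUE
  }
  if (!any(keep)) return(empty)

  if (refine_intensity) {
    thr_i <- otsu_threshold(brightfield[keep])
    keep <- keep & (brightfield > thr_i)
  }
  keep <- keep & geometry$mask == 1 & diatom_mask == 0
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(keep * 1)))

  # speckle suppression
  sizes <- tabulate(labels)
  drop <- which(sizes < min_area_px)
  if (length(drop)) {
    labels[labels %in% drop] <- 0L
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((labels > 0) * 1)))
  }
  n <- max(labels)
  if (n == 0) return(empty)

  px <- geometry$pixel_size_um
  obs <- lapply(seq_len(n), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
    dte <- distance_from_edge(c(cx, cy), geometry)
    o2 <- if (is.null(o2_field)) NA_real_ else {
      vals <- o2_field[labels == k]
      median(vals[!is.na(vals)])
    }
    data.frame(frame_index = as.integer(frame_index), time_h = time_h,
               label = k, area_um2 = nrow(idx) * px^2,
               centroid_x = cx, centroid_y = cy,
               distance_to_edge_um = dte,
               median_o2_umol_L = o2,
               o2_category = if (is.na(o2)) NA_character_ else
                 as.character(classify_oxygen(o2)),
               stringsAsFactors = FALSE)
  })
  list(observations = do.call(rbind, obs), labels = labels)
}

#' @noRd
empty_observations <- function() {
  data.frame(frame_index = integer(0), time_h = numeric(0), label = integer(0),
             area_um2 = numeric(0), centroid_x = numeric(0),
             centroid_y = numeric(0), distance_to_edge_um = numeric(0),
             median_o2_umol_L = numeric(0), o2_category = character(0),
             stringsAsFactors = FALSE)
}

#' Segment every frame of a scene
#'
#' Convenience driver: detects diatoms once on the first frame (they are
#' static), converts each sensor frame to oxygen with the supplied
#' calibration, and segments colonies frame by frame.
#'
#' @param scene a `particle_scene` from [render_scene()], or a list with
#'   `brightfield`/`sensor` arrays, `geometry` and `time_h`.
#' @param calibration optional `calibration_model`; when omitted the oxygen
#'   columns are `NA`.
#' @param ... passed to [segment_colonies()].
#' @return list of per-frame results (each as in [segment_colonies()]),
#'   with the diatom mask as attribute `"diatom_mask"`.
#' @export
segment_stack <- function(scene, calibration = NULL, ...) {
  geometry <- scene$geometry
  nT <- dim(scene$brightfield)[3]
  dia <- mask_diatoms(scene$brightfield[, , 1], geometry)
  frames <- vector("list", nT)
  for (t in seq_len(nT)) {
    o2 <- if (is.null(calibration)) NULL else
      fluorescence_to_oxygen(scene$sensor[, , t], calibration, geometry)
    frames[[t]] <- segment_colonies(scene$brightfield[, , t], geometry,
                                    diatom_mask = dia, o2_field = o2,
                                    frame_index = t, time_h = scene$time_h[t],
                                    ...)
  }
  attr(frames, "diatom_mask") <- dia
  attr(frames, "pixel_size_um") <- geometry$pixel_size_um
  frames
}
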