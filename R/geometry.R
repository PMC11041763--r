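#' Particle geometry: mask, center, radius and distance-to-edge
#'
#' All radial statistics in the pipeline are expressed as distance from the
#' particle edge, so the particle mask and its Euclidean distance-to-edge
#' transform are computed once (from the first frame of a stack) and reused
#' for every later frame.
#'
#' A `particle_geometry` object is a list with elements:
#' \describe{
#'   \item{mask}{binary matrix (1 inside the particle), first index = x,
#'     second = y, 1-based pixel-center coordinates}
#'   \item{center}{numeric (x, y) centroid in pixels}
#'   \item{equivalent_radius_um}{radius of the circle with the mask's area}
#'   \item{contour}{n x 2 matrix of boundary pixel coordinates (pixels of the
#'     mask with at least one 4-neighbour outside)}
#'   \item{distance_to_edge_um}{matrix of distances (µm) to the nearest
#'     contour pixel; `NA` outside the mask, 0 on the contour}
#'   \item{pixel_size_um}{physical pixel pitch}
#' }
#'
#' @name particle_geometry
NULL

#' Build geometry from a binary mask
#'
#' Used both by [detect_particle()] and by the synthetic-scene generator
#' (which knows the mask analytically and skips detection).
#'
#' @param mask binary matrix, 1 inside the particle.
#' @param pixel_size_um physical size of one pixel in µm.
#' @param center optional (x, y); defaults to the mask centroid.
#' @param nominal_radius_px optional analytic disk radius in pixels; when
#'   present it is carried along so that downstream consumers (e.g. the
#'   oxygen solver) can use boundary-fitted stencils.
#' @return a `particle_geometry` object.
#' @export
geometry_from_mask <- function(mask, pixel_size_um, center = NULL,
                               nominal_radius_px = NULL) {
  mask <- as_matrix_image(mask, "mask")
  mask <- (mask > 0) * 1
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  area <- sum(mask)
  if (area < 1L) stop("no particle found: empty mask", call. = FALSE)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (is.null(center)) center <- c(mean(idx[, 1]), mean(idx[, 2]))
  if (mask[round(center[1]), round(center[2])] != 1)
    warning("particle centroid falls outside the mask; non-convex particle?")

  contour_img <- mask_contour(mask)
  contour <- which(contour_img == 1, arr.ind = TRUE)
  colnames(contour) <- c("x", "y")

  # distance to nearest contour pixel: distmap measures distance to the
  # nearest zero pixel, so feed it the contour complement
  dte <- EBImage::imageData(EBImage::distmap(1 - contour_img))
  dte[mask == 0] <- NA_real_
  dte <- dte * pixel_size_um

  structure(list(
    mask = mask,
    center = as.numeric(center),
    equivalent_radius_um = sqrt(area / pi) * pixel_size_um,
    contour = contour,
    distance_to_edge_um = dte,
    pixel_size_um = pixel_size_um,
    nominal_radius_px = nominal_radius_px
  ), class = "particle_geometry")
}

#' Analytic disk geometry
#'
#' @param size image size in pixels (square image, `size x size`).
#' @param radius_px disk radius in pixels.
#' @param pixel_size_um physical pixel pitch in µm.
#' @param center (x, y) disk center in pixels; defaults to the image center.
#' @return a `particle_geometry` object whose mask is the set of pixel
#'   centers strictly inside the circle.
#' @export
disk_geometry <- function(size, radius_px, pixel_size_um,
                          center = c((size + 1) / 2, (size + 1) / 2)) {
  check_scalar(radius_px, "radius_px", positive = TRUE)
  x <- matrix(seq_len(size), size, size)
  y <- t(x)
  mask <- ((x - center[1])^2 + (y - center[2])^2 < radius_px^2) * 1
  geometry_from_mask(mask, pixel_size_um, center = center,
                     nominal_radius_px = radius_px)
}

#' @noRd
mask_contour <- function(mask) {
  n1 <- rbind(mask[-1, , drop = FALSE], 0)
  n2 <- rbind(0, mask[-nrow(mask), , drop = FALSE])
  n3 <- cbind(mask[, -1, drop = FALSE], 0)
  n4 <- cbind(0, mask[, -ncol(mask), drop = FALSE])
  interior <- (n1 + n2 + n3 + n4 == 4) & (mask == 1)
  (mask == 1 & !interior) * 1
}

#' Detect the particle in the first frame of a stack
#'
#' Contrast stretch, heavy Gaussian blur, Otsu global threshold, largest
#' connected component and hole fill; region properties then give the
#' center, equivalent radius and edge contour, and the Euclidean distance
#' transform gives the per-pixel distance to the edge.
#'
#' @param frame 2-D numeric matrix (brightfield, pseudo dark field: particle
#'   brighter than background).
#' @param pixel_size_um physical pixel pitch in µm.
#' @param sigma standard deviation (pixels) of the Gaussian smoothing kernel.
#' @param min_area_px components smaller than this are not accepted as the
#'   particle.
#' @param stretch_quantiles lower/upper quantiles for the initial contrast
#'   stretch.
#' @return a `particle_geometry` object.
#' @export
detect_particle <- function(frame, pixel_size_um, sigma = 20,
                            min_area_px = 100,
                            stretch_quantiles = c(0.01, 0.99)) {
  frame <- as_matrix_image(frame, "frame")
  check_scalar(sigma, "sigma", positive = TRUE)
  q <- stats::quantile(frame, stretch_quantiles, names = FALSE, na.rm = TRUE)
  if (q[2] <= q[1]) stop("no particle found: flat image", call. = FALSE)
  stretched <- pmin(pmax((frame - q[1]) / (q[2] - q[1]), 0), 1)

  blurred <- EBImage::gblur(EBImage::Image(stretched), sigma = sigma)
  thr <- EBImage::otsu(blurred)
  bin <- EBImage::imageData(blurred) > thr
  if (!any(bin)) stop("no particle found: empty threshold result", call. = FALSE)

  labels <- EBImage::bwlabel(EBImage::Image(bin * 1))
  tab <- tabulate(EBImage::imageData(labels))
  if (max(tab) < min_area_px)
    stop("no particle found: largest component below minimum area", call. = FALSE)
  biggest <- which.max(tab)
  mask <- (EBImage::imageData(labels) == biggest) * 1
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask)))

  border <- c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)])
  if (mean(border) > 0.5)
    warning("particle touches more than half the image border; likely truncated")

  geometry_from_mask(mask, pixel_size_um)
}

#' Distance from the particle edge at a pixel
#'
#' @param point numeric (x, y) pixel coordinates (1-based, may be fractional;
#'   rounded to the nearest pixel center).
#' @param geometry a [particle_geometry] object.
#' @return distance to the particle edge in µm.
#' @export
distance_from_edge <- function(point, geometry) {
  stopifnot(inherits(geometry, "particle_geometry"))
  i <- round(point[1]); j <- round(point[2])
  dims <- dim(geometry$mask)
  if (i < 1 || j < 1 || i > dims[1] || j > dims[2] || geometry$mask[i, j] != 1)
    stop("point lies outside the particle mask", call. = FALSE)
  geometry$distance_to_edge_um[i, j]
}

#' @export
print.particle_geometry <- function(x, ...) {
  cat("Particle geometry\n")
  cat(sprintf("  image: %d x %d px (%.3g um/px)\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_um))
  cat(sprintf("  center: (%.1f, %.1f) px\n", x$center[1], x$center[2]))
  cat(sprintf("  equivalent radius: %.1f um (%.1f px)\n",
              x$equivalent_radius_um, x$equivalent_radius_um / x$pixel_size_um))
  cat(sprintf("  area: %d px\n", as.integer(sum(x$mask))))
  invisible(x)
}

#' Serialize geometry to JSON (mask omitted; regenerate from contour if needed)
#' @param geometry a [particle_geometry] object.
#' @param path file path.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "particle_geometry"))
  jsonlite::write_json(list(
    center = geometry$center,
    equivalent_radius_um = geometry$equivalent_radius_um,
    pixel_size_um = geometry$pixel_size_um,
    dim = dim(geometry$mask),
    contour = unname(apply(geometry$contour, 1, as.numeric, simplify = FALSE))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
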