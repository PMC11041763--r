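#' Radial biomass profile
#'
#' Bins each track's final-frame observation by distance from the particle
#' edge and reports, per bin, the cumulative colony area, the mean colony
#' size and the colony count. Empty bins have `NA` mean size.
#'
#' @param tracks a `colony_tracks` object.
#' @param geometry a [particle_geometry] object (sets the bin span).
#' @param n_bins number of equal-width distance bins over
#'   `[0, equivalent radius]`.
#' @return data.frame of class `radial_profile`: `bin_lo_um`, `bin_hi_um`,
#'   `bin_mid_um`, `total_area_um2`, `mean_area_um2`, `n_colonies`.
#' @export
radial_biomass_profile <- function(tracks, geometry, n_bins = 15) {
  stopifnot(inherits(geometry, "particle_geometry"))
  if (length(tracks) == 0) stop("no tracks", call. = FALSE)
  finals <- do.call(rbind, lapply(tracks, function(tr)
    tail(tr$observations, 1)))
  edges <- seq(0, geometry$equivalent_radius_um, length.out = n_bins + 1)
  b <- zone_index(finals$distance_to_edge_um, edges)
  out <- data.frame(
    bin_lo_um = edges[-length(edges)], bin_hi_um = edges[-1],
    bin_mid_um = (edges[-1] + edges[-length(edges)]) / 2,
    total_area_um2 = 0, mean_area_um2 = NA_real_, n_colonies = 0L)
  for (z in seq_len(n_bins)) {
    sel <- !is.na(b) & b == z
    if (any(sel)) {
      out$total_area_um2[z] <- sum(finals$area_um2[sel])
      out$mean_area_um2[z] <- mean(finals$area_um2[sel])
      out$n_colonies[z] <- sum(sel)
    }
  }
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Probability density of colony positions along the radius
#'
#' Gaussian kernel density estimate of colony distance-to-edge, with the
#' kernel reflected at the particle edge (distance 0) so the density is
#' not biased low where the biology concentrates; numerically normalized
#' to integrate to 1 over `[0, R]`.
#'
#' @param tracks a `colony_tracks` object, or a numeric vector of
#'   distances (µm).
#' @param geometry a [particle_geometry] object.
#' @param bandwidth kernel bandwidth (µm); Silverman's rule by default.
#' @param n_grid evaluation grid size.
#' @return data.frame of class `radial_density`: `distance_um`, `density`;
#'   attribute `"bandwidth"`.
#' @export
colony_radial_pdf <- function(tracks, geometry, bandwidth = NULL,
                              n_grid = 512) {
  stopifnot(inherits(geometry, "particle_geometry"))
  x <- if (is.numeric(tracks)) tracks else
    vapply(tracks, function(tr) tr$final_distance_to_edge_um, numeric(1))
  x <- x[!is.na(x)]
  if (length(x) < 2)
    stop("degenerate density: need at least two colonies", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(x)
  if (bandwidth <= 0) bandwidth <- max(sd(x), 1)
  R <- geometry$equivalent_radius_um
  grid <- seq(0, R, length.out = n_grid)
  f <- vapply(grid, function(g)
    mean(stats::dnorm(g, x, bandwidth) + stats::dnorm(g, -x, bandwidth)),
    numeric(1))
  dx <- grid[2] - grid[1]
  total <- sum((f[-1] + f[-n_grid]) / 2) * dx
  out <- data.frame(distance_um = grid, density = f / total)
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("radial_density", "data.frame")
  out
}

#' Radial gene-expression profile and peak statistics
#'
#' Background-subtracted reporter intensity (NarK-GFP or NirS-dsRed) as a
#' function of distance from the particle edge. The background is the
#' median intensity outside the particle; diatom pixels are excluded
#' (chlorophyll bleeds into the dsRed channel). The per-bin statistic is
#' the mean pixel intensity of the annulus — the radial line-profile
#' equivalent, which does not confound the signal with annulus area — and
#' the binned profile is normalized to a probability density over
#' distance. Peak statistics are the density-weighted mean, sd and median
#' distance; count weighting (total intensity per annulus) is available
#' behind `weighting`.
#'
#' @param expression_image reporter channel image.
#' @param geometry a [particle_geometry] object.
#' @param diatom_mask optional binary diatom mask.
#' @param channel label stored in the result (`"NarK"`, `"NirS"`, ...).
#' @param bin_width_um distance bin width.
#' @param weighting `"intensity"` (mean per annulus; default) or
#'   `"total"` (summed intensity per annulus).
#' @return object of class `expression_profile`: list with `channel`,
#'   `profile` (data.frame: `distance_um`, `density`), `peak_mean_um`,
#'   `peak_sd_um`, `peak_median_um`, `background`.
#' @export
expression_radial_profile <- function(expression_image, geometry,
                                      diatom_mask = NULL,
                                      channel = "NarK", bin_width_um = 10,
                                      weighting = c("intensity", "total")) {
  img <- as_matrix_image(expression_image, "expression_image")
  stopifnot(inherits(geometry, "particle_geometry"))
  weighting <- match.arg(weighting)
  inside <- geometry$mask == 1
  bg <- median(img[!inside])
  # no per-pixel clipping: rectified noise would put a spurious uniform
  # floor under every annulus and drag the peak statistics inward; noise
  # cancels in the per-bin means instead, which are clamped at zero below
  I <- img - bg
  valid <- inside
  if (!is.null(diatom_mask)) valid <- valid & diatom_mask == 0
  if (sum(pmax(I[valid], 0)) <= 0)
    stop("expression channel carries no signal above background", call. = FALSE)

  d <- geometry$distance_to_edge_um
  d_max <- max(d[valid])
  edges <- seq(0, d_max + bin_width_um, by = bin_width_um)
  b <- zone_index(d, edges)
  nb <- length(edges) - 1
  sigma_bg <- stats::mad(img[!inside])
  stat <- rep(NA_real_, nb)
  for (z in seq_len(nb)) {
    sel <- valid & !is.na(b) & b == z
    if (any(sel)) {
      n_sel <- sum(sel)
      s <- if (weighting == "intensity") mean(I[sel]) else sum(I[sel])
      # annuli indistinguishable from background noise carry no signal
      floor_z <- 2 * sigma_bg / sqrt(n_sel) * if (weighting == "total") n_sel else 1
      stat[z] <- if (s < floor_z) 0 else s
    }
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  ok <- !is.na(stat)
  w <- stat[ok] / sum(stat[ok])
  dens <- stat[ok] / (sum(stat[ok]) * bin_width_um)
  mu <- sum(mids[ok] * w)
  sdv <- sqrt(sum(w * (mids[ok] - mu)^2))
  cw <- cumsum(w)
  med_i <- which(cw >= 0.5)[1]
  med <- mids[ok][med_i]

  structure(list(
    channel = channel,
    profile = data.frame(distance_um = mids[ok], density = dens),
    peak_mean_um = mu, peak_sd_um = sdv, peak_median_um = med,
    background = bg, weighting = weighting
  ), class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("%s radial expression profile (%s-weighted)\n",
              x$channel, x$weighting))
  cat(sprintf("  peak: %.0f +/- %.0f um from the edge (median %.0f um)\n",
              x$peak_mean_um, x$peak_sd_um, x$peak_median_um))
  invisible(x)
}

#' Depth-translated bulk chemistry profile
#'
#' Maps a sampled time series of bulk seawater chemistry (DOC, nitrate,
#' nitrite) onto ocean depth through the sinking speed, averaging across
#' replicates when a `replicate` column is present.
#'
#' @param series data.frame with columns `time_h`, `doc_mg_L`,
#'   `no3_umol_L`, `no2_umol_L` (and optionally `replicate`), or the path
#'   of such a CSV.
#' @param speed_m_per_d sinking speed for the depth translation.
#' @return data.frame of class `chemistry_profile`: `depth_m`, per-analyte
#'   mean and (with replicates) sd columns.
#' @export
chemistry_depth_profile <- function(series, speed_m_per_d = 4.8) {
  if (is.character(series)) series <- read.csv(series)
  need <- c("time_h", "doc_mg_L", "no3_umol_L", "no2_umol_L")
  if (!all(need %in% names(series)))
    stop("series must have columns ", paste(need, collapse = ", "), call. = FALSE)
  analytes <- need[-1]
  if ("replicate" %in% names(series)) {
    per_rep <- split(series, series$replicate)
    times <- sort(unique(series$time_h))
    if (any(vapply(per_rep, function(d) is.unsorted(d$time_h, strictly = TRUE),
                   logical(1))))
      stop("non-monotone time axis", call. = FALSE)
    out <- data.frame(time_h = times, depth_m = depth_from_time(times, speed_m_per_d))
    for (a in analytes) {
      vals <- vapply(times, function(tt) {
        v <- series[[a]][series$time_h == tt]
        c(mean(v), sd(v))
      }, numeric(2))
      out[[a]] <- vals[1, ]
      out[[paste0(a, "_sd")]] <- vals[2, ]
    }
  } else {
    if (is.unsorted(series$time_h, strictly = TRUE))
      stop("non-monotone time axis", call. = FALSE)
    out <- data.frame(time_h = series$time_h,
                      depth_m = depth_from_time(series$time_h, speed_m_per_d))
    for (a in analytes) out[[a]] <- series[[a]]
  }
  class(out) <- c("chemistry_profile", "data.frame")
  out
}

#' Welch two-sample comparison of a scalar between conditions
#'
#' Routine supporting statistic (not a novel computation): Welch's t-test
#' on e.g. initial DOC or lag duration between the broken- and
#' intact-diatom conditions.
#'
#' @param a,b numeric samples (>= 2 values each).
#' @return list with `t`, `df`, `p`.
#' @export
compare_conditions <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two values per condition", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = 2 * (length(a) - 1), p = 1))
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
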