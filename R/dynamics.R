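#' Translate experiment time to ocean depth
#'
#' The flow-through device imposes a sinking speed, so time maps linearly
#' to depth: `depth = speed * t / 24` (t in hours, speed in m per day). At
#' the default 4.8 m d⁻¹, 100 h is 20 m and 200 h is 40 m.
#'
#' @param t_h time(s) in hours; must be non-negative.
#' @param speed_m_per_d sinking speed, m d⁻¹; must be positive.
#' @return depth(s) in meters.
#' @export
depth_from_time <- function(t_h, speed_m_per_d = 4.8) {
  if (any(t_h < 0)) stop("t_h must be >= 0", call. = FALSE)
  check_scalar(speed_m_per_d, "speed_m_per_d", positive = TRUE)
  speed_m_per_d * t_h / 24
}

#' Daily through-flow volume of the millifluidic device
#'
#' @param rate_mL_min volumetric flow rate (default the device's
#'   0.01 mL min⁻¹).
#' @return volume in mL flowing past the particles per day.
#' @export
daily_throughflow_mL <- function(rate_mL_min = 0.01) {
  check_scalar(rate_mL_min, "rate_mL_min", positive = TRUE)
  rate_mL_min * 60 * 24
}

#' Diffusive flushing time scale of a particle
#'
#' The time `R^2 / D` for diffusion to exchange the particle's volume with
#' the bulk — about 20 minutes for a 1.5 mm particle.
#'
#' @param radius_m particle radius, m.
#' @param diffusivity_m2_s solute diffusivity, m² s⁻¹.
#' @return time in minutes.
#' @export
diffusive_flush_min <- function(radius_m = 1.5e-3, diffusivity_m2_s = 1.9e-9) {
  check_scalar(radius_m, "radius_m", positive = TRUE)
  check_scalar(diffusivity_m2_s, "diffusivity_m2_s", positive = TRUE)
  radius_m^2 / diffusivity_m2_s / 60
}

# ---- growth-phase decomposition --------------------------------------------

#' Decompose a colony growth curve into diauxic phases
#'
#' Fits log(area) versus time with a penalized piecewise-linear model (up
#' to `max_changepoints` changepoints; exact dynamic programming over
#' segment boundaries, BIC model selection) and labels the segments:
#' the first segment is the initial exponential (`exp1`, rate `mu1`); the
#' lag is the longest interior segment whose slope falls below
#' `lag_slope_frac * mu1`; a later segment with slope back above the
#' threshold is the second exponential (`exp2`); trailing low-slope
#' segments after `exp2` are `stationary`. Lag duration is reported in
#' hours and in depth-translated meters.
#'
#' @param track a `colony_track` (or any data.frame with `time_h` and
#'   `area_um2`).
#' @param speed_m_per_d sinking speed for depth translation.
#' @param min_track_len tracks shorter than this are flagged (`too_short`)
#'   and excluded from lag statistics.
#' @param max_changepoints maximum number of changepoints (0-3).
#' @param min_seg_len minimum points per segment.
#' @param lag_slope_frac lag threshold as a fraction of `mu1`.
#' @return object of class `growth_phases`: list with `segments`
#'   (data.frame: `phase`, `t_start_h`, `t_end_h`, `slope_per_h`,
#'   `depth_start_m`, `depth_end_m`), `mu1`, `mu2`, `lag_start_h`,
#'   `lag_duration_h`, `lag_duration_m`, `flagged`.
#' @export
fit_growth_phases <- function(track, speed_m_per_d = 4.8,
                              min_track_len = 12, max_changepoints = 3,
                              min_seg_len = 4, lag_slope_frac = 0.1) {
  obs <- if (inherits(track, "colony_track")) track$observations else track
  keep <- is.finite(obs$area_um2) & obs$area_um2 > 0 # below-detection = missing
  t <- obs$time_h[keep]
  y <- log(obs$area_um2[keep])
  n <- length(t)
  if (n < min_track_len) {
    return(structure(list(segments = NULL, mu1 = NA_real_, mu2 = NA_real_,
                          lag_start_h = NA_real_, lag_duration_h = NA_real_,
                          lag_duration_m = NA_real_, flagged = "too_short"),
                     class = "growth_phases"))
  }

  fit <- piecewise_linear_bic(t, y, max_changepoints, min_seg_len)
  segs <- fit$segments

  mu1 <- segs$slope[1]
  thr <- lag_slope_frac * max(mu1, 0)
  m <- nrow(segs)
  phase <- rep("exp", m)
  lag_idx <- NA_integer_
  if (m >= 2) {
    interior <- 2:m
    low <- interior[segs$slope[interior] < thr]
    # a diauxic lag sits between two growth phases: prefer low-slope
    # segments with a later above-threshold segment; fall back to the
    # longest interior low-slope segment (track may end mid-lag)
    followed <- low[vapply(low, function(i)
      i < m && any(segs$slope[(i + 1):m] >= thr), logical(1))]
    pick <- if (length(followed)) followed else low
    if (length(pick))
      lag_idx <- pick[which.max(segs$t_end[pick] - segs$t_start[pick])]
  }
  phase[1] <- "exp1"
  if (!is.na(lag_idx)) {
    phase[lag_idx] <- "lag"
    after <- seq_len(m) > lag_idx
    phase[after & segs$slope >= thr] <- "exp2"
    phase[after & segs$slope < thr] <- "stationary"
    if (lag_idx > 2) phase[2:(lag_idx - 1)] <- "exp1"
  } else if (m >= 2) {
    phase[2:m] <- ifelse(segs$slope[2:m] < thr, "stationary", "exp1")
  }

  mu2 <- if (any(phase == "exp2")) segs$slope[which(phase == "exp2")[1]] else NA_real_
  lag_start <- if (!is.na(lag_idx)) segs$t_start[lag_idx] else NA_real_
  lag_dur <- if (!is.na(lag_idx)) segs$t_end[lag_idx] - segs$t_start[lag_idx] else NA_real_

  structure(list(
    segments = data.frame(
      phase = phase, t_start_h = segs$t_start, t_end_h = segs$t_end,
      slope_per_h = segs$slope,
      depth_start_m = depth_from_time(segs$t_start, speed_m_per_d),
      depth_end_m = depth_from_time(segs$t_end, speed_m_per_d),
      stringsAsFactors = FALSE),
    mu1 = mu1, mu2 = mu2, lag_start_h = lag_start,
    lag_duration_h = lag_dur,
    lag_duration_m = if (is.na(lag_dur)) NA_real_ else
      speed_m_per_d * lag_dur / 24,
    flagged = NA_character_
  ), class = "growth_phases")
}

#' @export
print.growth_phases <- function(x, ...) {
  if (!is.na(x$flagged)) {
    cat("Growth phases: flagged (", x$flagged, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Growth phases:\n")
  print(x$segments, row.names = FALSE, digits = 4)
  if (!is.na(x$lag_duration_h))
    cat(sprintf("  lag: starts %.1f h, lasts %.1f h (%.2f m of sinking)\n",
                x$lag_start_h, x$lag_duration_h, x$lag_duration_m))
  invisible(x)
}

# Exact DP over changepoints for piecewise-linear least squares, BIC choice
# of the number of segments. O(n^2) segment costs via prefix sums.
#' @noRd
piecewise_linear_bic <- function(t, y, max_changepoints, min_seg_len) {
  n <- length(t)
  St <- cumsum(t); Stt <- cumsum(t^2); Sy <- cumsum(y)
  Sty <- cumsum(t * y); Syy <- cumsum(y^2)
  pre <- function(S, i, j) S[j] - if (i > 1) S[i - 1] else 0
  seg_cost <- function(i, j) { # RSS of OLS line on points i..j
    m <- j - i + 1
    st <- pre(St, i, j); stt <- pre(Stt, i, j)
    sy <- pre(Sy, i, j); sty <- pre(Sty, i, j); syy <- pre(Syy, i, j)
    vt <- stt - st^2 / m
    cty <- sty - st * sy / m
    vy <- syy - sy^2 / m
    if (vt <= 0) return(vy)
    max(vy - cty^2 / vt, 0)
  }
  cost <- matrix(Inf, n, n)
  for (i in 1:(n - min_seg_len + 1))
    for (j in (i + min_seg_len - 1):n)
      cost[i, j] <- seg_cost(i, j)

  kmax <- max_changepoints + 1
  dp <- matrix(Inf, kmax, n)
  back <- matrix(NA_integer_, kmax, n)
  dp[1, ] <- cost[1, ]
  for (k in seq_len(kmax)[-1]) {
    if (k * min_seg_len > n) next
    for (j in (k * min_seg_len):n) {
      i_opts <- ((k - 1) * min_seg_len):(j - min_seg_len)
      vals <- dp[k - 1, i_opts] + cost[i_opts + 1, j]
      b <- which.min(vals)
      dp[k, j] <- vals[b]
      back[k, j] <- i_opts[b]
    }
  }
  sigma_floor <- 1e-12
  bic <- vapply(1:kmax, function(k) {
    rss <- dp[k, n]
    p <- 2 * k + (k - 1)
    n * log(max(rss, sigma_floor) / n) + p * log(n)
  }, numeric(1))
  k_best <- which.min(bic)

  bounds <- n
  k <- k_best
  j <- n
  while (k > 1) {
    i <- back[k, j]
    bounds <- c(i, bounds)
    j <- i; k <- k - 1
  }
  starts <- c(1, head(bounds, -1) + 1)
  ends <- bounds
  segs <- data.frame(t_start = t[starts], t_end = t[ends],
                     slope = NA_real_, intercept = NA_real_)
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    f <- lm(y[idx] ~ t[idx])
    segs$intercept[s] <- coef(f)[1]
    segs$slope[s] <- coef(f)[2]
  }
  list(segments = segs, k = k_best, rss = dp[k_best, n])
}

# ---- oxygen exposure --------------------------------------------------------

#' Fraction of colony area below each oxygen threshold
#'
#' Area-weighted fraction of the colony biomass experiencing oxygen
#' strictly below each threshold; by construction the fractions are nested
#' (`frac(<1) <= frac(<5) <= frac(<10) <= frac(<40)`). Pass pixel-level
#' oxygen values (equal weights) or per-colony medians with colony areas
#' as weights.
#'
#' @param o2 oxygen values, µmol L⁻¹.
#' @param weights optional area weights (same length as `o2`).
#' @param thresholds strict upper bounds, µmol L⁻¹.
#' @return named numeric vector (`frac_lt_40`, ... in the order given);
#'   all-`NA` when no colony is present (an empty frame has no defined
#'   fraction — it is missing, not zero).
#' @export
oxygen_exposure_fractions <- function(o2, weights = NULL,
                                      thresholds = c(40, 10, 5, 1)) {
  nm <- paste0("frac_lt_", thresholds)
  o2 <- o2[!is.na(o2)]
  if (length(o2) == 0) return(setNames(rep(NA_real_, length(thresholds)), nm))
  if (is.null(weights)) weights <- rep(1, length(o2))
  w <- weights / sum(weights)
  setNames(vapply(thresholds, function(th) sum(w[o2 < th]), numeric(1)), nm)
}

#' Per-frame oxygen-exposure series from segmented frames
#'
#' @param frames list of per-frame [segment_colonies()] results with oxygen
#'   fields attached (`segment_stack()` with a calibration), or a list of
#'   per-frame `o2_field` + `labels`.
#' @param o2_fields optional list of oxygen matrices (one per frame); when
#'   omitted, per-colony medians weighted by area are used instead of
#'   pixel-level values.
#' @param thresholds strict upper bounds, µmol L⁻¹.
#' @return data.frame: `frame_index`, `time_h`, one column per threshold.
#' @export
exposure_series <- function(frames, o2_fields = NULL,
                            thresholds = c(40, 10, 5, 1)) {
  rows <- lapply(seq_along(frames), function(t) {
    fr <- frames[[t]]
    obs <- fr$observations
    fr_time <- if (nrow(obs)) obs$time_h[1] else NA_real_
    fx <- if (!is.null(o2_fields)) {
      vals <- o2_fields[[t]][fr$labels > 0]
      oxygen_exposure_fractions(vals, thresholds = thresholds)
    } else {
      oxygen_exposure_fractions(obs$median_o2_umol_L, weights = obs$area_um2,
                                thresholds = thresholds)
    }
    cbind(data.frame(frame_index = t, time_h = fr_time), as.list(fx))
  })
  do.call(rbind, rows)
}

#' Mean colony oxygen over time, with replicate spread
#'
#' Per frame, the mean of the per-colony median oxygen values; when a list
#' of replicate track sets is given, the across-replicate mean and standard
#' deviation of that per-particle series.
#'
#' @param tracks a `colony_tracks` object, or a list of them (replicates).
#' @return data.frame: `frame_index`, `time_h`, `mean_o2`, `sd_o2`, `n`
#'   (colonies for one replicate; replicates otherwise, with per-replicate
#'   series in attribute `"replicates"`).
#' @export
particle_mean_o2_series <- function(tracks) {
  if (inherits(tracks, "colony_tracks")) {
    df <- as.data.frame(tracks)
    sp <- split(df, df$frame_index)
    out <- do.call(rbind, lapply(sp, function(d) data.frame(
      frame_index = d$frame_index[1], time_h = d$time_h[1],
      mean_o2 = mean(d$median_o2_umol_L, na.rm = TRUE),
      sd_o2 = sd(d$median_o2_umol_L, na.rm = TRUE),
      n = sum(!is.na(d$median_o2_umol_L)))))
    rownames(out) <- NULL
    return(out)
  }
  reps <- lapply(tracks, particle_mean_o2_series)
  frames <- sort(unique(unlist(lapply(reps, `[[`, "frame_index"))))
  out <- do.call(rbind, lapply(frames, function(f) {
    vals <- vapply(reps, function(r) {
      v <- r$mean_o2[r$frame_index == f]
      if (length(v)) v else NA_real_
    }, numeric(1))
    th <- unlist(lapply(reps, function(r) r$time_h[r$frame_index == f]))[1]
    data.frame(frame_index = f, time_h = th,
               mean_o2 = mean(vals, na.rm = TRUE),
               sd_o2 = sd(vals, na.rm = TRUE),
               n = sum(!is.na(vals)))
  }))
  attr(out, "replicates") <- reps
  out
}

#' Population lag statistics from fitted growth phases
#'
#' Fits [fit_growth_phases()] to every track and summarizes the
#' depth-translated lag durations as mean, sd and median (the dual
#' reporting convention for lag distributions).
#'
#' @param tracks a `colony_tracks` object.
#' @param ... passed to [fit_growth_phases()].
#' @return list with `lag_m` (per-track depth-translated lags),
#'   `mean_m`, `sd_m`, `median_m`, `n_fitted`, `n_excluded`.
#' @export
lag_statistics <- function(tracks, ...) {
  fits <- lapply(tracks, fit_growth_phases, ...)
  lag_m <- vapply(fits, function(f) f$lag_duration_m, numeric(1))
  excluded <- vapply(fits, function(f) !is.na(f$flagged), logical(1))
  lag_m <- lag_m[!excluded]
  ok <- !is.na(lag_m)
  list(lag_m = lag_m[ok],
       mean_m = mean(lag_m[ok]), sd_m = sd(lag_m[ok]),
       median_m = median(lag_m[ok]),
       n_fitted = sum(ok), n_excluded = sum(excluded) + sum(!ok))
}
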