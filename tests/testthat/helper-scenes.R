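# Shared fixtures, built in code. Scenes are kept small (100 px particle
# radius, a handful of frames) so the whole suite stays fast.

small_scene <- function(n_frames = 8, n_colonies = 6, n_diatoms = 5,
                        noise_sd = 0, seed = 7,
                        growth = diauxic_growth(mu1 = 0.05, lag_start_h = 100,
                                                lag_duration_h = 0, mu2 = 0,
                                                area0_um2 = 6000), ...) {
  render_scene(scene_config(
    particle_radius_um = 1500, pixel_size_um = 15, n_frames = n_frames,
    n_colonies = n_colonies, n_diatoms = n_diatoms, noise_sd = noise_sd,
    growth_law = growth, rng_seed = seed, ...))
}

# hand-built frame for tracking tests: disks on a blank particle
make_frame <- function(geometry, centers, radii, frame_index, time_h = frame_index) {
  size <- nrow(geometry$mask)
  labs <- matrix(0L, size, size)
  xs <- matrix(seq_len(size), size, size); ys <- t(xs)
  obs <- list()
  k <- 0
  for (i in seq_len(nrow(centers))) {
    if (radii[i] <= 0) next
    k <- k + 1
    disk <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radii[i]^2
    labs[disk] <- k
    idx <- which(disk, arr.ind = TRUE)
    obs[[k]] <- data.frame(
      frame_index = frame_index, time_h = time_h, label = k,
      area_um2 = nrow(idx) * geometry$pixel_size_um^2,
      centroid_x = mean(idx[, 1]), centroid_y = mean(idx[, 2]),
      distance_to_edge_um = distance_from_edge(c(mean(idx[, 1]), mean(idx[, 2])),
                                               geometry),
      median_o2_umol_L = NA_real_, o2_category = NA_character_,
      stringsAsFactors = FALSE)
  }
  list(observations = if (k > 0) do.call(rbind, obs) else
    aggrescope:::empty_observations(), labels = labs)
}

make_track <- function(id, time_h, area_um2, o2 = NA_real_, dist = NA_real_) {
  obs <- data.frame(
    frame_index = seq_along(time_h), time_h = time_h, label = id,
    area_um2 = area_um2, centroid_x = NA_real_, centroid_y = NA_real_,
    distance_to_edge_um = dist, median_o2_umol_L = o2,
    o2_category = NA_character_, stringsAsFactors = FALSE)
  aggrescope:::new_colony_track(id, obs)
}

as_tracks <- function(...) {
  trs <- list(...)
  structure(trs, class = "colony_tracks",
            qc = data.frame(track_id = seq_along(trs), split_orphan = FALSE))
}
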