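#' Colony tracks
#'
#' A `colony_track` is a list with `track_id`, `birth_frame`,
#' `observations` (a data.frame of per-frame [segment_colonies()] rows in
#' increasing frame order) and `final_distance_to_edge_um`. A set of tracks
#' is a `colony_tracks` list with a `qc` attribute (data.frame:
#' `track_id`, `split_orphan`).
#'
#' @name colony_track
NULL

#' @noRd
new_colony_track <- function(track_id, observations, split_orphan = FALSE) {
  observations <- observations[order(observations$frame_index), , drop = FALSE]
  structure(list(
    track_id = track_id,
    birth_frame = observations$frame_index[1],
    observations = observations,
    final_distance_to_edge_um =
      observations$distance_to_edge_um[nrow(observations)]
  ), class = "colony_track", split_orphan = split_orphan)
}

#' Resolve overlap conflicts between later-frame colonies and earlier ones
#'
#' Greedy injective assignment in descending overlap, with deterministic
#' tie-breaks (larger later-colony area, then lower earlier label id, then
#' lower track id). When two later colonies both overlap one earlier colony
#' (a split, viewed forward), the larger overlap claims the ancestor and
#' the other candidate is left unassigned — shared ancestry is not allowed.
#'
#' @param candidates data.frame with columns `track` (later-frame claimant
#'   id), `prev_label` (earlier-frame colony), `overlap` (shared pixels),
#'   `area` (later colony area).
#' @return the accepted subset of `candidates`, one row per track and per
#'   `prev_label` at most.
#' @export
resolve_overlap_conflicts <- function(candidates) {
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(-candidates$overlap, -candidates$area,
               candidates$prev_label, candidates$track)
  candidates <- candidates[ord, , drop = FALSE]
  taken_prev <- integer(0); taken_track <- integer(0)
  acc <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (candidates$prev_label[i] %in% taken_prev) next
    if (candidates$track[i] %in% taken_track) next
    acc[i] <- TRUE
    taken_prev <- c(taken_prev, candidates$prev_label[i])
    taken_track <- c(taken_track, candidates$track[i])
  }
  candidates[acc, , drop = FALSE]
}

#' Backtrack colonies from the final frame into per-colony trajectories
#'
#' Colonies only appear and grow, so the final frame is the richest anchor:
#' starting there, every colony is followed backward, matched to at most
#' one colony in the preceding frame by maximal pixel overlap (fallback:
#' nearest centroid within `max_link_distance_um` when no overlap exists,
#' e.g. after a transient segmentation dropout). Matching is injective per
#' frame pair; a track that loses its only overlap candidates to a
#' larger-overlap claimant terminates and is flagged `split_orphan` in the
#' QC table. Tracks tolerate up to `max_gap` missing frames. Colonies in an
#' earlier frame that no later track claims start their own (forward-dying)
#' track, so every observation belongs to exactly one track.
#'
#' @param frames list of per-frame [segment_colonies()] results
#'   (`observations` + `labels`), in increasing frame order.
#' @param max_gap maximum tolerated missing frames within a track.
#' @param max_link_distance_um centroid-fallback search radius.
#' @return a `colony_tracks` object (tracks ordered by decreasing final
#'   frame, then label), with attribute `qc`.
#' @export
backtrack <- function(frames, max_gap = 2, max_link_distance_um = 20,
                      pixel_size_um = NULL) {
  if (is.null(pixel_size_um))
    pixel_size_um <- attr(frames, "pixel_size_um") %||% 1
  if (length(frames) == 0)
    return(structure(list(), class = "colony_tracks",
                     qc = data.frame(track_id = integer(0),
                                     split_orphan = logical(0))))
  nT <- length(frames)
  obs_list <- lapply(frames, `[[`, "observations")

  # open tracks: rows = (id, frame of current anchor, label at that frame,
  # gap count); observations accumulated per id
  next_id <- 1L
  open <- list()
  done <- list()
  orphan_flag <- logical(0)

  start_tracks <- function(frame_idx, labels_vec) {
    for (lb in labels_vec) {
      row <- obs_list[[frame_idx]][obs_list[[frame_idx]]$label == lb, , drop = FALSE]
      open[[length(open) + 1]] <<- list(
        id = next_id, frame = frame_idx, label = lb, gap = 0L,
        obs = row)
      orphan_flag[next_id] <<- FALSE
      next_id <<- next_id + 1L
    }
  }

  start_tracks(nT, obs_list[[nT]]$label)

  for (f in rev(seq_len(nT - 1L))) {
    prev_labels <- obs_list[[f]]$label
    prev_labs_img <- frames[[f]]$labels
    # overlap candidates between each open track's current mask and frame f
    cands <- list()
    for (oi in seq_along(open)) {
      tr <- open[[oi]]
      cur_img <- frames[[tr$frame]]$labels
      ov_labels <- prev_labs_img[cur_img == tr$label]
      ov_labels <- ov_labels[ov_labels > 0]
      if (length(ov_labels)) {
        tab <- table(ov_labels)
        cands[[length(cands) + 1]] <- data.frame(
          track = oi, prev_label = as.integer(names(tab)),
          overlap = as.integer(tab),
          area = tr$obs$area_um2[1])
      }
    }
    cands <- if (length(cands)) do.call(rbind, cands) else
      data.frame(track = integer(0), prev_label = integer(0),
                 overlap = integer(0), area = numeric(0))
    assigned <- resolve_overlap_conflicts(cands)

    claimed_prev <- assigned$prev_label
    matched_tracks <- assigned$track
    had_overlap <- unique(cands$track)

    # centroid fallback for tracks with no overlap at all
    free_prev <- setdiff(prev_labels, claimed_prev)
    for (oi in setdiff(seq_along(open), c(matched_tracks, had_overlap))) {
      if (!length(free_prev)) break
      tr <- open[[oi]]
      prev_obs <- obs_list[[f]][obs_list[[f]]$label %in% free_prev, , drop = FALSE]
      if (nrow(prev_obs) == 0) next
      dx <- (prev_obs$centroid_x - tr$obs$centroid_x[1])
      dy <- (prev_obs$centroid_y - tr$obs$centroid_y[1])
      dist_um <- sqrt(dx^2 + dy^2) * pixel_size_um
      j <- which.min(dist_um)
      if (length(j) && dist_um[j] <= max_link_distance_um) {
        assigned <- rbind(assigned, data.frame(
          track = oi, prev_label = prev_obs$label[j], overlap = 0L,
          area = tr$obs$area_um2[1]))
        matched_tracks <- c(matched_tracks, oi)
        free_prev <- setdiff(free_prev, prev_obs$label[j])
      }
    }

    new_open <- list()
    for (oi in seq_along(open)) {
      tr <- open[[oi]]
      hit <- assigned[assigned$track == oi, , drop = FALSE]
      if (nrow(hit) == 1) {
        row <- obs_list[[f]][obs_list[[f]]$label == hit$prev_label, , drop = FALSE]
        tr$obs <- rbind(row, tr$obs)
        tr$frame <- f; tr$label <- hit$prev_label; tr$gap <- 0L
        new_open[[length(new_open) + 1]] <- tr
      } else if (oi %in% had_overlap) {
        # lost all its overlap candidates to other tracks: split orphan
        orphan_flag[tr$id] <- TRUE
        done[[length(done) + 1]] <- tr
      } else if (tr$gap < max_gap) {
        tr$gap <- tr$gap + 1L
        new_open[[length(new_open) + 1]] <- tr
      } else {
        done[[length(done) + 1]] <- tr
      }
    }
    open <- new_open
    # unclaimed earlier colonies become their own (forward-dying) tracks
    start_tracks(f, setdiff(prev_labels, assigned$prev_label))
  }
  done <- c(done, open)

  tracks <- lapply(done, function(tr)
    new_colony_track(tr$id, tr$obs, split_orphan = orphan_flag[tr$id]))
  ord <- order(vapply(tracks, function(t) t$track_id, numeric(1)))
  tracks <- tracks[ord]
  for (i in seq_along(tracks)) tracks[[i]]$track_id <- i
  qc <- data.frame(
    track_id = seq_along(tracks),
    split_orphan = vapply(tracks, function(t) isTRUE(attr(t, "split_orphan")),
                          logical(1)))
  structure(tracks, class = "colony_tracks", qc = qc)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.colony_tracks <- function(x, ...) {
  qc <- attr(x, "qc")
  lens <- vapply(x, function(t) nrow(t$observations), integer(1))
  cat(sprintf("%d colony track(s); lengths %s; %d split-orphan(s)\n",
              length(x),
              if (length(lens)) paste0(min(lens), "-", max(lens)) else "-",
              sum(qc$split_orphan)))
  invisible(x)
}

#' Flatten tracks to a tidy observations table
#'
#' @param x a `colony_tracks` object.
#' @param ... unused.
#' @return data.frame with a `track_id` column followed by the observation
#'   columns.
#' @export
as.data.frame.colony_tracks <- function(x, ...) {
  do.call(rbind, lapply(x, function(tr)
    cbind(track_id = tr$track_id, tr$observations)))
}

#' Write tracks to CSV
#' @param tracks a `colony_tracks` object.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Assemble tracks from a tidy observations table
#'
#' Inverse of [as.data.frame.colony_tracks()]: rebuilds a `colony_tracks`
#' object from a data.frame (or CSV path) with a `track_id` column plus the
#' per-frame observation columns.
#'
#' @param df data.frame or CSV path.
#' @return a `colony_tracks` object.
#' @export
as_colony_tracks <- function(df) {
  if (is.character(df)) df <- read.csv(df)
  if (!"track_id" %in% names(df))
    stop("`df` must have a track_id column", call. = FALSE)
  ids <- sort(unique(df$track_id))
  tracks <- lapply(ids, function(id)
    new_colony_track(id, df[df$track_id == id,
                            setdiff(names(df), "track_id"), drop = FALSE]))
  structure(tracks, class = "colony_tracks",
            qc = data.frame(track_id = ids, split_orphan = FALSE))
}
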