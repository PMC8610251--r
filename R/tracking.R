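#' Detect particles in a single frame
#'
#' Thresholded detection feeding the tracker: pixels strictly above the
#' threshold (the same 2x-cytosol rule as in volumetrics, here in 2D) are
#' grouped with 8-connectivity and each component is reduced to its
#' intensity-weighted centroid in micrometres.
#'
#' @param frame numeric matrix.
#' @param pixel_size micrometres per pixel.
#' @param threshold intensity cut-off; defaults to twice the frame's dimmer
#'   half mean, i.e. the whole-frame stand-in for the cytosol sample.
#' @param min_pixels discard components smaller than this (speckle guard).
#' @return tibble: `detection`, `x_um`, `y_um`, `n_pixels`, `intensity`.
#' @export
detect_particles <- function(frame, pixel_size,
                             threshold = NULL, min_pixels = 4L) {
  stopifnot(is.matrix(frame), nrow(frame) >= 1, ncol(frame) >= 1)
  if (is.null(threshold)) {
    dim_half <- frame[frame <= stats::median(frame)]
    threshold <- 2 * mean(dim_half)
  }
  mask <- frame > threshold
  if (!any(mask)) {
    return(tibble(
      detection = integer(), x_um = numeric(), y_um = numeric(),
      n_pixels = integer(), intensity = numeric()
    ))
  }
  lab <- label_components(mask, 8L)
  idx <- which(lab > 0)
  co <- arrayInd(idx, dim(frame))
  w <- frame[idx]
  df <- tibble(
    l = lab[idx],
    x = (co[, 2] - 0.5) * pixel_size,
    y = (co[, 1] - 0.5) * pixel_size,
    w = w
  ) %>%
    group_by(.data$l) %>%
    summarise(
      x_um = sum(.data$x * .data$w) / sum(.data$w),
      y_um = sum(.data$y * .data$w) / sum(.data$w),
      n_pixels = dplyr::n(),
      intensity = sum(.data$w),
      .groups = "drop"
    ) %>%
    filter(.data$n_pixels >= min_pixels)
  tibble(
    detection = seq_len(nrow(df)),
    x_um = df$x_um, y_um = df$y_um,
    n_pixels = df$n_pixels, intensity = df$intensity
  )
}

#' Link per-frame detections into tracks
#'
#' Deterministic greedy nearest-neighbour linking: candidate pairs between
#' consecutive frames are taken in ascending distance order; pairs farther
#' apart than `max_step` are never linked; unmatched detections start new
#' tracks. There is no gap closing, merging or splitting, so every
#' detection belongs to exactly one track.
#'
#' @param detections list of detection tibbles (one per frame, in order),
#'   as produced by [detect_particles()].
#' @param max_step hard linking gate in micrometres per frame.
#' @return tibble of track points: `track_id`, `frame`, `x_um`, `y_um`.
#' @export
link_tracks <- function(detections, max_step = 2) {
  if (max_step <= 0) abort("max_step must be > 0")
  n_frames <- length(detections)
  points <- list()
  next_track <- 0L
  prev_tracks <- integer(0) # track id of each detection in previous frame
  prev_xy <- NULL
  for (f in seq_len(n_frames)) {
    det <- detections[[f]]
    nd <- nrow(det)
    assigned <- rep(NA_integer_, nd)
    if (!is.null(prev_xy) && nd > 0 && nrow(prev_xy) > 0) {
      dmat <- outer(prev_xy[, 1], det$x_um, `-`)^2 +
        outer(prev_xy[, 2], det$y_um, `-`)^2
      cand <- which(dmat <= max_step^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(dmat[cand], cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        used_prev <- logical(nrow(prev_xy))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (!used_prev[i] && is.na(assigned[j])) {
            assigned[j] <- prev_tracks[i]
            used_prev[i] <- TRUE
          }
        }
      }
    }
    new_ids <- which(is.na(assigned))
    if (length(new_ids) > 0) {
      assigned[new_ids] <- next_track + seq_along(new_ids)
      next_track <- next_track + length(new_ids)
    }
    if (nd > 0) {
      points[[f]] <- tibble(
        track_id = assigned, frame = f,
        x_um = det$x_um, y_um = det$y_um
      )
    }
    prev_tracks <- assigned
    prev_xy <- if (nd > 0) cbind(det$x_um, det$y_um) else matrix(numeric(0), 0, 2)
  }
  out <- bind_rows(points)
  if (nrow(out) == 0) {
    return(tibble(track_id = integer(), frame = integer(),
                  x_um = numeric(), y_um = numeric()))
  }
  arrange(out, .data$track_id, .data$frame)
}

#' Motility metrics for linked tracks
#'
#' The three motility read-outs per track: `track_length_um` (sum of
#' consecutive Euclidean steps), `displacement_um` (straight-line distance
#' from first to last point), and `speed_um_s` (track length divided by the
#' elapsed time, `frame_interval * (n_points - 1)`). Displacement can never
#' exceed track length. Single-point tracks have undefined metrics and are
#' excluded; their number is returned in the `n_excluded` attribute.
#'
#' @param track_points tibble from [link_tracks()].
#' @param frame_interval seconds between frames.
#' @param min_points tracks shorter than this are dropped from the output
#'   (default 3: two-point tracks are noise-dominated; set to 2 to keep
#'   them).
#' @return tibble: `track_id`, `n_points`, `speed_um_s`, `track_length_um`,
#'   `displacement_um`, with attribute `n_excluded`.
#' @export
track_metrics <- function(track_points, frame_interval, min_points = 3L) {
  per <- track_points %>%
    group_by(.data$track_id) %>%
    summarise(
      n_points = dplyr::n(),
      track_length_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      displacement_um = sqrt(
        (dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
          (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2
      ),
      .groups = "drop"
    ) %>%
    mutate(speed_um_s = ifelse(
      .data$n_points >= 2,
      .data$track_length_um / (frame_interval * (.data$n_points - 1)),
      NA_real_
    ))
  n_excluded <- sum(per$n_points < min_points)
  out <- per %>%
    filter(.data$n_points >= min_points) %>%
    select("track_id", "n_points", "speed_um_s",
           "track_length_um", "displacement_um")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' One-call tracking of a time-lapse movie
#'
#' Detects particles in every frame, links them, and computes per-track
#' motility metrics.
#'
#' @param movie a [time_lapse()].
#' @param max_step linking gate in um per frame.
#' @param threshold optional fixed detection threshold.
#' @param min_points minimum track length kept in the metrics table.
#' @return list with `points` (per-point tibble) and `tracks` (per-track
#'   metrics tibble).
#' @export
track_movie <- function(movie, max_step = 2, threshold = NULL, min_points = 3L) {
  px <- attr(movie, "pixel_size")
  dt <- attr(movie, "frame_interval")
  detections <- purrr::map(
    seq_len(dim(movie)[3]),
    function(f) detect_particles(unclass(movie)[, , f], px, threshold = threshold)
  )
  points <- link_tracks(detections, max_step = max_step)
  list(points = points, tracks = track_metrics(points, dt, min_points))
}
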