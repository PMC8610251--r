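#' Motion models for time-lapse scenes
#'
#' Three particle motion laws for the synthetic movies: no motion, constant
#' velocity, and an isotropic Gaussian random walk. Positions that would
#' leave the usable field reflect off the boundary, so ground-truth tracks
#' are never truncated.
#'
#' @param vx,vy velocity components in um/s.
#' @param step_sd per-frame step standard deviation in um (per axis).
#' @return a `motion_model` list consumed by [generate_timelapse()].
#' @name motion-models
NULL

#' @rdname motion-models
#' @export
motion_stationary <- function() {
  structure(list(type = "stationary"), class = "motion_model")
}

#' @rdname motion-models
#' @export
motion_constant_velocity <- function(vx, vy = 0) {
  structure(list(type = "constant_velocity", v = c(vx, vy)), class = "motion_model")
}

#' @rdname motion-models
#' @export
motion_random_walk <- function(step_sd) {
  if (step_sd < 0) abort("step_sd must be >= 0")
  structure(list(type = "random_walk", step_sd = step_sd), class = "motion_model")
}

# reflect a coordinate into [lo, hi] (triangle fold)
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Generate a synthetic single-plane time-lapse with ground-truth tracks
#'
#' Renders diffraction-blurred particles moving under a chosen motion model.
#' The exact continuous particle positions at every frame are recorded in
#' the returned truth table; rendered frames get PSF blur, background and
#' noise exactly as z-stacks do. Frame-count presets follow the two
#' live-imaging regimes: 4 s intervals for 3 min or 8 s for 6 min, both 46
#' frames (see [timelapse_preset()]).
#'
#' @param config a [scene_config()]; `frame_interval` is taken from here.
#' @param n_particles number of particles.
#' @param motion a motion model from [motion_stationary()],
#'   [motion_constant_velocity()] or [motion_random_walk()].
#' @param n_frames number of frames (>= 2).
#' @param frame_size_um field of view `c(width, height)` in micrometres.
#' @param radius_um rendered particle radius.
#' @param intensity particle intensity.
#' @param min_separation_um minimum initial centre separation.
#' @return list with `movie` (a [time_lapse()]) and `truth` (tibble with one
#'   row per particle per frame: exact x/y in um).
#' @export
generate_timelapse <- function(config,
                               n_particles = 10L,
                               motion = motion_random_walk(0.3),
                               n_frames = 46L,
                               frame_size_um = c(30, 30),
                               radius_um = 0.5,
                               intensity = 1000,
                               min_separation_um = 4) {
  stopifnot(inherits(config, "scene_config"), inherits(motion, "motion_model"))
  if (n_frames < 2) abort("n_frames must be >= 2")
  px <- config$pixel_size_xy
  dims <- c(round(frame_size_um[2] / px), round(frame_size_um[1] / px))
  margin <- radius_um + 3 * config$psf_sigma + px
  lo <- margin
  hix <- frame_size_um[1] - margin
  hiy <- frame_size_um[2] - margin
  dt <- config$frame_interval

  set.seed(config$random_seed)
  # initial placement with a separation floor so detections stay unambiguous
  pos <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n_particles)) {
    for (try in 1:2000) {
      cand <- c(runif(1, lo, hix), runif(1, lo, hiy))
      if (nrow(pos) == 0 ||
        min(sqrt(colSums((t(pos) - cand)^2))) >= min_separation_um) {
        pos <- rbind(pos, cand)
        break
      }
      if (try == 2000) abort(sprintf("could not place particle %d", k))
    }
  }

  truth <- vector("list", n_frames)
  cur <- pos
  # per-particle velocity state so that a wall bounce reverses direction
  vel <- if (motion$type == "constant_velocity") {
    matrix(motion$v, n_particles, 2, byrow = TRUE)
  } else {
    matrix(0, n_particles, 2)
  }
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      step <- switch(motion$type,
        stationary = matrix(0, n_particles, 2),
        constant_velocity = vel * dt,
        random_walk = matrix(rnorm(2 * n_particles, 0, motion$step_sd), n_particles, 2)
      )
      cur <- cur + step
      for (ax in 1:2) {
        hi <- if (ax == 1) hix else hiy
        over <- cur[, ax] > hi | cur[, ax] < lo
        cur[, ax] <- reflect_into(cur[, ax], lo, hi)
        vel[over, ax] <- -vel[over, ax]
      }
    }
    truth[[f]] <- tibble(
      object_id = seq_len(n_particles),
      frame = f,
      t_s = (f - 1) * dt,
      x_um = cur[, 1],
      y_um = cur[, 2]
    )
  }
  truth <- bind_rows(truth)

  frames <- array(0, c(dims, n_frames))
  sigma_px <- config$psf_sigma / px
  for (f in seq_len(n_frames)) {
    tf <- truth[truth$frame == f, ]
    img <- rasterize_disks(
      dims, px, as.matrix(tf[, c("x_um", "y_um")]),
      rep(radius_um, n_particles), rep(intensity, n_particles)
    )
    img <- gaussian_blur(img, c(sigma_px, sigma_px))
    frames[, , f] <- img + config$background_level
  }
  frames <- add_noise(frames, config)

  list(
    movie = time_lapse(frames, frame_interval = dt, pixel_size = px),
    truth = truth
  )
}
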