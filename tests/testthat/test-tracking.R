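test_that("particle detection recovers sub-pixel centroids", {
  cfg <- scene_config(random_seed = 1, gaussian_sd = 0)
  tl <- generate_timelapse(cfg, n_particles = 1, motion = motion_stationary(),
                           n_frames = 2, frame_size_um = c(15, 15))
  det <- detect_particles(unclass(tl$movie)[, , 1], cfg$pixel_size_xy)
  expect_equal(nrow(det), 1)
  tr <- tl$truth[tl$truth$frame == 1, ]
  expect_lt(abs(det$x_um - tr$x_um), 0.5 * cfg$pixel_size_xy)
  expect_lt(abs(det$y_um - tr$y_um), 0.5 * cfg$pixel_size_xy)

  expect_equal(nrow(detect_particles(matrix(0, 20, 20), 0.1)), 0)

  two <- generate_timelapse(cfg, n_particles = 2, motion = motion_stationary(),
                            n_frames = 2, frame_size_um = c(25, 25),
                            min_separation_um = 10)
  expect_equal(nrow(detect_particles(unclass(two$movie)[, , 1], 0.1)), 2)
})

test_that("greedy linking builds one track per particle and never swaps distant ones", {
  # one particle across 46 frames
  one <- purrr::map(1:46, ~ tibble::tibble(
    detection = 1L, x_um = 5 + 0.05 * .x, y_um = 5,
    n_pixels = 9L, intensity = 100
  ))
  pts <- link_tracks(one, max_step = 2)
  expect_equal(length(unique(pts$track_id)), 1)
  expect_equal(nrow(pts), 46)

  # two stationary particles far apart
  two <- purrr::map(1:10, ~ tibble::tibble(
    detection = 1:2, x_um = c(1, 20), y_um = c(1, 1),
    n_pixels = 9L, intensity = 100
  ))
  pts2 <- link_tracks(two, max_step = 2)
  per_track <- dplyr::summarise(
    dplyr::group_by(pts2, track_id),
    sx = sd(x_um), n = dplyr::n()
  )
  expect_equal(nrow(per_track), 2)
  expect_true(all(per_track$sx == 0))

  # hand-traced crossing: ascending-distance greedy resolves A->C, B->D
  crossing <- list(
    tibble::tibble(detection = 1:2, x_um = c(0, 10), y_um = 0,
                   n_pixels = 9L, intensity = 100),
    tibble::tibble(detection = 1:2, x_um = c(4, 6), y_um = 0,
                   n_pixels = 9L, intensity = 100)
  )
  pts3 <- link_tracks(crossing, max_step = 10)
  t1 <- pts3[pts3$track_id == 1, ]
  expect_equal(t1$x_um, c(0, 4)) # A (x=0) linked to C (x=4): distance 4 < 6
  t2 <- pts3[pts3$track_id == 2, ]
  expect_equal(t2$x_um, c(10, 6))

  # detections beyond the gate start fresh tracks
  jump <- list(
    tibble::tibble(detection = 1L, x_um = 0, y_um = 0, n_pixels = 9L, intensity = 1),
    tibble::tibble(detection = 1L, x_um = 50, y_um = 0, n_pixels = 9L, intensity = 1)
  )
  expect_equal(length(unique(link_tracks(jump, max_step = 2)$track_id)), 2)
})

test_that("track metrics follow the kinematic definitions", {
  # (0,0) -> (3,4) over one 4 s interval: length 5, displacement 5, speed 1.25
  pts <- tibble::tibble(track_id = 1L, frame = 1:2, x_um = c(0, 3), y_um = c(0, 4))
  m <- track_metrics(pts, frame_interval = 4, min_points = 2)
  expect_equal(m$track_length_um, 5)
  expect_equal(m$displacement_um, 5)
  expect_equal(m$speed_um_s, 1.25)

  # stationary
  still <- tibble::tibble(track_id = 1L, frame = 1:5, x_um = 2, y_um = 2)
  ms <- track_metrics(still, 4, min_points = 2)
  expect_equal(ms$speed_um_s, 0)
  expect_equal(ms$track_length_um, 0)
  expect_equal(ms$displacement_um, 0)

  # square path returns to the origin: length 20, displacement exactly 0
  sq <- tibble::tibble(
    track_id = 1L, frame = 1:5,
    x_um = c(0, 5, 5, 0, 0), y_um = c(0, 0, 5, 5, 0)
  )
  msq <- track_metrics(sq, 4, min_points = 2)
  expect_equal(msq$track_length_um, 20)
  expect_identical(msq$displacement_um, 0)

  # short tracks are excluded with a logged count
  short <- tibble::tibble(track_id = c(1L, 1L, 2L), frame = c(1L, 2L, 1L),
                          x_um = 0, y_um = 0)
  out <- track_metrics(short, 4, min_points = 3)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_excluded"), 2)
})

test_that("displacement never exceeds track length on random walks", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    pts <- tibble::tibble(
      track_id = 1L, frame = seq_len(n),
      x_um = cumsum(rnorm(n, 0, 0.4)), y_um = cumsum(rnorm(n, 0, 0.4))
    )
    m <- track_metrics(pts, 4, min_points = 2)
    expect_gte(m$track_length_um, m$displacement_um - 1e-12)
  }
})

test_that("constant-velocity speed is recovered within 5% at both presets", {
  for (preset in c("RAW", "RPE")) {
    pr <- timelapse_preset(preset)
    cfg <- scene_config(random_seed = 30 + pr$frame_interval,
                        frame_interval = pr$frame_interval)
    v <- 0.1
    tl <- generate_timelapse(cfg, n_particles = 1,
                             motion = motion_constant_velocity(v / sqrt(2), v / sqrt(2)),
                             n_frames = 25, frame_size_um = c(75, 75))
    res <- track_movie(tl$movie)
    expect_equal(nrow(res$tracks), 1)
    expect_lt(abs(res$tracks$speed_um_s - v) / v, 0.05)
  }
})

test_that("random-walk ensembles scale as sqrt(n) in displacement but n in path length", {
  set.seed(7)
  mean_metrics <- function(n_frames) {
    ms <- purrr::map_dfr(1:100, function(i) {
      pts <- tibble::tibble(
        track_id = 1L, frame = seq_len(n_frames),
        x_um = cumsum(c(0, rnorm(n_frames - 1, 0, 0.3))),
        y_um = cumsum(c(0, rnorm(n_frames - 1, 0, 0.3)))
      )
      track_metrics(pts, 4, min_points = 2)
    })
    c(disp = mean(ms$displacement_um), len = mean(ms$track_length_um))
  }
  m10 <- mean_metrics(10)
  m40 <- mean_metrics(40)
  # 9 vs 39 steps: path length grows by 39/9, displacement by sqrt(39/9)
  expect_equal(unname(m40["len"] / m10["len"]), 39 / 9, tolerance = 0.15)
  expect_equal(unname(m40["disp"] / m10["disp"]), sqrt(39 / 9), tolerance = 0.3)
})
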