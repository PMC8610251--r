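test_that("identical configurations reproduce scenes bit for bit", {
  cfg <- scene_config(random_seed = 11, n_planes = 10)
  a <- generate_lysosome_stack(cfg, spheres_per_cell = 5, cell_size_um = 8)
  b <- generate_lysosome_stack(cfg, spheres_per_cell = 5, cell_size_um = 8)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth, b$truth)

  tl1 <- generate_timelapse(cfg, n_particles = 3, n_frames = 5,
                            frame_size_um = c(15, 15))
  tl2 <- generate_timelapse(cfg, n_particles = 3, n_frames = 5,
                            frame_size_um = c(15, 15))
  expect_identical(unclass(tl1$movie), unclass(tl2$movie))
})

test_that("sphere scenes record exact ground truth with the default 0.7 um radius", {
  cfg <- scene_config(random_seed = 1, n_planes = 20)
  sc <- generate_lysosome_stack(cfg, spheres_per_cell = 20, cell_size_um = 15)
  expect_equal(nrow(sc$truth), 20)
  expect_true(all(sc$truth$radius_um == 0.7))
  # ideal sphere volume 4/3 pi r^3
  expect_equal(4 / 3 * pi * 0.7^3, 1.4368, tolerance = 1e-3)
  # all spheres inside image bounds, ids unique
  expect_equal(anyDuplicated(sc$truth$object_id), 0)
  expect_true(all(sc$truth$x_um > 0 & sc$truth$x_um < 15))
  expect_true(all(sc$truth$z_um > 0 & sc$truth$z_um < 20 * cfg$z_spacing))
})

test_that("an empty scene is background and noise only", {
  cfg <- scene_config(random_seed = 2, n_planes = 8)
  sc <- generate_lysosome_stack(cfg, spheres_per_cell = 0, cell_size_um = 6)
  expect_equal(nrow(sc$truth), 0)
  expect_lt(max(unclass(sc$image)),
            cfg$background_level + 6 * cfg$gaussian_sd)
})

test_that("without blur or noise the lit voxels equal the rasterized geometry", {
  cfg <- scene_config(random_seed = 3, psf_sigma = 0, gaussian_sd = 0,
                      n_planes = 16)
  sc <- generate_lysosome_stack(cfg, spheres_per_cell = 6, cell_size_um = 10)
  vs <- c(cfg$pixel_size_xy, cfg$pixel_size_xy, cfg$z_spacing)
  above <- unclass(sc$image) > cfg$background_level
  expect_identical(above, rasterize_truth_spheres(sc$truth, dim(above), vs))
})

test_that("sphere placement failure names the offending cell", {
  cfg <- scene_config(random_seed = 4, n_planes = 5)
  expect_error(
    generate_lysosome_stack(cfg, spheres_per_cell = 500, cell_size_um = 4,
                            max_retries = 20),
    "cell_01"
  )
})

test_that("time-lapse presets reproduce the two acquisition regimes", {
  raw <- timelapse_preset("RAW")
  expect_equal(raw$frame_interval, 4)
  expect_equal(raw$duration / raw$frame_interval + 1, 46)
  rpe <- timelapse_preset("RPE")
  expect_equal(rpe$frame_interval, 8)
  expect_equal(rpe$n_frames, 46L)
})

test_that("motion models produce the advertised ground-truth kinematics", {
  cfg <- scene_config(random_seed = 5, frame_interval = 4)
  st <- generate_timelapse(cfg, n_particles = 2, motion = motion_stationary(),
                           n_frames = 6, frame_size_um = c(15, 15))
  pos_sd <- st$truth |>
    dplyr::group_by(object_id) |>
    dplyr::summarise(sx = sd(x_um), sy = sd(y_um))
  expect_true(all(pos_sd$sx == 0 & pos_sd$sy == 0))

  # 1.25 um/s along +x for 10 frames at 4 s: 9 intervals of 5 um
  cv <- generate_timelapse(cfg, n_particles = 1,
                           motion = motion_constant_velocity(1.25),
                           n_frames = 10, frame_size_um = c(60, 10))
  tr <- cv$truth
  disp <- sqrt(diff(range(tr$x_um))^2)
  expect_equal(disp, 45, tolerance = 1e-9)
  path <- sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2))
  expect_equal(path, 45, tolerance = 1e-9)
})

test_that("random walks reflect at the frame boundary", {
  cfg <- scene_config(random_seed = 6)
  tl <- generate_timelapse(cfg, n_particles = 4,
                           motion = motion_random_walk(2.5),
                           n_frames = 40, frame_size_um = c(12, 12))
  expect_true(all(tl$truth$x_um >= 0 & tl$truth$x_um <= 12))
  expect_true(all(tl$truth$y_um >= 0 & tl$truth$y_um <= 12))
})

test_that("filament graphs carry exact topology by construction", {
  g1 <- fg_line(c(2, 10), c(22, 10))
  expect_equal(g1$topology$n_junctions, 0)
  expect_equal(g1$topology$n_branches, 1)
  expect_equal(g1$topology$branch_lengths_um, 20)

  g4 <- fg_star(c(10, 10), n_arms = 4, arm_length_um = 5)
  expect_equal(g4$topology$n_junctions, 1)
  expect_equal(g4$topology$n_branches, 4)

  # an X overlaid on a + sharing the centre
  g8 <- fg_star(c(10, 10), n_arms = 8, arm_length_um = 5)
  expect_equal(g8$topology$n_junctions, 1)
  expect_equal(g8$topology$n_branches, 8)

  expect_error(filament_graph(list(rbind(c(1, 1), c(1, 1)))), "zero-length")
})

test_that("phagosome scenes separate internal and external bacteria", {
  cfg <- scene_config(random_seed = 7, psf_sigma = 0, gaussian_sd = 0,
                      background_level = 0)
  ps <- generate_phagosome_scene(cfg, n_internal = 3, n_external = 2,
                                 lamp_ring_intensity = 500)
  expect_equal(sum(ps$truth$kind == "bacterium_internal"), 3)
  expect_equal(sum(ps$truth$kind == "bacterium_external"), 2)
  # channel 2 holds exactly the two external bacteria
  lab2 <- label_components(ps$channels[, , 2] > 0, 8L)
  expect_equal(max(lab2), 2)
  # noiseless identity: LAMP-1 over its own support is the stated intensity
  lamp <- ps$channels[, , 3]
  expect_equal(mean(lamp[lamp > 0]), 500)

  none <- generate_phagosome_scene(cfg, n_internal = 0, n_external = 2)
  expect_true(all(none$channels[, , 3] == 0))
})

test_that("TIFF and ROI round trips preserve data", {
  cfg <- scene_config(random_seed = 8, n_planes = 8)
  sc <- generate_lysosome_stack(cfg, spheres_per_cell = 2, cell_size_um = 5)
  tmp <- tempfile(fileext = ".tif")
  write_image_tiff(sc$image, tmp)
  back <- read_image_tiff(tmp)
  expect_equal(dim(back), dim(sc$image))
  expect_equal(back, unclass(sc$image), tolerance = 1e-4, ignore_attr = TRUE)

  roi_tmp <- tempfile(fileext = ".csv")
  write_roi_table(sc$regions, roi_tmp)
  regs <- read_roi_table(roi_tmp, dim(sc$image))
  expect_equal(names(regs), names(sc$regions))
  expect_equal(
    lysoquant:::region_footprint(regs[[1]]$mask),
    lysoquant:::region_footprint(sc$regions[[1]]$mask)
  )
})
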