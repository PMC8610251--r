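test_that("the F_H/F_L ratio follows its definition", {
  # ten values of 100 and ten of 10 -> 10.0 exactly
  expect_equal(line_profile_ratio(c(rep(100, 10), rep(10, 10))), 10)
  # uniform profile -> 1.0 exactly
  expect_identical(line_profile_ratio(rep(7, 24)), 1)
  # length bounds
  expect_error(line_profile_ratio(rep(1, 19)), "at least 20")
  expect_error(line_profile_ratio(rep(1, 41)), "at most 40")
  # non-positive F_L rejected, not clamped
  expect_error(line_profile_ratio(c(rep(10, 10), rep(0, 10))), "F_L")
})

test_that("F_H/F_L is scale invariant and always at least 1", {
  set.seed(99)
  for (i in 1:100) {
    p <- runif(sample(20:40, 1), 5, 500)
    r <- line_profile_ratio(p)
    expect_gte(r, 1)
    expect_equal(line_profile_ratio(p * runif(1, 0.1, 50)), r)
  }
  # removing a shared offset strictly increases a contrasted ratio
  p <- c(rep(100, 10), rep(50, 10))
  expect_gt(line_profile_ratio(p - 40), line_profile_ratio(p))
})

test_that("line profiles average across the 3-pixel width before sorting", {
  img <- matrix(10, 30, 40)
  img[14, ] <- 40 # bright centre row; rows 13 and 15 stay dim
  prof <- sample_line_profile(img, start = c(14, 5), end = c(14, 34),
                              width = 3, n_samples = 30)
  # each sample = mean(10, 40, 10) = 20
  expect_true(all(prof == 20))
  # grid-placed lines stay inside the cell and avoid the nucleus
  cell <- cell_region("c1", matrix(TRUE, 30, 40))
  nuc <- matrix(FALSE, 30, 40); nuc[, 1:20] <- TRUE
  lines <- place_profile_lines(cell, length_px = 15, k = 3,
                               nucleus_mask = nuc, seed = 1)
  expect_gt(nrow(lines), 0)
  expect_true(all(lines$start_col > 20 & lines$end_col > 20))
})

test_that("organelle-to-cytosol ratios use background-corrected means", {
  img <- matrix(50, 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[10:15, 10:15] <- TRUE
  img[mask] <- 200
  bg <- matrix(FALSE, 40, 40); bg[35:40, 35:40] <- TRUE
  img[bg] <- 0
  cellm <- matrix(TRUE, 40, 40) & !bg # cell excludes the extracellular box
  cell <- cell_region("c1", cellm)
  r <- organelle_to_cytosol_ratio(img, mask, cell, bg)
  expect_equal(r$value, 4)
  expect_equal(r$background_used, 0)

  # marker uniform across the cell: ratio exactly 1
  uni <- matrix(80, 40, 40)
  uni[bg] <- 0
  r2 <- organelle_to_cytosol_ratio(uni, mask, cell, bg)
  expect_equal(r2$value, 1)

  # empty reference mask: flagged NA, not zero
  r3 <- organelle_to_cytosol_ratio(img, matrix(FALSE, 40, 40), cell, bg)
  expect_true(is.na(r3$value))
})

test_that("mean cell intensity is background corrected and vehicle-normalizable", {
  img <- matrix(20, 30, 30)
  cellm <- matrix(FALSE, 30, 30); cellm[5:20, 5:20] <- TRUE
  img[cellm] <- 120
  bg <- matrix(FALSE, 30, 30); bg[25:30, 25:30] <- TRUE
  cell <- cell_region("c1", cellm)
  expect_equal(mean_cell_intensity(img, cell, bg), 100)
  expect_equal(mean_cell_intensity(matrix(20, 30, 30), cell, bg), 0)

  # normalization: vehicle mean 50, treated 350 -> 7-fold
  tab <- tibble::tibble(
    experiment_id = "e1",
    condition = c(rep("vehicle", 3), "treated"),
    value = c(40, 50, 60, 350)
  )
  norm <- normalize_to_vehicle(tab, "vehicle")
  expect_equal(norm$value[4], 7)
  expect_equal(mean(norm$value[1:3]), 1)
})

test_that("puncta are gated by area and counted per cell", {
  px <- 1 # 1 um/px so px^2 = um^2
  img <- matrix(0, 60, 120)
  img[2:6, 2:7] <- 100          # 30 px
  img[20:25, 20:29] <- 100      # 60 px
  img[40:59, 40:99] <- 100      # 1200 px
  cell <- cell_region("c1", matrix(TRUE, 60, 120))
  res <- count_puncta(img, cell, threshold = 50, gate = c(50, 1000),
                      pixel_size = px)
  expect_equal(res$count, 1)
  expect_equal(res$puncta$area_um2, 60)

  blank <- count_puncta(matrix(0, 20, 20), cell_region("c2", matrix(TRUE, 20, 20)),
                        threshold = 50, pixel_size = px)
  expect_equal(blank$count, 0)

  # monotone in the gate bounds
  wider <- count_puncta(img, cell, threshold = 50, gate = c(20, 2000), pixel_size = px)
  expect_gte(wider$count, res$count)
  narrower <- count_puncta(img, cell, threshold = 50, gate = c(50, 59), pixel_size = px)
  expect_lte(narrower$count, res$count)
})

test_that("gated puncta counts recover generated ground truth", {
  # galectin-style scene: disks above and below the area gate, on a um^2
  # scale where the printed 50-1000 gate is plausible
  dims <- c(240, 240) # 120 x 120 um at 0.5 um/px
  centers <- as.matrix(expand.grid(x = c(15, 45, 75), y = c(15, 45, 75)))
  radii <- c(5, 5, 5, 5, 6, 6, 6, 2, 18) # areas ~79, ~113, ~13, ~1018 um^2
  img <- lysoquant:::rasterize_disks(dims, 0.5, centers, radii,
                                     rep(100, nrow(centers)))
  img <- img + 10
  in_gate <- (pi * radii^2) >= 50 & (pi * radii^2) <= 1000
  stopifnot(sum(in_gate) == 7) # the intended galectin-style scene
  cell <- cell_region("c1", matrix(TRUE, dims[1], dims[2]))
  res <- count_puncta(img, cell, threshold = 50, gate = c(50, 1000),
                      pixel_size = 0.5)
  expect_equal(res$count, sum(in_gate))
})

test_that("puncta-lysosome association uses the distance to the nearest lysosome", {
  lyso <- matrix(FALSE, 100, 100)
  lyso[40:60, 40:60] <- TRUE
  px <- 0.1
  puncta <- tibble::tibble(
    punctum = 1:3,
    x_um = c(5.0, 6.15, 1.0), # inside; 0.2 um from the edge; 3 um away
    y_um = c(5.0, 5.0, 5.0),
    area_um2 = 1, mean_intensity = 100
  )
  res <- lysosome_associated_puncta(puncta, lyso, px, association_distance = 0.25)
  expect_equal(res$puncta$associated, c(TRUE, TRUE, FALSE))
  expect_equal(res$n_associated, 2)
  expect_equal(res$puncta$distance_um[1], 0)

  # a punctum 5 um away is never associated at 0.5 um
  far <- tibble::tibble(punctum = 1L, x_um = 0.5, y_um = 0.5,
                        area_um2 = 1, mean_intensity = 1)
  res2 <- lysosome_associated_puncta(far, lyso, px, association_distance = 0.5)
  expect_equal(res2$n_associated, 0)

  # generated scene: 4 of 10 puncta planted on lysosome rims
  set.seed(21)
  lyso2 <- matrix(FALSE, 200, 200)
  lcent <- cbind(x = runif(5, 3, 17), y = runif(5, 3, 17))
  for (i in 1:5) {
    d2 <- outer(((1:200 - 0.5) * 0.1 - lcent[i, "y"])^2,
                ((1:200 - 0.5) * 0.1 - lcent[i, "x"])^2, `+`)
    lyso2 <- lyso2 | (d2 <= 0.7^2)
  }
  on_rim <- cbind(x = lcent[1:4, "x"] + 0.75, y = lcent[1:4, "y"]) # 0.05 um out
  off <- cbind(x = runif(6, 0.5, 2), y = runif(6, 0.5, 2))
  pts <- tibble::tibble(
    punctum = 1:10,
    x_um = c(on_rim[, "x"], off[, "x"]),
    y_um = c(on_rim[, "y"], off[, "y"]),
    area_um2 = 1, mean_intensity = 1
  )
  res3 <- lysosome_associated_puncta(pts, lyso2, 0.1, association_distance = 0.25)
  expect_equal(res3$n_associated, 4)
})
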