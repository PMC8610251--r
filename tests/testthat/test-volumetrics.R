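make_cell <- function(dims, cytosol_vals = NULL) {
  m <- matrix(TRUE, dims[1], dims[2])
  cs <- array(TRUE, dims)
  cell_region("cell_01", m, cs)
}

test_that("cytosolic threshold is factor times the cytosol mean", {
  img <- volumetric_image(array(50, c(10, 10, 3)), c(0.1, 0.1, 0.3))
  cell <- make_cell(c(10, 10, 3))
  expect_equal(cytosolic_threshold(img, cell, 2), 100)

  # {10, 20, 30} mean 20, factor 2 -> 40
  arr <- array(0, c(3, 1, 1))
  arr[, 1, 1] <- c(10, 20, 30)
  img2 <- volumetric_image(arr, c(1, 1, 1))
  cell2 <- cell_region("c", matrix(TRUE, 3, 1), array(TRUE, c(3, 1, 1)))
  expect_equal(quiet_threshold(img2, cell2, 2), 40)

  # empty cytosol sample is an error
  cell3 <- cell_region("c", matrix(TRUE, 3, 1))
  expect_error(cytosolic_threshold(img2, cell3), "cytosol_sample")

  # a uniform image can never exceed its own doubled mean
  segs <- segment_lysosomes(img, cell, cytosolic_threshold(img, cell))
  expect_equal(nrow(segs), 0)
})

test_that("twenty separated spheres are recovered with volumes near the ideal", {
  cfg <- scene_config(random_seed = 1)
  sc <- generate_lysosome_stack(cfg, spheres_per_cell = 20)
  cell <- sc$regions[[1]]
  th <- cytosolic_threshold(sc$image, cell)
  segs <- segment_lysosomes(sc$image, cell, th)
  expect_equal(nrow(segs), 20)
  ideal <- 4 / 3 * pi * 0.7^3
  expect_true(all(abs(segs$volume_um3 - ideal) / ideal < 0.15))
  # centroids match ground truth to well under a pixel
  tr <- sc$truth[order(sc$truth$x_um), ]
  sg <- segs[order(segs$centroid_x_um), ]
  expect_lt(max(abs(tr$x_um - sg$centroid_x_um)), 0.05)
  expect_lt(max(abs(tr$y_um - sg$centroid_y_um)), 0.05)
})

test_that("spheres below the volume gate are excluded", {
  # r = 0.4 um: ideal volume 0.268 um^3 < 0.3
  expect_lt(4 / 3 * pi * 0.4^3, 0.3)
  cfg <- scene_config(random_seed = 5)
  sc <- generate_lysosome_stack(cfg, spheres_per_cell = 5, radius_um = 0.4,
                                cell_size_um = 10)
  cell <- sc$regions[[1]]
  th <- cytosolic_threshold(sc$image, cell)
  segs <- segment_lysosomes(sc$image, cell, th, min_volume = 0.3)
  expect_equal(nrow(segs), 0)
  # the same spheres are found when the gate is lifted
  expect_equal(nrow(segment_lysosomes(sc$image, cell, th, min_volume = 0)), 5)
})

test_that("an all-zero image yields no segments", {
  img <- volumetric_image(array(0, c(8, 8, 4)), c(0.1, 0.1, 0.3))
  cell <- make_cell(c(8, 8, 4))
  expect_equal(nrow(segment_lysosomes(img, cell, threshold = 1)), 0)
})

test_that("watershed splits a touching pair and conserves voxels", {
  # analytic overlapping spheres, centre distance 1.1 um
  vs <- c(0.1, 0.1, 0.3)
  dims <- c(31, 41, 11)
  g <- expand.grid(
    y = (1:31 - 0.5) * 0.1, x = (1:41 - 0.5) * 0.1, z = (1:11 - 0.5) * 0.3
  )
  c1 <- c(1.5, 1.55, 1.65); c2 <- c(2.6, 1.55, 1.65)
  m1 <- array((g$x - c1[1])^2 + (g$y - c1[2])^2 + (g$z - c1[3])^2 <= 0.49, dims)
  m2 <- array((g$x - c2[1])^2 + (g$y - c2[2])^2 + (g$z - c2[3])^2 <= 0.49, dims)
  mm <- m1 | m2
  wl <- watershed_split(mm, vs)
  expect_equal(max(wl), 2)
  # voxel conservation
  expect_equal(sum(wl > 0), sum(mm))
  expect_true(all((wl > 0) == mm))
  # each half within 20% of the ideal sphere volume
  ideal <- 4 / 3 * pi * 0.7^3
  vols <- tabulate(wl[wl > 0]) * prod(vs)
  expect_true(all(abs(vols - ideal) / ideal < 0.2))
  # truth-geometry nearest-centre oracle: basins match exactly
  near1 <- array(
    (g$x - c1[1])^2 + (g$y - c1[2])^2 < (g$x - c2[1])^2 + (g$y - c2[2])^2, dims
  )
  expect_equal(sum(wl == 1), sum(mm & near1))

  # an isolated component is returned unchanged
  wl1 <- watershed_split(m1 & !m2, vs)
  expect_equal(max(wl1), 1)
  expect_true(all((wl1 > 0) == (m1 & !m2)))
})

test_that("watershed conservation holds on rendered touching pairs", {
  for (s in 1:3) {
    sc <- generate_lysosome_stack(scene_config(random_seed = s),
                                  spheres_per_cell = 0, coalesced_pairs = 1)
    cell <- sc$regions[[1]]
    th <- cytosolic_threshold(sc$image, cell)
    merged <- segment_lysosomes(sc$image, cell, th, split = FALSE)
    split <- segment_lysosomes(sc$image, cell, th, split = TRUE)
    expect_equal(nrow(merged), 1)
    expect_equal(nrow(split), 2)
    expect_equal(sum(split$n_voxels), sum(merged$n_voxels))
  }
})

test_that("per-cell metrics sum and count segments", {
  segs <- tibble::tibble(
    label = 1:3, cell_id = "c1", n_voxels = c(10L, 20L, 30L),
    volume_um3 = c(1, 2, 3),
    centroid_x_um = 0, centroid_y_um = 0, centroid_z_um = 0,
    voxels = list(1:10, 11:30, 31:60)
  )
  rep <- per_cell_metrics(segs)
  expect_equal(rep$lysosome_count, 3)
  expect_equal(rep$total_volume_um3, 6)
  expect_equal(rep$individual_volumes_um3[[1]], c(1, 2, 3))

  empty <- per_cell_metrics(segs[0, ])
  expect_equal(empty$lysosome_count, 0)
  expect_equal(empty$total_volume_um3, 0)

  segs2 <- segs
  segs2$cell_id <- c("c1", "c1", "c2")
  expect_error(per_cell_metrics(segs2), "multiple cells")
})

test_that("the coalescence signature shows in the metrics", {
  # merging pairs of equal spheres halves the count but conserves total
  # volume: fewer, larger lysosomes at constant total volume
  cfg_sep <- scene_config(random_seed = 21)
  sep <- generate_lysosome_stack(cfg_sep, spheres_per_cell = 8)
  cfg_mrg <- scene_config(random_seed = 21)
  mrg <- generate_lysosome_stack(cfg_mrg, spheres_per_cell = 0,
                                 coalesced_pairs = 4)
  get_rep <- function(sc) {
    cell <- sc$regions[[1]]
    th <- cytosolic_threshold(sc$image, cell)
    per_cell_metrics(segment_lysosomes(sc$image, cell, th, split = FALSE))
  }
  rep_sep <- get_rep(sep)
  rep_mrg <- get_rep(mrg)
  expect_equal(rep_sep$lysosome_count, 8)
  expect_equal(rep_mrg$lysosome_count, 4)
  expect_lt(
    abs(rep_mrg$total_volume_um3 - rep_sep$total_volume_um3) /
      rep_sep$total_volume_um3,
    0.1
  )
})

test_that("raising the threshold never grows a segment", {
  cfg <- scene_config(random_seed = 9)
  sc <- generate_lysosome_stack(cfg, spheres_per_cell = 5, cell_size_um = 10)
  cell <- sc$regions[[1]]
  th <- cytosolic_threshold(sc$image, cell)
  lower <- segment_lysosomes(sc$image, cell, th, min_volume = 0)
  higher <- segment_lysosomes(sc$image, cell, th * 1.3, min_volume = 0)
  expect_lte(sum(higher$n_voxels), sum(lower$n_voxels))
  # and every higher-threshold voxel set is inside the lower-threshold one
  expect_true(all(unlist(higher$voxels) %in% unlist(lower$voxels)))
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(42)
  for (i in 1:4) {
    m <- array(runif(16 * 16 * 8) < 0.25, c(16, 16, 8))
    ours <- label_components(m)
    oracle <- flood_fill_label(m)
    # same partition: relabelling-invariant comparison
    expect_equal(max(ours), max(oracle))
    expect_true(all((ours > 0) == (oracle > 0)))
    key <- paste(ours[ours > 0], oracle[oracle > 0])
    expect_equal(length(unique(key)), max(ours))
  }
  # 2D case against the independent EBImage implementation (4-connected)
  m2 <- matrix(runif(64 * 64) < 0.3, 64, 64)
  ours2 <- label_components(m2, 4L)
  eb <- EBImage::bwlabel(EBImage::Image(m2 * 1))
  expect_equal(max(ours2), max(eb))
})
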