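#' Generate a synthetic lysosome z-stack with ground truth
#'
#' Renders spherical lysosomes (default radius 0.7 um, the estimated radius
#' of intact lysosomes) into a 3D confocal-like stack: voxel-centre
#' rasterisation, Gaussian PSF blur, cytosolic background inside each cell
#' footprint, additive noise. Cells are laid out side by side; spheres are
#' placed by rejection sampling subject to a pairwise centre-distance floor
#' of `0.5 * (r1 + r2)` (the overlap budget), with a stricter default
#' separation so that distinct lysosomes stay resolvable after blur.
#' Optionally, touching pairs are planted at a fixed centre distance to
#' emulate coalescing lysosomes for watershed and count/volume signature
#' experiments.
#'
#' @param config a [scene_config()].
#' @param n_cells number of cells (side-by-side square regions).
#' @param spheres_per_cell number of separated spheres per cell (coalesced
#'   pairs are added on top).
#' @param radius_um sphere radius in micrometres: scalar, vector recycled
#'   over spheres, or `function(n)` drawing radii.
#' @param intensity fluorophore intensity of sphere voxels. The default,
#'   twice the background level, places the 2x-cytosol threshold exactly at
#'   the half-maximum of the blurred object boundary -- the condition under
#'   which thresholding recovers an object's geometric size.
#' @param cell_size_um side of each square cell footprint.
#' @param coalesced_pairs number of touching sphere pairs per cell.
#' @param pair_distance_um centre distance within a touching pair (default
#'   1.1 um: touching for 0.7 um spheres).
#' @param separation_factor placement keeps centre distances at or above
#'   `separation_factor * (r1 + r2)` for non-pair spheres; must be >= 0.5.
#' @param max_retries placement attempts per sphere before giving up.
#' @return list with `image` (a [volumetric_image()]), `regions` (list of
#'   [cell_region()] with ground-truth cytosol samples), and `truth`
#'   (tibble: one row per sphere with exact centre and radius).
#' @export
generate_lysosome_stack <- function(config,
                                    n_cells = 1L,
                                    spheres_per_cell = 20L,
                                    radius_um = 0.7,
                                    intensity = NULL,
                                    cell_size_um = 15,
                                    coalesced_pairs = 0L,
                                    pair_distance_um = 1.1,
                                    separation_factor = 1.3,
                                    max_retries = 2000L) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(intensity)) intensity <- 2 * config$background_level
  if (separation_factor < 0.5) abort("separation_factor must be >= 0.5 (overlap budget)")
  px <- config$pixel_size_xy
  vs <- c(px, px, config$z_spacing)
  n_side <- round(cell_size_um / px)
  dims <- c(n_side, n_side * n_cells, config$n_planes)
  Lz <- config$n_planes * config$z_spacing

  draw_radius <- radius_sampler(radius_um)
  set.seed(config$random_seed)

  truth <- list()
  obj_id <- 0L
  for (ci in seq_len(n_cells)) {
    x0 <- (ci - 1) * cell_size_um
    placed <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    pair_of <- integer(0) # index of pair partner, NA when separated
    want <- spheres_per_cell + 2L * coalesced_pairs
    kind_pair <- c(
      rep(FALSE, spheres_per_cell),
      rep(TRUE, 2L * coalesced_pairs)
    )
    k <- 0L
    while (k < want) {
      k <- k + 1L
      r <- draw_radius(1)
      margin <- r + 3 * config$psf_sigma + px
      ok <- FALSE
      second_of_pair <- kind_pair[k] && (k - spheres_per_cell) %% 2L == 0L
      for (try in seq_len(max_retries)) {
        if (second_of_pair) {
          # partner of the previous sphere, at the fixed touching distance
          base <- placed[k - 1L, ]
          ang <- runif(1, 0, 2 * pi)
          # pairs stay in-plane so the centre distance is exactly as requested
          cand <- base + pair_distance_um * c(cos(ang), sin(ang), 0)
        } else {
          cand <- c(
            x0 + runif_within(margin, cell_size_um - margin),
            runif_within(margin, cell_size_um - margin),
            runif_within(r + vs[3], Lz - r - vs[3])
          )
        }
        in_bounds <- all(is.finite(cand)) &&
          cand[1] >= x0 + margin && cand[1] <= x0 + cell_size_um - margin &&
          cand[2] >= margin && cand[2] <= cell_size_um - margin &&
          cand[3] >= r + vs[3] && cand[3] <= Lz - r - vs[3]
        if (!in_bounds) next
        if (nrow(placed) > 0) {
          others <- seq_len(nrow(placed))
          if (second_of_pair) others <- others[others != k - 1L]
          if (length(others) > 0) {
            dd <- sqrt(colSums((t(placed[others, , drop = FALSE]) - cand)^2))
            need <- separation_factor * (radii[others] + r)
            # planted pairs must stay clear of everything else too
            if (any(dd < need)) next
          }
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        abort(sprintf(
          "could not place sphere %d in cell_%02d within %d retries",
          k, ci, max_retries
        ))
      }
      placed <- rbind(placed, cand)
      radii <- c(radii, r)
      obj_id <- obj_id + 1L
      truth[[length(truth) + 1L]] <- tibble(
        object_id = obj_id,
        cell_id = sprintf("cell_%02d", ci),
        kind = "sphere",
        x_um = cand[1], y_um = cand[2], z_um = cand[3],
        radius_um = r, intensity = intensity,
        coalesced_pair = kind_pair[k],
        channel = "lysosome"
      )
    }
  }
  truth <- if (length(truth)) bind_rows(truth) else tibble(
    object_id = integer(), cell_id = character(), kind = character(),
    x_um = numeric(), y_um = numeric(), z_um = numeric(),
    radius_um = numeric(), intensity = numeric(),
    coalesced_pair = logical(), channel = character()
  )

  arr <- rasterize_spheres(
    dims, vs,
    as.matrix(truth[, c("x_um", "y_um", "z_um")]),
    truth$radius_um, rep(intensity, nrow(truth))
  )
  sigma_px <- config$psf_sigma / vs
  arr <- gaussian_blur(arr, sigma_px)

  regions <- grid_cell_regions(dims, n_cells)
  bg <- array(0, dims)
  for (r in regions) bg <- bg + expand_mask(r$mask, dims) * config$background_level
  arr <- arr + bg
  arr <- add_noise(arr, config)

  regions <- purrr::map(regions, function(reg) {
    attach_truth_cytosol(reg, truth, dims, vs, config)
  })

  list(
    image = volumetric_image(arr, vs, "lysosome"),
    regions = regions,
    truth = truth
  )
}

# uniform draw on [lo, hi]; NA when the interval is empty (object cannot fit)
runif_within <- function(lo, hi) {
  if (lo > hi) NA_real_ else runif(1, lo, hi)
}

radius_sampler <- function(radius_um) {
  if (is.function(radius_um)) {
    radius_um
  } else {
    rv <- as.numeric(radius_um)
    i <- 0L
    function(n) {
      out <- rv[(i + seq_len(n) - 1L) %% length(rv) + 1L]
      i <<- i + n
      out
    }
  }
}

# ground-truth cytosol sample: inside the cell footprint (2 px in from the
# edge), clear of every sphere by its radius plus the blur apron
attach_truth_cytosol <- function(reg, truth, dims, vs, config) {
  foot <- region_footprint(reg$mask)
  d2 <- edt_sq(as.logical(foot), dim(foot), c(1, 1))
  core <- array(matrix(d2 > 4, dims[1], dims[2]), dims)
  rows <- truth[truth$cell_id == reg$cell_id, ]
  if (nrow(rows) > 0) {
    clear <- rows$radius_um + 3 * config$psf_sigma + 2 * vs[1]
    for (k in seq_len(nrow(rows))) {
      ys <- pmax(1, floor((rows$y_um[k] - clear[k]) / vs[2])):
        pmin(dims[1], ceiling((rows$y_um[k] + clear[k]) / vs[2] + 1))
      xs <- pmax(1, floor((rows$x_um[k] - clear[k]) / vs[1])):
        pmin(dims[2], ceiling((rows$x_um[k] + clear[k]) / vs[1] + 1))
      zs <- pmax(1, floor((rows$z_um[k] - clear[k]) / vs[3])):
        pmin(dims[3], ceiling((rows$z_um[k] + clear[k]) / vs[3] + 1))
      core[ys, xs, zs] <- FALSE
    }
  }
  cell_region(reg$cell_id, reg$mask, core)
}
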