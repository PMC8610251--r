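#' Cytosolic threshold for organelle segmentation
#'
#' The segmentation threshold is anchored to the cell's own cytosolic
#' fluorescence: `factor` times the mean intensity over the cytosol sample
#' (default factor 2, the 2x-cytosol rule). Voxels must *exceed* the
#' threshold strictly, so a uniform image can never segment.
#'
#' @param image a [volumetric_image()] (or 2D matrix).
#' @param cell a [cell_region()] with a non-empty `cytosol_sample` (see
#'   [estimate_cytosol_sample()] when no ground-truth sample exists).
#' @param factor positive multiplier of the cytosolic mean.
#' @return scalar intensity threshold.
#' @export
cytosolic_threshold <- function(image, cell, factor = 2) {
  if (factor <= 0) abort("factor must be positive")
  if (is.null(cell$cytosol_sample) || !any(cell$cytosol_sample)) {
    abort(sprintf("cell '%s': cytosol_sample is empty", cell$cell_id))
  }
  dims <- dim(as.array(unclass(image)))
  samp <- expand_mask(cell$cytosol_sample, dims)
  n <- sum(samp)
  if (n < 100) {
    warning(sprintf("cell '%s': cytosol sample has only %d voxels", cell$cell_id, n))
  }
  factor * masked_mean(unclass(image), samp)
}

#' Split a connected region along distance-transform basins
#'
#' Marker-based watershed used to separate touching organelles that
#' thresholding fused into one component. Seeds are the local maxima of the
#' anisotropy-corrected Euclidean distance transform, thinned to a minimum
#' physical separation (default `min_volume^(1/3)`); flooding proceeds from
#' deep to shallow and equidistant voxels go to the lower seed label, so the
#' result is deterministic and conserves the input voxel set exactly.
#'
#' @param mask logical array holding one connected component.
#' @param voxel_size physical sizes `(x, y, z)` um (or `(x, y)` for 2D).
#' @param min_seed_sep minimum seed separation in um.
#' @return integer array of region labels (1..k) covering exactly `mask`.
#' @export
watershed_split <- function(mask, voxel_size, min_seed_sep = 0.3^(1 / 3)) {
  mask <- as.array(mask)
  d <- dim(mask)
  nd <- length(d)
  # array axes are (y, x[, z]); voxel_size arrives as (x, y[, z])
  vs_axes <- if (nd == 3) c(voxel_size[2], voxel_size[1], voxel_size[3]) else
    c(voxel_size[2], voxel_size[1])
  dist <- distance_transform(mask, vs_axes)
  seeds <- dt_maxima_seeds(dist, mask, vs_axes, min_seed_sep)
  ws_flood(
    as.numeric(dist), as.integer(seeds), as.logical(mask),
    as.integer(d), if (nd == 3) 26L else 8L
  )
}

#' Segment lysosomes in a 3D stack
#'
#' Thresholded connected-component segmentation of one cell's lysosomes:
#' voxels strictly above the threshold inside the cell mask are grouped with
#' 26-connectivity, optionally watershed-split to separate aggregates, and
#' particles are retained only when their volume exceeds `min_volume`
#' (default 0.3 um^3, the particle inclusion gate).
#'
#' @param image a [volumetric_image()].
#' @param cell a [cell_region()].
#' @param threshold intensity cut-off, usually from [cytosolic_threshold()].
#' @param min_volume retain particles with volume strictly greater than
#'   this, in um^3.
#' @param split apply [watershed_split()] to each component before the
#'   volume gate.
#' @return tibble with one row per segment: `label`, `cell_id`, `n_voxels`,
#'   `volume_um3`, centroid coordinates in um, and a `voxels` list-column of
#'   linear voxel indices. Zero rows is a valid result.
#' @export
segment_lysosomes <- function(image, cell, threshold,
                              min_volume = 0.3, split = TRUE) {
  vs <- voxel_size(image)
  arr <- unclass(image)
  dims <- dim(arr)
  mask <- (arr > threshold) & expand_mask(cell$mask, dims)
  if (!any(mask)) return(empty_segments(cell$cell_id))
  lab <- label_components(mask, 26L)
  if (split) lab <- split_labels(lab, mask, vs, min_volume)
  segments_from_labels(lab, vs, cell$cell_id, min_volume)
}

empty_segments <- function(cell_id) {
  tibble(
    label = integer(), cell_id = character(), n_voxels = integer(),
    volume_um3 = numeric(), centroid_x_um = numeric(),
    centroid_y_um = numeric(), centroid_z_um = numeric(),
    voxels = list()
  )
}

# run watershed_split per component (on a cropped window) and relabel
split_labels <- function(lab, mask, vs, min_volume) {
  d <- dim(lab)
  out <- array(0L, d)
  next_label <- 0L
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    co <- arrayInd(idx, d)
    lo <- pmax(apply(co, 2, min) - 1L, 1L)
    hi <- pmin(apply(co, 2, max) + 1L, d)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == l
    dim(sub) <- hi - lo + 1L
    wl <- watershed_split(sub, vs, min_seed_sep = min_volume^(1 / 3))
    win <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    win[sub] <- wl[sub] + next_label
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- win
    next_label <- next_label + max(wl)
  }
  out
}

segments_from_labels <- function(lab, vs, cell_id, min_volume) {
  vox_vol <- prod(vs)
  d <- dim(lab)
  idx <- which(lab > 0)
  if (length(idx) == 0) return(empty_segments(cell_id))
  labs <- lab[idx]
  split_idx <- split(idx, labs)
  rows <- purrr::imap(split_idx, function(vox, l) {
    vol <- length(vox) * vox_vol
    co <- arrayInd(vox, d) # (y, x, z)
    tibble(
      label = as.integer(l),
      cell_id = cell_id,
      n_voxels = length(vox),
      volume_um3 = vol,
      centroid_x_um = mean((co[, 2] - 0.5) * vs[1]),
      centroid_y_um = mean((co[, 1] - 0.5) * vs[2]),
      centroid_z_um = mean((co[, 3] - 0.5) * vs[3]),
      voxels = list(vox)
    )
  })
  segs <- bind_rows(rows) %>%
    filter(.data$volume_um3 > min_volume) %>%
    arrange(.data$label)
  segs$label <- seq_len(nrow(segs)) # dense labels after the volume gate
  segs
}

#' Per-cell lysosome volumetrics
#'
#' The three headline morphology metrics for one cell: number of lysosomes,
#' their individual volumes, and the total lysosomal volume.
#'
#' @param segments tibble from [segment_lysosomes()]; all rows must share
#'   one `cell_id`.
#' @return one-row tibble: `cell_id`, `lysosome_count`,
#'   `individual_volumes_um3` (list-column), `total_volume_um3`.
#' @export
per_cell_metrics <- function(segments) {
  ids <- unique(segments$cell_id)
  if (length(ids) > 1) {
    abort(sprintf("segments span multiple cells: %s", paste(ids, collapse = ", ")))
  }
  tibble(
    cell_id = if (length(ids)) ids else NA_character_,
    lysosome_count = nrow(segments),
    individual_volumes_um3 = list(segments$volume_um3),
    total_volume_um3 = sum(segments$volume_um3)
  )
}

#' @rdname per_cell_metrics
#' @details `volumetrics_report()` applies the same summary across many
#'   cells at once.
#' @export
volumetrics_report <- function(segments) {
  segments %>%
    group_by(.data$cell_id) %>%
    summarise(
      lysosome_count = dplyr::n(),
      individual_volumes_um3 = list(.data$volume_um3),
      total_volume_um3 = sum(.data$volume_um3),
      .groups = "drop"
    )
}
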