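#' Per-cell regions of interest
#'
#' A `cell_region` holds the hand-drawn (or generated) outline of one cell:
#' a binary mask (2D footprint, applied to every z-plane, or full 3D), plus
#' an optional cytosol sample — a sub-region inside the cell that excludes
#' segmented organelles and the nucleus, used to estimate the cytosolic
#' fluorescence level that anchors the 2x threshold rule.
#'
#' @param cell_id character identifier.
#' @param mask logical matrix or 3D array; must contain at least one TRUE.
#' @param cytosol_sample optional logical mask of the same (2D or 3D) shape;
#'   must be a subset of `mask` (evaluated on the shared footprint).
#' @return A `cell_region` object.
#' @export
cell_region <- function(cell_id, mask, cytosol_sample = NULL) {
  mask <- as.array(mask)
  if (!any(mask)) abort(sprintf("cell '%s': mask is empty", cell_id))
  if (!is.null(cytosol_sample)) {
    cytosol_sample <- as.array(cytosol_sample)
    foot_m <- region_footprint(mask)
    foot_c <- region_footprint(cytosol_sample)
    if (any(foot_c & !foot_m)) {
      abort(sprintf("cell '%s': cytosol_sample is not contained in mask", cell_id))
    }
  }
  structure(
    list(cell_id = as.character(cell_id), mask = mask, cytosol_sample = cytosol_sample),
    class = "cell_region"
  )
}

region_footprint <- function(mask) {
  if (length(dim(mask)) == 3L) apply(mask, c(1, 2), any) else mask
}

# expand a 2D footprint mask to the z-extent of an image; pass 3D through
expand_mask <- function(mask, dims) {
  if (length(dim(mask)) == 3L) {
    stopifnot(all(dim(mask) == dims))
    return(mask)
  }
  stopifnot(all(dim(mask) == dims[1:2]))
  array(mask, dims)
}

#' @export
print.cell_region <- function(x, ...) {
  cat(sprintf(
    "<cell_region> '%s': %s mask, %d px in footprint%s\n",
    x$cell_id, paste(dim(x$mask), collapse = "x"), sum(region_footprint(x$mask)),
    if (is.null(x$cytosol_sample)) "" else sprintf(", cytosol sample %d px", sum(x$cytosol_sample))
  ))
  invisible(x)
}

#' Rectangular cell regions on a grid
#'
#' Convenience constructor used by the scene generators: splits an image
#' into `n_cells` side-by-side rectangular cells.
#'
#' @param dims image dimensions `c(ny, nx)` or `c(ny, nx, nz)`.
#' @param n_cells number of equal-width cells along x.
#' @return list of `cell_region` objects named by cell id.
#' @export
grid_cell_regions <- function(dims, n_cells = 1L) {
  ny <- dims[1]; nx <- dims[2]
  bounds <- floor(seq(0, nx, length.out = n_cells + 1))
  purrr::map(seq_len(n_cells), function(i) {
    m <- matrix(FALSE, ny, nx)
    m[, (bounds[i] + 1):bounds[i + 1]] <- TRUE
    cell_region(sprintf("cell_%02d", i), m)
  }) %>% setNames(sprintf("cell_%02d", seq_len(n_cells)))
}

#' Read and write rectangular ROI tables
#'
#' ROIs interchange as a CSV (or JSON) table with columns `cell_id, y_min,
#' y_max, x_min, x_max` in 1-based pixel indices.
#'
#' @param path file to read or write.
#' @param regions a list of `cell_region`s (rectangular masks assumed for
#'   writing: the bounding box is stored).
#' @param dims image dimensions used to materialise masks on read.
#' @return `read_roi_table()` returns a list of `cell_region`s.
#' @export
read_roi_table <- function(path, dims) {
  df <- if (grepl("[.]json$", path)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  regions <- purrr::pmap(df, function(cell_id, y_min, y_max, x_min, x_max) {
    m <- matrix(FALSE, dims[1], dims[2])
    m[y_min:y_max, x_min:x_max] <- TRUE
    cell_region(cell_id, m)
  })
  setNames(regions, df$cell_id)
}

#' @rdname read_roi_table
#' @export
write_roi_table <- function(regions, path) {
  df <- purrr::map_dfr(regions, function(r) {
    foot <- region_footprint(r$mask)
    idx <- which(foot, arr.ind = TRUE)
    tibble(
      cell_id = r$cell_id,
      y_min = min(idx[, 1]), y_max = max(idx[, 1]),
      x_min = min(idx[, 2]), x_max = max(idx[, 2])
    )
  })
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Estimate a cytosol sample from image intensities
#'
#' When the generator's ground-truth cytosol region is unavailable (real
#' data), the cytosol sample is approximated as the in-cell voxels at or
#' below an intensity quantile, which excludes bright organelle voxels.
#'
#' @param image a `volumetric_image` or matrix.
#' @param cell a `cell_region`.
#' @param quantile upper intensity quantile retained (default 0.5,
#'   i.e. the dimmer half of the cell).
#' @return the `cell_region` with `cytosol_sample` filled in.
#' @export
estimate_cytosol_sample <- function(image, cell, quantile = 0.5) {
  dims <- dim(image)
  m <- expand_mask(cell$mask, dims)
  vals <- as.numeric(image)[m]
  cut <- stats::quantile(vals, quantile, names = FALSE)
  samp <- m & (unclass(image) <= cut)
  cell_region(cell$cell_id, cell$mask, samp)
}
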