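#' Membrane-recruitment ratio from a line profile
#'
#' The F_H/F_L statistic: along a 3-pixel-wide, 20-40-pixel-long line the
#' width-averaged intensities are sorted and the mean of the 10 highest
#' values is divided by the mean of the 10 lowest. Values near 1 indicate a
#' cytosolic (uniform) distribution; values above 1 indicate punctate or
#' membrane-localised signal. The ratio is invariant to multiplying the
#' image by a positive constant.
#'
#' @param profile numeric vector of width-averaged intensities (length
#'   20-40), e.g. from [sample_line_profile()].
#' @return scalar F_H/F_L ratio (always >= 1).
#' @export
line_profile_ratio <- function(profile) {
  n <- length(profile)
  if (n < 20) abort("profile must have at least 20 samples")
  if (n > 40) abort("profile must have at most 40 samples")
  srt <- sort(profile, decreasing = TRUE)
  f_h <- mean(srt[1:10])
  f_l <- mean(srt[(n - 9):n])
  if (f_l <= 0) abort("F_L is not positive; background subtraction went below zero")
  f_h / f_l
}

#' Sample a width-averaged line profile from an image
#'
#' Walks `n_samples` equally spaced points from `start` to `end` (pixel
#' coordinates), averaging across `width` parallel offsets perpendicular to
#' the line (nearest-pixel sampling), which mirrors a plotted profile of a
#' 3-pixel-wide line.
#'
#' @param image numeric matrix.
#' @param start,end `c(row, col)` pixel coordinates of the line ends.
#' @param width odd number of parallel lines averaged (default 3).
#' @param n_samples number of points along the line (20-40).
#' @return numeric vector of length `n_samples`.
#' @export
sample_line_profile <- function(image, start, end, width = 3L, n_samples = 20L) {
  if (n_samples < 20 || n_samples > 40) abort("n_samples must be in 20..40")
  if (width %% 2 == 0) abort("width must be odd")
  dvec <- end - start
  len <- sqrt(sum(dvec^2))
  if (len == 0) abort("degenerate line")
  u <- dvec / len
  perp <- c(-u[2], u[1])
  t_seq <- seq(0, 1, length.out = n_samples)
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  vapply(t_seq, function(t) {
    p <- start + t * dvec
    mean(vapply(offs, function(o) {
      q <- round(p + o * perp)
      q <- pmin(pmax(q, 1), dim(image))
      image[q[1], q[2]]
    }, numeric(1)))
  }, numeric(1))
}

#' Deterministic unbiased line placement within a cell
#'
#' Emulates grid-based blinded line placement: a fixed 4x4 grid of anchor
#' points spans the cell bounding box; lines that would overlap the nucleus
#' are discarded; `k` of the surviving candidates are chosen by a seeded
#' draw.
#'
#' @param cell a [cell_region()].
#' @param length_px line length in pixels (20-40).
#' @param k number of lines to keep.
#' @param nucleus_mask optional logical matrix marking the nucleus.
#' @param seed integer seed for the selection draw.
#' @return tibble with `start_row`, `start_col`, `end_row`, `end_col`.
#' @export
place_profile_lines <- function(cell, length_px = 30L, k = 4L,
                                nucleus_mask = NULL, seed = 1L) {
  foot <- region_footprint(cell$mask)
  idx <- which(foot, arr.ind = TRUE)
  r_rng <- range(idx[, 1]); c_rng <- range(idx[, 2])
  anchors <- expand.grid(
    row = round(seq(r_rng[1], r_rng[2], length.out = 4)),
    col = round(seq(c_rng[1], c_rng[2], length.out = 4))
  )
  cand <- purrr::pmap(anchors, function(row, col) {
    end <- c(row, col + length_px - 1L)
    if (end[2] > c_rng[2]) end <- c(row, col - length_px + 1L)
    if (end[2] < c_rng[1]) return(NULL)
    pts_c <- seq(col, end[2])
    if (!all(foot[cbind(rep(row, length(pts_c)), pts_c)])) return(NULL)
    if (!is.null(nucleus_mask) &&
      any(nucleus_mask[cbind(rep(row, length(pts_c)), pts_c)])) {
      return(NULL)
    }
    tibble(start_row = row, start_col = col, end_row = end[1], end_col = end[2])
  })
  cand <- bind_rows(purrr::compact(cand))
  if (nrow(cand) == 0) abort(sprintf("no admissible lines in cell '%s'", cell$cell_id))
  set.seed(seed)
  cand[sample(nrow(cand), min(k, nrow(cand))), ]
}

#' Organelle-to-cytosol intensity ratio through a reference mask
#'
#' A reference channel (e.g. fluid-phase dextran filling lysosomes) is
#' thresholded into a mask, which is applied to the marker channel; the
#' ratio of background-corrected marker means over the mask versus over the
#' remaining cytosol quantifies organelle enrichment. Reused with the role
#' of the channels swapped for Ca2+-sensor and GFP/mCherry tandem probes.
#'
#' @param marker numeric matrix, the measured channel.
#' @param reference numeric matrix thresholded into the organelle mask, or
#'   a logical matrix used as the mask directly.
#' @param cell a [cell_region()] with a cytosol sample.
#' @param background_region logical matrix of extracellular pixels.
#' @param ref_threshold threshold for the reference channel; default is the
#'   2x-cytosol rule evaluated on the reference channel.
#' @return one-row tibble: `cell_id`, `metric_name`, `value`,
#'   `background_used`; `value` is `NA` (flagged, not zero) when the
#'   reference mask is empty.
#' @export
organelle_to_cytosol_ratio <- function(marker, reference, cell,
                                       background_region,
                                       ref_threshold = NULL) {
  bg <- masked_mean(marker, background_region)
  if (is.logical(reference)) {
    ref_mask <- reference
  } else {
    if (is.null(ref_threshold)) {
      ref_threshold <- cytosolic_threshold(reference, cell)
    }
    ref_mask <- reference > ref_threshold
  }
  foot <- region_footprint(cell$mask)
  ref_mask <- ref_mask & foot
  if (!any(ref_mask)) {
    return(tibble(
      cell_id = cell$cell_id, metric_name = "organelle_to_cytosol",
      value = NA_real_, background_used = bg
    ))
  }
  cyto <- foot & !ref_mask
  if (!is.null(cell$cytosol_sample)) {
    cyto <- region_footprint(cell$cytosol_sample) & !ref_mask
  }
  num <- masked_mean(marker, ref_mask) - bg
  den <- masked_mean(marker, cyto) - bg
  tibble(
    cell_id = cell$cell_id, metric_name = "organelle_to_cytosol",
    value = num / den, background_used = bg
  )
}

#' Background-corrected mean intensity per cell
#'
#' Mean fluorescence over the cell mask minus the mean over an
#' extracellular background region; the read-out for whole-cell probes
#' (oxidative-stress dyes, viability stains) before vehicle normalization.
#'
#' @param image numeric matrix or [volumetric_image()].
#' @param cell a [cell_region()].
#' @param background_region logical mask of extracellular pixels.
#' @return scalar corrected intensity.
#' @export
mean_cell_intensity <- function(image, cell, background_region) {
  dims <- dim(as.array(unclass(image)))
  m <- expand_mask(cell$mask, dims)
  bgm <- expand_mask(background_region, dims)
  masked_mean(unclass(image), m) - masked_mean(unclass(image), bgm)
}

#' Count area-gated puncta in a cell
#'
#' Per-cell thresholding (2x-cytosol rule by default) followed by
#' 8-connected component analysis; components whose area falls inside the
#' gate are counted as puncta, smaller ones being treated as noise. The
#' default gate of 50-1000 um^2 follows the published galectin-3 recipe
#' verbatim; that unit is likely pixel^2 in the original, so the gate is
#' fully configurable (see `gate_unit`).
#'
#' @param image numeric matrix.
#' @param cell a [cell_region()].
#' @param threshold intensity cut-off; default [cytosolic_threshold()] on
#'   this cell.
#' @param gate `c(min, max)` area gate, inclusive bounds.
#' @param pixel_size micrometres per pixel.
#' @param gate_unit `"um2"` or `"px"`.
#' @return list with `count` and `puncta` (tibble: centroid, area, mean
#'   intensity per punctum, gated).
#' @export
count_puncta <- function(image, cell, threshold = NULL,
                         gate = c(50, 1000), pixel_size = 0.1,
                         gate_unit = c("um2", "px")) {
  gate_unit <- match.arg(gate_unit)
  if (is.null(threshold)) threshold <- cytosolic_threshold(image, cell)
  foot <- region_footprint(cell$mask)
  mask <- (image > threshold) & foot
  if (!any(mask)) {
    return(list(count = 0L, puncta = tibble(
      punctum = integer(), x_um = numeric(), y_um = numeric(),
      area_um2 = numeric(), mean_intensity = numeric()
    )))
  }
  lab <- label_components(mask, 8L)
  idx <- which(lab > 0)
  co <- arrayInd(idx, dim(image))
  df <- tibble(
    l = lab[idx],
    x = (co[, 2] - 0.5) * pixel_size,
    y = (co[, 1] - 0.5) * pixel_size,
    v = image[idx]
  ) %>%
    group_by(.data$l) %>%
    summarise(
      x_um = mean(.data$x), y_um = mean(.data$y),
      n_px = dplyr::n(), mean_intensity = mean(.data$v),
      .groups = "drop"
    ) %>%
    mutate(area_um2 = .data$n_px * pixel_size^2)
  area <- if (gate_unit == "um2") df$area_um2 else df$n_px
  df <- df[area >= gate[1] & area <= gate[2], ]
  puncta <- tibble(
    punctum = seq_len(nrow(df)),
    x_um = df$x_um, y_um = df$y_um,
    area_um2 = df$area_um2, mean_intensity = df$mean_intensity
  )
  list(count = nrow(puncta), puncta = puncta)
}

#' Count puncta associated with lysosomes
#'
#' A punctum (e.g. an actin focus) is associated with a lysosome when its
#' centroid lies inside a lysosome segment or within `association_distance`
#' of its boundary, measured by the Euclidean distance transform of the
#' lysosome mask's complement.
#'
#' @param puncta tibble from [count_puncta()]`$puncta`.
#' @param lysosome_mask logical matrix of segmented lysosomes.
#' @param pixel_size micrometres per pixel.
#' @param association_distance micrometres (default 0.25, about 2-3
#'   pixels).
#' @return list with `n_associated` and the puncta tibble gaining
#'   `distance_um` and `associated` columns.
#' @export
lysosome_associated_puncta <- function(puncta, lysosome_mask, pixel_size,
                                       association_distance = 0.25) {
  if (nrow(puncta) == 0) {
    return(list(n_associated = 0L, puncta = mutate(
      puncta, distance_um = numeric(0), associated = logical(0)
    )))
  }
  dist_out <- distance_transform(!lysosome_mask, c(pixel_size, pixel_size))
  rows <- pmin(pmax(round(puncta$y_um / pixel_size + 0.5), 1), nrow(lysosome_mask))
  cols <- pmin(pmax(round(puncta$x_um / pixel_size + 0.5), 1), ncol(lysosome_mask))
  dists <- dist_out[cbind(rows, cols)]
  out <- mutate(puncta,
    distance_um = dists,
    associated = dists <= association_distance
  )
  list(n_associated = sum(out$associated), puncta = out)
}
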