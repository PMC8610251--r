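#' Mask of internal (phagocytosed) bacteria
#'
#' Subtraction masking: all-bacteria and external-label channels are
#' thresholded (per-channel Otsu by default); any bacterial component that
#' overlaps the external-label mask by even one pixel is classified
#' external and removed whole (the antibody decorates entire bacteria);
#' remaining specks of at most `noise_max_area` pixels are dropped as
#' noise.
#'
#' @param all_bacteria numeric matrix, channel containing every bacterium.
#' @param external numeric matrix, antibody label on external bacteria.
#' @param noise_max_area components with area <= this many pixels are
#'   removed (default 4, "a few pixels in size").
#' @param threshold_all,threshold_external optional fixed thresholds
#'   overriding Otsu.
#' @return logical matrix marking internal bacteria.
#' @export
internal_bacteria_mask <- function(all_bacteria, external,
                                   noise_max_area = 4L,
                                   threshold_all = NULL,
                                   threshold_external = NULL) {
  m_all <- channel_mask(all_bacteria, threshold_all)
  m_ext <- channel_mask(external, threshold_external)
  if (!any(m_all)) return(m_all)
  lab <- label_components(m_all, 8L)
  ext_labels <- unique(lab[m_ext & lab > 0])
  keep <- lab > 0 & !(lab %in% ext_labels)
  lab2 <- label_components(keep, 8L)
  if (max(lab2) > 0) {
    sizes <- tabulate(lab2[lab2 > 0])
    small <- which(sizes <= noise_max_area)
    keep <- lab2 > 0 & !(lab2 %in% small)
  }
  keep
}

channel_mask <- function(img, threshold = NULL) {
  mx <- max(img)
  if (mx <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  if (is.null(threshold)) {
    if (length(unique(as.numeric(img))) < 2) {
      return(matrix(FALSE, nrow(img), ncol(img)))
    }
    threshold <- EBImage::otsu(
      EBImage::Image(img / mx), range = c(0, 1), levels = 256
    ) * mx
  }
  img > threshold
}

#' Dilate internal-bacteria masks out to the phagosome membrane
#'
#' Isotropic morphological dilation by a Euclidean disk of
#' `dilation_radius` pixels, taking the bacterial mask out to the
#' phagosomal membrane where the LAMP-1 signal lives. Pixels of the
#' external-bacteria mask are excluded after dilation, so external signal
#' can never leak into a score.
#'
#' @param internal_mask logical matrix from [internal_bacteria_mask()].
#' @param dilation_radius radius in pixels (>= 0; 0 is the identity).
#' @param external_mask optional logical matrix to carve out post-dilation.
#' @return logical matrix; always a superset of `internal_mask` minus the
#'   external carve-out.
#' @export
dilate_to_phagosome <- function(internal_mask, dilation_radius = 3,
                                external_mask = NULL) {
  if (dilation_radius < 0) abort("dilation_radius must be >= 0")
  out <- if (dilation_radius == 0 || !any(internal_mask)) {
    internal_mask
  } else {
    d2 <- edt_sq(
      as.logical(!internal_mask), as.integer(dim(internal_mask)), c(1, 1)
    )
    matrix(d2 <= dilation_radius^2, nrow(internal_mask), ncol(internal_mask))
  }
  if (!is.null(external_mask)) out <- out & !external_mask
  out
}

#' Score phagosome-lysosome fusion from LAMP-1 intensity
#'
#' Mean background-corrected LAMP-1 intensity over each cell's dilated
#' phagosome masks: the fusion proxy. Two per-cell summaries are emitted —
#' the mean over the union of the cell's phagosome masks (headline) and
#' the mean of per-phagosome means — along with the per-phagosome values.
#' Cells without any phagosome are excluded and counted.
#'
#' @param lamp1 numeric matrix, LAMP-1 channel.
#' @param phagosome_mask logical matrix from [dilate_to_phagosome()].
#' @param regions list of [cell_region()]s.
#' @param background_region logical matrix of extracellular pixels.
#' @return list with `per_cell` (tibble: `cell_id`, `n_phagosomes`,
#'   `mean_lamp1` (union mask), `mean_of_phagosome_means`), `per_phagosome`
#'   (tibble: `phagosome_id`, `cell_id`, `area_px`, `mean_lamp1`) and
#'   `n_cells_excluded`.
#' @export
phagosome_lamp_score <- function(lamp1, phagosome_mask, regions,
                                 background_region) {
  bg <- masked_mean(lamp1, background_region)
  lab <- label_components(phagosome_mask, 8L)
  per_ph <- list()
  per_cell <- list()
  n_excluded <- 0L
  pid <- 0L
  for (reg in regions) {
    foot <- region_footprint(reg$mask)
    cell_lab <- lab * foot
    labs_here <- setdiff(unique(as.integer(cell_lab)), 0L)
    if (length(labs_here) == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    vals_union <- lamp1[cell_lab > 0]
    ph_means <- vapply(sort(labs_here), function(l) {
      v <- lamp1[cell_lab == l]
      pid <<- pid + 1L
      per_ph[[pid]] <<- tibble(
        phagosome_id = pid, cell_id = reg$cell_id,
        area_px = length(v), mean_lamp1 = mean(v) - bg
      )
      mean(v) - bg
    }, numeric(1))
    per_cell[[length(per_cell) + 1L]] <- tibble(
      cell_id = reg$cell_id,
      n_phagosomes = length(labs_here),
      mean_lamp1 = mean(vals_union) - bg,
      mean_of_phagosome_means = mean(ph_means)
    )
  }
  list(
    per_cell = bind_rows(per_cell),
    per_phagosome = bind_rows(per_ph),
    n_cells_excluded = n_excluded
  )
}

#' End-to-end phagosome fusion scoring of a three-channel scene
#'
#' Convenience pipeline: thresholds the bacteria and external-label
#' channels, builds the internal-bacteria mask, dilates it to the
#' phagosome membrane, and scores background-corrected LAMP-1. The
#' background region is everything outside bacteria and phagosome masks
#' (with a safety margin of one dilation), an unbiased estimate of the
#' LAMP-1 channel background.
#'
#' @param scene a list as returned by [generate_phagosome_scene()] (or any
#'   list with `channels`, `pixel_size`, `region`).
#' @param dilation_radius pixels of isotropic dilation (default 3).
#' @param noise_max_area see [internal_bacteria_mask()].
#' @return as [phagosome_lamp_score()].
#' @export
phagosome_fusion_score <- function(scene, dilation_radius = 3,
                                   noise_max_area = 4L) {
  ch <- scene$channels
  im <- internal_bacteria_mask(ch[, , 1], ch[, , 2], noise_max_area)
  ext <- channel_mask(ch[, , 2])
  ph <- dilate_to_phagosome(im, dilation_radius, ext)
  allb <- channel_mask(ch[, , 1])
  lamp <- ch[, , 3]
  bgreg <- !dilate_to_phagosome(allb | ph, dilation_radius)
  regions <- if (!is.null(scene$regions)) scene$regions else list(scene$region)
  phagosome_lamp_score(lamp, ph, regions, bgreg)
}
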