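#' Generate a synthetic phagosome scene with internal/external bacteria
#'
#' Three co-registered channels emulating a phagosome maturation field:
#' channel 1 carries all bacteria (rendered as disks), channel 2 the
#' antibody label on external (non-internalised) bacteria only, and channel
#' 3 the LAMP-1 signal, rendered as an annulus of stated intensity around
#' internal bacteria only — the phagosomal membrane that a fused lysosome
#' population decorates. Ground truth marks each bacterium internal or
#' external.
#'
#' @param config a [scene_config()].
#' @param n_internal,n_external bacteria counts.
#' @param lamp_ring_intensity LAMP-1 annulus intensity (internal only).
#' @param field_um field of view `c(width, height)` um.
#' @param bacterium_radius_um rendered bacterium radius.
#' @param ring_width_um radial extent of the LAMP-1 signal beyond the
#'   bacterium edge (the phagosomal membrane).
#' @param lamp_filled render LAMP-1 as a filled structure out to the
#'   membrane (default): at confocal resolution a sub-half-micrometre
#'   membrane ring around a 0.5 um bacterium is unresolved and appears
#'   filled. `FALSE` renders a bare annulus starting at the bacterium
#'   edge.
#' @param bacteria_intensity intensity for channels 1 and 2.
#' @param adjacency_pairs number of external bacteria deliberately placed
#'   adjacent to an internal one (adversarial fixture for the exclusion
#'   rule); requires both counts > 0.
#' @return list with `channels` (array `ny x nx x 3`, names all_bacteria /
#'   external_label / lamp1), `pixel_size`, `truth` (tibble) and `region`
#'   (one whole-field [cell_region()]).
#' @export
generate_phagosome_scene <- function(config,
                                     n_internal = 3L,
                                     n_external = 2L,
                                     lamp_ring_intensity = 500,
                                     field_um = c(30, 30),
                                     bacterium_radius_um = 0.5,
                                     ring_width_um = 0.4,
                                     lamp_filled = TRUE,
                                     bacteria_intensity = 800,
                                     adjacency_pairs = 0L) {
  stopifnot(inherits(config, "scene_config"))
  if (adjacency_pairs > min(n_internal, n_external)) {
    abort("adjacency_pairs cannot exceed the smaller bacteria count")
  }
  px <- config$pixel_size_xy
  dims <- c(round(field_um[2] / px), round(field_um[1] / px))
  rb <- bacterium_radius_um
  r_out <- rb + ring_width_um
  clear <- 2 * r_out + 3 * config$psf_sigma + 2 * px # rings must not touch
  margin <- r_out + 3 * config$psf_sigma + 2 * px

  set.seed(config$random_seed)
  n_total <- n_internal + n_external
  pos <- matrix(numeric(0), 0, 2)
  is_internal <- c(rep(TRUE, n_internal), rep(FALSE, n_external))
  # the first `adjacency_pairs` external bacteria snuggle up to an internal one
  for (k in seq_len(n_total)) {
    adjacent_to <- 0L
    if (!is_internal[k] && (k - n_internal) <= adjacency_pairs) {
      adjacent_to <- k - n_internal # pair with that internal bacterium
    }
    placed <- FALSE
    for (try in 1:2000) {
      if (adjacent_to > 0L) {
        ang <- runif(1, 0, 2 * pi)
        # adjacent but distinct: two pixels of clearance keeps the disks
        # separate components while the dilated mask still reaches them
        cand <- pos[adjacent_to, ] + (2 * rb + 2 * px) * c(cos(ang), sin(ang))
      } else {
        cand <- c(runif(1, margin, field_um[1] - margin),
                  runif(1, margin, field_um[2] - margin))
      }
      if (cand[1] < margin || cand[1] > field_um[1] - margin ||
        cand[2] < margin || cand[2] > field_um[2] - margin) next
      if (nrow(pos) > 0) {
        others <- seq_len(nrow(pos))
        if (adjacent_to > 0L) others <- others[others != adjacent_to]
        if (length(others) > 0 &&
          min(sqrt(colSums((t(pos[others, , drop = FALSE]) - cand)^2))) < clear) next
      }
      pos <- rbind(pos, cand)
      placed <- TRUE
      break
    }
    if (!placed) abort(sprintf("could not place bacterium %d", k))
  }

  truth <- tibble(
    object_id = seq_len(n_total),
    kind = ifelse(is_internal, "bacterium_internal", "bacterium_external"),
    x_um = pos[, 1], y_um = pos[, 2],
    radius_um = rb,
    ring_intensity = ifelse(is_internal, lamp_ring_intensity, 0)
  )

  ch_all <- rasterize_disks(dims, px, pos, rep(rb, n_total),
                            rep(bacteria_intensity, n_total))
  ext <- pos[!is_internal, , drop = FALSE]
  ch_ext <- rasterize_disks(dims, px, ext, rep(rb, nrow(ext)),
                            rep(bacteria_intensity, nrow(ext)))
  int <- pos[is_internal, , drop = FALSE]
  r_in <- if (lamp_filled) 0 else rb
  ch_lamp <- rasterize_rings(dims, px, int,
                             rep(r_in, nrow(int)), rep(r_out, nrow(int)),
                             rep(lamp_ring_intensity, nrow(int)))

  s <- config$psf_sigma / px
  chans <- array(0, c(dims, 3))
  chans[, , 1] <- gaussian_blur(ch_all, c(s, s))
  chans[, , 2] <- gaussian_blur(ch_ext, c(s, s))
  chans[, , 3] <- gaussian_blur(ch_lamp, c(s, s)) + config$background_level
  chans <- add_noise(chans, config)
  dimnames(chans) <- list(NULL, NULL, c("all_bacteria", "external_label", "lamp1"))

  region <- cell_region("cell_01", matrix(TRUE, dims[1], dims[2]))
  list(channels = chans, pixel_size = px, truth = truth, region = region)
}
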