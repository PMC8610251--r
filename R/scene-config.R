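#' Configuration for synthetic microscopy scenes
#'
#' Bundles the acquisition geometry and noise model shared by all scene
#' generators. Defaults emulate spinning-disc confocal acquisition of
#' macrophage-like cells: 50 z-planes at 0.3 um spacing, 0.1 um/pixel in xy
#' (63x/1.4 NA scale), a Gaussian point-spread approximation, and additive
#' Gaussian read noise with optional Poisson shot noise.
#'
#' @param random_seed integer seed; identical configurations give
#'   bit-identical scenes.
#' @param pixel_size_xy micrometres per pixel in x and y.
#' @param z_spacing micrometres between consecutive z-planes.
#' @param n_planes number of z-planes in a stack.
#' @param frame_interval seconds between time-lapse frames (4 for the
#'   macrophage preset, 8 for the epithelial preset).
#' @param psf_sigma Gaussian blur sigma in micrometres (applied isotropically
#'   in physical units, so anisotropic in voxels).
#' @param gaussian_sd standard deviation of additive Gaussian noise.
#' @param poisson_scaling photon-count scaling for Poisson noise; 0 disables.
#' @param background_level cytosolic background intensity inside cells.
#' @return A `scene_config` list.
#' @export
scene_config <- function(random_seed = 1L,
                         pixel_size_xy = 0.1,
                         z_spacing = 0.3,
                         n_planes = 50L,
                         frame_interval = 4,
                         psf_sigma = 0.1,
                         gaussian_sd = 5,
                         poisson_scaling = 0,
                         background_level = 50) {
  if (pixel_size_xy <= 0) abort("pixel_size_xy must be > 0")
  if (z_spacing <= 0) abort("z_spacing must be > 0")
  if (n_planes < 1) abort("n_planes must be >= 1")
  if (psf_sigma < 0) abort("psf_sigma must be >= 0")
  if (gaussian_sd < 0 || poisson_scaling < 0 || background_level < 0) {
    abort("noise parameters must be >= 0")
  }
  if (!frame_interval %in% c(4, 8)) {
    # the two acquisition presets; other intervals allowed but flagged
    if (frame_interval <= 0) abort("frame_interval must be positive")
  }
  structure(list(
    random_seed = as.integer(random_seed),
    pixel_size_xy = pixel_size_xy,
    z_spacing = z_spacing,
    n_planes = as.integer(n_planes),
    frame_interval = frame_interval,
    psf_sigma = psf_sigma,
    gaussian_sd = gaussian_sd,
    poisson_scaling = poisson_scaling,
    background_level = background_level
  ), class = "scene_config")
}

#' Time-lapse acquisition presets
#'
#' The two live-imaging regimes used for lysosome motility: macrophages
#' ("RAW") imaged at a single mid-cell plane every 4 s for 3 min, and
#' epithelial cells ("RPE") every 8 s for 6 min. Both yield 46 frames
#' (duration/interval + 1).
#'
#' @param cell_type `"RAW"` or `"RPE"`.
#' @return list with `frame_interval` (s), `duration` (s) and `n_frames`.
#' @export
timelapse_preset <- function(cell_type = c("RAW", "RPE")) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "RAW") {
    list(frame_interval = 4, duration = 180, n_frames = 46L)
  } else {
    list(frame_interval = 8, duration = 360, n_frames = 46L)
  }
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> seed %d | %g um/px, %d planes @ %g um | psf %g um | noise sd %g, bg %g\n",
    x$random_seed, x$pixel_size_xy, x$n_planes, x$z_spacing,
    x$psf_sigma, x$gaussian_sd, x$background_level
  ))
  invisible(x)
}
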