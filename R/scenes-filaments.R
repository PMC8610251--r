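#' Filament graphs with known topology
#'
#' A filament graph is a set of branches (polylines in micrometre
#' coordinates) whose shared endpoints define junctions. It is the ground
#' truth for skeleton morphometry: the number of junctions (points where at
#' least three branches arise), the number of branches, and each branch's
#' polyline length.
#'
#' @param branches list of numeric matrices (>= 2 rows, columns x and y in
#'   um); each matrix is one branch.
#' @param width_um rendered branch thickness.
#' @return a `filament_graph` with a `topology` list: `n_junctions`,
#'   `n_branches`, `branch_lengths_um`, and a tibble of junction
#'   coordinates.
#' @export
filament_graph <- function(branches, width_um = 0.3) {
  stopifnot(length(branches) >= 1)
  lens <- purrr::map_dbl(branches, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 2) abort("each branch needs at least 2 points")
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  })
  if (any(lens <= 0)) abort("zero-length branch rejected")
  ends <- purrr::map(branches, function(p) {
    p <- as.matrix(p)
    rbind(p[1, ], p[nrow(p), ])
  })
  ends <- do.call(rbind, ends)
  key <- paste(round(ends[, 1], 6), round(ends[, 2], 6))
  deg <- table(key)
  jkeys <- names(deg)[deg >= 3]
  jxy <- ends[match(jkeys, key), , drop = FALSE]
  structure(list(
    branches = purrr::map(branches, as.matrix),
    width_um = width_um,
    topology = list(
      n_junctions = length(jkeys),
      n_branches = length(branches),
      branch_lengths_um = lens,
      junctions = tibble(x_um = jxy[, 1], y_um = jxy[, 2])
    )
  ), class = "filament_graph")
}

#' @rdname filament_graph
#' @param a,b segment endpoints `c(x, y)` in um.
#' @export
fg_line <- function(a, b, width_um = 0.3) {
  filament_graph(list(rbind(a, b)), width_um)
}

#' @rdname filament_graph
#' @param center junction position `c(x, y)` um.
#' @param n_arms number of branches radiating from the centre.
#' @param arm_length_um branch length.
#' @param angle_offset rotation of the first arm, radians.
#' @export
fg_star <- function(center, n_arms = 4L, arm_length_um = 5,
                    angle_offset = 0, width_um = 0.3) {
  ang <- angle_offset + 2 * pi * (seq_len(n_arms) - 1) / n_arms
  branches <- purrr::map(ang, function(a) {
    rbind(center, center + arm_length_um * c(cos(a), sin(a)))
  })
  filament_graph(branches, width_um)
}

#' Random field of star-shaped filament motifs
#'
#' Places `n_junctions` star motifs (3-5 branches each) on a jittered grid
#' with centre separations large enough that motifs never touch, so the
#' ground-truth topology is the sum of the motifs. Used for topology
#' recovery experiments.
#'
#' @param n_junctions number of star centres.
#' @param field_um field of view side length.
#' @param arm_length_um arm length (also sets the safety spacing).
#' @param width_um branch thickness.
#' @param seed integer RNG seed.
#' @return a `filament_graph`.
#' @export
random_filament_field <- function(n_junctions = 4L, field_um = 30,
                                  arm_length_um = 3, width_um = 0.3,
                                  seed = 1L) {
  set.seed(seed)
  spacing <- 2 * arm_length_um + 2
  per_side <- max(1L, floor((field_um - 2 * arm_length_um - 1) / spacing) + 1L)
  if (per_side^2 < n_junctions) {
    abort("field too small for the requested number of junctions")
  }
  slots <- expand.grid(
    gx = seq_len(per_side), gy = seq_len(per_side)
  )[sample(per_side^2, n_junctions), ]
  branches <- list()
  for (i in seq_len(n_junctions)) {
    cx <- arm_length_um + 1 + (slots$gx[i] - 1) * spacing + runif(1, -0.5, 0.5)
    cy <- arm_length_um + 1 + (slots$gy[i] - 1) * spacing + runif(1, -0.5, 0.5)
    st <- fg_star(c(cx, cy),
      n_arms = sample(3:5, 1),
      arm_length_um = arm_length_um,
      angle_offset = runif(1, 0, 2 * pi), width_um = width_um
    )
    branches <- c(branches, st$branches)
  }
  filament_graph(branches, width_um)
}

#' Render a filament graph into a 2D fluorescence image
#'
#' Branches are drawn as anti-aliased thick lines, then blurred and
#' corrupted with background and noise per the scene configuration.
#'
#' @param config a [scene_config()].
#' @param graph a [filament_graph()].
#' @param field_um field of view `c(width, height)` um.
#' @param intensity filament peak intensity.
#' @return list with `image` (matrix), `pixel_size`, `graph` and `truth`
#'   (the graph topology).
#' @export
generate_filament_image <- function(config, graph,
                                    field_um = c(30, 30),
                                    intensity = 200) {
  stopifnot(inherits(config, "scene_config"), inherits(graph, "filament_graph"))
  px <- config$pixel_size_xy
  if (graph$width_um < px) abort("branch width must be at least 1 pixel")
  dims <- c(round(field_um[2] / px), round(field_um[1] / px))
  set.seed(config$random_seed)
  img <- rasterize_polylines(dims, px, graph$branches, graph$width_um, intensity)
  s <- config$psf_sigma / px
  img <- gaussian_blur(img, c(s, s))
  img <- img + config$background_level
  img <- add_noise(img, config)
  list(image = img, pixel_size = px, graph = graph, truth = graph$topology)
}
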