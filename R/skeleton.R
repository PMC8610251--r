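#' Binarize a filament image
#'
#' Reproduces the filament masking recipe: the image is converted to 8-bit,
#' a global threshold selects filament pixels (Otsu's method on the in-cell
#' histogram by default; a fixed value may be supplied), and the mask is
#' restricted to the cell region.
#'
#' @param image numeric matrix (single-plane fluorescence).
#' @param cell optional [cell_region()]; default uses the whole frame.
#' @param threshold `"otsu"` or a fixed cut-off on the 8-bit scale (0-255).
#' @return logical matrix.
#' @export
binarize_filaments <- function(image, cell = NULL, threshold = "otsu") {
  stopifnot(is.matrix(image))
  mask_cell <- if (is.null(cell)) matrix(TRUE, nrow(image), ncol(image)) else
    region_footprint(cell$mask)
  mx <- max(image)
  if (mx <= 0) return(matrix(FALSE, nrow(image), ncol(image)))
  img8 <- round(image / mx * 255)
  th <- if (identical(threshold, "otsu")) {
    vals <- img8[mask_cell]
    if (length(unique(vals)) < 2) return(matrix(FALSE, nrow(image), ncol(image)))
    EBImage::otsu(EBImage::Image(matrix(vals / 255, ncol = 1)), range = c(0, 1), levels = 256) * 255
  } else {
    as.numeric(threshold)
  }
  (img8 > th) & mask_cell
}

# shifted copies of a padded matrix for the 8 neighbours
shift8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  core_r <- 2:(nr + 1); core_c <- 2:(nc + 1)
  list(
    n = p[core_r - 1, core_c], ne = p[core_r - 1, core_c + 1],
    e = p[core_r, core_c + 1], se = p[core_r + 1, core_c + 1],
    s = p[core_r + 1, core_c], sw = p[core_r + 1, core_c - 1],
    w = p[core_r, core_c - 1], nw = p[core_r - 1, core_c - 1]
  )
}

#' Skeletonize a binary mask
#'
#' Guo-Hall two-subiteration thinning to a 1-pixel-wide, 8-connected medial
#' line (chosen over Zhang-Suen for its near absence of staircase
#' artifacts), followed by removal of residual redundant corner pixels;
#' connectivity of the mask is preserved.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      s <- shift8(m)
      # P2..P9 in circular order: N, NE, E, SE, S, SW, W, NW
      p2 <- s$n; p3 <- s$ne; p4 <- s$e; p5 <- s$se
      p6 <- s$s; p7 <- s$sw; p8 <- s$w; p9 <- s$nw
      C <- ((1L - p2) * (p3 | p4)) + ((1L - p4) * (p5 | p6)) +
        ((1L - p6) * (p7 | p8)) + ((1L - p8) * (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(n1, n2)
      O <- if (step == 1) (p6 | p7 | (1L - p9)) & p8 else (p2 | p3 | (1L - p5)) & p4
      del <- m == 1L & C == 1L & N >= 2 & N <= 3 & O == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  prune_redundant(m) == 1L
}

# Zhang-Suen output can keep redundant staircase corners (a pixel whose 8
# neighbours form one contiguous arc: crossing number 1) which later read
# as spurious junctions. Removing them sequentially preserves connectivity
# and leaves a minimal 8-connected skeleton.
prune_redundant <- function(m) {
  nbr <- rbind(
    c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
    c(1, 0), c(1, -1), c(0, -1), c(-1, -1)
  ) # circular order
  nr <- nrow(m); nc <- ncol(m)
  ring_at <- function(r, c) {
    vapply(1:8, function(i) {
      rr <- r + nbr[i, 1]; cc <- c + nbr[i, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) 0L else m[rr, cc]
    }, integer(1))
  }
  repeat {
    removed <- FALSE
    idx <- which(m == 1L, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c <- idx[k, 2]
      if (m[r, c] == 0L) next
      ring <- ring_at(r, c)
      B <- sum(ring)
      if (B < 2) next # endpoints and isolated pixels stay
      trans <- sum(ring == 0L & ring[c(2:8, 1)] == 1L)
      if (trans == 1) {
        m[r, c] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

#' Analyze a skeleton into junctions and branches
#'
#' Classifies every skeleton pixel by its 8-neighbour count: one neighbour
#' marks an endpoint, two a slab (branch interior), three or more a
#' junction candidate. Adjacent junction candidates are merged into a
#' single junction node (a thick crossing thins into a small cluster of
#' candidate pixels, but it is one biological junction). Branches are the
#' maximal slab paths between nodes; their length accumulates 1 pixel for
#' orthogonal steps and sqrt(2) pixels for diagonal ones, including the
#' step onto an adjacent junction cluster. Spur branches shorter than
#' `prune_px` pixels that end at a free endpoint are pruned as thinning
#' artifacts.
#'
#' @param skeleton logical matrix from [skeletonize()].
#' @param pixel_size micrometres per pixel.
#' @param prune_px prune spurs with fewer than this many pixels.
#' @return list with `n_junctions`, `n_branches`, `branch_lengths_um`,
#'   `mean_branch_length_um`, and the junction/endpoint pixel sets.
#' @export
analyze_skeleton <- function(skeleton, pixel_size = 1, prune_px = 3L) {
  if (!any(skeleton)) {
    return(list(
      n_junctions = 0L, n_branches = 0L,
      branch_lengths_um = numeric(), mean_branch_length_um = NA_real_,
      junction_pixels = which(skeleton), endpoint_pixels = which(skeleton)
    ))
  }
  m <- matrix(as.integer(skeleton), nrow(skeleton), ncol(skeleton))
  s <- shift8(m)
  nn <- Reduce(`+`, s)
  jcand <- skeleton & nn >= 3
  endpt <- skeleton & nn == 1
  jclusters <- label_components(jcand, 8L)
  n_junctions <- max(jclusters, 0L)

  slab <- skeleton & !jcand
  slab_lab <- label_components(slab, 8L)
  d <- dim(skeleton)
  branches <- list()
  for (l in seq_len(max(slab_lab, 0L))) {
    vox <- which(slab_lab == l)
    path <- order_path(vox, d)
    if (is.null(path)) next # not a simple path (rare thinning residue)
    len_px <- path_length_px(path$coords)
    ends <- path$coords[c(1, nrow(path$coords)), , drop = FALSE]
    if (path$cyclic) {
      # closed loop with no junction: one cyclic branch incl. closing step
      len_px <- len_px + step_cost(path$coords[nrow(path$coords), ], path$coords[1, ])
      branches[[length(branches) + 1L]] <-
        list(len_px = len_px, n_px = length(vox), free_ends = 0L,
             clusters = integer(0))
      next
    }
    free_ends <- 0L
    clusters <- integer(0)
    for (e in 1:2) {
      jn <- adjacent_cluster(ends[e, ], jclusters, d)
      if (jn$found) {
        len_px <- len_px + jn$cost
        clusters <- c(clusters, jn$cluster)
      } else {
        free_ends <- free_ends + 1L
      }
    }
    branches[[length(branches) + 1L]] <-
      list(len_px = len_px, n_px = length(vox), free_ends = free_ends,
           clusters = clusters)
  }
  # a thick multi-way crossing can thin into two junction clusters bridged
  # by a slab of 1-2 pixels; such a bridge is part of one junction, not a
  # branch, so its clusters are merged and the bridge dropped
  parent <- seq_len(n_junctions)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  bridge <- purrr::map_lgl(branches, function(b) {
    b$free_ends == 0L && length(b$clusters) == 2L && b$n_px < prune_px
  })
  for (b in branches[bridge]) {
    r1 <- find_root(b$clusters[1]); r2 <- find_root(b$clusters[2])
    if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
  }
  n_junctions_merged <- length(unique(vapply(seq_len(n_junctions), find_root, integer(1))))
  keep <- purrr::map_lgl(branches, function(b) {
    !(b$free_ends > 0L && b$n_px < prune_px)
  }) & !bridge
  lens <- purrr::map_dbl(branches[keep], "len_px") * pixel_size
  list(
    n_junctions = n_junctions_merged,
    n_branches = length(lens),
    branch_lengths_um = lens,
    mean_branch_length_um = if (length(lens)) mean(lens) else NA_real_,
    junction_pixels = which(jcand),
    endpoint_pixels = which(endpt)
  )
}

step_cost <- function(a, b) {
  if (all(abs(a - b) <= 1) && any(a != b)) {
    if (sum(abs(a - b)) == 2) sqrt(2) else 1
  } else {
    0
  }
}

path_length_px <- function(coords) {
  if (nrow(coords) < 2) return(0)
  steps <- abs(coords[-1, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE])
  sum(ifelse(rowSums(steps) == 2, sqrt(2), 1))
}

# order the pixels of a degree-<=2 component into a path; NULL if not a path
order_path <- function(vox, d) {
  coords <- arrayInd(vox, d)
  n <- nrow(coords)
  if (n == 1) return(list(coords = coords, cyclic = FALSE))
  key <- paste(coords[, 1], coords[, 2])
  lookup <- setNames(seq_len(n), key)
  adj <- vector("list", n)
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_len(n)) {
    nb <- sweep(offs, 2, as.numeric(coords[i, ]), `+`)
    hits <- lookup[paste(nb[, 1], nb[, 2])]
    adj[[i]] <- unname(hits[!is.na(hits)])
  }
  deg <- lengths(adj)
  if (any(deg > 2)) return(NULL)
  start <- which(deg <= 1)[1]
  cyclic <- is.na(start)
  if (cyclic) start <- 1L
  path <- integer(n)
  visited <- logical(n)
  cur <- start
  for (i in seq_len(n)) {
    path[i] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(nxt) == 0) break
    cur <- nxt[1]
  }
  if (any(!visited)) return(NULL)
  list(coords = coords[path, , drop = FALSE], cyclic = cyclic)
}

# is a pixel 8-adjacent to a junction cluster? returns the chamfer cost
# and the cluster id (lowest-cost, orthogonal preferred)
adjacent_cluster <- function(px, jclusters, d) {
  best <- Inf
  cluster <- NA_integer_
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r <- px[1] + dr; c <- px[2] + dc
    if (r < 1 || r > d[1] || c < 1 || c > d[2]) next
    if (jclusters[r, c] > 0) {
      cost <- if (abs(dr) + abs(dc) == 2) sqrt(2) else 1
      if (cost < best) {
        best <- cost
        cluster <- jclusters[r, c]
      }
    }
  }
  list(found = is.finite(best), cost = if (is.finite(best)) best else 0,
       cluster = cluster)
}

#' Tubulin patch areas by watershed
#'
#' Splits a filament/patch mask into watershed basins seeded from
#' distance-transform maxima (the 2D counterpart of the organelle
#' splitting) and measures patch areas; depolymerised tubulin pools into
#' large patches, so the maximum patch area per cell is the headline
#' read-out (the mean is also reported).
#'
#' @param mask logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param min_seed_sep minimum watershed seed separation in um.
#' @return one-row tibble: `n_patches`, `max_patch_area_um2`,
#'   `mean_patch_area_um2`. An empty mask yields zero area.
#' @export
patch_area <- function(mask, pixel_size = 1, min_seed_sep = 0.3^(1 / 3)) {
  if (!any(mask)) {
    return(tibble(n_patches = 0L, max_patch_area_um2 = 0, mean_patch_area_um2 = 0))
  }
  lab <- label_components(mask, 8L)
  areas <- numeric(0)
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    wl <- watershed_split(comp, c(pixel_size, pixel_size), min_seed_sep)
    areas <- c(areas, tabulate(wl[wl > 0]) * pixel_size^2)
  }
  areas <- areas[areas > 0]
  tibble(
    n_patches = length(areas),
    max_patch_area_um2 = max(areas),
    mean_patch_area_um2 = mean(areas)
  )
}

#' Per-cell skeleton morphometry summary
#'
#' End-to-end filament morphometry for one cell: binarize, skeletonize,
#' analyze, and measure patch areas.
#'
#' @param image numeric matrix.
#' @param cell optional [cell_region()].
#' @param pixel_size micrometres per pixel.
#' @param threshold passed to [binarize_filaments()].
#' @param prune_px passed to [analyze_skeleton()].
#' @return one-row tibble: `cell_id`, `n_junctions`, `n_branches`,
#'   `mean_branch_length_um`, `max_patch_area_um2`, `mean_patch_area_um2`.
#' @export
skeleton_summary <- function(image, cell = NULL, pixel_size = 1,
                             threshold = "otsu", prune_px = 3L) {
  mask <- binarize_filaments(image, cell, threshold)
  sk <- skeletonize(mask)
  an <- analyze_skeleton(sk, pixel_size, prune_px)
  pa <- patch_area(mask, pixel_size)
  tibble(
    cell_id = if (is.null(cell)) "cell_01" else cell$cell_id,
    n_junctions = an$n_junctions,
    n_branches = an$n_branches,
    mean_branch_length_um = an$mean_branch_length_um,
    max_patch_area_um2 = pa$max_patch_area_um2,
    mean_patch_area_um2 = pa$mean_patch_area_um2
  )
}
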