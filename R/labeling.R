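#' Connected-component labelling
#'
#' Labels foreground regions of a 2D or 3D mask. The default connectivity is
#' the permissive standard: 26 neighbours in 3D, which degenerates to
#' 8-connectivity for single-plane masks. Labels are dense from 1 in raster
#' scan order, so the labelling is deterministic.
#'
#' @param mask logical array (2D or 3D).
#' @param connectivity 26 (8 in 2D) or 6 (4 in 2D).
#' @return integer array of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- as.array(mask)
  d <- dim(mask)
  cc_label(as.logical(mask), as.integer(d), as.integer(connectivity))
}

#' Anisotropic Euclidean distance transform
#'
#' Distance from every foreground element to the nearest background element,
#' measured in physical units: axes are scaled by the voxel size before
#' distances are taken, which matters because axial spacing (0.3 um) exceeds
#' the lateral pixel size.
#'
#' @param mask logical array.
#' @param voxel_size physical element sizes per array axis `(y, x[, z])` —
#'   note array-axis order, not x/y/z order.
#' @return numeric array of distances in the same units.
#' @export
distance_transform <- function(mask, voxel_size = c(1, 1, 1)) {
  mask <- as.array(mask)
  d <- dim(mask)
  voxel_size <- voxel_size[seq_along(d)]
  sqrt(edt_sq(as.logical(mask), as.integer(d), as.numeric(voxel_size)))
}

# local maxima of a distance map inside a mask, greedily thinned so kept
# seeds are at least min_sep apart (physical units). Plateaus collapse to
# one representative (lowest linear index). Returns an integer seed array.
dt_maxima_seeds <- function(dist, mask, voxel_size, min_sep) {
  d <- dim(dist)
  nd <- length(d)
  is_max <- mask & dist > 0
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  idx_rng <- purrr::map(d, seq_len)
  for (r in seq_len(nrow(offs))) {
    src <- purrr::map2(idx_rng, offs[r, ], function(ix, o) pmin(pmax(ix + o, 1), length(ix)))
    shifted <- do.call(`[`, c(list(dist), src, list(drop = FALSE)))
    dim(shifted) <- d
    is_max <- is_max & (dist >= shifted)
  }
  if (!any(is_max)) {
    # degenerate mask; seed at the global maximum inside the mask
    is_max <- array(FALSE, d)
    cand <- which(mask)
    is_max[cand[which.max(dist[cand])]] <- TRUE
  }
  # merge plateau clusters, keep one representative per cluster
  plat <- label_components(is_max, if (nd == 3) 26L else 8L)
  nlab <- max(plat)
  reps <- vapply(seq_len(nlab), function(l) min(which(plat == l)), integer(1))
  # greedy separation filter, strongest (deepest) first, index as tie-break
  ord <- order(-dist[reps], reps)
  reps <- reps[ord]
  coords <- arrayInd(reps, d)
  phys <- sweep(coords, 2, voxel_size[seq_len(nd)], `*`)
  keep <- logical(length(reps))
  for (i in seq_along(reps)) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    dd <- sqrt(rowSums((phys[keep, , drop = FALSE] -
      matrix(phys[i, ], sum(keep), nd, byrow = TRUE))^2))
    if (all(dd >= min_sep)) keep[i] <- TRUE
  }
  seeds <- array(0L, d)
  seeds[reps[keep]] <- seq_len(sum(keep))
  seeds
}
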