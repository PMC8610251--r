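# Rasterisation and optics for the synthetic scene generators.
#
# Geometry is defined in continuous micrometre coordinates; a voxel is lit
# when its *centre* falls inside the object. Rendering order is always:
# rasterise -> Gaussian blur (the PSF approximation) -> background ->
# additive noise, so with psf_sigma = 0 and no noise the above-background
# support equals the rasterised geometry exactly.

px_centers <- function(n, w) (seq_len(n) - 0.5) * w

# separable Gaussian blur; sigma_px per array dimension, in pixels.
# Truncated at 3 sigma with per-row renormalisation at the borders.
gaussian_blur <- function(arr, sigma_px) {
  d <- dim(arr)
  for (ax in seq_along(d)) {
    s <- sigma_px[ax]
    if (s <= 0 || d[ax] == 1L) next
    half <- max(1L, ceiling(3 * s))
    n <- d[ax]
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      w <- exp(-((i - j)^2) / (2 * s^2))
      w * (abs(i - j) <= half)
    })
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(seq_along(d), ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], prod(dm[-1]))
    m <- K %*% m
    dim(m) <- dm
    arr <- aperm(m, order(perm))
  }
  arr
}

# spheres: centers = matrix with columns x, y, z (um); max-composited
rasterize_spheres <- function(dims, vs, centers, radii, intensities) {
  arr <- array(0, dims)
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]; cz <- centers[k, 3]
    r <- radii[k]
    ys <- max(1, floor((cy - r) / vs[2])):min(ny, ceiling((cy + r) / vs[2] + 1))
    xs <- max(1, floor((cx - r) / vs[1])):min(nx, ceiling((cx + r) / vs[1] + 1))
    zs <- max(1, floor((cz - r) / vs[3])):min(nz, ceiling((cz + r) / vs[3] + 1))
    yy <- (ys - 0.5) * vs[2] - cy
    xx <- (xs - 0.5) * vs[1] - cx
    zz <- (zs - 0.5) * vs[3] - cz
    d2 <- outer(outer(yy^2, xx^2, `+`), zz^2, `+`)
    sub <- arr[ys, xs, zs, drop = FALSE]
    hit <- d2 <= r^2
    sub[hit] <- pmax(sub[hit], intensities[k])
    arr[ys, xs, zs] <- sub
  }
  arr
}

# filled disks in 2D; centers = matrix with columns x, y (um)
rasterize_disks <- function(dims, px, centers, radii, intensities) {
  img <- matrix(0, dims[1], dims[2])
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]; r <- radii[k]
    ys <- max(1, floor((cy - r) / px)):min(dims[1], ceiling((cy + r) / px + 1))
    xs <- max(1, floor((cx - r) / px)):min(dims[2], ceiling((cx + r) / px + 1))
    d2 <- outer(((ys - 0.5) * px - cy)^2, ((xs - 0.5) * px - cx)^2, `+`)
    sub <- img[ys, xs, drop = FALSE]
    hit <- d2 <= r^2
    sub[hit] <- pmax(sub[hit], intensities[k])
    img[ys, xs] <- sub
  }
  img
}

# annuli (r_in < d <= r_out), used for LAMP-1 rings around phagosomes
rasterize_rings <- function(dims, px, centers, r_in, r_out, intensities) {
  img <- matrix(0, dims[1], dims[2])
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]; ro <- r_out[k]
    ys <- max(1, floor((cy - ro) / px)):min(dims[1], ceiling((cy + ro) / px + 1))
    xs <- max(1, floor((cx - ro) / px)):min(dims[2], ceiling((cx + ro) / px + 1))
    d2 <- outer(((ys - 0.5) * px - cy)^2, ((xs - 0.5) * px - cx)^2, `+`)
    sub <- img[ys, xs, drop = FALSE]
    hit <- d2 <= ro^2 & d2 > r_in[k]^2
    sub[hit] <- pmax(sub[hit], intensities[k])
    img[ys, xs] <- sub
  }
  img
}

# point-to-segment distance for a grid of pixel centres
seg_dist2 <- function(py, pxx, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  tx <- ((pxx - a[1]) * abx + (py - a[2]) * aby) / len2
  tx <- pmin(pmax(tx, 0), 1)
  (pxx - (a[1] + tx * abx))^2 + (py - (a[2] + tx * aby))^2
}

# thick anti-aliased polylines: per-pixel coverage ramps over one pixel at
# the edge of the half-width band
rasterize_polylines <- function(dims, px, polylines, width_um, intensity) {
  img <- matrix(0, dims[1], dims[2])
  hw <- width_um / 2
  pad <- hw + px
  for (b in seq_along(polylines)) {
    pts <- polylines[[b]]
    for (s in seq_len(nrow(pts) - 1)) {
      a <- pts[s, ]; bb <- pts[s + 1, ]
      ys <- max(1, floor((min(a[2], bb[2]) - pad) / px)):
        min(dims[1], ceiling((max(a[2], bb[2]) + pad) / px + 1))
      xs <- max(1, floor((min(a[1], bb[1]) - pad) / px)):
        min(dims[2], ceiling((max(a[1], bb[1]) + pad) / px + 1))
      gy <- matrix((ys - 0.5) * px, length(ys), length(xs))
      gx <- matrix((xs - 0.5) * px, length(ys), length(xs), byrow = TRUE)
      d <- sqrt(seg_dist2(gy, gx, a, bb))
      cov <- pmin(pmax((hw + px / 2 - d) / px, 0), 1)
      img[ys, xs] <- pmax(img[ys, xs], intensity * cov)
    }
  }
  img
}

# additive Gaussian noise + optional Poisson resampling; caller seeds the RNG
add_noise <- function(arr, config) {
  d <- dim(arr)
  n <- length(arr)
  if (config$poisson_scaling > 0) {
    lam <- pmax(as.numeric(arr), 0) * config$poisson_scaling
    arr[] <- rpois(n, lam) / config$poisson_scaling
  }
  if (config$gaussian_sd > 0) {
    arr[] <- arr + rnorm(n, 0, config$gaussian_sd)
  }
  arr[] <- pmax(as.numeric(arr), 0)
  dim(arr) <- d
  arr
}
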