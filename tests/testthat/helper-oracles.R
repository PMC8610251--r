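# Independent oracles used across the suite. These deliberately avoid the
# package's own labelling/segmentation code paths.

# brute-force flood fill labelling (queue-based), 26-connectivity in 3D /
# 8 in 2D; for masks up to ~32^3
flood_fill_label <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(d, 1)
  m <- array(mask, d)
  lab <- array(0L, d)
  nxt <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k] || lab[i, j, k] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j, k))
    lab[i, j, k] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        q <- p + c(di, dj, dk)
        if (any(q < 1) || any(q > d)) next
        if (m[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# voxel-centre-in-sphere rasterisation from ground truth (x, y, z in um)
rasterize_truth_spheres <- function(truth, dims, vs) {
  yc <- (seq_len(dims[1]) - 0.5) * vs[2]
  xc <- (seq_len(dims[2]) - 0.5) * vs[1]
  zc <- (seq_len(dims[3]) - 0.5) * vs[3]
  out <- array(FALSE, dims)
  for (k in seq_len(nrow(truth))) {
    d2 <- outer(outer((yc - truth$y_um[k])^2, (xc - truth$x_um[k])^2, `+`),
                (zc - truth$z_um[k])^2, `+`)
    out <- out | (d2 <= truth$radius_um[k]^2)
  }
  out
}

# number of voxel centres inside one sphere
sphere_voxel_volume <- function(center, r, dims, vs) {
  tr <- tibble::tibble(x_um = center[1], y_um = center[2], z_um = center[3],
                       radius_um = r)
  sum(rasterize_truth_spheres(tr, dims, vs)) * prod(vs)
}

# reference one-way ANOVA + Tukey HSD from first principles
anova_tukey_oracle <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  ms_within <- ss_within / df2
  F <- (ss_between / df1) / ms_within
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  pw <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(ms_within / 2 * (1 / n[i] + 1 / n[j])) # Tukey-Kramer
    q <- abs(means[j] - means[i]) / se
    stats::ptukey(q, k, df2, lower.tail = FALSE)
  })
  list(F = F, p = p, tukey_p = pw,
       pair_names = apply(pairs, 2, function(ij) {
         paste(names(groups)[ij[2]], names(groups)[ij[1]], sep = "-")
       }))
}

quiet_threshold <- function(image, cell, ...) {
  suppressWarnings(cytosolic_threshold(image, cell, ...))
}
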