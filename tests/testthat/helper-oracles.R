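# Independent brute-force oracles, kept deliberately naive: plain R loops
# and first-principles definitions, sharing no code with the package
# internals they check.

# 26-connected component labeling by BFS flood fill over explicit indices.
oracle_label <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k] || labels[i, j, k] > 0) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j, k), ncol = 3)
    labels[i, j, k] <- nxt
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(nb))) {
        w <- v + unlist(nb[r, ])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0) {
          labels[w[1], w[2], w[3]] <- nxt
          queue <- rbind(queue, w)
        }
      }
    }
  }
  labels
}

# Exhaustive voxel-by-voxel isocontour delineation: threshold, exclusion,
# flood-fill components, then prior-intersection or minimum-size filter.
oracle_delineate <- function(vals, threshold, exclusion = NULL, prior = NULL,
                             min_vox = 1L) {
  above <- vals > threshold
  if (!is.null(exclusion)) above <- above & !exclusion
  if (!any(above)) return(array(FALSE, dim(vals)))
  labels <- oracle_label(above)
  keep <- integer(0)
  for (l in seq_len(max(labels))) {
    inl <- labels == l
    ok <- if (!is.null(prior)) any(inl & prior) else sum(inl) >= min_vox
    if (ok) keep <- c(keep, l)
  }
  array(labels %in% keep & above, dim(vals))
}

# O(n * m) exact Euclidean distance transform on tiny grids.
oracle_edt <- function(mask, spacing) {
  d <- dim(mask)
  out <- array(0, d)
  outside <- which(!mask, arr.ind = TRUE)
  inside <- which(mask, arr.ind = TRUE)
  if (nrow(inside) == 0 || nrow(outside) == 0) return(out)
  ow <- sweep(outside, 2, spacing, `*`)
  for (r in seq_len(nrow(inside))) {
    iw <- inside[r, ] * spacing
    d2 <- (ow[, 1] - iw[1])^2 + (ow[, 2] - iw[2])^2 + (ow[, 3] - iw[3])^2
    out[inside[r, 1], inside[r, 2], inside[r, 3]] <- sqrt(min(d2))
  }
  out
}

# Separable Gaussian smoothing written independently with stats::filter-free
# per-line loops: normalized kernel truncated at 4 sigma, zero padding.
oracle_smooth <- function(x, spacing, fwhm) {
  d <- dim(x)
  for (axis in 1:3) {
    s <- (fwhm / (2 * sqrt(2 * log(2)))) / spacing[axis]
    if (s < 1e-8) next
    r <- ceiling(4 * s)
    kern <- exp(-0.5 * ((-r:r) / s)^2)
    kern <- kern / sum(kern)
    out <- array(0, d)
    n <- d[axis]
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      pos <- c(i, j, k)[axis]
      acc <- 0
      for (t in max(-r, 1 - pos):min(r, n - pos)) {
        w <- c(i, j, k); w[axis] <- pos + t
        acc <- acc + kern[t + r + 1] * x[w[1], w[2], w[3]]
      }
      out[i, j, k] <- acc
    }
    x <- out
  }
  x
}

# Random logical mask with set density p.
random_mask <- function(dims, p = 0.4) array(runif(prod(dims)) < p, dims)

# Small phantom used across tests: 64 mm per side keeps runtimes low while
# leaving room for brain, tumor and background ROI.
small_spec <- function(..., grid = c(48, 48, 48), radius_mm = 12,
                       contrast = 3, noise_sd = 0, margin_mm = 0) {
  phantom_spec(grid_shape = grid, spacing = c(2, 2, 2),
               tumor_foci = list(list(center = c(0.64, 0.5, 0.5) * grid,
                                      radius_mm = radius_mm,
                                      contrast = contrast,
                                      margin_mm = margin_mm)),
               noise_sd = noise_sd, ...)
}

# Solid sphere mask on a volume_image grid (world-coordinate construction,
# independent of the phantom generator).
sphere_mask <- function(template, center_mm, radius_mm) {
  d <- dim(template$values)
  w1 <- template$origin[1] + (seq_len(d[1]) - 1) * template$spacing[1]
  w2 <- template$origin[2] + (seq_len(d[2]) - 1) * template$spacing[2]
  w3 <- template$origin[3] + (seq_len(d[3]) - 1) * template$spacing[3]
  d2 <- outer(outer((w1 - center_mm[1])^2, (w2 - center_mm[2])^2, `+`),
              (w3 - center_mm[3])^2, `+`)
  volume_image(d2 <= radius_mm^2, template$spacing, template$origin)
}
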