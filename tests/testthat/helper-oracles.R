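# Brute-force oracles, independent of the package's C++ implementations.

# 8-connected components by recursive flood fill (depth-first with an
# explicit stack); returns an integer matrix of component ids, 0 = background
flood_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  comp <- matrix(0L, h, w)
  nid <- 0L
  for (c0 in seq_len(w)) {
    for (r0 in seq_len(h)) {
      if (!mask[r0, c0] || comp[r0, c0] > 0L) next
      nid <- nid + 1L
      stack <- list(c(r0, c0))
      comp[r0, c0] <- nid
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr < 1 || rr > h || cc < 1 || cc > w) next
          if (mask[rr, cc] && comp[rr, cc] == 0L) {
            comp[rr, cc] <- nid
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  comp
}

# boundary pixels: in the mask with a 4-neighbour outside the mask (pixels
# beyond the frame edge count as outside)
boundary_set <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (c in seq_len(w)) {
    for (r in seq_len(h)) {
      if (!mask[r, c]) next
      nb <- c(if (r > 1) mask[r - 1, c] else FALSE,
              if (r < h) mask[r + 1, c] else FALSE,
              if (c > 1) mask[r, c - 1] else FALSE,
              if (c < w) mask[r, c + 1] else FALSE)
      if (!all(nb)) out[r, c] <- TRUE
    }
  }
  out
}

# hole-free random blob: union of a few disks, then background-connectivity
# hole filling
random_blob_mask <- function(h = 20, w = 20, n_disks = 3, rmin = 2, rmax = 4) {
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(n_disks)) {
    r0 <- runif(1, rmax + 1, h - rmax)
    c0 <- runif(1, rmax + 1, w - rmax)
    rad <- runif(1, rmin, rmax)
    rr <- row(mask); cc <- col(mask)
    mask <- mask | ((rr - r0)^2 + (cc - c0)^2 <= rad^2)
  }
  # fill holes: anything not 4-connected to the border background is
  # foreground (4-connectivity is the dual of the 8-connected foreground)
  !flood4_outside(!mask, h, w)
}

# fill a closed contour: contour pixels plus everything not reachable from
# the frame border through non-contour pixels (4-connected background fill)
fill_contour <- function(points, h, w) {
  on_contour <- matrix(FALSE, h, w)
  on_contour[points] <- TRUE
  outside <- flood4_outside(!on_contour, h, w)
  !outside
}

flood4_outside <- function(open, h, w) {
  outside <- matrix(FALSE, h, w)
  stack <- list()
  for (r in seq_len(h)) for (c in c(1L, w))
    if (open[r, c] && !outside[r, c]) { outside[r, c] <- TRUE; stack[[length(stack) + 1L]] <- c(r, c) }
  for (c in seq_len(w)) for (r in c(1L, h))
    if (open[r, c] && !outside[r, c]) { outside[r, c] <- TRUE; stack[[length(stack) + 1L]] <- c(r, c) }
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- p[1] + d[1]; cc <- p[2] + d[2]
      if (rr < 1 || rr > h || cc < 1 || cc > w) next
      if (open[rr, cc] && !outside[rr, cc]) {
        outside[rr, cc] <- TRUE
        stack[[length(stack) + 1L]] <- c(rr, cc)
      }
    }
  }
  outside
}

# compact study conditions for fast tests: same geometry scaled down
small_video_config <- function(n_frames = 3, seed = 1, noise_sigma = 0.05,
                               n_blob_artifacts = 2, height = 50L,
                               width = 192L, ...) {
  synthetic_config(height = height, width = width, n_frames = n_frames,
                   noise_sigma = noise_sigma,
                   n_blob_artifacts = n_blob_artifacts, seed = seed, ...)
}

small_pipeline_opts <- list(K = 400L, smooth_sigma = 0.5)

raster_disk <- function(radius, pad = 5) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  m <- matrix(FALSE, n, n)
  (row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2
}
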