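test_that("Lab conversion follows the CIELAB conventions", {
  black <- array(0, c(2, 2, 3))
  expect_equal(rgb_to_lab(black)[1, 1, 1], 0)
  gray <- array(0.5, c(2, 2, 3))
  lab <- rgb_to_lab(gray)
  expect_equal(lab[1, 1, 2], 0, tolerance = 1e-6)
  expect_equal(lab[1, 1, 3], 0, tolerance = 1e-6)
  expect_error(rgb_to_lab(matrix(0, 2, 2)), "3")
})

test_that("colour and spatial distances are Euclidean and symmetric", {
  p <- lab_pixel(10, 3, 4, x = 0, y = 0)
  q <- lab_pixel(13, 7, 4, x = 3, y = 4)
  expect_equal(color_distance(p, p), 0)
  expect_equal(color_distance(p, q), 5)
  expect_equal(color_distance(p, q), color_distance(q, p))
  expect_equal(spatial_distance(p, p), 0)
  expect_equal(spatial_distance(p, q), 5)
  expect_equal(spatial_distance(p, q), spatial_distance(q, p))
})

test_that("the combined metric normalises colour by m and space by S", {
  expect_equal(combined_distance(0, 0, m = 10, S = 5), 0)
  expect_equal(combined_distance(10, 0, m = 10, S = 5), 1)
  S <- 7.3
  expect_equal(combined_distance(10, S, m = 10, S = S), sqrt(2))
  expect_error(combined_distance(1, 1, m = 0, S = 5), "m")
  expect_error(combined_distance(1, 1, m = 10, S = -1), "S")
})

test_that("pre-grouping a uniform frame yields near-equal compact tiles", {
  f <- matrix(0.5, 40, 40)
  part <- pregroup(f, K = 4, smooth_sigma = 0)
  expect_s3_class(part, "superpixel_partition")
  sizes <- tabulate(part$labels, part$K)
  expect_true(all(sizes > 0))
  expect_equal(sum(sizes), 1600)
  S2 <- part$grid_spacing^2
  expect_true(all(abs(sizes - 1600 / part$K) <= 2 * S2))
})

test_that("every pixel belongs to exactly one non-empty group", {
  cfg <- small_video_config(n_frames = 1, seed = 6)
  f <- generate_video(cfg)$video$frames[[1]]
  part <- pregroup(f, K = 150)
  expect_true(all(part$labels >= 1 & part$labels <= part$K))
  expect_true(all(tabulate(part$labels, part$K) > 0))
  expect_equal(length(part$labels), length(f))
})

test_that("superpixels do not straddle a sharp high-contrast boundary", {
  f <- matrix(0.05, 40, 60)
  f[, 31:60] <- 0.95
  part <- pregroup(f, K = 24, smooth_sigma = 0)
  for (k in seq_len(part$K)) {
    cols <- col(part$labels)[part$labels == k]
    expect_false(min(cols) <= 29 && max(cols) >= 32,
                 label = sprintf("group %d spans the step edge", k))
  }
})

test_that("groups are spatially connected after enforcement", {
  cfg <- small_video_config(n_frames = 1, seed = 7)
  f <- generate_video(cfg)$video$frames[[1]]
  part <- pregroup(f, K = 120)
  for (k in sample.int(part$K, 20)) {
    comp <- flood_components(part$labels == k)
    expect_equal(max(comp), 1L)
  }
})

test_that("the SLIC objective does not increase with more iterations", {
  cfg <- small_video_config(n_frames = 1, seed = 8)
  f <- generate_video(cfg)$video$frames[[1]]
  energy <- function(part, lab) {
    m <- 10; S <- part$grid_spacing
    lv <- cbind(as.vector(lab[, , 1]), as.vector(lab[, , 2]),
                as.vector(lab[, , 3]),
                as.vector(row(part$labels)), as.vector(col(part$labels)))
    tot <- 0
    for (k in seq_len(part$K)) {
      sel <- as.vector(part$labels == k)
      ctr <- colMeans(lv[sel, , drop = FALSE])
      d <- sweep(lv[sel, , drop = FALSE], 2, ctr)
      tot <- tot + sum((d[, 1]^2 + d[, 2]^2 + d[, 3]^2) / m^2 +
                         (d[, 4]^2 + d[, 5]^2) / S^2)
    }
    tot
  }
  lab <- rgb_to_lab(corneaseg:::as_rgb_array(f))
  # compare the raw assignment (before connectivity enforcement, which is
  # outside the clustering objective)
  e1 <- energy(pregroup(f, K = 100, n_iter = 1, smooth_sigma = 0,
                        enforce_connectivity = FALSE), lab)
  e10 <- energy(pregroup(f, K = 100, n_iter = 10, smooth_sigma = 0,
                         enforce_connectivity = FALSE), lab)
  expect_lte(e10, e1 * 1.02)
})

test_that("boundary recall matches a reference SLIC implementation", {
  cfg <- small_video_config(n_frames = 1, seed = 9, noise_sigma = 0.03,
                            n_blob_artifacts = 0)
  gv <- generate_video(cfg)
  f <- gv$video$frames[[1]]
  gt <- gv$truth$masks[[1]]
  true_bnd <- which(boundary_set(gt), arr.ind = TRUE)

  part_bnd <- function(labels) {
    h <- nrow(labels); w <- ncol(labels)
    b <- matrix(FALSE, h, w)
    b[-h, ] <- b[-h, ] | labels[-h, ] != labels[-1, ]
    b[, -w] <- b[, -w] | labels[, -w] != labels[, -1]
    b
  }
  recall <- function(labels, tol = 2L) {
    bnd <- which(part_bnd(labels), arr.ind = TRUE)
    hits <- vapply(seq_len(nrow(true_bnd)), function(i) {
      any(abs(bnd[, 1] - true_bnd[i, 1]) <= tol &
            abs(bnd[, 2] - true_bnd[i, 2]) <= tol)
    }, logical(1))
    mean(hits)
  }

  mine <- pregroup(f, K = 150, m = 10, smooth_sigma = 0)
  r_mine <- recall(mine$labels)

  td <- withr::local_tempdir()
  write.table(f, file.path(td, "f.csv"), row.names = FALSE,
              col.names = FALSE, sep = ",")
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from skimage.segmentation import slic\n",
    "f = np.loadtxt(r'%s', delimiter=',')\n",
    "img = np.stack([f]*3, axis=-1)\n",
    "seg = slic(img, n_segments=150, compactness=10, sigma=0,\n",
    "           start_label=1, channel_axis=-1)\n",
    "np.savetxt(r'%s', seg, fmt='%%d', delimiter=',')\n"),
    file.path(td, "f.csv"), file.path(td, "seg.csv"))
  writeLines(script, file.path(td, "slic_ref.py"))
  status <- system2("python", file.path(td, "slic_ref.py"))
  expect_equal(status, 0L)
  seg <- as.matrix(read.table(file.path(td, "seg.csv"), sep = ","))
  r_ref <- recall(matrix(as.integer(seg), nrow(f), ncol(f)))
  expect_lt(abs(r_mine - r_ref), 0.05)
})

test_that("group counts outside the valid range are rejected", {
  f <- matrix(0.5, 10, 10)
  expect_error(pregroup(f, K = 1), "K")
  expect_error(pregroup(f, K = 101), "K")
})
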