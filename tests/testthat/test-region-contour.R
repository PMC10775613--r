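test_that("connected regions match a flood-fill oracle on random label maps", {
  set.seed(31)
  for (rep in 1:15) {
    lm <- matrix(sample.int(3, 400, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                 20, 20)
    regs <- connected_regions(lm, min_area = 1)
    n_oracle <- 0L
    for (lab in sort(unique(as.vector(lm))))
      n_oracle <- n_oracle + max(flood_components(lm == lab))
    expect_equal(nrow(regs), n_oracle)
    expect_equal(sum(regs$area_S), 400)
  }
})

test_that("a block on background yields two regions; tiny ones are dropped", {
  lm <- matrix(1L, 150, 576)
  lm[50:59, 100:109] <- 2L
  regs <- connected_regions(lm, min_area = 1)
  expect_equal(nrow(regs), 2L)
  expect_setequal(regs$area_S, c(100L, 150L * 576L - 100L))
  # 3x3 block is below the default 50 px minimum at this frame size
  lm2 <- matrix(1L, 150, 576)
  lm2[10:12, 10:12] <- 2L
  regs2 <- connected_regions(lm2)
  expect_equal(nrow(regs2), 1L)
  expect_equal(regs2$label, 1L)
  expect_error(connected_regions(matrix(integer(0), 0, 0)), "empty")
})

test_that("region statistics satisfy the shape-factor identity", {
  lm <- matrix(1L, 60, 60)
  lm[20:40, 15:45] <- 2L
  regs <- connected_regions(lm, min_area = 1)
  expect_equal(regs$shape_factor_Fs,
               regs$perimeter_L^2 / (4 * pi * regs$area_S))
  expect_true(all(regs$area_S > 0))
  expect_true(all(regs$perimeter_L > 0))
})

test_that("shape factor approaches its continuum values for simple shapes", {
  expect_equal(shape_factor(raster_disk(50)), 1, tolerance = 0.1)
  sq <- matrix(FALSE, 60, 60); sq[6:55, 6:55] <- TRUE
  expect_equal(shape_factor(sq), 4 / pi, tolerance = 0.1 * 4 / pi)
  # translation invariance
  sq2 <- matrix(FALSE, 60, 60); sq2[2:51, 9:58] <- TRUE
  expect_equal(shape_factor(sq), shape_factor(sq2))
  expect_error(shape_factor(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 10, 10); two[1, 1] <- TRUE; two[9, 9] <- TRUE
  expect_error(shape_factor(two), "single")
})

test_that("shape factor grows without bound for elongated rectangles", {
  fs_rect <- vapply(c(10, 20, 40, 80), function(n) {
    m <- matrix(FALSE, 5, n + 4)
    m[3, 3:(n + 2)] <- TRUE
    shape_factor(m)
  }, numeric(1))
  expect_true(all(diff(fs_rect) > 0))
  expect_gt(fs_rect[4] / fs_rect[1], 4)  # roughly proportional to length
})

test_that("corneal region selection follows the shape-factor prior", {
  regs <- data.frame(label = 1:3, component_id = 1:3,
                     area_S = c(5000, 12000, 800),
                     perimeter_L = c(280, 1230, 630),
                     shape_factor_Fs = c(1.2, 9.4, 40),
                     top_border_frac = c(0, 0, 0))
  expect_equal(select_corneal_region(regs, 10)$label, 2L)
  # a single region is returned regardless of its Fs
  expect_equal(select_corneal_region(regs[3, ], 10)$label, 3L)
  # exact ties break towards the larger area
  tie <- data.frame(label = 1:2, component_id = 1:2,
                    area_S = c(100, 500), perimeter_L = c(1, 1),
                    shape_factor_Fs = c(9, 11), top_border_frac = c(0, 0))
  expect_equal(select_corneal_region(tie, 10)$area_S, 500)
  # background suppression: top-border components are not candidates
  bg <- data.frame(label = 1:2, component_id = 1:2,
                   area_S = c(40000, 12000), perimeter_L = c(1200, 1230),
                   shape_factor_Fs = c(10.01, 9.4),
                   top_border_frac = c(0.95, 0))
  expect_equal(select_corneal_region(bg, 10)$label, 2L)
  expect_error(select_corneal_region(bg[0, ], 10), "no candidate")
  expect_error(select_corneal_region(bg[1, ], 10), "top border")
})

test_that("contour extraction matches the brute-force boundary set", {
  set.seed(32)
  for (rep in 1:10) {
    mask <- random_blob_mask(20, 20)
    if (!any(mask)) next
    comp <- flood_components(mask)
    mask <- comp == 1  # one component at a time
    ct <- extract_contour(mask)
    expect_setequal(
      paste(ct[, "row"], ct[, "col"]),
      paste(which(boundary_set(mask), arr.ind = TRUE)[, 1],
            which(boundary_set(mask), arr.ind = TRUE)[, 2]))
    # consecutive points (and the closing pair) are 8-connected
    nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
    steps <- pmax(abs(nxt[, 1] - ct[, 1]), abs(nxt[, 2] - ct[, 2]))
    expect_true(all(steps <= 1))
  }
})

test_that("contours handle degenerate and tiny masks", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  ct <- extract_contour(one)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct[1, ], c(row = 3L, col = 3L))
  blk <- matrix(FALSE, 5, 5); blk[2:4, 2:4] <- TRUE
  ct3 <- extract_contour(blk)
  expect_equal(nrow(unique(ct3)), 8L)  # all but the centre pixel
  expect_error(extract_contour(matrix(FALSE, 3, 3)), "empty")
})

test_that("tracing and filling a contour reproduces the mask", {
  set.seed(33)
  for (rep in 1:8) {
    mask <- random_blob_mask(25, 25, n_disks = 2)
    comp <- flood_components(mask)
    mask <- comp == 1
    ct <- extract_contour(mask)
    refilled <- fill_contour(unique(ct), nrow(mask), ncol(mask))
    expect_identical(refilled, mask)
  }
})
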