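test_that("initialisation is deterministic and warm starts copy exactly", {
  cfg <- train_config(seed = 42)
  a <- init_network(cfg)
  b <- init_network(cfg)
  expect_identical(a, b)
  warm <- init_network(cfg, warm = a)
  expect_identical(warm, a)
  cfg2 <- train_config(seed = 43)
  expect_false(identical(init_network(cfg2), a))
  # incompatible layer spec (different class count) is refused
  cfg3 <- train_config(seed = 42, n_classes = 3)
  other <- init_network(cfg3)
  expect_error(init_network(cfg, warm = other), "incompatible")
  expect_error(init_network(cfg, warm = list()), "network_state")
})

test_that("the network is fully convolutional and outputs softmax maps", {
  cfg <- train_config(seed = 1)
  st <- init_network(cfg)
  fm <- forward(st, matrix(runif(64 * 48), 64, 48))
  expect_equal(dim(fm), c(64L, 48L, 4L))
  sums <- apply(fm, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
  expect_true(all(fm >= 0))
  # odd sizes preserved too (stride-1, same padding)
  fm2 <- forward(st, matrix(runif(33 * 17), 33, 17))
  expect_equal(dim(fm2), c(33L, 17L, 4L))
})

test_that("the network handles the native frame geometry", {
  cfg <- train_config(seed = 1)
  st <- init_network(cfg)
  fm <- forward(st, matrix(runif(150 * 576), 150, 576))
  expect_equal(dim(fm), c(150L, 576L, 4L))
})

test_that("argmax labelling breaks ties towards the lowest channel", {
  fm <- array(0.1, c(1, 1, 4))
  fm[1, 1, ] <- c(0.1, 0.7, 0.1, 0.1)
  expect_equal(assign_labels(fm)[1, 1], 2L)
  fm[1, 1, ] <- rep(0.25, 4)
  expect_equal(assign_labels(fm)[1, 1], 1L)
  fm <- array(runif(10 * 8 * 4), c(10, 8, 4))
  lm <- assign_labels(fm)
  expect_true(all(lm %in% 1:4))
  expect_equal(dim(lm), c(10L, 8L))
})

test_that("superpixel majority refinement is modal, tie-stable and idempotent", {
  part <- structure(list(labels = matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 2, 3),
                         K = 2L, grid_spacing = sqrt(3)),
                    class = "superpixel_partition")
  lm <- matrix(c(1L, 1L, 2L, 3L, 3L, 4L), 2, 3)
  ref <- refine_labels(lm, part)
  expect_equal(as.vector(ref), c(1L, 1L, 1L, 3L, 3L, 3L))
  # tie among [1, 1, 2, 2] -> lowest label value
  part2 <- structure(list(labels = matrix(1L, 2, 2), K = 1L,
                          grid_spacing = 2), class = "superpixel_partition")
  lm2 <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  expect_true(all(refine_labels(lm2, part2) == 1L))
  # idempotence on random label maps
  set.seed(99)
  for (i in 1:5) {
    labs <- matrix(sample.int(4, 60, replace = TRUE), 6, 10)
    prt <- structure(list(labels = matrix(rep(1:5, each = 12), 6, 10),
                          K = 5L, grid_spacing = sqrt(12)),
                     class = "superpixel_partition")
    once <- refine_labels(labs, prt)
    expect_identical(refine_labels(once, prt), once)
  }
  expect_error(refine_labels(matrix(1L, 3, 3), part), "shape")
})

test_that("cross-entropy matches its closed forms", {
  h <- 6; w <- 5; q <- 4
  target <- matrix(sample.int(q, h * w, replace = TRUE), h, w)
  onehot <- array(0, c(h, w, q))
  for (i in seq_len(h)) for (j in seq_len(w)) onehot[i, j, target[i, j]] <- 1
  expect_equal(cross_entropy_loss(onehot, target), 0, tolerance = 1e-10)
  unif <- array(1 / q, c(h, w, q))
  expect_equal(cross_entropy_loss(unif, target), log(4), tolerance = 1e-12)
  rnd <- array(runif(h * w * q), c(h, w, q))
  rnd <- rnd / array(rep(apply(rnd, c(1, 2), sum), q), c(h, w, q))
  expect_gte(cross_entropy_loss(rnd, target), 0)
})

test_that("shape-factor loss targets the region closest to C", {
  # a disk has Fs ~ 1, so the loss to C = 10 is ~ 9
  lm <- matrix(1L, 39, 39)
  lm[raster_disk(12, 7)] <- 2L
  # background touches the borders and is very non-circular; the disk wins
  sfl <- shape_factor_loss(lm, C_target = 10)
  expect_equal(as.numeric(sfl), 9, tolerance = 0.5)
  expect_false(attr(sfl, "degenerate"))
  # perfect match gives zero
  expect_equal(as.numeric(shape_factor_loss(lm, C_target = attr(sfl, "Fs"))),
               0, tolerance = 1e-12)
  # translation invariance
  lm2 <- matrix(1L, 39, 39)
  lm2[raster_disk(12, 7)[c(6:39, 1:5), ]] <- 2L
  expect_equal(as.numeric(shape_factor_loss(lm2, 10)), as.numeric(sfl))
  # constant map flags degeneracy but still returns a value
  const <- matrix(2L, 20, 20)
  dg <- shape_factor_loss(const, 10)
  expect_true(attr(dg, "degenerate"))
  expect_true(is.finite(as.numeric(dg)))
})

test_that("the combined loss is the weighted sum of its terms", {
  h <- 10; w <- 20
  lm <- matrix(1L, h, w); lm[4:7, 5:16] <- 2L
  fm <- array(runif(h * w * 4), c(h, w, 4))
  fm <- fm / array(rep(apply(fm, c(1, 2), sum), 4), c(h, w, 4))
  cfg <- train_config(alpha = 0.1)
  tot <- total_loss(fm, lm, lm, cfg)
  expect_equal(as.numeric(tot),
               attr(tot, "ce") + 0.1 * attr(tot, "fs_loss"))
  expect_gte(as.numeric(tot), attr(tot, "ce"))
  cfg0 <- train_config(alpha = 0)
  expect_equal(as.numeric(total_loss(fm, lm, lm, cfg0)),
               cross_entropy_loss(fm, lm))
})

test_that("frame training is seeded-deterministic and bounded by the budget", {
  cfg <- small_video_config(n_frames = 1, seed = 21)
  f <- generate_video(cfg)$video$frames[[1]]
  part <- pregroup(f, K = 300, smooth_sigma = 0.5)
  tc <- train_config(seed = 7)
  a <- train_frame(f, part, init = NULL, cfg = tc, max_epochs = 8)
  b <- train_frame(f, part, init = NULL, cfg = tc, max_epochs = 8)
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$labels, b$labels)
  expect_lte(a$epochs_used, 8)
  expect_lte(length(a$loss_history), 8)
})

test_that("training separates the corneal band from the background", {
  cfg <- small_video_config(n_frames = 1, seed = 22, noise_sigma = 0,
                            n_blob_artifacts = 0)
  gv <- generate_video(cfg)
  f <- gv$video$frames[[1]]
  gt <- gv$truth$masks[[1]]
  part <- pregroup(f, K = 300, smooth_sigma = 0.5)
  tc <- train_config(seed = 1)
  res <- train_frame(f, part, init = NULL, cfg = tc)
  modal <- function(x) as.integer(names(which.max(table(x))))
  expect_false(modal(res$labels[gt]) == modal(res$labels[!gt]))
})

test_that("both training paths compute the same loss trajectory", {
  # the compiled path (float) against the reference R path (double)
  cfg <- small_video_config(n_frames = 1, seed = 23, height = 30, width = 80)
  f <- generate_video(cfg)$video$frames[[1]]
  part <- pregroup(f, K = 60, smooth_sigma = 0.5)
  tc_fast <- train_config(seed = 3)
  tc_ref <- train_config(seed = 3, shape_loss_grad = TRUE, alpha = 0)
  tc_fast$alpha <- 0
  a <- train_frame(f, part, init = NULL, cfg = tc_fast, max_epochs = 3)
  b <- train_frame(f, part, init = NULL, cfg = tc_ref, max_epochs = 3)
  expect_equal(a$loss_history, b$loss_history, tolerance = 1e-3)
})

test_that("warm training needs no more epochs than a cold start", {
  cfg <- small_video_config(n_frames = 2, seed = 24)
  gv <- generate_video(cfg)
  tc <- train_config(seed = 5)
  p1 <- pregroup(gv$video$frames[[1]], K = 400, smooth_sigma = 0.5)
  p2 <- pregroup(gv$video$frames[[2]], K = 400, smooth_sigma = 0.5)
  cold1 <- train_frame(gv$video$frames[[1]], p1, init = NULL, cfg = tc)
  warm2 <- train_frame(gv$video$frames[[2]], p2, init = cold1$state, cfg = tc)
  cold2 <- train_frame(gv$video$frames[[2]], p2, init = NULL, cfg = tc)
  eff <- function(r) if (is.na(r$epochs_to_threshold)) r$epochs_used + 1L else
    r$epochs_to_threshold
  expect_lte(eff(warm2), eff(cold2))
})
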