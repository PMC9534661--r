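test_that("bounding-box arithmetic follows the half-open convention", {
  v <- array(0, c(12, 12, 12))
  m <- array(0L, c(12, 12, 12))
  m[6, 6, 6] <- 1L                     # 0-based voxel (5,5,5)
  cr <- crop_to_bbox(v, m, margin = 0)
  expect_equal(cr$record$bbox_low, c(5L, 5L, 5L))
  expect_equal(cr$record$bbox_high, c(6L, 6L, 6L))
  expect_equal(dim(cr$volume), c(1L, 1L, 1L))
  # span 2..10 (0-based) with margin 2 clips to the full 12-extent axis
  m2 <- array(0L, c(12, 12, 12))
  m2[3:11, 6, 6] <- 1L
  cr2 <- crop_to_bbox(v, m2, margin = 2)
  expect_equal(cr2$record$bbox_low[1], 0L)
  expect_equal(cr2$record$bbox_high[1], 12L)
  # margin larger than the volume saturates to a full-volume crop
  cr3 <- crop_to_bbox(v, m, margin = 100)
  expect_equal(dim(cr3$volume), c(12L, 12L, 12L))
  expect_error(crop_to_bbox(v, m * 0L, margin = 1), "empty")
})

test_that("restore after crop is the identity on the box interior", {
  set.seed(21)
  for (r in 1:100) {
    d <- sample(6:14, 3, replace = TRUE)
    m <- array(as.integer(runif(prod(d)) < 0.15), d)
    if (sum(m) == 0) m[sample(prod(d), 1)] <- 1L
    margin <- sample(0:3, 1)
    cr <- crop_to_bbox(m, m, margin = margin)
    back <- restore_to_grid(cr$volume, cr$record)
    expect_identical(back, m)          # every foreground coordinate kept
  }
  # full-volume crop restores identically
  m <- array(1L, c(4, 4, 4))
  cr <- crop_to_bbox(m, m, margin = 2)
  expect_identical(restore_to_grid(cr$volume, cr$record), m)
  expect_error(restore_to_grid(array(0L, c(2, 2, 2)),
                               crop_to_bbox(m, m, 0)$record), "shape")
})

test_that("coarse stage restores resolution and flags missing arteries", {
  ds <- generate_phantom_dataset(1, seed = 3, shape = c(32, 32, 32),
                                 spec_ranges = list(noise_sd = c(0, 0)))
  ph <- ds$phantoms[[1]]
  # block-average downsampling dilutes thin branches, so the coarse
  # stage thresholds permissively (high recall is its whole job)
  thr <- threshold_segmenter(112.5)
  cm <- coarse_segment(ph$volume, thr, down_factor = 2)
  expect_equal(dim(cm), dim(ph$volume))
  # a threshold net recovers most lumen voxels through the down/up trip
  cc <- confusion_counts(cm, ph$truth$mask)
  expect_gt(sensitivity(cc), 0.9)
  # all-background volume yields the distinct no-artery outcome
  flat <- array(0, c(8, 8, 8))
  cm0 <- coarse_segment(flat, threshold_segmenter(175), down_factor = 2)
  expect_true(isTRUE(attr(cm0, "no_artery")))
  expect_true(all(cm0 == 0L))
})

test_that("c2f composition: oracle nets, containment, and metadata", {
  ds <- generate_phantom_dataset(1, seed = 5, shape = c(32, 32, 32))
  ph <- ds$phantoms[[1]]
  gold <- ph$truth$mask
  thr <- threshold_segmenter(175)
  out <- c2f_segment(ph$volume, thr, thr, down_factor = 2, margin = 4)
  expect_equal(dim(out), dim(gold))
  # containment: output foreground inside the margin-expanded coarse box
  rec <- attr(out, "crop_record")
  fg <- which(out != 0L, arr.ind = TRUE)
  expect_true(all(t(fg) - 1L >= rec$bbox_low))
  expect_true(all(t(fg) <= rec$bbox_high))
  # near-perfect agreement on a high-contrast phantom
  expect_gt(dice(confusion_counts(out, gold)), 0.85)
  # no-artery propagation
  out0 <- c2f_segment(array(0, c(8, 8, 8)), thr, thr, down_factor = 2)
  expect_true(isTRUE(attr(out0, "no_artery")))
})

test_that("trained two-stage cascade is at least as good as coarse alone", {
  ds <- generate_phantom_dataset(4, seed = 17, shape = c(32, 32, 32))
  train_ph <- ds$phantoms[1:3]
  test_ph <- ds$phantoms[[4]]
  sl <- phantom_slices(train_ph, 60, seed = 1)
  spec <- network_spec(depth = 2, base_channels = 8, se_reduction = 4)
  wins <- 0L
  for (seed in 1:3) {
    fit <- train_daunet(sl$x, sl$y, spec, epochs = 2, seed = seed)
    coarse_only <- coarse_segment(test_ph$volume, fit, down_factor = 2)
    full <- c2f_segment(test_ph$volume, fit, fit, down_factor = 2,
                        margin = 4)
    d_coarse <- dice(confusion_counts(coarse_only, test_ph$truth$mask))
    d_c2f <- dice(confusion_counts(full, test_ph$truth$mask))
    if (d_c2f >= d_coarse) wins <- wins + 1L
  }
  expect_equal(wins, 3L)
})
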