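test_that("confusion counts match hand-enumerated voxel sets", {
  # identical masks
  g <- array(0L, c(2, 2, 2)); g[c(1, 3, 5)] <- 1L
  cc <- confusion_counts(g, g)
  expect_equal(cc$tp, 3L); expect_equal(cc$fp, 0L); expect_equal(cc$fn, 0L)
  # empty prediction
  cc <- confusion_counts(array(0L, dim(g)), g)
  expect_equal(cc$tp, 0L); expect_equal(cc$fn, 3L)
  # pred {v1,v2,v3}, gold {v2,v3,v4} on a 2x2x2 grid
  pred <- array(0L, c(2, 2, 2)); pred[1:3] <- 1L
  gold <- array(0L, c(2, 2, 2)); gold[2:4] <- 1L
  cc <- confusion_counts(pred, gold)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 1L, fn = 1L, tn = 4L))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 8L)
})

test_that("shape and value validation is enforced", {
  expect_error(confusion_counts(array(0L, c(2, 2)), array(0L, c(2, 3))),
               "shape")
  expect_error(confusion_counts(array(2L, c(2, 2)), array(0L, c(2, 2))),
               "binary")
})

test_that("metric formulas agree with set-overlap oracles on fixed cases", {
  cc <- list(tp = 2L, fp = 1L, fn = 1L, tn = 4L)
  expect_equal(dice(cc), 2 / 3)
  expect_equal(jaccard(cc), 0.5)
  expect_equal(sensitivity(cc), 2 / 3)
  expect_equal(auc_paper(list(tp = 1L, fn = 1L, fp = 1L, tn = 1L)), 0.5)
  # disjoint masks
  expect_equal(dice(list(tp = 0L, fp = 3L, fn = 2L, tn = 5L)), 0)
  expect_equal(jaccard(list(tp = 0L, fp = 3L, fn = 2L, tn = 5L)), 0)
  expect_equal(sensitivity(list(tp = 0L, fp = 0L, fn = 4L, tn = 5L)), 0)
  expect_equal(auc_paper(list(tp = 0L, tn = 0L, fp = 2L, fn = 3L)), 0)
})

test_that("degenerate masks follow the documented conventions", {
  empty <- list(tp = 0L, fp = 0L, fn = 0L, tn = 8L)
  expect_equal(dice(empty), 1)
  expect_equal(jaccard(empty), 1)
  expect_error(sensitivity(empty), "empty gold")
  expect_error(auc_paper(list(tp = 2L, fn = 1L, fp = 0L, tn = 0L)), "absent")
  z <- array(0L, c(2, 2, 2)); o <- z; o[1] <- 1L
  expect_error(avd_paper(z, o), "empty prediction")
})

test_that("relative volume difference is the signed printed ratio", {
  base <- array(0L, c(10, 10, 10))
  a <- base; a[seq_len(100)] <- 1L
  b <- base; b[seq_len(120)] <- 1L
  expect_equal(avd_paper(a, b), 0.2)
  expect_equal(avd_paper(b, a), -1 / 6)
  expect_equal(avd_paper(a, a), 0)
})

test_that("avd antisymmetry identity holds numerically", {
  set.seed(31)
  for (r in 1:50) {
    mp <- random_mask_pair()
    if (sum(mp$pred) == 0 || sum(mp$gold) == 0) next
    f <- avd_paper(mp$pred, mp$gold)
    g <- avd_paper(mp$gold, mp$pred)
    expect_equal(f, -g / (1 + g), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under joint voxel permutation", {
  set.seed(7)
  for (r in 1:20) {
    mp <- random_mask_pair()
    perm <- sample(length(mp$pred))
    p2 <- mp$pred[perm]; g2 <- mp$gold[perm]
    c1 <- confusion_counts(mp$pred, mp$gold)
    c2 <- confusion_counts(p2, g2)
    expect_identical(unclass(c1), unclass(c2))
  }
})

test_that("average Hausdorff distance matches a brute-force oracle", {
  # identical masks -> 0
  m <- array(0L, c(5, 5, 5)); m[2:3, 2:3, 2:3] <- 1L
  expect_equal(average_hausdorff(m, m), 0)
  # two single voxels three apart at 1 mm spacing
  a <- array(0L, c(6, 3, 3)); a[2, 2, 2] <- 1L
  b <- array(0L, c(6, 3, 3)); b[5, 2, 2] <- 1L
  expect_equal(average_hausdorff(a, b), 3)
  # anisotropic spacing scales the same pair
  expect_equal(average_hausdorff(a, b, spacing = c(0.5, 1, 1)), 1.5)
  # a translated cube, against the naive surface oracle
  cube <- array(0L, c(8, 8, 8)); cube[2:6, 2:6, 2:6] <- 1L
  shift <- array(0L, c(8, 8, 8)); shift[3:7, 2:6, 2:6] <- 1L
  expect_equal(average_hausdorff(cube, shift),
               oracle_avg_hausdorff(cube, shift), tolerance = 1e-12)
  # unit shift: mean surface distance positive but bounded by the shift
  expect_gt(average_hausdorff(cube, shift), 0)
  expect_lte(average_hausdorff(cube, shift), 1)
  # random small masks
  set.seed(11)
  for (r in 1:5) {
    mp <- random_mask_pair(max_extent = 7L)
    if (sum(mp$pred) == 0 || sum(mp$gold) == 0) next
    expect_equal(average_hausdorff(mp$pred, mp$gold),
                 oracle_avg_hausdorff(mp$pred, mp$gold), tolerance = 1e-12)
  }
  expect_error(average_hausdorff(m * 0L, m), "empty")
})

test_that("seg_metrics returns a coherent one-row tibble", {
  set.seed(3)
  mp <- random_mask_pair()
  rep <- seg_metrics(mp$pred, mp$gold, hausdorff = TRUE)
  expect_s3_class(rep, "tbl_df")
  expect_equal(nrow(rep), 1L)
  cc <- confusion_counts(mp$pred, mp$gold)
  expect_equal(rep$dice, dice(cc))
  expect_equal(rep$dice, 2 * rep$jaccard / (1 + rep$jaccard))
})
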