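test_that("frame construction: midpoint origin and orthonormal axes", {
  f <- build_frame(c(0, 0, 0), c(0, 0, 10), surface_normal_hint = c(1, 0, 0))
  expect_equal(f$origin, c(0, 0, 5))
  expect_equal(f$axis_long, c(0, 0, 1))
  set.seed(22)
  for (r in 1:20) {
    a <- rnorm(3) * 50; b <- rnorm(3) * 50; h <- rnorm(3)
    if (sum((a - b)^2) < 1e-6) next
    f <- build_frame(a, b, h)
    M <- rbind(f$axis_long, f$axis_surface, f$axis_third)
    expect_equal(M %*% t(M), diag(3), tolerance = 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)       # right-handed
    # world -> frame -> world round-trips
    pts <- matrix(rnorm(30) * 100, 10, 3)
    back <- frame_to_world(world_to_frame(pts, f), f)
    expect_equal(back, pts, tolerance = 1e-9)
  }
  expect_error(build_frame(c(1, 1, 1), c(1, 1, 1)), "coincide")
  expect_error(build_frame(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)), "parallel")
})

test_that("surface projection is the nearest plane point", {
  plane <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  expect_equal(project_to_surface(c(3, 4, 0), plane), c(3, 4, 0))
  expect_equal(project_to_surface(c(1, 2, 7), plane), c(1, 2, 0))
  # oblique plane: projection beats a dense sample of plane points
  set.seed(23)
  plane <- list(point = c(1, 1, 1), normal = c(1, 2, 2) / 3)
  p <- c(5, -3, 4)
  proj <- project_to_surface(p, plane)
  expect_lt(abs(sum((proj - plane$point) * plane$normal)), 1e-9)
  u <- c(2, -1, 0) / sqrt(5)                     # in-plane basis
  v <- c(plane$normal[2] * u[3] - plane$normal[3] * u[2],
         plane$normal[3] * u[1] - plane$normal[1] * u[3],
         plane$normal[1] * u[2] - plane$normal[2] * u[1])
  samples <- t(sapply(1:10000, function(i) {
    plane$point + runif(1, -20, 20) * u + runif(1, -20, 20) * v
  }))
  dmin <- min(sqrt(colSums((t(samples) - p)^2)))
  expect_lte(localization_error(p, proj), dmin + 1e-9)
})

test_that("localization error is plain Euclidean distance", {
  expect_equal(localization_error(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(localization_error(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(24)
  for (r in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(localization_error(a, b), sqrt(sum((a - b)^2)))
  }
})

test_that("point matching counts and statistics on enumerated cases", {
  ref <- rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0))
  m <- match_perforators(ref, ref, threshold = 5)
  expect_equal(m$tp, 3L); expect_equal(m$fp, 0L); expect_equal(m$fn, 0L)
  expect_equal(m$sensitivity, 1)
  # 2 predictions, 3 references, exactly one pair within threshold
  pred <- rbind(c(0, 0, 1), c(100, 100, 100))
  m <- match_perforators(pred, ref, threshold = 5)
  expect_equal(m$tp, 1L); expect_equal(m$fp, 1L); expect_equal(m$fn, 2L)
  expect_equal(m$sensitivity, 1 / 3)
  # tp is symmetric under swapping the roles
  set.seed(25)
  for (r in 1:20) {
    a <- matrix(runif(15, 0, 30), 5, 3)
    b <- matrix(runif(9, 0, 30), 3, 3)
    m1 <- match_perforators(a, b, threshold = 8)
    m2 <- match_perforators(b, a, threshold = 8)
    expect_equal(m1$tp, m2$tp)
  }
  expect_error(match_perforators(pred, ref, threshold = 0), "positive")
})

test_that("specificity requires an explicit candidate-site denominator", {
  pred <- rbind(c(0, 0, 0), c(50, 0, 0))
  ref <- rbind(c(0, 0, 1), c(100, 0, 0))
  m <- match_perforators(pred, ref, threshold = 5)
  expect_true(is.na(m$specificity))
  m2 <- match_perforators(pred, ref, threshold = 5, candidate_sites = 10)
  expect_equal(m2$tn, 10L - 1L - 1L - 1L)
  expect_equal(m2$specificity, 7 / 8)
  expect_equal(m2$accordance, (1 + 7) / 10)
})

test_that("matching statistics are rigid-motion invariant", {
  set.seed(26)
  a <- matrix(runif(12, 0, 40), 4, 3)
  b <- matrix(runif(12, 0, 40), 4, 3)
  m0 <- match_perforators(a, b, threshold = 12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -3, 11)
  m1 <- match_perforators(sweep(a %*% t(R), 2, shift, "+"),
                          sweep(b %*% t(R), 2, shift, "+"), threshold = 12)
  expect_equal(m0$tp, m1$tp)
  expect_equal(sort(m0$distances), sort(m1$distances), tolerance = 1e-9)
})

test_that("greedy and optimal matching agree on small unambiguous sets", {
  set.seed(27)
  for (r in 1:10) {
    a <- matrix(runif(9, 0, 50), 3, 3)
    b <- a + matrix(rnorm(9, 0, 1), 3, 3)
    mg <- match_perforators(a, b, threshold = 6, method = "greedy")
    mo <- match_perforators(a, b, threshold = 6, method = "optimal")
    expect_equal(mg$tp, mo$tp)
  }
})

test_that("exit-point extraction recovers every perforator from the gold mask", {
  ds <- generate_phantom_dataset(6, seed = 31,
                                 spec_ranges = list(n_perforators = c(2, 4)))
  for (ph in ds$phantoms) {
    pts <- extract_exit_points(ph$truth$mask, ph$spec$spacing,
                               ph$truth$skin_plane)
    expect_equal(nrow(pts), ph$spec$n_perforators)
    m <- match_perforators(pts, ph$truth$perforator_points, threshold = 10)
    expect_equal(m$sensitivity, 1)
    expect_lte(max(m$distances), max(ph$spec$spacing) * 2)
  }
})

test_that("oracle-segmenter study: zero-noise statistics are perfect", {
  ds <- generate_phantom_dataset(5, seed = 33)
  st <- localization_study(ds$phantoms, segmenter = NULL, threshold = 10)
  expect_equal(st$summary$sensitivity, 1)
  expect_equal(st$summary$accordance, 1)
  expect_lte(st$summary$mean_distance_mm, 1)     # within a voxel spacing
  expect_equal(nrow(st$per_phantom), 5L)
})
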