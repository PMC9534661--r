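test_that("spec validation enforces the architectural invariants", {
  expect_error(network_spec(depth = 0), "depth")
  expect_error(network_spec(supervision_levels = 5, depth = 4),
               "supervision_levels")
  expect_error(network_spec(base_channels = 6, se_reduction = 4),
               "divisible")
  s <- network_spec(depth = 2, base_channels = 8)
  expect_equal(unet_baseline_spec(s)$supervision_levels, 1L)
  expect_false(unet_baseline_spec(s)$use_se)
})

test_that("forward pass honours the shape contract and determinism", {
  spec <- network_spec(depth = 2, base_channels = 4, se_reduction = 2)
  m1 <- build_daunet(spec, seed = 5)
  m2 <- build_daunet(spec, seed = 5)
  expect_identical(m1$params, m2$params)
  fit <- structure(list(model = m1, center = 0, scale = 1, bypass = list()),
                   class = "daunet_fit")
  x <- matrix(rnorm(16 * 16), 16, 16)
  pr <- predict(fit, x, type = "prob")
  expect_equal(dim(pr), c(16L, 16L, 2L))
  expect_equal(apply(pr, c(1, 2), sum), matrix(1, 16, 16),
               tolerance = 1e-6)
  lab <- predict(fit, x)
  expect_true(all(lab %in% 0:1))
  # extent not divisible by 2^depth is rejected at the forward level
  ns <- asNamespace("daunet")
  expect_error(ns$daunet_forward(m1, matrix(rnorm(15 * 16), ncol = 1),
                                 15, 16, 1), "divisible")
})

test_that("bypassed SE and attention reproduce the plain U-Net forward", {
  da_spec <- network_spec(depth = 2, base_channels = 4, se_reduction = 2,
                          supervision_levels = 1)
  un_spec <- unet_baseline_spec(da_spec)
  da <- build_daunet(da_spec, seed = 3)
  un <- build_daunet(un_spec, seed = 4)
  # share every common parameter (conv, batch norm, class head)
  for (nm in names(un$params)) un$params[[nm]] <- da$params[[nm]]
  ns <- asNamespace("daunet")
  set.seed(1)
  x <- matrix(rnorm(16 * 16 * 2), ncol = 1)
  fa <- ns$daunet_forward(da, x, 16, 16, 2,
                          bypass = list(se = TRUE, attention = TRUE))
  fb <- ns$daunet_forward(un, x, 16, 16, 2)
  expect_equal(fa$probs, fb$probs, tolerance = 1e-12)
  # and without the bypass the graphs genuinely differ
  fc <- ns$daunet_forward(da, x, 16, 16, 2)
  expect_gt(max(abs(fc$probs - fb$probs)), 1e-6)
})

test_that("ablation flags change the parameterisation", {
  full <- build_daunet(network_spec(depth = 2, base_channels = 4,
                                    se_reduction = 2), seed = 1)
  plain <- build_daunet(unet_baseline_spec(
    network_spec(depth = 2, base_channels = 4, se_reduction = 2)), seed = 1)
  expect_true(any(grepl("^att", names(full$params))))
  expect_true(any(grepl("^se", names(full$params))))
  expect_false(any(grepl("^(att|se)", names(plain$params))))
  expect_true(sum(vapply(full$params, length, 1L)) >
                sum(vapply(plain$params, length, 1L)))
})

test_that("full-batch gradient descent decreases the loss monotonically", {
  sl <- tiny_slice_data(n_phantoms = 1L, n_slices = 4L, shape = 16L)
  spec <- network_spec(depth = 2, base_channels = 4, se_reduction = 2)
  fit <- train_daunet(sl$x, sl$y, spec, epochs = 50, lr = 0.05,
                      batch_size = 4, seed = 2, optimizer = "sgd")
  expect_true(all(diff(fit$history$loss) <= 1e-10))
  expect_lt(fit$history$loss[50], fit$history$loss[1])
})

test_that("a short Adam run learns the phantom task and is reproducible", {
  sl <- tiny_slice_data(n_phantoms = 2L, n_slices = 24L, shape = 32L)
  spec <- network_spec(depth = 2, base_channels = 8, se_reduction = 4)
  f1 <- train_daunet(sl$x, sl$y, spec, epochs = 8, seed = 7)
  f2 <- train_daunet(sl$x, sl$y, spec, epochs = 8, seed = 7)
  expect_identical(f1$model$params, f2$model$params)
  pred <- predict(f1, sl$x)
  expect_gt(dice(confusion_counts(pred, sl$y)), 0.6)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(tidy(f1)), 8L)
  expect_equal(glance(f1)$depth, 2L)
})
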