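test_that("patch extraction has the documented geometry", {
  set.seed(13)
  lr <- array(rnorm(8 * 8 * 8 * 44), c(8, 8, 8, 44))
  hr <- array(rnorm(16 * 16 * 16 * 44), c(16, 16, 16, 44))
  pd <- extract_patches(lr, hr)
  expect_equal(nrow(pd$inputs), 512)          # one example per LR voxel
  expect_equal(ncol(pd$inputs), 1188)         # 27 voxels x 44 coefficients
  expect_equal(ncol(pd$targets), 352)         # 8 voxels x 44 coefficients
  # center offset of the input vector is the central voxel itself
  center_slot <- 14L                           # offsets ordered z-fastest
  i <- which(pd$voxels[, 1] == 4 & pd$voxels[, 2] == 5 & pd$voxels[, 3] == 6)
  expect_equal(pd$inputs[i, ((center_slot - 1) * 44 + 1):(center_slot * 44)],
               lr[4, 5, 6, ])
  expect_error(extract_patches(lr, hr[1:14, , , ]), "double")
})

test_that("border neighborhoods are zero-padded", {
  set.seed(14)
  lr <- array(rnorm(6 * 6 * 6 * 3), c(6, 6, 6, 3))
  lr[lr == 0] <- 0.1
  hr <- array(rnorm(12 * 12 * 12 * 3), c(12, 12, 12, 3))
  m <- array(FALSE, c(6, 6, 6)); m[1, 1, 1] <- TRUE
  pd <- extract_patches(lr, hr, mask = m)
  slots <- colSums(matrix(pd$inputs[1, ], nrow = 3) != 0)
  expect_equal(sum(slots > 0), 8)   # corner keeps its 2x2x2 in-volume corner
  expect_equal(sum(slots == 0), 19)
})

test_that("patch targets scatter back to the exact high-resolution volume", {
  set.seed(15)
  lr <- array(rnorm(6 * 6 * 6 * 4), c(6, 6, 6, 4))
  hr <- array(rnorm(12 * 12 * 12 * 4), c(12, 12, 12, 4))
  pd <- extract_patches(lr, hr)
  rec <- scatter_hr_blocks(pd$targets, pd$voxels, c(6, 6, 6), 4)
  expect_identical(rec, hr)
})

test_that("parameter counts match closed-form hand counts", {
  toy <- dsr_model_spec(2, c(3), 1)
  expect_equal(count_parameters(toy), 2 * 3 + 3 + 6 + 3 * 1 + 1)  # 19
  expect_equal(count_parameters(dsr_model_spec()), 3549352L)
  # the published coarse precision
  expect_equal(round(count_parameters(dsr_model_spec()) / 1e6, 1), 3.5)
  # 5x5x5-input variant
  expect_equal(count_parameters(dsr_model_spec(input_dim = 5500)), 7861352L)
})

test_that("spline upsampling follows the half-voxel-offset coordinates", {
  # 1D worked example: values a, b at y = 1.5, 3.5; linear value at x = 2
  a <- 2; b <- 6
  v <- array(c(a, b), c(2, 1, 1))
  up <- spline_upsample(v, 1)
  expect_equal(up[2, 1, 1], a + 0.25 * (b - a))
  expect_equal(up[3, 1, 1], a + 0.75 * (b - a))
  # order 0 is exact block replication
  set.seed(16)
  v3 <- array(rnorm(64), c(4, 4, 4))
  u0 <- spline_upsample(v3, 0)
  for (off in list(c(1, 1, 1), c(3, 2, 4))) {
    blk <- u0[(2 * off[1] - 1):(2 * off[1]), (2 * off[2] - 1):(2 * off[2]),
              (2 * off[3] - 1):(2 * off[3])]
    expect_true(all(blk == v3[off[1], off[2], off[3]]))
  }
  # constants preserved at all orders; linearity (superposition)
  vc <- array(1.7, c(4, 4, 4))
  for (o in 0:2) {
    expect_lt(max(abs(spline_upsample(vc, o) - 1.7)), 1e-12)
    w1 <- array(rnorm(64), c(4, 4, 4)); w2 <- array(rnorm(64), c(4, 4, 4))
    expect_lt(max(abs(spline_upsample(w1 + 2 * w2, o) -
                        spline_upsample(w1, o) - 2 * spline_upsample(w2, o))),
              1e-10)
  }
  expect_error(spline_upsample(v3, 3), "order")
})

test_that("the network learns a linear map and trains deterministically", {
  set.seed(17)
  d <- 10; o <- 4
  W <- matrix(rnorm(d * o, sd = 0.3), d, o)
  X <- matrix(rnorm(200 * d), 200, d)
  Xv <- matrix(rnorm(100 * d), 100, d)
  data <- list(inputs = X, targets = X %*% W)
  val <- list(inputs = Xv, targets = Xv %*% W)
  cfg <- train_config(batch_size = 50, epochs = 600, learning_rate = 1e-2,
                      seed = 5)
  m <- train_dsr(data, dsr_model_spec(d, c(16), o), cfg, val = val)
  expect_equal(nrow(m$history), 600)
  target_var <- var(as.vector(data$targets))
  expect_lt(tail(m$history$val_mse, 1), 0.01 * target_var)
  expect_lt(tail(m$history$train_mse, 1), m$history$train_mse[1])
  # 5-epoch-smoothed loss descends: every later value sits below the start,
  # none regresses far above the running minimum (mini-batch normalization
  # makes the training metric jitter on the converged plateau), and the end
  # is far below the start
  sm <- stats::filter(m$history$train_mse, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  strided <- sm[seq(1, length(sm), by = 50)]
  expect_true(all(strided[-1] < strided[1]))
  runmin <- cummin(strided)
  expect_true(all(strided <= 1.5 * c(strided[1], runmin[-length(runmin)])))
  expect_lt(strided[length(strided)], 0.05 * strided[1])
  # same seed, same run
  m2 <- train_dsr(data, dsr_model_spec(d, c(16), o), cfg, val = val)
  expect_identical(m$history$train_mse, m2$history$train_mse)
  expect_identical(m$params$out$W, m2$params$out$W)
  expect_error(train_dsr(list(inputs = X[0, ], targets = (X %*% W)[0, ])),
               "nrow")
})

test_that("tidy and glance summarize a trained model", {
  set.seed(18)
  X <- matrix(rnorm(40 * 4), 40, 4)
  m <- train_dsr(list(inputs = X, targets = X[, 1:2]),
                 dsr_model_spec(4, c(5), 2),
                 train_config(batch_size = 20, epochs = 3, seed = 1))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(m)
  expect_equal(gl$n_parameters, count_parameters(dsr_model_spec(4, c(5), 2)))
  expect_equal(gl$epochs, 3L)
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("applying the network doubles the grid and respects the mask", {
  set.seed(19)
  C <- 3
  lr <- array(rnorm(4 * 4 * 4 * C), c(4, 4, 4, C))
  hr <- array(rnorm(8 * 8 * 8 * C), c(8, 8, 8, C))
  pd <- extract_patches(lr, hr)
  m <- train_dsr(pd, dsr_model_spec(27 * C, c(8), 8 * C),
                 train_config(batch_size = 32, epochs = 2, seed = 2))
  out <- apply_dsr(m, lr)
  expect_equal(dim(out), c(8L, 8L, 8L, C))
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, , ] <- TRUE
  out2 <- apply_dsr(m, lr, mask)
  expect_true(all(out2[5:8, , , ] == 0))
  expect_true(any(out2[1:4, , , ] != 0))
  # chaining doubles again: 4x the original resolution
  out4 <- apply_dsr(m, out)
  expect_equal(dim(out4)[1:3], c(16L, 16L, 16L))
  expect_error(apply_dsr(m, array(0, c(4, 4, 4, C + 1))), "dimension")
})

test_that("model save/load round-trips weights and predictions", {
  set.seed(20)
  X <- matrix(rnorm(60 * 6), 60, 6)
  m <- train_dsr(list(inputs = X, targets = X[, 1:3]),
                 dsr_model_spec(6, c(7), 3),
                 train_config(batch_size = 30, epochs = 2, seed = 3))
  dir <- tempfile("dsr")
  save_dsr_model(m, dir)
  m2 <- load_dsr_model(dir)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$spec, m$spec)
})
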