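test_that("patch grids enumerate sliding windows with boundary snap", {
  origins <- foramcurve:::.patch_origins
  # the full-scale case: 96 extent, patch 64, stride 32 -> origins {0, 32}
  expect_identical(origins(96L, 64L, 32L), c(0L, 32L))
  expect_identical(origins(64L, 64L, 32L), 0L)
  expect_identical(origins(100L, 64L, 32L), c(0L, 32L, 36L))  # snapped
  expect_error(origins(32L, 64L, 32L), "smaller than patch")

  cfg <- tiny_config()
  p <- separable_population(3, c(1, 1, 1), seed = 11)$train[[1]]
  patches <- extract_patches(p, cfg)  # 16^3 volume, patch 8, stride 8
  expect_length(patches, 8L)
  expect_identical(dim(patches[[1]]$grey), c(8L, 8L, 8L))
  # coverage: union of patch footprints is the full volume
  hit <- array(FALSE, dim(p$grey))
  og <- origins(16L, 8L, 8L)
  for (oz in og) for (oy in og) for (ox in og)
    hit[oz + 1:8, oy + 1:8, ox + 1:8] <- TRUE
  expect_true(all(hit))
  # label patches tile the label volume exactly
  expect_identical(patches[[1]]$labels, p$labels[1:8, 1:8, 1:8])
})

test_that("a 96^3 analogue grid gives 8 patches (2 per axis)", {
  lab <- array(0L, c(24L, 24L, 24L))
  grey <- array(0L, c(24L, 24L, 24L))
  pair <- volume_pair("grid", grey, lab, 1)
  cfg <- tiny_config(patch_size_vox = 16L)  # stride 8: origins {0, 8}
  expect_length(extract_patches(pair, cfg), 8L)
})

test_that("network gradients match finite differences", {
  C <- 2L
  w <- foramcurve:::.init_weights(C, seed = 1)
  set.seed(2)
  pd <- c(4L, 4L, 4L)
  g <- runif(64)
  lab <- sample(0:2, 64, replace = TRUE)
  for (cw in list(c(1, 1, 1), c(0.3, 1.5, 4))) {
    res <- foramcurve:::unet_grad_cpp(w, g, as.integer(lab), pd, C, cw)
    eps <- 1e-6
    for (l in sample(seq_along(w), 8)) {
      i <- sample(length(w[[l]]), 1)
      wp <- w; wp[[l]][i] <- wp[[l]][i] + eps
      wm <- w; wm[[l]][i] <- wm[[l]][i] - eps
      num <- (foramcurve:::unet_loss_cpp(wp, g, as.integer(lab), pd, C,
                                         cw) -
              foramcurve:::unet_loss_cpp(wm, g, as.integer(lab), pd, C,
                                         cw)) / (2 * eps)
      expect_equal(res$grads[[l]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training validates its inputs", {
  pop <- separable_population(3, c(1, 1, 1), seed = 11)
  cfg <- tiny_config(max_epochs = 1L, patience_epochs = 1L)
  expect_error(train(list(), pop$val, cfg), "empty")
  novol <- volume_pair("bg", array(0L, c(16L, 16L, 16L)),
                       array(0L, c(16L, 16L, 16L)), 1.75)
  expect_error(train(pop$train, list(novol), cfg),
               "no validation pair contains foreground")
  expect_error(train_config(stride_vox = 32L, patch_size_vox = 16L),
               "stride_vox")
  expect_error(train_config(patience_epochs = 10L, max_epochs = 5L))
})

test_that("training is deterministic and obeys the stopping contract", {
  pop <- separable_population(4, c(2, 1, 1), seed = 13)
  cfg <- tiny_config(max_epochs = 4L, patience_epochs = 4L)
  m1 <- train(pop$train, pop$val, cfg)
  m2 <- train(pop$train, pop$val, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$best_val_dice, max(m1$history))
  expect_identical(m1$best_epoch,
                   which(m1$history == m1$best_val_dice)[1])
  expect_lte(length(m1$history), cfg$max_epochs)
  # patience: halting no later than best_epoch + patience
  cfg2 <- tiny_config(max_epochs = 30L, patience_epochs = 3L)
  m3 <- train(pop$train, pop$val, cfg2)
  expect_lte(length(m3$history), m3$best_epoch + cfg2$patience_epochs)
})

test_that("prediction output matches the input shape and label codes", {
  pop <- separable_population(4, c(2, 1, 1), seed = 13)
  cfg <- tiny_config(max_epochs = 2L, patience_epochs = 2L)
  m <- train(pop$train, pop$val, cfg)
  pred <- predict(m, pop$test[[1]])
  expect_identical(dim(pred), dim(pop$test[[1]]$grey))
  expect_true(all(pred %in% 0:2))
  expect_error(predict(m, array(0, c(4, 4, 4))), "smaller than patch")
})

test_that("a separable phantom task trains to high validation Dice", {
  pop <- separable_population(6, c(3, 2, 1), seed = 17, noise_sd = 0)
  cfg <- tiny_config(max_epochs = 40L, patience_epochs = 40L,
                     base_channels = 2L)
  m <- train(augment_set(pop$train), pop$val, cfg)
  # intensity alone separates the classes, so the network must reach at
  # least the accuracy of a per-voxel intensity classifier
  expect_gte(m$best_val_dice, 0.9)
})

test_that("median replicate selection follows the stable lower-middle rule", {
  midx <- foramcurve:::.median_index
  expect_identical(midx(c(0.91, 0.95, 0.93)), 3L)
  expect_identical(midx(c(0.90, 0.90, 0.90)), 2L)  # ties: stable order
  expect_identical(midx(0.5), 1L)
  expect_identical(midx(c(0.8, 0.6, 0.9, 0.7)), 4L)  # lower middle = 0.7
})

test_that("train_replicates returns the median-accuracy network", {
  pop <- separable_population(4, c(2, 1, 1), seed = 13)
  cfg <- tiny_config(max_epochs = 3L, patience_epochs = 3L,
                     n_replicates = 3L)
  res <- train_replicates(pop$train, pop$val, cfg)
  expect_length(res$models, 3L)
  expect_identical(res$median_model$best_val_dice,
                   sort(res$dices)[2])
  cfg1 <- tiny_config(max_epochs = 2L, patience_epochs = 2L,
                      n_replicates = 1L)
  res1 <- train_replicates(pop$train, pop$val, cfg1)
  expect_identical(res1$median_model$best_val_dice, res1$dices[1])
})

test_that("volume resampling round-trips and preserves labels", {
  vol <- asym_pair()$grey
  d <- dim(vol)
  up <- foramcurve:::resize_trilinear_cpp(as.numeric(vol), d,
                                          c(40L, 48L, 56L))
  back <- foramcurve:::resize_trilinear_cpp(up, c(40L, 48L, 56L), d)
  expect_equal(array(back, d)[2:19, 2:23, 2:27],
               vol[2:19, 2:23, 2:27] + 0, tolerance = 0.15)
  lab <- asym_pair()$labels
  same <- foramcurve:::resize_nearest_cpp(as.integer(lab), d, d)
  expect_identical(array(same, d), lab)
})
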