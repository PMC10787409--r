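test_that("BCE loss matches closed forms and clamps near the boundary", {
  p <- array(0.5, c(4, 4, 1, 1))
  t0 <- array(rbinom(16, 1, 0.5), c(4, 4, 1, 1))
  expect_equal(bce_loss(p, t0), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(array(0.9, c(2, 2, 1, 1)), array(1, c(2, 2, 1, 1))),
               -log(0.9), tolerance = 1e-12)
  exact <- array(1, c(2, 2, 1, 1))
  expect_lte(bce_loss(exact, exact), 1.01e-7)
  expect_gte(bce_loss(exact, exact), 0)
  expect_error(bce_loss(array(0.5, c(2, 2, 1, 1)), array(1, c(2, 3, 1, 1))),
               "shape")
})

test_that("training config validates its domain", {
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(threshold = 0), "threshold")
  expect_error(train_config(threshold = 1), "threshold")
  d <- train_config()
  expect_equal(d$learning_rate, 1e-4)
  expect_identical(d$batch_size, 2L)
  expect_identical(d$epochs, 30L)
})

small_model <- function(seed = 1L) {
  seg_model(model_config(encoder_depth = 18L, use_attention = FALSE,
                         use_denseaspp = FALSE), seed = seed)
}

test_that("one epoch over four samples in batches of two takes two steps", {
  samples <- easy_samples(2, seed = 23L)  # 4 samples at 64 px
  fit <- train_model(small_model(), samples,
                     cfg = train_config(epochs = 1L, seed = 1L))
  expect_identical(nrow(fit$history), 1L)
  expect_identical(fit$history$steps, 2L)
  expect_true(is.finite(fit$history$loss) && fit$history$loss >= 0)
  expect_error(train_model(small_model(), list(), cfg = train_config()),
               "empty")
})

test_that("training is reproducible: same seed, identical history", {
  samples <- easy_samples(2, seed = 29L)
  cfg <- train_config(epochs = 2L, seed = 11L)
  f1 <- train_model(small_model(seed = 11L), samples, val_set = samples[1:2],
                    cfg = cfg)
  f2 <- train_model(small_model(seed = 11L), samples, val_set = samples[1:2],
                    cfg = cfg)
  expect_identical(f1$history, f2$history)
})

test_that("checkpoints round-trip with exactly reproduced predictions", {
  dir <- withr::local_tempdir()
  m <- small_model(seed = 3L)
  probe <- easy_samples(1, seed = 37L)[[1]]
  path <- file.path(dir, "ckpt.rds")
  save_checkpoint(m, path, seed = 3L)
  m2 <- load_checkpoint(path)
  x <- to_model_input(probe$image)
  xb <- array(aperm(x, c(2, 3, 1)), c(64, 64, 3, 1))
  expect_identical(model_forward(m, xb), model_forward(m2, xb))
  expect_identical(predict(m, probe$image), predict(m2, probe$image))
  expect_identical(m2$config, m$config)
  expect_identical(attr(m2, "seed"), 3L)
  expect_error(load_checkpoint(file.path(dir, "nope.rds")), "checkpoint error")
  bad <- file.path(dir, "bad.rds")
  writeLines("garbage", bad)
  expect_error(load_checkpoint(bad), "checkpoint error")
})

test_that("best and last checkpoints are written during training", {
  dir <- withr::local_tempdir()
  samples <- easy_samples(2, seed = 41L)
  fit <- train_model(small_model(), samples, val_set = samples,
                     cfg = train_config(epochs = 1L, seed = 2L),
                     checkpoint_dir = dir)
  expect_true(file.exists(file.path(dir, "best.rds")))
  expect_true(file.exists(file.path(dir, "last.rds")))
  expect_identical(fit$best_dice, fit$history$val_dice[1])
})

test_that("prediction binarizes at the configured threshold", {
  m <- small_model(seed = 5L)
  img <- easy_samples(1, seed = 43L)[[1]]$image
  mask1 <- predict(m, img, threshold = 0.5)
  expect_identical(dim(mask1), c(64L, 64L))
  expect_true(all(mask1 %in% c(0L, 1L)))
  # an extreme threshold close to 0 marks (almost) everything positive
  expect_gte(mean(predict(m, img, threshold = 1e-9)), mean(mask1))
  expect_error(predict(m, img, threshold = 0), "threshold")
  expect_error(predict(m, img[1:60, , ]), "input-size|image array")
})
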