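test_that("mask and image PNG io round-trips", {
  dir <- withr::local_tempdir()
  mask <- matrix(0L, 32, 32); mask[10:20, 5:25] <- 1L
  mp <- file.path(dir, "m.png")
  write_mask(mask, mp)
  back <- read_mask(mp)
  expect_identical(unname(back), unname(mask))
  # decoded file holds exactly {0, 255}
  raw <- png::readPNG(mp)
  expect_setequal(unique(as.vector(raw)) * 255, c(0, 255))
  expect_equal(mean(back), mean(mask))

  img <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32L, 32L, 3L))
  ip <- file.path(dir, "i.png")
  write_image(img, ip)
  expect_identical(read_image(ip), img)
})

test_that("grayscale PNGs are replicated to three channels", {
  dir <- withr::local_tempdir()
  g <- matrix(runif(128 * 128), 128, 128)
  p <- file.path(dir, "g.png")
  png::writePNG(g, p)
  x <- read_image(p)
  expect_identical(dim(x), c(128L, 128L, 3L))
  expect_identical(x[, , 1], x[, , 2])
  expect_identical(x[, , 1], x[, , 3])
})

test_that("non-PNG input fails with a format error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "not.png")
  writeLines("plain text", p)
  expect_error(read_image(p), "format error")
  expect_error(read_mask(file.path(dir, "absent.png")), "not found")
})

test_that("subject-level split uses largest-remainder counts and never leaks", {
  man <- data.frame(subject_id = rep(sprintf("s%02d", 1:60), each = 3),
                    slice_index = rep(1:3, 60),
                    image_path = NA_character_, mask_path = NA_character_)
  parts <- split_by_subject(man, split_spec(0.70, 0.15, 0.15, seed = 4L))
  counts <- vapply(parts, function(m) length(unique(m$subject_id)), integer(1))
  expect_identical(unname(counts), c(42L, 9L, 9L))
  expect_length(Reduce(intersect, lapply(parts, function(m) m$subject_id)), 0)
  expect_setequal(unlist(lapply(parts, function(m) unique(m$subject_id))),
                  unique(man$subject_id))
  # all slices of a subject travel together
  expect_identical(nrow(parts$train) + nrow(parts$val) + nrow(parts$test),
                   nrow(man))
  # determinism
  parts2 <- split_by_subject(man, split_spec(0.70, 0.15, 0.15, seed = 4L))
  expect_identical(parts, parts2)
})

test_that("split guards: fraction domain, subject minimum, empty parts", {
  man <- data.frame(subject_id = c("a", "a", "b", "c"), slice_index = c(1, 2, 1, 1),
                    image_path = NA_character_, mask_path = NA_character_)
  expect_error(split_spec(0.5, 0.3, 0.3), "sum to 1")
  expect_error(split_spec(-0.1, 0.55, 0.55), "\\[0, 1\\]")
  expect_error(split_by_subject(man[1:2, ], split_spec()), "at least 3")
  expect_error(split_by_subject(man, split_spec(0.98, 0.01, 0.01)),
               "more subjects")
})

test_that("augmentation expands exactly threefold with paired transforms", {
  samples <- easy_samples(2, seed = 31L)  # 4 samples
  aug <- augment_threefold(samples)
  expect_length(aug, 3 * length(samples))
  tags <- vapply(aug, `[[`, character(1), "augment")
  expect_identical(sum(tags == "original"), length(samples))
  expect_true("hflip" %in% tags && "vflip" %in% tags)
  # the same geometric transform is applied to image and mask
  for (k in seq_along(aug)) {
    src <- samples[[ceiling(k / 3)]]
    s <- aug[[k]]
    tr <- switch(s$augment,
                 original = identity,
                 rot90 = function(m) t(m[nrow(m):1, , drop = FALSE]),
                 hflip = function(m) m[, ncol(m):1, drop = FALSE],
                 vflip = function(m) m[nrow(m):1, , drop = FALSE])
    expect_identical(unname(s$mask), unname(tr(src$mask)))
    expect_identical(unname(s$image[, , 2]), unname(tr(src$image[, , 2])))
  }
})

test_that("flips are involutions and four quarter-turns are the identity", {
  s <- easy_samples(1, seed = 13L)[[1]]
  expect_identical(flip_sample(flip_sample(s, "horizontal"), "horizontal")[c("image", "mask")],
                   s[c("image", "mask")])
  expect_identical(flip_sample(flip_sample(s, "vertical"), "vertical")[c("image", "mask")],
                   s[c("image", "mask")])
  r4 <- rotate_sample(rotate_sample(rotate_sample(rotate_sample(s))))
  expect_identical(r4[c("image", "mask")], s[c("image", "mask")])
})

test_that("arbitrary-angle rotation resamples mask as binary", {
  s <- easy_samples(1, seed = 17L)[[1]]
  r <- rotate_sample(s, 37)
  expect_true(all(r$mask %in% c(0L, 1L)))
  expect_identical(dim(r$mask), dim(s$mask))
})

test_that("unpaired samples are rejected", {
  s <- easy_samples(1, seed = 19L)[[1]]
  s$mask <- s$mask[1:10, 1:10]
  expect_error(augment_threefold(list(s)), "pairing error")
})

test_that("model input scaling and stride guard", {
  img <- array(255L, c(64L, 64L, 3L))
  x <- to_model_input(img)
  expect_identical(dim(x), c(3L, 64L, 64L))
  expect_true(all(x == 1))
  expect_true(all(to_model_input(array(0L, c(64L, 64L, 3L))) == 0))
  img[1, 1, 1] <- 128L
  expect_equal(to_model_input(img)[1, 1, 1], 128 / 255)
  expect_error(to_model_input(array(0L, c(60L, 64L, 3L))), "input-size")
})
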