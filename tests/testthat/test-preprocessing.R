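test_that("oversampling balances the study-sized class counts", {
  d <- tiny_set(87, 44)
  out <- ros_oversample(d, seed = 1)
  expect_equal(unname(table(out$label)["cancerous"]), 87L)
  expect_equal(unname(table(out$label)["non-cancerous"]), 87L)
  expect_equal(sum(out$provenance == "oversampled"), 43L)
  # originals preserved verbatim, in place
  expect_identical(out[seq_len(nrow(d)), c("id", "image", "label")],
                   d[, c("id", "image", "label")])
  # duplicates drawn only from the minority class
  dup <- out[out$provenance == "oversampled", ]
  expect_true(all(dup$label == "non-cancerous"))
  minority_imgs <- d$image[d$label == "non-cancerous"]
  expect_true(all(vapply(dup$image, function(img) {
    any(vapply(minority_imgs, identical, logical(1), x = img))
  }, logical(1))))
  # determinism
  expect_identical(out, ros_oversample(d, seed = 1))
  expect_false(identical(out$id, ros_oversample(d, seed = 2)$id))
})

test_that("oversampling edge cases behave", {
  bal <- tiny_set(10, 10)
  expect_identical(ros_oversample(bal, seed = 1), bal)
  out <- ros_oversample(tiny_set(3, 1), seed = 1)
  expect_equal(as.vector(table(out$label)), c(3L, 3L))
  expect_true(all(out$label[out$provenance == "oversampled"] ==
                    "non-cancerous"))
  single <- image_set(list(tiny_gray()), "cancerous")
  expect_error(ros_oversample(single, seed = 1), "both classes")
})

test_that("resizing scales dimensions as requested", {
  img <- withr::with_seed(1, matrix(runif(100 * 100), 100, 100))
  expect_equal(dim(aug_resize(img, 2)), c(200, 200))
  expect_equal(dim(aug_resize(img, 0.5)), c(50, 50))
  rgb <- withr::with_seed(2, array(runif(40 * 30 * 3), c(40, 30, 3)))
  expect_equal(dim(aug_resize(rgb, 3)), c(120, 90, 3))
})

test_that("blur reduces pixel variance", {
  img <- withr::with_seed(3, matrix(runif(80 * 80), 80, 80))
  out <- aug_blur(img, sigma = 6)
  expect_lt(var(as.vector(out)), var(as.vector(img)))
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("zero translation is the identity and shifts move content", {
  img <- withr::with_seed(4, matrix(runif(20 * 20), 20, 20))
  expect_identical(aug_translate(img, 0, 0), img)
  sh <- aug_translate(img, 2, 3)
  expect_equal(sh[3:20, 4:20], img[1:18, 1:17])
  expect_true(all(sh[1:2, ] == 0))
  expect_true(all(sh[, 1:3] == 0))
})

test_that("crop keeps the original size and warp stays in range", {
  img <- withr::with_seed(5, matrix(runif(50 * 40), 50, 40))
  cr <- aug_crop(img, fraction = 0.8, off_y = 3, off_x = 5)
  expect_equal(dim(cr), dim(img))
  wp <- aug_warp(img, 50)
  expect_equal(dim(wp), dim(img))
  expect_true(all(wp >= 0 & wp <= 1))
})

test_that("identity jitter leaves the raster unchanged", {
  rgb <- withr::with_seed(6, array(runif(12 * 10 * 3), c(12, 10, 3)))
  expect_equal(aug_jitter(rgb), rgb, tolerance = 1e-12)
  gray <- withr::with_seed(7, matrix(runif(12 * 10), 12, 10))
  expect_equal(aug_jitter(gray), gray)
  # gray degrades gracefully: hue/saturation are no-ops
  expect_equal(aug_jitter(gray, hue = 0.3, saturation = 1.5),
               gray)
  # brightness scales the mean
  br <- aug_jitter(gray, brightness = 1.2)
  expect_gt(mean(br), mean(gray))
})

test_that("the full augmentation stack yields one valid raster per operator", {
  img <- withr::with_seed(8, array(runif(64 * 64 * 3), c(64, 64, 3)))
  out <- withr::with_seed(9, augment_image(img))
  expect_named(out, c("resize", "warp", "crop", "noise", "blur", "jitter",
                      "translate"))
  for (nm in names(out)) {
    expect_true(all(is.finite(out[[nm]])), label = nm)
    expect_true(all(out[[nm]] >= 0 & out[[nm]] <= 1), label = nm)
  }
  # determinism under a fixed stream
  out2 <- withr::with_seed(9, augment_image(img))
  expect_identical(out, out2)
})

test_that("translation is skipped with a warning on too-small images", {
  img <- matrix(0.5, 16, 16) # smaller than the 50 px max offset
  expect_warning(out <- withr::with_seed(1, augment_image(img)),
                 "translate skipped")
  expect_false("translate" %in% names(out))
  expect_length(out, 6)
})

test_that("standardize resizes to the exact target and preserves constants", {
  img <- withr::with_seed(10, matrix(runif(64 * 48), 64, 48))
  out <- standardize_image(img, c(32, 32))
  expect_equal(dim(out), c(32, 32))
  expect_identical(standardize_image(img, dim(img)), img) # identity resize
  const <- matrix(0.42, 20, 20)
  expect_equal(standardize_image(const, c(8, 8)), matrix(0.42, 8, 8),
               tolerance = 1e-6)
  expect_error(standardize_image(img, c(0, 10)), "positive")
})

test_that("augment_images appends tagged rows deterministically", {
  d <- synth_image_set(2, 2, size = 56, seed = 3)
  out <- augment_images(d, seed = 5)
  expect_equal(nrow(out), nrow(d) + 7 * nrow(d))
  expect_identical(out[seq_len(nrow(d)), ], d)
  aug <- out[-seq_len(nrow(d)), ]
  expect_true(all(aug$provenance == "augmented"))
  expect_equal(sum(aug$label == "cancerous"), 14)
  expect_identical(out, augment_images(d, seed = 5))
})
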