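test_that("mask stacks round-trip through PNG directories and multi-page TIFF", {
  set.seed(1)
  masks <- mask_stack(lapply(1:3, function(i) random_mask(6, 5, seed = i)))

  d <- withr::local_tempdir()
  write_mask_stack(masks, d)
  back <- read_mask_stack(d)
  expect_identical(back$slices, masks$slices)

  tf <- withr::local_tempfile(fileext = ".tiff")
  write_mask_stack(masks, tf)
  back2 <- read_mask_stack(tf)
  expect_identical(back2$slices, masks$slices)

  zero <- mask_stack(list(matrix(0L, 4, 4)))
  d2 <- withr::local_tempdir()
  write_mask_stack(zero, d2)
  expect_identical(read_mask_stack(d2)$slices[[1]], matrix(0L, 4, 4))
})

test_that("checkerboard masks are stored as {0, 255} at the expected pixels", {
  chk <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  d <- withr::local_tempdir()
  write_mask_stack(mask_stack(list(chk)), d)
  raw <- png::readPNG(list.files(d, full.names = TRUE)[1]) * 255
  expect_equal(raw, matrix(c(255, 0, 0, 255), 2, 2))
})

test_that("directory stacks are ordered by numeric filename suffix", {
  d <- withr::local_tempdir()
  # values identify each slice; b_2 must precede b_10 despite lexicographic order
  png::writePNG(matrix(10 / 255, 4, 4), file.path(d, "b_10.png"))
  png::writePNG(matrix(2 / 255, 4, 4), file.path(d, "b_2.png"))
  st <- read_image_stack(d)
  expect_equal(round(st$slices[[1]][1, 1] * 255), 2)
  expect_equal(round(st$slices[[2]][1, 1] * 255), 10)
})

test_that("multi-page TIFF reads as one stack with page order preserved", {
  tf <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:5, function(i) matrix(i / 10, 4, 4))
  tiff::writeTIFF(pages, tf)
  st <- read_image_stack(tf)
  expect_length(st$slices, 5)
  got <- vapply(st$slices, function(s) s[1, 1], numeric(1))
  expect_true(all(abs(got - (1:5) / 10) <= 1 / 255))
})

test_that("identical slices and dimension mismatches are handled", {
  d <- withr::local_tempdir()
  for (i in 1:3) png::writePNG(matrix(0.5, 4, 4), sprintf("%s/a_%d.png", d, i))
  st <- read_image_stack(d)
  expect_length(st$slices, 3)
  expect_equal(st$slices[[1]], st$slices[[3]])

  png::writePNG(matrix(0.5, 3, 4), file.path(d, "a_4.png"))
  expect_error(read_image_stack(d), "a_4")
  expect_error(read_image_stack(file.path(d, "missing")), "not found")
})

test_that("8-bit intensity normalization is lossless at the extremes", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 3, 3), f)  # all-255 on disk
  expect_identical(read_image_stack(f)$slices[[1]], matrix(1, 3, 3))
})

test_that("preprocess_geometry resizes, centres and zero-pads", {
  set.seed(2)
  img <- matrix(runif(460 * 500), 460, 500)
  out <- preprocess_geometry(img)
  expect_equal(dim(out), c(512, 512))
  # the central block is the resized content, the border exactly zero
  inner <- out[27:486, 27:486]
  expect_equal(inner, resize_bilinear_ref(img, 460, 460), tolerance = 1e-12)
  expect_equal(sum(out) - sum(inner), 0)

  # no-op resize: content unchanged, only padding added
  sq <- matrix(runif(460 * 460), 460, 460)
  out2 <- preprocess_geometry(sq)
  expect_equal(out2[27:486, 27:486], sq)

  expect_error(preprocess_geometry(img, resize_to = c(460, 460),
                                   pad_to = c(400, 512)), "pad_to")
})

test_that("bilinear resize matches an established implementation", {
  skip_if_not_installed("EBImage")
  set.seed(3)
  img <- matrix(runif(40 * 50), 40, 50)
  ours <- octdamage:::resize_bilinear(img, 23, 31)
  ref <- EBImage::imageData(EBImage::resize(EBImage::Image(img), w = 23, h = 31))
  expect_equal(ours, ref, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("masks restored to native geometry preserve foreground within 5%", {
  rr <- matrix(seq_len(460), 460, 500)
  cc <- matrix(seq_len(500), 460, 500, byrow = TRUE)
  ellipse <- matrix(as.integer(((rr - 230) / 60)^2 + ((cc - 250) / 90)^2 <= 1),
                    460, 500)
  pre <- preprocess_geometry(ellipse)
  expect_true(is.integer(pre))
  back <- restore_geometry(pre)
  expect_equal(dim(back), c(460, 500))
  expect_lt(abs(sum(back) - sum(ellipse)) / sum(ellipse), 0.05)
})
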