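test_that("save/load round trip is bounded by 8-bit quantization", {
  set.seed(1)
  img <- rand_img(16)
  path <- tempfile(fileext = ".png")
  save_image(img, path)
  back <- load_image(path)
  expect_equal(dim(back), dim(img))
  expect_lte(max(abs(back - img)), 1 / 255)
  # exact endpoints survive the round trip
  flat <- array(rep(c(0, 1), each = 8 * 16 * 3 / 2), dim = c(8, 16, 3))
  save_image(flat, path)
  expect_equal(load_image(path), flat)
})

test_that("non-RGB inputs are converted with a warning", {
  g <- matrix(runif(64), 8)
  path <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(g), path)
  expect_warning(img <- load_image(path), "grey")
  expect_equal(dim(img), c(8L, 8L, 3L))
  expect_equal(img[, , 1], img[, , 3])
  expect_error(load_image(tempfile(fileext = ".png")), "does not exist")
})

test_that("aspect-preserving resize scales 4:3 inputs without cropping", {
  const <- array(0.42, dim = c(1080, 1440, 3))
  out <- resize_keep_aspect(const, 720, 540)
  expect_equal(dim(out), c(540L, 720L, 3L))
  expect_equal(max(abs(out - 0.42)), 0, tolerance = 1e-6)
})

test_that("wider-than-target inputs are centre-cropped after scaling", {
  # 540 x 1000 source to 540 x 720: scale factor 1, symmetric 140-px crop
  src <- array(0, dim = c(540, 1000, 3))
  src[, , 1] <- matrix(rep(seq_len(1000) / 1000, each = 540), 540)
  out <- resize_keep_aspect(src, 720, 540)
  expect_equal(dim(out), c(540L, 720L, 3L))
  expect_equal(out[, , 1], src[, 141:860, 1])
})

test_that("random_crop is a pure function of image, size and seed", {
  set.seed(3)
  img <- rand_img(48)
  expect_identical(random_crop(img, 16L, 99L), random_crop(img, 16L, 99L))
  expect_identical(random_crop(img, 48L, 1L), img)
  expect_error(random_crop(img, 64L, 1L), "resize")
  # offsets stay within bounds over many seeds
  for (s in 1:25) {
    cr <- random_crop(img, 16L, s)
    expect_equal(dim(cr), c(16L, 16L, 3L))
  }
})
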