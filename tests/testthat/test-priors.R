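test_that("inter-channel discrepancy matches hand-worked pixels", {
  expect_equal(interchannel_pixel(c(0.5, 0.5, 0.5)), 0)
  expect_equal(interchannel_pixel(c(1, 0, 0)), 2)
  expect_equal(interchannel_pixel(c(0.8, 0.5, 0.2)), 1.2)
  # symmetric under channel permutation
  set.seed(2)
  for (i in 1:20) {
    p <- runif(3)
    expect_equal(interchannel_pixel(p), interchannel_pixel(sample(p)))
  }
})

test_that("image-level discrepancy equals the per-pixel loop oracle", {
  grey <- array(rep(matrix(runif(64), 8), 3), dim = c(8, 8, 3))
  expect_equal(interchannel_image(grey), 0)
  two <- array(c(1, 0.5, 0, 0.5, 0, 0.5), dim = c(2, 1, 3))
  expect_equal(interchannel_image(two), 1)
  set.seed(4)
  for (i in 1:10) {
    img <- rand_img(8)
    expect_equal(interchannel_image(img), interchannel_brute(img),
                 tolerance = 1e-13)
  }
})

test_that("dark channel matches the brute-force double-min oracle", {
  white <- array(1, dim = c(10, 10, 3))
  expect_true(all(dark_channel(white, 3) == 1))
  # every pixel has some zero channel -> dark channel identically 0
  set.seed(5)
  img <- rand_img(12)
  zc <- sample(1:3, 144, replace = TRUE)
  for (k in seq_len(144))
    img[((k - 1) %% 12) + 1, ((k - 1) %/% 12) + 1, zc[k]] <- 0
  expect_true(all(dark_channel(img, 5) == 0))
  for (i in 1:5) {
    r <- rand_img(16)
    expect_identical(dark_channel(r, 3), dark_channel_brute(r, 3))
    expect_identical(dark_channel(r, 5), dark_channel_brute(r, 5))
  }
  expect_error(dark_channel(img, 4), "odd")
})

test_that("dark channel is pointwise monotone in the image", {
  set.seed(6)
  for (i in 1:10) {
    a <- rand_img(12)
    b <- pmin(a + array(runif(length(a), 0, 0.3), dim = dim(a)), 1)
    expect_true(all(dark_channel(a, 5) <= dark_channel(b, 5)))
  }
})

test_that("soft matting agrees with a dense direct solve", {
  set.seed(7)
  raw <- matrix(runif(64), 8)
  guide <- rand_img(8)
  eps <- 1e-4
  Ld <- matting_laplacian_dense(guide)
  dense <- solve(Ld + eps * diag(64), eps * as.numeric(raw))
  ref <- refine_dark_channel(raw, guide, eps = eps)
  expect_lt(max(abs(ref - matrix(pmin(pmax(dense, 0), 1), 8))), 1e-6)
})

test_that("soft matting fixes constant maps and obeys the large-eps limit", {
  set.seed(8)
  guide <- rand_img(8)
  const <- matrix(0.37, 8, 8)
  expect_lt(max(abs(refine_dark_channel(const, guide) - const)), 1e-6)
  raw <- matrix(runif(64), 8)
  big <- refine_dark_channel(raw, guide, eps = 1e6)
  expect_lt(max(abs(big - raw)), 1e-4)
})

test_that("trimmed mean trims symmetric rank tails", {
  expect_equal(trimmed_mean(0:9, 0.1), 4.5)
  x <- runif(37)
  expect_equal(trimmed_mean(x, 0), mean(x))
  set.seed(9)
  expect_equal(trimmed_mean(x, 0.05), trimmed_mean(sample(x), 0.05))
  expect_error(trimmed_mean(numeric(0)), "empty")
  expect_error(trimmed_mean(1:3, 0.5), "0.5")
})
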