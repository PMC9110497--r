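test_that("layer backward passes match finite differences", {
  set.seed(21)
  x <- array(runif(6 * 8 * 2), c(6, 8, 2))
  for (cfg in list(list(s = 1L, p = 1L, refl = FALSE),
                   list(s = 2L, p = 1L, refl = TRUE))) {
    l <- desmokr:::nn_conv(2L, 3L, 3L, cfg$s, cfg$p, cfg$refl)
    f <- desmokr:::nn_forward(l, x)
    gy <- array(rnorm(length(f$y)), dim(f$y))
    desmokr:::nn_zero_grads(l)
    gx <- desmokr:::nn_backward(l, f$cache, gy)
    loss <- function() sum(desmokr:::nn_forward(l, x)$y * gy)
    eps <- 1e-6
    for (i in c(1L, 7L, length(l$W))) {
      w0 <- l$W[i]
      l$W[i] <- w0 + eps; up <- loss()
      l$W[i] <- w0 - eps; dn <- loss()
      l$W[i] <- w0
      expect_equal((up - dn) / (2 * eps), l$gW[i], tolerance = 1e-5)
    }
    for (i in c(1L, 25L)) {
      x0 <- x[i]
      x[i] <- x0 + eps; up <- loss()
      x[i] <- x0 - eps; dn <- loss()
      x[i] <- x0
      expect_equal((up - dn) / (2 * eps), gx[i], tolerance = 1e-5)
    }
  }
})

test_that("generator preserves shape and the unit range", {
  g <- build_generator(generator_spec(1L, 4L), seed = 31L)
  img <- rand_img(16)
  out <- apply_generator(g, img)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1 & is.finite(out)))
  # non-multiple-of-4 input is padded and cropped back
  odd <- rand_img(18, 22)
  expect_message(out2 <- apply_generator(g, odd), "padded")
  expect_equal(dim(out2), dim(odd))
})

test_that("initialisation is reproducible from the seed", {
  g1 <- build_generator(generator_spec(1L, 4L), seed = 5L)
  g2 <- build_generator(generator_spec(1L, 4L), seed = 5L)
  img <- rand_img(16)
  expect_identical(apply_generator(g1, img), apply_generator(g2, img))
})

test_that("parameter counts match layer-by-layer arithmetic", {
  # generator: conv params = cout*cin*k^2 + cout, instance norm unparametrised
  nres <- 2L; w <- 8L
  conv_p <- function(cin, cout, k) cout * cin * k^2 + cout
  gen_expected <- conv_p(3, w, 7) + conv_p(w, 2 * w, 3) +
    conv_p(2 * w, 4 * w, 3) +
    nres * 2 * conv_p(4 * w, 4 * w, 3) +
    conv_p(4 * w, 2 * w, 3) + conv_p(2 * w, w, 3) + conv_p(w, 3, 7)
  expect_equal(n_params(build_generator(generator_spec(nres, w), seed = 1L)),
               gen_expected)
  # discriminator, 3 stride-2 layers: 3->w->2w->4w then 8w then 1
  disc_expected <- conv_p(3, w, 4) + conv_p(w, 2 * w, 4) +
    conv_p(2 * w, 4 * w, 4) + conv_p(4 * w, 8 * w, 4) + conv_p(8 * w, 1, 4)
  expect_equal(n_params(build_discriminator(discriminator_spec(3L, w),
                                            seed = 1L)),
               disc_expected)
})

test_that("discriminator grid follows convolution arithmetic", {
  spec <- discriminator_spec(3L, 4L)
  d <- build_discriminator(spec, seed = 2L)
  s <- apply_discriminator(d, rand_img(256))
  expect_equal(dim(s), c(30L, 30L))
  expect_true(all(is.finite(s)))
  expect_equal(discriminator_output_shape(spec, 256L, 256L), c(30L, 30L))
  # doubling the input side roughly doubles each grid side
  expect_equal(discriminator_output_shape(spec, 512L, 512L), c(62L, 62L))
  expect_error(apply_discriminator(d, rand_img(8)), "receptive field")
})

test_that("checkpoints round-trip and detect tampering", {
  cfg <- tiny_cfg()
  st <- init_train_state(cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  st2 <- load_checkpoint(path)
  img <- rand_img(32)
  expect_identical(translate(st, img), translate(st2, img))
  # corrupt the weights file: the sidecar hash must catch it
  writeBin(as.raw(c(1, 2, 3)), path)
  expect_error(load_checkpoint(path), "hash mismatch")
})
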