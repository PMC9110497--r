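test_that("REA scores identity as 0 and edge removal as -1", {
  p <- make_tissue_phantom(64, 51)
  expect_equal(rea(p, p), 0)
  flat <- array(0.5, dim = dim(p))
  expect_equal(rea(p, flat), -1)
  expect_error(rea(flat, p), "no visible edges")
})

test_that("REA is the relative count of newly visible edges", {
  # one vertical step edge vs two identical ones (a band), far from the
  # borders: translation invariance of the edge detector makes the newly
  # visible edge rate exactly (2n - n) / n = 1
  h <- 64L; w <- 96L
  base <- array(0.25, dim = c(h, w, 3))
  one <- base; one[, 25:w, ] <- 0.75
  two <- base; two[, 25:48, ] <- 0.75
  expect_equal(rea(one, two), 1)
})

test_that("JNBM is deterministic and degrades under Gaussian blur", {
  p <- make_tissue_phantom(64, 61)
  expect_identical(jnbm(p), jnbm(p))
  expect_warning(expect_equal(jnbm(array(0.5, dim = c(64, 64, 3))), 0),
                 "no edge blocks")
  for (s in 1:3) {
    set.seed(s)
    img <- array(0.15, dim = c(64, 64, 3))
    for (k in 1:6) {   # edge-rich fixture: random bright rectangles
      i0 <- sample(5:40, 1); j0 <- sample(5:40, 1)
      img[i0:(i0 + sample(8:16, 1)), j0:(j0 + sample(8:16, 1)), ] <-
        runif(1, 0.7, 0.95)
    }
    j_sharp <- jnbm(img)
    j_mid <- jnbm(gauss_blur(img, 0.8))
    j_blur <- jnbm(gauss_blur(img, 1.6))
    expect_gt(j_sharp, j_mid)
    expect_gt(j_mid, j_blur)
  }
})

test_that("fog proxy is maximal on white and separates clear from hazy", {
  white <- array(1, dim = c(32, 32, 3))
  expect_equal(fog_density_proxy(white, patch = 7), 1)
  p <- make_tissue_phantom(48, 71)
  hz <- apply_scattering(p, make_transmission_field(
    48, smoke_params(density = 1.2, seed = 72)))
  expect_lt(fog_density_proxy(p, patch = 7),
            fog_density_proxy(hz, patch = 7))
  # with patch 1, no trimming and no refinement the proxy is a pixel mean,
  # invariant under channel-preserving pixel permutations
  set.seed(73)
  img <- rand_img(16)
  perm <- sample(256)
  shuffled <- array(apply(img, 3, function(ch) ch[perm]), dim = dim(img))
  expect_equal(fog_density_proxy(img, patch = 1, trim_frac = 0,
                                 refine = FALSE),
               fog_density_proxy(shuffled, patch = 1, trim_frac = 0,
                                 refine = FALSE))
})

test_that("evaluate_batch aggregates per-image metrics", {
  dir_a <- file.path(tempdir(), "eval_a")
  dir_b <- file.path(tempdir(), "eval_b")
  unlink(c(dir_a, dir_b), recursive = TRUE)
  dir.create(dir_a); dir.create(dir_b)
  for (i in 1:3) {
    p <- make_tissue_phantom(48, 80 + i)
    save_image(p, file.path(dir_a, sprintf("f%d.png", i)))
    save_image(p, file.path(dir_b, sprintf("f%d.png", i)))
  }
  csv <- tempfile(fileext = ".csv")
  rep <- evaluate_batch(dir_a, dir_b, patch = 7, refine = FALSE,
                        out_csv = csv)
  expect_equal(rep$per_image$rea, rep(0, 3))
  expect_equal(rep$aggregate$sd[rep$aggregate$metric == "rea"], 0)
  expect_equal(rep$aggregate$mean[rep$aggregate$metric == "jnbm"],
               mean(rep$per_image$jnbm))
  expect_true(file.exists(csv))
  # orphan filenames are an error
  save_image(make_tissue_phantom(48, 99), file.path(dir_a, "extra.png"))
  expect_error(evaluate_batch(dir_a, dir_b), "extra.png")
})
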