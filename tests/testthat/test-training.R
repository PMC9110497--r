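test_that("learning-rate schedule holds then decays linearly to zero", {
  cfg <- train_config(seed = 1L)            # 0.002, 50 + 50
  expect_equal(lr_at_epoch(cfg, 0), 0.002)
  expect_equal(lr_at_epoch(cfg, 10), 0.002)
  expect_equal(lr_at_epoch(cfg, 49), 0.002)
  expect_equal(lr_at_epoch(cfg, 50), 0.002)  # continuous at the boundary
  expect_equal(lr_at_epoch(cfg, 75), 0.001)
  expect_equal(lr_at_epoch(cfg, 99), 0.002 / 50)
  expect_equal(lr_at_epoch(cfg, 100), 0)
  expect_error(lr_at_epoch(cfg, 101), "outside")
  expect_error(lr_at_epoch(cfg, -1), "outside")
})

test_that("train_step is deterministic and its breakdown recomposes", {
  cfg <- tiny_cfg(seed = 13L)
  ba <- lapply(1:2, function(i) make_tissue_phantom(32, i))
  bb <- lapply(1:2, function(i)
    apply_scattering(make_tissue_phantom(32, 50 + i),
                     make_transmission_field(32, smoke_params(seed = 80 + i))))
  st1 <- init_train_state(cfg)
  set.seed(100); b1 <- train_step(ba, bb, st1)
  st2 <- init_train_state(cfg)
  set.seed(100); b2 <- train_step(ba, bb, st2)
  expect_identical(b1$total, b2$total)
  w <- cfg$weights
  expect_equal(b1$adversarial_G + b1$adversarial_F + w$lambda_cyc * b1$cycle +
                 w$alpha * b1$ic + w$beta * b1$dc, b1$total)
})

test_that("with alpha = beta = 0 the step loss equals an independent baseline", {
  cfg <- tiny_cfg(seed = 17L, alpha = 0, beta = 0)
  ba <- lapply(1:2, function(i) make_tissue_phantom(32, 200 + i))
  bb <- lapply(1:2, function(i)
    apply_scattering(make_tissue_phantom(32, 300 + i),
                     make_transmission_field(32, smoke_params(seed = 400 + i))))
  st <- init_train_state(cfg)
  # independent recomputation from the same initial weights
  oracle <- 0
  for (i in 1:2) {
    fy <- apply_generator(st$G, ba[[i]])
    fx <- apply_generator(st$F, bb[[i]])
    oracle <- oracle +
      (mean((apply_discriminator(st$Dy, fy) - 1)^2) +
       mean((apply_discriminator(st$Dx, fx) - 1)^2) +
       10 * (mean(abs(apply_generator(st$F, fy) - ba[[i]])) +
             mean(abs(apply_generator(st$G, fx) - bb[[i]])))) / 2
  }
  set.seed(5)
  br <- train_step(ba, bb, st)
  expect_equal(br$total, oracle, tolerance = 1e-6)
})

test_that("smoke-aware weights shift the objective by exactly their terms", {
  ba <- lapply(1:2, function(i) make_tissue_phantom(32, 600 + i))
  bb <- lapply(1:2, function(i)
    apply_scattering(make_tissue_phantom(32, 700 + i),
                     make_transmission_field(32, smoke_params(seed = 800 + i))))
  st_a <- init_train_state(tiny_cfg(seed = 19L, alpha = 3, beta = 0.05))
  st_b <- init_train_state(tiny_cfg(seed = 19L, alpha = 0, beta = 0))
  set.seed(7); br_a <- train_step(ba, bb, st_a)
  set.seed(7); br_b <- train_step(ba, bb, st_b)
  expect_equal(br_a$cycle, br_b$cycle)
  expect_equal(br_a$total - br_b$total, 3 * br_a$ic + 0.05 * br_a$dc,
               tolerance = 1e-12)
})

test_that("fit runs an epoch, logs losses and saves a checkpoint", {
  root <- tiny_dataset(n = 4L, size = 32L)
  out <- file.path(tempdir(), "fit_run")
  unlink(out, recursive = TRUE)
  ck <- suppressMessages(fit(tiny_cfg(seed = 23L), root, out, verbose = FALSE))
  expect_length(ck, 1L)
  expect_true(file.exists(ck))
  log <- read.csv(file.path(out, "losses.csv"))
  expect_equal(nrow(log), 1L)
  expect_named(log, c("epoch", "lr", "adv_G", "adv_F", "cycle", "ic", "dc",
                      "total"))
  expect_equal(log$lr, 0.002)
  # resuming restores the scheduled learning rate for the stored epoch
  st <- load_checkpoint(ck)
  expect_equal(st$epoch, 1L)
  expect_error(fit(tiny_cfg(), file.path(tempdir(), "nowhere")),
               "empty domain")
})

test_that("translation is deterministic and shape-preserving", {
  st <- init_train_state(tiny_cfg(seed = 29L))
  img <- rand_img(32)
  out1 <- translate(st, img)
  expect_equal(dim(out1), dim(img))
  expect_identical(out1, translate(st, img))
  expect_false(identical(out1, translate(st, img, "clear_to_hazy")))
})
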