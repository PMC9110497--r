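test_that("least-squares adversarial loss penalises score deviation", {
  ones <- matrix(1, 4, 4)
  expect_equal(adversarial_loss(ones, TRUE), 0)
  expect_equal(adversarial_loss(ones * 0, TRUE), 1)
  expect_equal(adversarial_loss(ones * 0.5, TRUE), 0.25)
  expect_equal(adversarial_loss(ones * 0.5, FALSE), 0.25)
  # logistic form of the original minimax objective
  expect_equal(adversarial_loss(ones * 0.5, TRUE, form = "log"), log(2))
  expect_error(adversarial_loss(matrix(NaN, 2, 2), TRUE), "finite")
})

test_that("cycle loss is the summed mean L1 of both round trips", {
  x <- rand_img(6); y <- rand_img(6)
  expect_equal(cycle_loss(x, x, y, y), 0)
  expect_equal(cycle_loss(x * 0, x * 0 + 1, y, y), 1)
  # symmetric in swapping the two cycles' roles
  xr <- rand_img(6); yr <- rand_img(6)
  expect_equal(cycle_loss(x, xr, y, yr), cycle_loss(y, yr, x, xr))
  expect_error(cycle_loss(x, rand_img(4), y, y), "match")
})

test_that("direction mapping uses 1 as the boundary", {
  expect_equal(ic_direction_map(1, "hazy_to_clear"), 0)
  expect_equal(ic_direction_map(1, "clear_to_hazy"), 1)
  expect_equal(ic_direction_map(0.3, "hazy_to_clear"), 0.7)
  expect_equal(ic_direction_map(0.3, "clear_to_hazy"), 0.3)
})

test_that("ic_loss composes the normalised discrepancy with the mapping", {
  grey <- array(0.5, dim = c(4, 4, 3))
  # both generated images achromatic: towards-hazy term 0, towards-clear 1
  expect_equal(ic_loss(grey, grey), 1)
  # raw discrepancy 1 (normalised 0.5) in both: 0.5 + 0.5
  mid <- array(rep(c(0.75, 0.25, 0.25), each = 16), dim = c(4, 4, 3))
  expect_equal(interchannel_image(mid), 1)
  expect_equal(ic_loss(mid, mid), 1)
  set.seed(11)
  for (i in 1:10) {
    fh <- rand_img(8); fc <- rand_img(8)
    oracle <- ic_direction_map(interchannel_image(fh) / 2, "clear_to_hazy") +
      ic_direction_map(interchannel_image(fc) / 2, "hazy_to_clear")
    expect_equal(ic_loss(fh, fc), oracle)
  }
})

test_that("dc_loss composes trimmed mean with the dark channel", {
  white <- array(1, dim = c(8, 8, 3))
  expect_equal(dc_loss(white, white, patch = 3), 2)
  zero_b <- rand_img(8); zero_b[, , 3] <- 0
  expect_equal(dc_loss(zero_b, zero_b, patch = 3), 0)
  set.seed(12)
  for (i in 1:5) {
    fh <- rand_img(10); fc <- rand_img(10)
    oracle <- trimmed_mean(as.numeric(dark_channel(fc, 5)), 0.02) +
      trimmed_mean(as.numeric(dark_channel(fh, 5)), 0.02)
    expect_equal(dc_loss(fh, fc, patch = 5, trim_frac = 0.02), oracle,
                 tolerance = 1e-10)
  }
})

test_that("total objective reduces to the baseline when alpha = beta = 0", {
  br <- total_objective(0.3, 0.4, 0.2, 0.9, 0.8,
                        loss_weights(alpha = 0, beta = 0))
  expect_equal(br$total, 0.3 + 0.4 + 10 * 0.2)
  br2 <- total_objective(1, 0, 1, 1, 1, loss_weights())
  expect_equal(br2$total, 14.05)
  # breakdown fields recompose to the total
  w <- loss_weights(alpha = 2, beta = 0.1, lambda_cyc = 5)
  br3 <- total_objective(0.1, 0.2, 0.3, 0.4, 0.5, w)
  expect_equal(br3$adversarial_G + br3$adversarial_F + 5 * br3$cycle +
                 2 * br3$ic + 0.1 * br3$dc, br3$total)
  expect_error(total_objective(Inf, 0, 0, 0, 0), "adversarial_G")
  expect_error(loss_weights(beta = -1), "non-negative")
})
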