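# shared fixtures and independent oracles

# brute-force dark channel: double loop over clamped windows
dark_channel_brute <- function(img, patch) {
  r <- patch %/% 2L
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- min(img[max(1, i - r):min(h, i + r),
                         max(1, j - r):min(w, j + r), ])
  out
}

# per-pixel loop oracle for the mean inter-channel discrepancy
interchannel_brute <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  acc <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    p <- img[i, j, ]
    acc <- acc + abs(p[1] - p[2]) + abs(p[2] - p[3]) + abs(p[3] - p[1])
  }
  acc / (h * w)
}

rand_img <- function(h, w = h) array(runif(h * w * 3), dim = c(h, w, 3))

gauss_blur <- function(img, sigma)
  desmokr:::eb_to_img(EBImage::gblur(desmokr:::img_to_eb(img),
                                     sigma = sigma))

# dense-matrix construction of the 3x3-window matting Laplacian, written
# independently of the package's sparse builder
matting_laplacian_dense <- function(guide, eps_cov = 1e-6) {
  h <- dim(guide)[1]; w <- dim(guide)[2]
  n <- h * w
  L <- matrix(0, n, n)
  for (cj in 2:(w - 1)) for (ci in 2:(h - 1)) {
    idx <- integer(0); cols <- NULL
    for (dj in -1:1) for (di in -1:1) {
      idx <- c(idx, (ci + di) + (cj + dj - 1) * h)
      cols <- rbind(cols, guide[ci + di, cj + dj, ])
    }
    mu <- colMeans(cols)
    G <- sweep(cols, 2, mu)
    S <- t(G) %*% G / 9 + diag(3) * eps_cov / 9
    Mi <- solve(S)
    val <- diag(9) - (1 + G %*% Mi %*% t(G)) / 9
    L[idx, idx] <- L[idx, idx] + val
  }
  L
}

# a small test dataset on disk; returns its root
tiny_dataset <- function(n = 4L, size = 32L, seed = 9L) {
  root <- file.path(tempdir(), paste0("ds_", n, "_", size, "_", seed))
  if (!dir.exists(root))
    make_dataset(n, size, c(light = 0.5, heavy = 0.5), seed = seed,
                 out_dir = root)
  root
}

# small train config for fast smoke tests
tiny_cfg <- function(seed = 7L, alpha = 3, beta = 0.05, crop = 32L,
                     epochs_const = 1L, epochs_decay = 0L) {
  train_config(epochs_const = epochs_const, epochs_decay = epochs_decay,
               batch_size = 2L, crop = crop, seed = seed,
               weights = loss_weights(alpha = alpha, beta = beta),
               gen_spec = generator_spec(1L, 4L),
               disc_spec = discriminator_spec(1L, 4L),
               pool_size = 4L, save_every = 1L)
}
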