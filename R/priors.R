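#' Inter-channel discrepancy of a single pixel
#'
#' For a pixel P with unit-range channels (R, G, B) the discrepancy is
#' \deqn{\Psi(P) = |P_R - P_G| + |P_G - P_B| + |P_B - P_R|,}
#' the sum of absolute pairwise channel differences.  Achromatic pixels
#' (R = G = B), which is what dense grey smoke produces, score 0; a fully
#' saturated primary scores the maximum of 2.
#'
#' @param p numeric vector of length 3 (R, G, B), each in [0, 1].
#' @return scalar in [0, 2].
#' @export
interchannel_pixel <- function(p) {
  if (length(p) != 3L || anyNA(p) || min(p) < 0 || max(p) > 1)
    stop("a pixel is a length-3 numeric in [0, 1]")
  abs(p[1] - p[2]) + abs(p[2] - p[3]) + abs(p[3] - p[1])
}

#' Mean inter-channel discrepancy of an image
#'
#' The per-pixel discrepancy \eqn{\Psi} averaged over all pixels:
#' \eqn{I^{IC} = \frac{1}{n}\sum_i \Psi(P_i)}.  Near 0 for grey (heavily
#' smoked) frames, larger for colourful smoke-free tissue.
#'
#' @param img H x W x 3 array in [0, 1].
#' @return scalar in [0, 2].
#' @export
interchannel_image <- function(img) {
  img <- image_rgb(img)
  if (length(img) == 0L) stop("empty image")
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  mean(abs(r - g) + abs(g - b) + abs(b - r))
}

# min filter along rows with the window clamped to the image
minfilt_rows <- function(m, r) {
  h <- nrow(m)
  out <- m
  if (r >= 1L) for (d in seq_len(min(r, h - 1L))) {
    out[1:(h - d), ] <- pmin(out[1:(h - d), , drop = FALSE],
                             m[(1 + d):h, , drop = FALSE])
    out[(1 + d):h, ] <- pmin(out[(1 + d):h, , drop = FALSE],
                             m[1:(h - d), , drop = FALSE])
  }
  out
}

#' Dark channel of an image
#'
#' The dark channel at pixel x is the minimum intensity over all three
#' colour channels within a patch centred at x:
#' \deqn{I^{dark}(x) = \min_{y \in \Omega(x)} \min_{c \in \{r,g,b\}} I^c(y).}
#' Smoke-free tissue drives it towards 0; haze (a convex shift towards
#' bright atmospheric light) lifts it.  The min window is clamped to the
#' image at the borders, so no artificial padding value ever wins.
#'
#' The patch minimum is computed separably (row pass then column pass),
#' which is exactly equivalent to the double minimum over the clamped
#' rectangular window.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param patch odd positive window side (default 15, the dehazing
#'   literature's standard at full resolution; use a smaller patch such as
#'   7 inside training losses on crops).
#' @return H x W matrix in [0, 1].
#' @export
dark_channel <- function(img, patch = 15L) {
  img <- image_rgb(img)
  patch <- as.integer(patch)
  if (patch < 1L || patch %% 2L == 0L)
    stop("patch must be an odd positive integer")
  m <- pmin(img[, , 1L], img[, , 2L], img[, , 3L])
  r <- patch %/% 2L
  t(minfilt_rows(t(minfilt_rows(m, r)), r))
}

# Matting Laplacian of Levin et al. with 3x3 windows, as a sparse matrix.
# eps_cov regularises the per-window colour covariance.
matting_laplacian <- function(guide, eps_cov = 1e-6) {
  h <- dim(guide)[1]; w <- dim(guide)[2]
  if (h < 3L || w < 3L) stop("guide image must be at least 3 x 3")
  n <- h * w
  ci <- rep(2:(h - 1L), times = w - 2L)
  cj <- rep(2:(w - 1L), each = h - 2L)
  nw <- length(ci)                        # number of 3x3 windows
  # indices of the 9 pixels of each window (column-major pixel ids)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  widx <- matrix(0L, nw, 9L)
  for (p in 1:9)
    widx[, p] <- (ci + offs$di[p]) + (cj + offs$dj[p] - 1L) * h
  # colours: nw x 9 x 3
  G <- array(0, dim = c(nw, 9L, 3L))
  for (c in 1:3) {
    ch <- guide[, , c]
    for (p in 1:9) G[, p, c] <- ch[widx[, p]]
  }
  mu <- array(0, dim = c(nw, 3L))
  for (c in 1:3) mu[, c] <- rowMeans(G[, , c])
  for (c in 1:3) G[, , c] <- G[, , c] - mu[, c]
  # per-window regularised covariance (biased, /9) and its inverse
  S <- array(0, dim = c(nw, 3L, 3L))
  for (a in 1:3) for (b in a:3) {
    v <- rowSums(G[, , a] * G[, , b]) / 9
    if (a == b) v <- v + eps_cov / 9
    S[, a, b] <- v; S[, b, a] <- v
  }
  # closed-form 3x3 inverse, vectorised over windows
  A <- S[, 1, 1]; B <- S[, 1, 2]; C <- S[, 1, 3]
  D <- S[, 2, 2]; E <- S[, 2, 3]; F <- S[, 3, 3]
  det <- A * (D * F - E * E) - B * (B * F - C * E) + C * (B * E - C * D)
  M <- array(0, dim = c(nw, 3L, 3L))
  M[, 1, 1] <- (D * F - E * E) / det
  M[, 1, 2] <- M[, 2, 1] <- (C * E - B * F) / det
  M[, 1, 3] <- M[, 3, 1] <- (B * E - C * D) / det
  M[, 2, 2] <- (A * F - C * C) / det
  M[, 2, 3] <- M[, 3, 2] <- (B * C - A * E) / det
  M[, 3, 3] <- (A * D - B * B) / det
  # T = G %*% M per window, then S9[p, q] = 1 + T[p, ] . G[q, ]
  TT <- array(0, dim = c(nw, 9L, 3L))
  for (k in 1:3)
    TT[, , k] <- G[, , 1] * M[, 1, k] + G[, , 2] * M[, 2, k] +
                 G[, , 3] * M[, 3, k]
  ii <- integer(nw * 81L); jj <- integer(nw * 81L); xx <- numeric(nw * 81L)
  pos <- 0L
  for (p in 1:9) for (q in 1:9) {
    s <- TT[, p, 1] * G[, q, 1] + TT[, p, 2] * G[, q, 2] +
         TT[, p, 3] * G[, q, 3]
    val <- (if (p == q) 1 else 0) - (1 + s) / 9
    rng <- pos + seq_len(nw)
    ii[rng] <- widx[, p]; jj[rng] <- widx[, q]; xx[rng] <- val
    pos <- pos + nw
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Refine a dark channel by soft matting
#'
#' Solves the matting-Laplacian-regularised linear system
#' \deqn{(L + \epsilon E)\, t = \epsilon\, t_{raw}}
#' where L is the matting Laplacian of the colour guide image built from
#' 3x3 local windows.  The refinement snaps discontinuities of the raw map
#' to edges of the guide while the data term keeps the overall level.
#' Solved by Jacobi-preconditioned conjugate gradients (the system is
#' symmetric positive definite); constant raw maps lie in the Laplacian's
#' null space and are returned unchanged.
#'
#' @param raw H x W matrix in [0, 1] (e.g. a raw dark channel).
#' @param guide H x W x 3 colour image guiding the refinement.
#' @param eps weight of the data term (default 1e-4, the soft-matting
#'   refinement's standard value).
#' @param eps_cov covariance regulariser inside the matting Laplacian
#'   (default 1e-6).
#' @param tol relative residual tolerance of the solver (default 1e-6).
#' @param maxit iteration cap (default 4000).
#' @return H x W matrix in [0, 1].
#' @export
refine_dark_channel <- function(raw, guide, eps = 1e-4, eps_cov = 1e-6,
                                tol = 1e-6, maxit = 4000L) {
  check_gray(raw)
  guide <- image_rgb(guide)
  if (!all(dim(raw) == dim(guide)[1:2]))
    stop("raw map and guide image must share their spatial shape")
  if (eps <= 0) stop("eps must be positive")
  n <- length(raw)
  L <- matting_laplacian(guide, eps_cov)
  A <- L + eps * Matrix::Diagonal(n)
  b <- eps * as.numeric(raw)
  dinv <- 1 / Matrix::diag(A)
  x <- as.numeric(raw)
  r <- b - as.numeric(A %*% x)
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- max(sqrt(sum(b^2)), .Machine$double.eps)
  it <- 0L
  while (sqrt(sum(r^2)) / bnorm > tol && it < maxit) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    it <- it + 1L
  }
  res <- sqrt(sum(r^2)) / bnorm
  if (res > tol)
    stop(sprintf(
      "soft-matting solver did not converge: relative residual %.3e after %d iterations",
      res, it))
  matrix(pmin(pmax(x, 0), 1), nrow(raw), ncol(raw))
}

#' Trimmed mean with symmetric rank-based trimming
#'
#' Discards the lowest and highest `trim_frac` fractions of the values (by
#' rank, `floor(n * trim_frac)` from each tail) and averages the rest.
#' Used to aggregate dark channels robustly: specular highlights and
#' near-black vignette pixels are excluded before averaging.
#'
#' @param values non-empty numeric vector.
#' @param trim_frac fraction trimmed from each tail, in [0, 0.5)
#'   (default 0.01).
#' @return scalar mean of the kept values.
#' @export
trimmed_mean <- function(values, trim_frac = 0.01) {
  if (length(values) == 0L) stop("trimmed_mean of an empty collection")
  if (trim_frac < 0 || trim_frac >= 0.5)
    stop("trim_frac must lie in [0, 0.5)")
  n <- length(values)
  k <- floor(n * trim_frac)
  if (n - 2 * k < 1L) stop("trimming removed every value")
  s <- sort(values)
  mean(s[(k + 1L):(n - k)])
}

# Per-element subgradient weights of trimmed_mean: 1/n_kept on kept ranks,
# 0 on trimmed ones (first-occurrence rank for ties).  Internal.
trimmed_mean_grad <- function(values, trim_frac = 0.01) {
  n <- length(values)
  k <- floor(n * trim_frac)
  ord <- order(values)
  w <- numeric(n)
  kept <- ord[(k + 1L):(n - k)]
  w[kept] <- 1 / length(kept)
  w
}
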