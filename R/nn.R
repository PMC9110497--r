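# Minimal CNN layer framework with explicit forward caches and hand-written
# backward passes.  Layers are environments (mutable parameter + gradient
# buffers); convolutions run through the compiled im2col/GEMM kernels in
# src/conv.cpp.  Arrays are H x W x C throughout.

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  class(e) <- "desmokr_layer"
  e
}

# convolution, weights drawn from N(0, 0.02), bias zero
nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L, reflect = FALSE) {
  e <- new_layer("conv", k = as.integer(k), stride = as.integer(stride),
                 pad = as.integer(pad), reflect = reflect,
                 cin = as.integer(cin), cout = as.integer(cout))
  e$W <- matrix(stats::rnorm(cout * cin * k * k, 0, 0.02), nrow = cout)
  e$b <- numeric(cout)
  e$gW <- matrix(0, cout, cin * k * k)
  e$gb <- numeric(cout)
  e
}

nn_inorm <- function() new_layer("inorm")
nn_act <- function(type) new_layer(match.arg(type, c("relu", "lrelu", "tanh")))
nn_up2 <- function() new_layer("up2")
nn_affine <- function(a, b0) new_layer("affine", a = a, b0 = b0)
nn_seq <- function(layers) new_layer("seq", layers = layers)
nn_res <- function(body) new_layer("res", body = body)

# forward pass; returns list(y, cache) where cache holds what backward needs
nn_forward <- function(l, x) {
  switch(l$kind,
    conv = list(y = conv2d_fwd(x, l$W, l$b, l$k, l$stride, l$pad, l$reflect),
                cache = x),
    inorm = {
      d <- dim(x); m <- d[1] * d[2]
      xm <- matrix(x, m)
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      s <- sqrt(colMeans(xc^2) + 1e-5)
      xh <- sweep(xc, 2, s, "/")
      list(y = array(xh, d), cache = list(xh = xh, s = s, d = d))
    },
    relu = { y <- x; y[y < 0] <- 0; list(y = y, cache = x > 0) },
    lrelu = {
      pos <- x > 0
      y <- x; y[!pos] <- 0.2 * y[!pos]
      list(y = y, cache = pos)
    },
    tanh = { y <- tanh(x); list(y = y, cache = y) },
    affine = list(y = l$a * x + l$b0, cache = NULL),
    up2 = {
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
             drop = FALSE]
      list(y = y, cache = d)
    },
    seq = {
      caches <- vector("list", length(l$layers))
      for (i in seq_along(l$layers)) {
        r <- nn_forward(l$layers[[i]], x)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    res = {
      r <- nn_forward(l$body, x)
      list(y = x + r$y, cache = r$cache)
    },
    stop("unknown layer kind: ", l$kind))
}

# backward pass; returns the input gradient and (when acc) accumulates
# parameter gradients into the layer environments
nn_backward <- function(l, cache, gy, acc = TRUE) {
  switch(l$kind,
    conv = {
      g <- conv2d_bwd(cache, l$W, gy, l$k, l$stride, l$pad, l$reflect)
      if (acc) {
        l$gW <- l$gW + g$gW
        l$gb <- l$gb + as.numeric(g$gb)
      }
      g$gx
    },
    inorm = {
      d <- cache$d; m <- d[1] * d[2]
      gym <- matrix(gy, m)
      xh <- cache$xh
      gx <- sweep(gym, 2, colMeans(gym)) -
        sweep(xh, 2, colMeans(gym * xh), "*")
      array(sweep(gx, 2, cache$s, "/"), d)
    },
    relu = gy * cache,
    lrelu = { g <- gy; g[!cache] <- 0.2 * g[!cache]; g },
    tanh = gy * (1 - cache^2),
    affine = l$a * gy,
    up2 = {
      d <- cache
      r1 <- seq(1L, 2L * d[1], 2L); r2 <- r1 + 1L
      c1 <- seq(1L, 2L * d[2], 2L); c2 <- c1 + 1L
      gy[r1, c1, , drop = FALSE] + gy[r2, c1, , drop = FALSE] +
        gy[r1, c2, , drop = FALSE] + gy[r2, c2, , drop = FALSE]
    },
    seq = {
      for (i in rev(seq_along(l$layers)))
        gy <- nn_backward(l$layers[[i]], cache[[i]], gy, acc)
      gy
    },
    res = gy + nn_backward(l$body, cache, gy, acc),
    stop("unknown layer kind: ", l$kind))
}

# flat list of the parameter-carrying (conv) layer environments
nn_param_layers <- function(l) {
  switch(l$kind,
    conv = list(l),
    seq = do.call(c, lapply(l$layers, nn_param_layers)),
    res = nn_param_layers(l$body),
    list())
}

nn_zero_grads <- function(l) {
  for (e in nn_param_layers(l)) {
    e$gW[] <- 0
    e$gb[] <- 0
  }
  invisible(NULL)
}

nn_n_params <- function(l)
  sum(vapply(nn_param_layers(l),
             function(e) length(e$W) + length(e$b), numeric(1)))

# parameter snapshot / restore, for checkpointing
nn_state <- function(l)
  lapply(nn_param_layers(l), function(e) list(W = e$W, b = e$b))

nn_set_state <- function(l, state) {
  layers <- nn_param_layers(l)
  if (length(layers) != length(state))
    stop("checkpoint state does not match the network architecture")
  for (i in seq_along(layers)) {
    if (!all(dim(layers[[i]]$W) == dim(state[[i]]$W)))
      stop("checkpoint weight shapes do not match the network architecture")
    layers[[i]]$W <- state[[i]]$W
    layers[[i]]$b <- state[[i]]$b
  }
  invisible(NULL)
}

# Adam over a list of conv-layer environments (momenta kept in the optimiser)
adam_new <- function(param_layers, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$layers <- param_layers
  o$beta1 <- beta1; o$beta2 <- beta2; o$eps <- eps; o$t <- 0L
  o$mW <- lapply(param_layers, function(e) e$gW * 0)
  o$vW <- lapply(param_layers, function(e) e$gW * 0)
  o$mb <- lapply(param_layers, function(e) e$gb * 0)
  o$vb <- lapply(param_layers, function(e) e$gb * 0)
  o
}

adam_step <- function(o, lr) {
  o$t <- o$t + 1L
  c1 <- 1 - o$beta1^o$t
  c2 <- 1 - o$beta2^o$t
  for (i in seq_along(o$layers)) {
    e <- o$layers[[i]]
    o$mW[[i]] <- o$beta1 * o$mW[[i]] + (1 - o$beta1) * e$gW
    o$vW[[i]] <- o$beta2 * o$vW[[i]] + (1 - o$beta2) * e$gW^2
    o$mb[[i]] <- o$beta1 * o$mb[[i]] + (1 - o$beta1) * e$gb
    o$vb[[i]] <- o$beta2 * o$vb[[i]] + (1 - o$beta2) * e$gb^2
    e$W <- e$W - lr * (o$mW[[i]] / c1) / (sqrt(o$vW[[i]] / c2) + o$eps)
    e$b <- e$b - lr * (o$mb[[i]] / c1) / (sqrt(o$vb[[i]] / c2) + o$eps)
  }
  invisible(NULL)
}
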