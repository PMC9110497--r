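#' Generator architecture specification
#'
#' A ResNet-style encoder/decoder generator: a 7x7 stem, two stride-2
#' downsampling convolutions, `n_res_blocks` residual blocks at 4x the
#' base width, two nearest-neighbour-upsample + convolution stages, and a
#' 7x7 output convolution with a tanh squashing.  Instance normalisation
#' throughout.
#'
#' @param n_res_blocks number of residual blocks (default 9, the standard
#'   choice for 256x256 inputs).
#' @param base_width channel width of the stem (default 64).
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n_res_blocks = 9L, base_width = 64L) {
  if (n_res_blocks < 1L) stop("n_res_blocks must be >= 1")
  if (base_width < 1L) stop("base_width must be >= 1")
  structure(list(n_res_blocks = as.integer(n_res_blocks),
                 base_width = as.integer(base_width)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' A PatchGAN discriminator: `n_layers` stride-2 4x4 convolutions followed
#' by two stride-1 convolutions, emitting a grid of patch scores whose
#' receptive field is 70x70 for the default 3-layer spec.
#'
#' @param n_layers number of stride-2 convolution layers (default 3).
#' @param base_width channel width of the first layer (default 64).
#' @return list of class `discriminator_spec`.
#' @export
discriminator_spec <- function(n_layers = 3L, base_width = 64L) {
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (base_width < 1L) stop("base_width must be >= 1")
  structure(list(n_layers = as.integer(n_layers),
                 base_width = as.integer(base_width)),
            class = "discriminator_spec")
}

generator_layers <- function(spec) {
  w <- spec$base_width
  layers <- list(
    nn_affine(2, -1),                                   # [0,1] -> [-1,1]
    nn_conv(3L, w, 7L, 1L, 3L, reflect = TRUE), nn_inorm(), nn_act("relu"),
    nn_conv(w, 2L * w, 3L, 2L, 1L), nn_inorm(), nn_act("relu"),
    nn_conv(2L * w, 4L * w, 3L, 2L, 1L), nn_inorm(), nn_act("relu"))
  for (i in seq_len(spec$n_res_blocks))
    layers <- c(layers, list(nn_res(nn_seq(list(
      nn_conv(4L * w, 4L * w, 3L, 1L, 1L, reflect = TRUE), nn_inorm(),
      nn_act("relu"),
      nn_conv(4L * w, 4L * w, 3L, 1L, 1L, reflect = TRUE), nn_inorm())))))
  c(layers, list(
    nn_up2(), nn_conv(4L * w, 2L * w, 3L, 1L, 1L), nn_inorm(),
    nn_act("relu"),
    nn_up2(), nn_conv(2L * w, w, 3L, 1L, 1L), nn_inorm(), nn_act("relu"),
    nn_conv(w, 3L, 7L, 1L, 3L, reflect = TRUE), nn_act("tanh"),
    nn_affine(0.5, 0.5)))                               # [-1,1] -> [0,1]
}

#' Build a generator network
#'
#' The generator maps a unit-range RGB image to a unit-range RGB image of
#' the same spatial shape.  Internally values are remapped to [-1, 1] and
#' squashed back through tanh at the boundary; all loss functions operate
#' on the [0, 1] output.  Weights are initialised from N(0, 0.02).
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer; when given, initialisation is a pure
#'   function of the seed.
#' @return object of class `desmokr_generator`.
#' @export
build_generator <- function(spec = generator_spec(), seed = NULL) {
  net <- if (is.null(seed)) nn_seq(generator_layers(spec)) else
    withr::with_seed(as.integer(seed), nn_seq(generator_layers(spec)))
  structure(list(net = net, spec = spec), class = "desmokr_generator")
}

# reflect-pad an image on the bottom/right to a multiple of `mult`
pad_to_multiple <- function(img, mult = 4L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ph <- (mult - h %% mult) %% mult
  pw <- (mult - w %% mult) %% mult
  if (ph > 0L) img <- img[c(seq_len(h), (h - 1L):(h - ph)), , , drop = FALSE]
  if (pw > 0L) img <- img[, c(seq_len(w), (w - 1L):(w - pw)), , drop = FALSE]
  list(img = img, ph = ph, pw = pw)
}

#' Apply a generator to an image
#'
#' Inference-only forward pass.  Inputs whose sides are not divisible by
#' the network's downsampling factor (4) are reflect-padded and the output
#' cropped back, with a `message()` noting the padding.
#'
#' @param gen a `desmokr_generator`.
#' @param img H x W x 3 array in [0, 1].
#' @return H x W x 3 array in [0, 1].
#' @export
apply_generator <- function(gen, img) {
  img <- image_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  p <- pad_to_multiple(img, 4L)
  if (p$ph > 0L || p$pw > 0L)
    message("input ", h, "x", w,
            " reflect-padded to a multiple of 4 and cropped back")
  y <- nn_forward(gen$net, p$img)$y
  image_rgb(y[seq_len(h), seq_len(w), , drop = FALSE])
}

discriminator_layers <- function(spec) {
  w <- spec$base_width; n <- spec$n_layers
  layers <- list(nn_affine(2, -1),
                 nn_conv(3L, w, 4L, 2L, 1L), nn_act("lrelu"))
  mult <- 1L
  if (n >= 2L) for (i in 2:n) {
    prev <- mult
    mult <- min(2L^(i - 1L), 8L)
    layers <- c(layers, list(nn_conv(w * prev, w * mult, 4L, 2L, 1L),
                             nn_inorm(), nn_act("lrelu")))
  }
  prev <- mult
  mult <- min(2L^n, 8L)
  c(layers, list(nn_conv(w * prev, w * mult, 4L, 1L, 1L), nn_inorm(),
                 nn_act("lrelu"),
                 nn_conv(w * mult, 1L, 4L, 1L, 1L)))
}

#' Patch-score grid shape of a discriminator
#'
#' Convolution output-size arithmetic for the PatchGAN stack: `n_layers`
#' 4x4 stride-2 convolutions (pad 1) followed by two 4x4 stride-1
#' convolutions (pad 1).
#'
#' @param spec a [discriminator_spec()].
#' @param h,w input height and width.
#' @return integer vector (grid height, grid width).
#' @export
discriminator_output_shape <- function(spec, h, w) {
  conv_out <- function(n, k, s) (n + 2L - k) %/% s + 1L
  for (i in seq_len(spec$n_layers)) {
    h <- conv_out(h, 4L, 2L); w <- conv_out(w, 4L, 2L)
  }
  for (i in 1:2) { h <- conv_out(h, 4L, 1L); w <- conv_out(w, 4L, 1L) }
  c(h, w)
}

#' Build a PatchGAN discriminator
#'
#' Emits a grid of unbounded patch scores, each judging one receptive
#' field of the input (70x70 pixels for the default 3-layer spec).  Scores
#' feed the least-squares adversarial loss; they are not probabilities.
#'
#' @param spec a [discriminator_spec()].
#' @param seed optional integer for reproducible initialisation.
#' @return object of class `desmokr_discriminator`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = NULL) {
  net <- if (is.null(seed)) nn_seq(discriminator_layers(spec)) else
    withr::with_seed(as.integer(seed), nn_seq(discriminator_layers(spec)))
  structure(list(net = net, spec = spec), class = "desmokr_discriminator")
}

#' Apply a discriminator to an image
#'
#' @param disc a `desmokr_discriminator`.
#' @param img H x W x 3 array in [0, 1].
#' @return matrix of patch scores, strictly smaller than the input.
#' @export
apply_discriminator <- function(disc, img) {
  img <- image_rgb(img)
  shp <- discriminator_output_shape(disc$spec, dim(img)[1], dim(img)[2])
  if (any(shp < 1L))
    stop("input ", dim(img)[1], "x", dim(img)[2],
         " is smaller than one discriminator receptive field")
  y <- nn_forward(disc$net, img)$y
  y[, , 1L]
}

#' Number of trainable parameters of a network
#'
#' @param x a `desmokr_generator` or `desmokr_discriminator`.
#' @return integer parameter count (weights + biases).
#' @export
n_params <- function(x) nn_n_params(x$net)
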