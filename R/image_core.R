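#' Construct / validate a unit-range RGB image
#'
#' Images throughout the package are plain H x W x 3 numeric arrays with
#' values in [0, 1] and fixed channel order R, G, B.  `image_rgb()` checks
#' an array against that contract (clamping tiny numeric overshoots) and
#' returns it.
#'
#' @param pixels numeric H x W x 3 array.
#' @param clamp clamp values within `1e-9` of the unit range instead of
#'   failing (default TRUE).
#' @return the validated array.
#' @export
image_rgb <- function(pixels, clamp = TRUE) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("an RGB image must be an H x W x 3 array")
  if (!is.numeric(pixels) || anyNA(pixels))
    stop("image contains non-numeric or missing values")
  if (clamp) pixels <- pmin(pmax(pixels, 0), 1)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image values must lie in [0, 1]")
  pixels
}

#' @keywords internal
check_gray <- function(g) {
  if (!is.matrix(g) || !is.numeric(g))
    stop("a grey map must be a numeric H x W matrix")
  g
}

# EBImage stores images as (x = width, y = height[, channel]); the package
# convention is (row = height, col = width, channel).
eb_to_img <- function(eb) {
  a <- as.array(eb)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  aperm(a, c(2L, 1L, 3L))
}

img_to_eb <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
}

#' Load an image file as a unit-range RGB array
#'
#' Reads a PNG or JPEG file and returns an H x W x 3 array in [0, 1]
#' (8-bit values are divided by 255 by the decoder).  Greyscale input is
#' replicated to three channels and an alpha channel is dropped, each with
#' a warning.
#'
#' @param path path to a PNG or JPEG file.
#' @return H x W x 3 numeric array in [0, 1].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image, file does not exist: ", path)
  eb <- tryCatch(EBImage::readImage(path),
                 error = function(e) stop("cannot decode image '", path, "': ",
                                          conditionMessage(e)))
  a <- as.array(eb)
  nd <- length(dim(a))
  if (nd == 2L) {
    warning("greyscale image '", path, "' replicated to three channels")
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3] == 4L) {
    warning("alpha channel of '", path, "' dropped")
    a <- a[, , 1:3, drop = FALSE]
  } else if (dim(a)[3] == 2L) {
    warning("grey+alpha image '", path, "' converted to RGB")
    a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  } else if (dim(a)[3] != 3L) {
    stop("unsupported channel count in '", path, "': ", dim(a)[3])
  }
  image_rgb(aperm(a, c(2L, 1L, 3L)))
}

#' Save a unit-range RGB image to disk
#'
#' @param img H x W x 3 array in [0, 1].
#' @param path output path; format chosen from the extension (.png, .jpg).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- image_rgb(img)
  EBImage::writeImage(img_to_eb(img), path)
  invisible(path)
}

#' Save a grey map as a 16-bit PNG
#'
#' Exports dark channels, transmission maps and other grey maps for visual
#' inspection at full precision.
#'
#' @param gmap H x W matrix in [0, 1].
#' @param path output path ending in .png.
#' @return `path`, invisibly.
#' @export
save_gray_png <- function(gmap, path) {
  check_gray(gmap)
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(gmap, 0), 1))),
                      path, bits = 16L)
  invisible(path)
}

#' Resize an image to a target shape, preserving aspect ratio
#'
#' The image is scaled (bilinear) by the single factor that makes it cover
#' the target rectangle, then symmetrically centre-cropped to exactly
#' `target_h` x `target_w`.  When the aspect ratios already agree this is a
#' pure rescale with no cropping.  Upsampling (target larger than source in
#' both axes) is allowed but reported via `message()`.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param target_w,target_h positive target width and height in pixels.
#' @return `target_h` x `target_w` x 3 array.
#' @export
resize_keep_aspect <- function(img, target_w, target_h) {
  img <- image_rgb(img)
  if (target_w < 1 || target_h < 1) stop("target dimensions must be positive")
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- max(target_w / w, target_h / h)
  if (target_w > w && target_h > h)
    message("upsampling from ", h, "x", w, " to ", target_h, "x", target_w)
  nh <- max(target_h, as.integer(round(h * s)))
  nw <- max(target_w, as.integer(round(w * s)))
  out <- if (nh == h && nw == w) img else
    image_rgb(eb_to_img(EBImage::resize(img_to_eb(img), w = nw, h = nh)))
  # symmetric centre crop down to the target
  i0 <- (nh - target_h) %/% 2L
  j0 <- (nw - target_w) %/% 2L
  out[i0 + seq_len(target_h), j0 + seq_len(target_w), , drop = FALSE]
}

#' Extract a reproducible random square crop
#'
#' A pure function of `(img, size, seed)`: the same seed always yields the
#' same crop offsets (drawn uniformly over all valid positions).  Used for
#' the random-position data augmentation applied before training.
#'
#' @param img H x W x 3 array.
#' @param size side length of the square crop.
#' @param seed integer seed controlling the crop position.
#' @return `size` x `size` x 3 array.
#' @export
random_crop <- function(img, size, seed) {
  img <- image_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (size > h || size > w)
    stop("crop size ", size, " exceeds image ", h, "x", w,
         "; resize the image first")
  off <- withr::with_seed(as.integer(seed), c(
    sample.int(h - size + 1L, 1L) - 1L,
    sample.int(w - size + 1L, 1L) - 1L))
  img[off[1] + seq_len(size), off[2] + seq_len(size), , drop = FALSE]
}
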