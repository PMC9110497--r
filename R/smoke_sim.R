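# Synthetic fixture generator: procedural tissue-like clear frames and
# scattering-model smoke overlays, so the whole pipeline is testable
# without any surgical recordings.

#' Smoke simulation parameters
#'
#' Parameters of the atmospheric scattering model I = J * t + A * (1 - t):
#' global atmospheric light A, and a transmission field t(x) built as
#' exp(-density * n(x)) from a positive spatial noise field n with unit
#' mean, so `density` is the mean optical thickness of the smoke layer.
#'
#' @param atmos_light length-3 RGB atmospheric light, near-white by
#'   default.
#' @param density mean optical thickness, >= 0 (0 = no smoke).  The
#'   dataset generator grades light/medium/heavy as 0.3 / 0.8 / 1.8.
#' @param heterogeneity spatial noise scale of the smoke field, >= 0
#'   (0 = perfectly homogeneous smoke).
#' @param partial_fraction fraction of the frame covered by smoke, in
#'   (0, 1]; below 1 the transmission is 1 outside a random smooth mask.
#' @param seed integer seed; the whole simulation is a pure function of it.
#' @return list of class `smoke_params`.
#' @export
smoke_params <- function(atmos_light = c(0.95, 0.95, 0.93), density = 0.8,
                         heterogeneity = 1, partial_fraction = 1,
                         seed = 1L) {
  if (length(atmos_light) != 3L || any(atmos_light < 0) ||
      any(atmos_light > 1))
    stop("atmos_light must be three values in [0, 1]")
  if (density < 0) stop("density must be >= 0")
  if (heterogeneity < 0) stop("heterogeneity must be >= 0")
  if (partial_fraction <= 0 || partial_fraction > 1)
    stop("partial_fraction must lie in (0, 1]")
  structure(list(atmos_light = atmos_light, density = density,
                 heterogeneity = heterogeneity,
                 partial_fraction = partial_fraction,
                 seed = as.integer(seed)),
            class = "smoke_params")
}

# multi-octave value noise in roughly [0, 1]; consumes the current RNG
value_noise <- function(size, octaves = 4L, base_res = 4L) {
  acc <- matrix(0, size, size)
  amp <- 1; tot <- 0
  for (o in seq_len(octaves)) {
    res <- min(base_res * 2L^(o - 1L), size)
    coarse <- matrix(runif(res * res), res)
    up <- if (res == size) coarse else
      EBImage::imageData(EBImage::resize(EBImage::Image(coarse),
                                         w = size, h = size))
    acc <- acc + amp * up
    tot <- tot + amp
    amp <- amp / 2
  }
  acc / tot
}

#' Generate a tissue-like clear frame
#'
#' A procedural stand-in for a clear laparoscopic frame: smooth
#' multi-octave noise mapped into a reddish tissue gamut (red channel
#' dominant, blue suppressed, hence a low dark channel), with a dark
#' vignette towards the corners and a few small specular highlights.
#' Deterministic in `seed`.
#'
#' @param size side length in pixels, >= 32.
#' @param seed integer seed.
#' @return `size` x `size` x 3 array in [0, 1].
#' @export
make_tissue_phantom <- function(size, seed) {
  if (size < 32L) stop("phantom size must be >= 32")
  withr::with_seed(as.integer(seed), {
    n1 <- value_noise(size)
    n2 <- 0.6 * n1 + 0.4 * value_noise(size)
    n3 <- 0.5 * n1 + 0.5 * value_noise(size)
    img <- array(0, dim = c(size, size, 3L))
    img[, , 1L] <- 0.45 + 0.40 * n1
    img[, , 2L] <- 0.12 + 0.30 * n2
    img[, , 3L] <- 0.06 + 0.16 * n3
    # dark vignette corners
    cx <- (col(n1) - (size + 1) / 2) / (size / 2)
    cy <- (row(n1) - (size + 1) / 2) / (size / 2)
    vig <- 1 - 0.35 * pmin((cx^2 + cy^2) / 2, 1)
    for (c in 1:3) img[, , c] <- img[, , c] * vig
    # specular spots (blend towards white)
    for (s in seq_len(sample(2:4, 1L))) {
      sx <- runif(1, 0.15, 0.85) * size
      sy <- runif(1, 0.15, 0.85) * size
      sig <- runif(1, 0.01, 0.035) * size
      amp <- runif(1, 0.5, 0.9)
      spot <- amp * exp(-((row(n1) - sy)^2 + (col(n1) - sx)^2) / (2 * sig^2))
      for (c in 1:3) img[, , c] <- img[, , c] + spot * (1 - img[, , c])
    }
    image_rgb(img)
  })
}

#' Generate a spatially varying transmission field
#'
#' Builds t(x) = exp(-density * n(x)) where n is a positive multi-octave
#' noise field normalised to unit mean (so the mean optical thickness
#' -mean(log t) equals `density` exactly for full coverage).  For partial
#' smoke, t is reset to 1 outside a smooth random mask covering a
#' `partial_fraction` share of the frame.
#'
#' @param size side length in pixels.
#' @param params a [smoke_params()].
#' @return `size` x `size` matrix with values in (0, 1].
#' @export
make_transmission_field <- function(size, params) {
  stopifnot(inherits(params, "smoke_params"))
  withr::with_seed(params$seed, {
    z <- value_noise(size)
    z <- (z - mean(z)) / max(sd(z), 1e-9)
    n <- exp(params$heterogeneity * z)
    n <- n / mean(n)
    t <- exp(-params$density * n)
    if (params$partial_fraction < 1) {
      m <- value_noise(size)
      thr <- quantile(m, 1 - params$partial_fraction, names = FALSE)
      t[m < thr] <- 1
    }
    pmax(t, 1e-6)
  })
}

#' Overlay smoke on a clear image via the scattering model
#'
#' Per pixel and channel, the hazy observation is the convex combination
#' I = J * t + A * (1 - t) of the clear scene J and the atmospheric light
#' A, weighted by the transmission t.  With near-white A this can only
#' raise the dark channel.
#'
#' @param clear H x W x 3 clear image.
#' @param t H x W transmission map in (0, 1].
#' @param atmos_light length-3 RGB atmospheric light.
#' @return H x W x 3 hazy image.
#' @export
apply_scattering <- function(clear, t, atmos_light = c(0.95, 0.95, 0.93)) {
  clear <- image_rgb(clear)
  check_gray(t)
  if (!all(dim(clear)[1:2] == dim(t)))
    stop("clear image and transmission map shapes must match")
  if (min(t) <= 0 || max(t) > 1) stop("transmission values must lie in (0, 1]")
  out <- clear
  for (c in 1:3)
    out[, , c] <- clear[, , c] * t + atmos_light[c] * (1 - t)
  image_rgb(out)
}

# grade -> (density, partial_fraction); recorded in the dataset manifest
grade_table <- function() {
  data.frame(grade = c("light", "medium", "heavy", "partial"),
             density = c(0.3, 0.8, 1.8, 1.2),
             partial_fraction = c(1, 1, 1, 0.4),
             stringsAsFactors = FALSE)
}

# deterministic integer counts matching a mixture of proportions
mixture_counts <- function(n, mix) {
  mix <- mix / sum(mix)
  k <- floor(n * mix)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- n * mix - k
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1L
  }
  k
}

#' Write an unpaired clear/hazy fixture dataset to disk
#'
#' Emits the conventional unpaired-translation layout `trainA/` (clear),
#' `trainB/` (hazy), `testA/`, `testB/` with `n_per_domain` PNGs each.
#' Clear and hazy domains use *different* phantom seeds, so the dataset is
#' unpaired by construction.  Hazy images receive scattering-model smoke
#' with a grade drawn from `grading` (light / medium / heavy / partial);
#' per-image parameters and the ground-truth mean transmission go into
#' `manifest.json`.
#'
#' @param n_per_domain images per directory, >= 1.
#' @param size image side length (default 256).
#' @param grading named proportions over
#'   `c("light", "medium", "heavy", "partial")`.
#' @param seed master seed; the whole dataset is a pure function of it.
#' @param out_dir output directory (created if needed).
#' @param atmos_light RGB atmospheric light used for every hazy image.
#' @param heterogeneity smoke spatial noise scale.
#' @return the manifest, invisibly (also written as JSON).
#' @export
make_dataset <- function(n_per_domain, size = 256L,
                         grading = c(light = 0.25, medium = 0.25,
                                     heavy = 0.25, partial = 0.25),
                         seed = 1L, out_dir,
                         atmos_light = c(0.95, 0.95, 0.93),
                         heterogeneity = 1) {
  if (n_per_domain < 1L) stop("n_per_domain must be >= 1")
  gt <- grade_table()
  if (is.null(names(grading)) || !all(names(grading) %in% gt$grade))
    stop("grading must be named proportions over light/medium/heavy/partial")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  splits <- c("trainA", "trainB", "testA", "testB")
  for (d in splits) dir.create(file.path(out_dir, d), showWarnings = FALSE)

  records <- list()
  withr::with_seed(as.integer(seed), {
    for (split in c("train", "test")) {
      counts <- mixture_counts(n_per_domain, grading)
      grades <- sample(rep(names(grading), counts))
      for (i in seq_len(n_per_domain)) {
        # clear domain: a phantom of its own
        sA <- sample.int(2^30, 1L)
        file_a <- file.path(paste0(split, "A"), sprintf("img_%04d.png", i))
        save_image(make_tissue_phantom(size, sA), file.path(out_dir, file_a))
        records[[length(records) + 1L]] <-
          list(file = file_a, domain = "clear", split = split, grade = "none",
               phantom_seed = sA, density = 0, partial_fraction = 1,
               mean_transmission = 1)
        # hazy domain: a *different* phantom plus smoke
        sB <- sample.int(2^30, 1L)
        sT <- sample.int(2^30, 1L)
        gr <- grades[i]
        row <- gt[gt$grade == gr, ]
        sp <- smoke_params(atmos_light = atmos_light, density = row$density,
                           heterogeneity = heterogeneity,
                           partial_fraction = row$partial_fraction,
                           seed = sT)
        tmap <- make_transmission_field(size, sp)
        hazy <- apply_scattering(make_tissue_phantom(size, sB), tmap,
                                 atmos_light)
        file_b <- file.path(paste0(split, "B"), sprintf("img_%04d.png", i))
        save_image(hazy, file.path(out_dir, file_b))
        records[[length(records) + 1L]] <-
          list(file = file_b, domain = "hazy", split = split, grade = gr,
               phantom_seed = sB, smoke_seed = sT, density = row$density,
               partial_fraction = row$partial_fraction,
               mean_transmission = mean(tmap))
      }
    }
  })
  manifest <- list(seed = as.integer(seed), size = as.integer(size),
                   n_per_domain = as.integer(n_per_domain),
                   grading = as.list(grading),
                   grade_parameters = gt,
                   atmos_light = atmos_light,
                   heterogeneity = heterogeneity,
                   images = records)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
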