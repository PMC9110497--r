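#' Loss weights of the combined desmoking objective
#'
#' The full training objective is
#' \deqn{L = L_{GAN} + \lambda_{cyc} L_{cyc} + \alpha L_{IC} + \beta L_{DC}.}
#' `alpha` balances the inter-channel term against the cycle loss
#' (default 3), `beta` regulates the dark-channel term (default 0.05), and
#' `lambda_cyc` is the standard cycle-consistency weight (default 10).
#' Setting `alpha = beta = 0` recovers the plain cycle-consistent
#' adversarial objective exactly.
#'
#' @param alpha inter-channel loss weight, >= 0.
#' @param beta dark-channel loss weight, >= 0.
#' @param lambda_cyc cycle-consistency weight, >= 0.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 3, beta = 0.05, lambda_cyc = 10) {
  if (alpha < 0 || beta < 0 || lambda_cyc < 0)
    stop("loss weights must be non-negative")
  structure(list(alpha = alpha, beta = beta, lambda_cyc = lambda_cyc),
            class = "loss_weights")
}

#' Adversarial loss of a patch-score grid
#'
#' In the least-squares form (used for training) the loss is the mean
#' squared deviation of the discriminator's patch scores from the target
#' label: 1 for real, 0 for fake.  The logistic ("log") form of the
#' original minimax objective is also available; it expects scores already
#' mapped to (0, 1).
#'
#' @param scores numeric matrix (or vector) of patch scores.
#' @param target_is_real logical; TRUE compares against 1, FALSE against 0.
#' @param form `"lsgan"` (default) or `"log"`.
#' @return scalar loss.
#' @export
adversarial_loss <- function(scores, target_is_real, form = c("lsgan", "log")) {
  form <- match.arg(form)
  if (any(!is.finite(scores))) stop("non-finite discriminator scores")
  if (form == "lsgan") {
    target <- if (target_is_real) 1 else 0
    mean((scores - target)^2)
  } else {
    s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
    if (target_is_real) mean(-log(s)) else mean(-log(1 - s))
  }
}

#' Cycle-consistency loss
#'
#' Mean L1 reconstruction error of the two round trips
#' x -> G(x) -> F(G(x)) and y -> F(y) -> G(F(y)):
#' each term is the absolute difference averaged over pixels and channels,
#' and the two terms are summed.
#'
#' @param x,x_rec clear image and its round-trip reconstruction.
#' @param y,y_rec hazy image and its round-trip reconstruction.
#' @return scalar loss >= 0.
#' @export
cycle_loss <- function(x, x_rec, y, y_rec) {
  if (!all(dim(x) == dim(x_rec)) || !all(dim(y) == dim(y_rec)))
    stop("image and reconstruction shapes must match within each cycle")
  mean(abs(x - x_rec)) + mean(abs(y - y_rec))
}

#' Direction-dependent mapping of an inter-channel score
#'
#' Maps a normalised inter-channel discrepancy v >= 0 through the boundary
#' value 1: translating towards the clear domain penalises distance *from*
#' colourfulness, `|v - 1|`, so residual grey smoke (small v) costs most;
#' translating towards the hazy domain uses the complement `1 - |v - 1|`.
#'
#' @param v non-negative score (normalised inter-channel discrepancy).
#' @param direction `"hazy_to_clear"` or `"clear_to_hazy"`.
#' @return scalar.
#' @export
ic_direction_map <- function(v, direction = c("hazy_to_clear",
                                              "clear_to_hazy")) {
  direction <- match.arg(direction)
  if (any(v < 0)) stop("inter-channel score must be non-negative")
  if (direction == "hazy_to_clear") abs(v - 1) else 1 - abs(v - 1)
}

#' Inter-channel loss of a pair of generated images
#'
#' \deqn{L_{IC} = f(I^{IC}(G(x))) + f(I^{IC}(F(y)))}
#' where G(x) is the generated hazy image (clear-to-hazy branch of f) and
#' F(y) the generated clear image (hazy-to-clear branch).  The raw
#' discrepancy `interchannel_image()` lies in [0, 2] and is normalised by
#' 2 before the boundary mapping so that the loss shares the unit range of
#' the cycle loss.
#'
#' @param fake_hazy generated hazy image G(x).
#' @param fake_clear generated clear image F(y).
#' @return scalar loss in [0, 2].
#' @export
ic_loss <- function(fake_hazy, fake_clear) {
  v_hazy <- interchannel_image(fake_hazy) / 2
  v_clear <- interchannel_image(fake_clear) / 2
  ic_direction_map(v_hazy, "clear_to_hazy") +
    ic_direction_map(v_clear, "hazy_to_clear")
}

#' Dark-channel loss of a pair of generated images
#'
#' The trimmed mean of the (optionally soft-matting-refined) dark channel
#' of each generated image, summed over the two translation directions:
#' \deqn{L_{DC} = \overline{I^{dark}(F(y))} + \overline{I^{dark}(G(x))}.}
#' Residual haze in either generated image lifts its dark channel and so
#' the loss; the trimming excludes specular highlights and near-black
#' pixels from the average.
#'
#' @param fake_hazy generated hazy image G(x).
#' @param fake_clear generated clear image F(y).
#' @param patch odd dark-channel window (default 7, suited to training
#'   crops; use 15 at full resolution).
#' @param trim_frac tail fraction trimmed from the dark-channel average
#'   (default 0.01).
#' @param refine apply soft-matting refinement before averaging (default
#'   FALSE; refinement is intended for reported values, not per-step
#'   training losses).
#' @return scalar loss in [0, 2].
#' @export
dc_loss <- function(fake_hazy, fake_clear, patch = 7L, trim_frac = 0.01,
                    refine = FALSE) {
  one <- function(img) {
    d <- dark_channel(img, patch)
    if (refine) d <- refine_dark_channel(d, img)
    trimmed_mean(as.numeric(d), trim_frac)
  }
  one(fake_clear) + one(fake_hazy)
}

#' Combine loss components into the full weighted objective
#'
#' Returns a `loss_breakdown` whose `total` is
#' `adversarial_G + adversarial_F + lambda_cyc * cycle + alpha * ic +
#' beta * dc`.  With `alpha = beta = 0` this is exactly the baseline
#' cycle-consistent adversarial objective.
#'
#' @param adversarial_G,adversarial_F generator adversarial losses for the
#'   clear-to-hazy and hazy-to-clear mappings.
#' @param cycle,ic,dc unweighted component losses.
#' @param weights a [loss_weights()] object.
#' @return list of class `loss_breakdown` with fields `adversarial_G`,
#'   `adversarial_F`, `cycle`, `ic`, `dc`, `total`.
#' @export
total_objective <- function(adversarial_G, adversarial_F, cycle, ic, dc,
                            weights = loss_weights()) {
  parts <- list(adversarial_G = adversarial_G, adversarial_F = adversarial_F,
                cycle = cycle, ic = ic, dc = dc)
  for (nm in names(parts))
    if (!is.finite(parts[[nm]]))
      stop("non-finite loss component: ", nm)
  total <- adversarial_G + adversarial_F + weights$lambda_cyc * cycle +
    weights$alpha * ic + weights$beta * dc
  structure(c(parts, list(total = total, weights = weights)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss breakdown: adv_G %.4f  adv_F %.4f  cycle %.4f  ic %.4f  dc %.4f  total %.4f\n",
    x$adversarial_G, x$adversarial_F, x$cycle, x$ic, x$dc, x$total))
  invisible(x)
}
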