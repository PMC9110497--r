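#' Training configuration
#'
#' Defaults follow the published schedule: learning rate 0.002 held for
#' the first 50 epochs then decayed linearly to 0 over the next 50, batch
#' size 4, 256x256 random crops, Adam with betas (0.5, 0.999), a 50-image
#' history pool for each discriminator.  Smaller `gen_spec` / `disc_spec`
#' values scale the experiment down to desk size.
#'
#' @param lr0 initial learning rate, > 0 (default 0.002).
#' @param epochs_const epochs at constant `lr0` (default 50).
#' @param epochs_decay epochs of linear decay to 0 (default 50; may be 0).
#' @param batch_size images per domain per step (default 4).
#' @param crop training crop side (default 256); images equal to the crop
#'   size are used whole.
#' @param seed master seed for initialisation, shuffling, crops and the
#'   history pool.
#' @param weights a [loss_weights()] object.
#' @param pool_size discriminator history pool size (default 50).
#' @param gen_spec,disc_spec network architecture specifications.
#' @param dc_patch dark-channel window inside the training loss
#'   (default 7).
#' @param dc_trim trimmed-mean tail fraction of the dark-channel loss.
#' @param dc_refine report the soft-matting-refined dark-channel loss in
#'   the breakdown (gradients always flow through the unrefined dark
#'   channel; default FALSE).
#' @param dc_on_fake_hazy include the generated *hazy* image's dark
#'   channel in the DC loss, as the objective states (default TRUE);
#'   FALSE drops that term for ablation.
#' @param save_every checkpoint frequency in epochs (default 1).
#' @return list of class `train_config`.
#' @export
train_config <- function(lr0 = 0.002, epochs_const = 50L, epochs_decay = 50L,
                         batch_size = 4L, crop = 256L, seed = 1L,
                         weights = loss_weights(), pool_size = 50L,
                         gen_spec = generator_spec(),
                         disc_spec = discriminator_spec(),
                         dc_patch = 7L, dc_trim = 0.01, dc_refine = FALSE,
                         dc_on_fake_hazy = TRUE, save_every = 1L) {
  if (lr0 <= 0) stop("lr0 must be positive")
  if (epochs_const < 1L || epochs_decay < 0L)
    stop("epochs_const must be >= 1 and epochs_decay >= 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (pool_size < 0L) stop("pool_size must be >= 0")
  stopifnot(inherits(weights, "loss_weights"),
            inherits(gen_spec, "generator_spec"),
            inherits(disc_spec, "discriminator_spec"))
  structure(list(lr0 = lr0, epochs_const = as.integer(epochs_const),
                 epochs_decay = as.integer(epochs_decay),
                 batch_size = as.integer(batch_size), crop = as.integer(crop),
                 seed = as.integer(seed), weights = weights,
                 pool_size = as.integer(pool_size), gen_spec = gen_spec,
                 disc_spec = disc_spec, dc_patch = as.integer(dc_patch),
                 dc_trim = dc_trim, dc_refine = dc_refine,
                 dc_on_fake_hazy = dc_on_fake_hazy,
                 save_every = as.integer(save_every)),
            class = "train_config")
}

#' Learning rate at a given (0-based) epoch
#'
#' Constant at `lr0` for the first `epochs_const` epochs, then linear to 0
#' across the decay epochs, reaching exactly 0 one epoch past the final
#' one.  Continuous at the constant/decay boundary.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index in `[0, epochs_const + epochs_decay]`.
#' @return learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  total <- cfg$epochs_const + cfg$epochs_decay
  if (epoch < 0 || epoch > total)
    stop("epoch ", epoch, " outside the schedule [0, ", total, "]")
  if (epoch < cfg$epochs_const) return(cfg$lr0)
  if (cfg$epochs_decay == 0L) return(0)
  cfg$lr0 * (total - epoch) / cfg$epochs_decay
}

# ---- discriminator history pool -------------------------------------------

pool_new <- function(size) {
  e <- new.env(parent = emptyenv())
  e$size <- as.integer(size)
  e$imgs <- list()
  e
}

# with probability 1/2 swap the incoming fake for a stored older one
pool_query <- function(pool, img) {
  if (pool$size == 0L) return(img)
  if (length(pool$imgs) < pool$size) {
    pool$imgs[[length(pool$imgs) + 1L]] <- img
    return(img)
  }
  if (runif(1) < 0.5) {
    i <- sample.int(length(pool$imgs), 1L)
    old <- pool$imgs[[i]]
    pool$imgs[[i]] <- img
    old
  } else img
}

# ---- training state --------------------------------------------------------

#' Initialise the training state
#'
#' Builds the two generators (G: clear to hazy, F: hazy to clear), the two
#' discriminators, their Adam optimisers (betas 0.5 / 0.999; one optimiser
#' over both generators, one over both discriminators) and the history
#' pools, all deterministically from `cfg$seed`.
#'
#' @param cfg a [train_config()].
#' @return an environment of class `train_state`.
#' @export
init_train_state <- function(cfg) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  withr::with_seed(cfg$seed, {
    st$G <- build_generator(cfg$gen_spec)
    st$F <- build_generator(cfg$gen_spec)
    st$Dx <- build_discriminator(cfg$disc_spec)
    st$Dy <- build_discriminator(cfg$disc_spec)
  })
  st$opt_G <- adam_new(c(nn_param_layers(st$G$net), nn_param_layers(st$F$net)))
  st$opt_D <- adam_new(c(nn_param_layers(st$Dx$net),
                         nn_param_layers(st$Dy$net)))
  st$pool_x <- pool_new(cfg$pool_size)
  st$pool_y <- pool_new(cfg$pool_size)
  st$lr <- cfg$lr0
  st$epoch <- 0L
  class(st) <- "train_state"
  st
}

# gradient of the mean inter-channel discrepancy w.r.t. the image
ic_image_grad <- function(img) {
  n <- dim(img)[1] * dim(img)[2]
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  out <- img * 0
  out[, , 1L] <- (sign(r - g) + sign(r - b)) / n
  out[, , 2L] <- (sign(g - r) + sign(g - b)) / n
  out[, , 3L] <- (sign(b - r) + sign(b - g)) / n
  out
}

#' One training step on a pair of unpaired batches
#'
#' Performs one generator update (adversarial + cycle + alpha * IC +
#' beta * DC, evaluated on the generated images only) and one
#' least-squares discriminator update per domain using the history pools,
#' and returns the generator-side loss breakdown computed before the
#' update.  With `alpha = beta = 0` the generator objective is exactly the
#' baseline cycle-consistent adversarial loss.
#'
#' @param batch_clear,batch_hazy lists of same-sized H x W x 3 arrays;
#'   crops are assumed to have been applied already.
#' @param state a `train_state` from [init_train_state()].
#' @return a `loss_breakdown`.
#' @export
train_step <- function(batch_clear, batch_hazy, state) {
  cfg <- state$cfg
  wts <- cfg$weights
  nb <- length(batch_clear)
  if (nb < 1L || nb != length(batch_hazy))
    stop("batches must be non-empty and of equal length")
  G <- state$G$net; Fn <- state$F$net
  Dx <- state$Dx$net; Dy <- state$Dy$net
  nn_zero_grads(G); nn_zero_grads(Fn)
  comp <- c(adv_G = 0, adv_F = 0, cyc = 0, ic = 0, dc = 0)
  fakes_x <- vector("list", nb); fakes_y <- vector("list", nb)

  for (i in seq_len(nb)) {
    x <- image_rgb(batch_clear[[i]])
    y <- image_rgb(batch_hazy[[i]])
    fy <- nn_forward(G, x)    # G(x): fake hazy
    fx <- nn_forward(Fn, y)   # F(y): fake clear
    rx <- nn_forward(Fn, fy$y)
    ry <- nn_forward(G, fx$y)
    sy <- nn_forward(Dy, fy$y)
    sx <- nn_forward(Dx, fx$y)

    adv_G_i <- mean((sy$y - 1)^2)
    adv_F_i <- mean((sx$y - 1)^2)
    cyc_i <- mean(abs(rx$y - x)) + mean(abs(ry$y - y))
    vy <- interchannel_image(fy$y) / 2
    vx <- interchannel_image(fx$y) / 2
    ic_i <- ic_direction_map(vy, "clear_to_hazy") +
      ic_direction_map(vx, "hazy_to_clear")
    dfy <- dark_channel(fy$y, cfg$dc_patch)
    dfx <- dark_channel(fx$y, cfg$dc_patch)
    dc_report <- function(d, img) {
      if (cfg$dc_refine) d <- refine_dark_channel(d, img)
      trimmed_mean(as.numeric(d), cfg$dc_trim)
    }
    dc_i <- dc_report(dfx, fx$y) +
      if (cfg$dc_on_fake_hazy) dc_report(dfy, fy$y) else 0
    comp <- comp + c(adv_G_i, adv_F_i, cyc_i, ic_i, dc_i) / nb
    if (any(!is.finite(comp)))
      stop("non-finite loss encountered; restore the last good checkpoint")

    # gradients w.r.t. the generated images (per-image, scaled by 1/nb)
    g_fy <- nn_backward(Dy, sy$cache, 2 * (sy$y - 1) / length(sy$y) / nb,
                        acc = FALSE)
    g_fx <- nn_backward(Dx, sx$cache, 2 * (sx$y - 1) / length(sx$y) / nb,
                        acc = FALSE)
    npx <- length(x)
    g_fy <- g_fy + nn_backward(Fn, rx$cache,
                               wts$lambda_cyc * sign(rx$y - x) / npx / nb)
    g_fx <- g_fx + nn_backward(G, ry$cache,
                               wts$lambda_cyc * sign(ry$y - y) / npx / nb)
    if (wts$alpha > 0) {
      # d f/d v: towards hazy f = 1 - |v-1| (v <= 1 so slope +1);
      # towards clear f = |v-1| (slope sign(v-1))
      slope_y <- if (vy <= 1) 1 else -1
      slope_x <- sign(vx - 1)
      g_fy <- g_fy + wts$alpha * slope_y * ic_image_grad(fy$y) / 2 / nb
      g_fx <- g_fx + wts$alpha * slope_x * ic_image_grad(fx$y) / 2 / nb
    }
    if (wts$beta > 0) {
      gm <- matrix(trimmed_mean_grad(as.numeric(dfx), cfg$dc_trim),
                   nrow(dfx))
      g_fx <- g_fx + wts$beta *
        dark_channel_grad(fx$y, gm, cfg$dc_patch) / nb
      if (cfg$dc_on_fake_hazy) {
        gm <- matrix(trimmed_mean_grad(as.numeric(dfy), cfg$dc_trim),
                     nrow(dfy))
        g_fy <- g_fy + wts$beta *
          dark_channel_grad(fy$y, gm, cfg$dc_patch) / nb
      }
    }
    nn_backward(Fn, fx$cache, g_fx)
    nn_backward(G, fy$cache, g_fy)
    fakes_y[[i]] <- fy$y
    fakes_x[[i]] <- fx$y
  }
  adam_step(state$opt_G, state$lr)

  # least-squares discriminator updates with history pools
  nn_zero_grads(Dx); nn_zero_grads(Dy)
  for (i in seq_len(nb)) {
    x <- image_rgb(batch_clear[[i]])
    y <- image_rgb(batch_hazy[[i]])
    pfx <- pool_query(state$pool_x, fakes_x[[i]])
    pfy <- pool_query(state$pool_y, fakes_y[[i]])
    for (du in list(list(net = Dy, real = y, fake = pfy),
                    list(net = Dx, real = x, fake = pfx))) {
      sr <- nn_forward(du$net, du$real)
      nn_backward(du$net, sr$cache, (sr$y - 1) / length(sr$y) / nb)
      sf <- nn_forward(du$net, du$fake)
      nn_backward(du$net, sf$cache, sf$y / length(sf$y) / nb)
    }
  }
  adam_step(state$opt_D, state$lr)

  total_objective(comp[["adv_G"]], comp[["adv_F"]], comp[["cyc"]],
                  comp[["ic"]], comp[["dc"]], wts)
}

# ---- checkpoints -----------------------------------------------------------

#' Save a training checkpoint
#'
#' Serialises the four networks' weights, the architecture specifications,
#' the configuration and the epoch, and writes a JSON sidecar recording
#' the specs and an MD5 hash of the weights file.
#'
#' @param state a `train_state`.
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  ck <- list(format = 1L, epoch = state$epoch, cfg = state$cfg,
             gen_spec = state$cfg$gen_spec, disc_spec = state$cfg$disc_spec,
             G = nn_state(state$G$net), F = nn_state(state$F$net),
             Dx = nn_state(state$Dx$net), Dy = nn_state(state$Dy$net))
  saveRDS(ck, path)
  side <- list(file = basename(path), epoch = ck$epoch,
               gen_spec = unclass(ck$gen_spec),
               disc_spec = unclass(ck$disc_spec),
               md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a training checkpoint
#'
#' Verifies the sidecar's MD5 hash when present and rebuilds the four
#' networks with the stored weights.
#'
#' @param path `.rds` checkpoint path.
#' @return a `train_state` (optimiser momenta reset).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint does not exist: ", path)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path)
    actual <- unname(tools::md5sum(path))
    if (!identical(side$md5, actual))
      stop("checkpoint hash mismatch for ", path, ": sidecar records ",
           side$md5, " but file hashes to ", actual)
  }
  ck <- tryCatch(readRDS(path),
                 error = function(e) stop("corrupt checkpoint '", path,
                                          "': ", conditionMessage(e)))
  st <- init_train_state(ck$cfg)
  nn_set_state(st$G$net, ck$G)
  nn_set_state(st$F$net, ck$F)
  nn_set_state(st$Dx$net, ck$Dx)
  nn_set_state(st$Dy$net, ck$Dy)
  st$epoch <- ck$epoch
  st$lr <- lr_at_epoch(ck$cfg, min(ck$epoch, ck$cfg$epochs_const +
                                     ck$cfg$epochs_decay))
  st
}

# ---- fit -------------------------------------------------------------------

list_domain <- function(root, sub) {
  d <- file.path(root, sub)
  files <- list.files(d, pattern = "\\.(png|jpg|jpeg)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    stop("empty domain directory: ", d)
  sort(files)
}

prep_crop <- function(img, crop, seed) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < crop || w < crop)
    stop("image ", h, "x", w, " smaller than the training crop ", crop,
         "; resize the dataset or lower cfg$crop")
  if (h == crop && w == crop) img else random_crop(img, crop, seed)
}

#' Train the desmoking model on an unpaired two-domain dataset
#'
#' Runs `epochs_const + epochs_decay` epochs over the `trainA/` (clear)
#' and `trainB/` (hazy) directories under `data_root`, applying random
#' crops, the scheduled learning rate and [train_step()].  Writes one
#' checkpoint every `save_every` epochs plus the final one, and a CSV of
#' per-epoch mean loss components
#' (`epoch, lr, adv_G, adv_F, cycle, ic, dc, total`) suitable for loss
#' trajectory plots.
#'
#' @param cfg a [train_config()].
#' @param data_root dataset root containing `trainA/` and `trainB/`.
#' @param out_dir output directory for checkpoints and the loss log.
#' @param resume_from optional checkpoint path to continue from.
#' @param verbose print per-epoch losses (default TRUE).
#' @return character vector of checkpoint paths (final checkpoint last).
#' @export
fit <- function(cfg, data_root, out_dir = file.path(data_root, "run"),
                resume_from = NULL, verbose = TRUE) {
  files_a <- list_domain(data_root, "trainA")
  files_b <- list_domain(data_root, "trainB")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- if (is.null(resume_from)) init_train_state(cfg) else
    load_checkpoint(resume_from)
  total <- cfg$epochs_const + cfg$epochs_decay
  log_path <- file.path(out_dir, "losses.csv")
  first_epoch <- state$epoch
  if (is.null(resume_from) || !file.exists(log_path))
    cat("epoch,lr,adv_G,adv_F,cycle,ic,dc,total\n", file = log_path)
  ckpts <- character(0)
  if (first_epoch >= total) return(ckpts)
  withr::local_seed(cfg$seed + 1L)
  for (epoch in first_epoch:(total - 1L)) {
    state$lr <- lr_at_epoch(cfg, epoch)
    ord_a <- sample(files_a)
    ord_b <- sample(files_b)
    n_steps <- min(length(ord_a), length(ord_b)) %/% cfg$batch_size
    if (n_steps == 0L)
      stop("fewer images than one batch; lower batch_size")
    acc <- c(adv_G = 0, adv_F = 0, cycle = 0, ic = 0, dc = 0, total = 0)
    for (s in seq_len(n_steps)) {
      idx <- (s - 1L) * cfg$batch_size + seq_len(cfg$batch_size)
      seeds <- sample.int(.Machine$integer.max, 2L * cfg$batch_size)
      ba <- lapply(seq_along(idx), function(j)
        prep_crop(load_image(ord_a[idx[j]]), cfg$crop, seeds[j]))
      bb <- lapply(seq_along(idx), function(j)
        prep_crop(load_image(ord_b[idx[j]]), cfg$crop,
                  seeds[cfg$batch_size + j]))
      br <- train_step(ba, bb, state)
      acc <- acc + c(br$adversarial_G, br$adversarial_F, br$cycle, br$ic,
                     br$dc, br$total) / n_steps
    }
    state$epoch <- epoch + 1L
    cat(sprintf("%d,%.6g,%.6g,%.6g,%.6g,%.6g,%.6g,%.6g\n", epoch, state$lr,
                acc[1], acc[2], acc[3], acc[4], acc[5], acc[6]),
        file = log_path, append = TRUE)
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.5f  cycle %.4f  ic %.4f  dc %.4f  total %.4f",
        epoch, state$lr, acc[3], acc[4], acc[5], acc[6]))
    if ((epoch + 1L) %% cfg$save_every == 0L || epoch == total - 1L) {
      p <- file.path(out_dir, sprintf("ckpt_epoch_%03d.rds", epoch + 1L))
      save_checkpoint(state, p)
      ckpts <- c(ckpts, p)
    }
  }
  ckpts
}

#' Translate an image with a trained model
#'
#' Applies the hazy-to-clear generator F (desmoking) or the clear-to-hazy
#' generator G to a full-resolution image; inference is deterministic and
#' needs no cropping.
#'
#' @param checkpoint checkpoint path (or a loaded `train_state`).
#' @param img H x W x 3 array in [0, 1].
#' @param direction `"hazy_to_clear"` (default, desmoking) or
#'   `"clear_to_hazy"`.
#' @return translated H x W x 3 array.
#' @export
translate <- function(checkpoint, img,
                      direction = c("hazy_to_clear", "clear_to_hazy")) {
  direction <- match.arg(direction)
  state <- if (inherits(checkpoint, "train_state")) checkpoint else
    load_checkpoint(checkpoint)
  gen <- if (direction == "hazy_to_clear") state$F else state$G
  apply_generator(gen, img)
}
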