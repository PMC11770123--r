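# Convolutional autoencoder used to pretrain the H&E encoder.
#
# The encoder is an initial 3x3 convolution followed by `n_down`
# downsampling blocks (two residual blocks + stride-2 convolution each); the
# decoder mirrors it with residual blocks + nearest-neighbour upsampling.
# After pretraining, the encoder is frozen and reused inside the alignment
# network; the Raman encoder shares the architecture but is trained
# end-to-end (pretraining it was found counterproductive for
# classification), so only the H&E side goes through this module.

#' Build an untrained convolutional autoencoder
#'
#' @param in_ch input channels (3 for H&E images, the band count for cubes).
#' @param width latent channel width after the encoder (64 at full scale).
#' @param n_down number of downsampling blocks (each halves both extents).
#' @param groups preferred group count for group normalization.
#' @param seed integer seed for weight initialization.
#' @return an `rs_autoencoder` model (list of `params` + `config`).
#' @export
build_autoencoder <- function(in_ch, width = 64L, n_down = 2L, groups = 8L,
                              seed = 1L) {
  params <- with_seed(seed, {
    p <- list()
    p <- init_down_stack(p, "enc", in_ch, width, n_down)
    p <- init_up_stack(p, "dec", in_ch, width, n_down)
    p
  })
  structure(list(params = params,
                 config = list(in_ch = as.integer(in_ch),
                               width = as.integer(width),
                               n_down = as.integer(n_down),
                               groups = as.integer(groups))),
            class = "rs_autoencoder")
}

# Autodiff forward passes; `ctx` decides which parameters are trainable.
ae_encode_fwd <- function(ctx, cfg, x, prefix = "enc") {
  fwd_down_stack(ctx, prefix, as_ad(x), cfg$width, cfg$n_down, cfg$groups)
}

ae_decode_fwd <- function(ctx, cfg, h, prefix = "dec") {
  fwd_up_stack(ctx, prefix, as_ad(h), cfg$in_ch, cfg$width, cfg$n_down,
               cfg$groups)
}

#' Encode an image to its latent feature map
#'
#' Two downsampling blocks map `[3, 256, 256]` to `[64, 64, 64]` and
#' `[1340, 400, 48]` to `[64, 100, 12]` at full-scale configuration.
#'
#' @param model an `rs_autoencoder` (or alignment model encoder handle).
#' @param image array `[in_ch, H, W]` with spatial extents divisible by
#'   `2^n_down`.
#' @return feature map array `[width, H/2^n_down, W/2^n_down]`.
#' @export
encode_image <- function(model, image) {
  cfg <- model$config
  dm <- dim(image)
  if (any(dm[2:3] %% (2L^cfg$n_down) != 0L))
    stop("spatial extents must be divisible by ", 2L^cfg$n_down)
  ctx <- ad_ctx(model$params, frozen = "")  # all-frozen: pure inference
  ae_encode_fwd(ctx, cfg, image)$value
}

#' Decode a latent feature map back to image space
#' @param model an `rs_autoencoder`.
#' @param features array `[width, h, w]` from the matching encoder.
#' @return array `[in_ch, h * 2^n_down, w * 2^n_down]`.
#' @export
decode_features <- function(model, features) {
  cfg <- model$config
  if (dim(features)[1] != cfg$width) stop("feature channel mismatch")
  ctx <- ad_ctx(model$params, frozen = "")
  ae_decode_fwd(ctx, cfg, features)$value
}

#' Pretrain the autoencoder by reconstruction
#'
#' Mean-squared-error objective with AdamW; one optimizer update per
#' training step (gradient accumulation over `accum` images).
#'
#' @param model an `rs_autoencoder`.
#' @param images non-empty list of `[in_ch, H, W]` arrays.
#' @param steps number of optimizer updates.
#' @param lr,weight_decay AdamW settings.
#' @param accum images whose gradients are averaged per update.
#' @param seed RNG seed for image sampling.
#' @return model with trained `params` and a `loss_history` (length `steps`).
#' @export
pretrain_autoencoder <- function(model, images, steps = 200L, lr = 1e-5,
                                 weight_decay = 1e-5, accum = 1L, seed = 1L) {
  if (length(images) == 0L) stop("empty training set")
  cfg <- model$config
  params <- model$params
  opt <- adamw_new(lr = lr, weight_decay = weight_decay)
  history <- numeric(steps)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      gacc <- list(); lsum <- 0
      for (a in seq_len(accum)) {
        img <- images[[sample.int(length(images), 1L)]]
        ctx <- ad_ctx(params)
        h <- ae_encode_fwd(ctx, cfg, img)
        xr <- ae_decode_fwd(ctx, cfg, h)
        loss <- ad_mse(xr, img)
        gacc <- grad_accumulate(gacc, ad_backward(loss))
        lsum <- lsum + loss$value
      }
      st <- adamw_step(opt, params, grad_scale(gacc, 1 / accum))
      opt <- st$opt; params <- st$params
      history[s] <- lsum / accum
    }
  })
  model$params <- params
  model$loss_history <- history
  model
}

#' Extract and freeze the encoder half of a pretrained autoencoder
#'
#' The returned handle carries only the encoder parameters and is marked
#' frozen: downstream training (e.g. [train_alignnet()]) treats every
#' parameter under its prefix as a constant, so the weights stay
#' bit-identical.
#'
#' @param model a (pretrained) `rs_autoencoder`.
#' @return an `rs_frozen_encoder` handle.
#' @export
freeze_encoder <- function(model) {
  keep <- names(model$params)[startsWith(names(model$params), "enc.")]
  structure(list(params = model$params[keep],
                 config = model$config, frozen = TRUE),
            class = c("rs_frozen_encoder", "rs_autoencoder"))
}
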