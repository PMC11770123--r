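# Conditional denoising-diffusion model.
#
# Standard DDPM formulation: linear variance schedule, noise (epsilon)
# prediction, ancestral sampling (with an alpha-bar-ratio generalization
# when sampling on a timestep subsequence). The denoiser is a UNet whose
# down/up blocks halve/double the spatial extents; self- and cross-attention
# run only at stages whose extent is at or below `attn_max` (16 at full
# scale), and the cross-attention context is the [K, d] conditioning matrix
# built from the alignment network's H&E targets. Images live in [-1, 1].

#' Linear-variance noise schedule
#'
#' @param T_steps diffusion step count.
#' @param beta_start,beta_end endpoints of the linear variance ramp.
#' @return list with `T`, `betas`, `alphas` and cumulative signal retention
#'   `alphabar` (strictly decreasing from ~1 toward 0).
#' @export
noise_schedule <- function(T_steps = 1000L, beta_start = 1e-4, beta_end = 0.02) {
  stopifnot(T_steps >= 1L)
  betas <- seq(beta_start, beta_end, length.out = T_steps)
  alphas <- 1 - betas
  list(T = as.integer(T_steps), betas = betas, alphas = alphas,
       alphabar = cumprod(alphas))
}

#' Forward-noise an image to timestep t
#'
#' `x_t = sqrt(alphabar_t) * x0 + sqrt(1 - alphabar_t) * noise`.
#'
#' @param x0 clean image array.
#' @param t timestep in `1..T`.
#' @param schedule a [noise_schedule()].
#' @param noise array shaped like `x0` (standard normal draws).
#' @return the noised image.
#' @export
forward_noise <- function(x0, t, schedule, noise) {
  if (t < 1L || t > schedule$T) stop("t out of range")
  ab <- schedule$alphabar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

#' Conditional UNet configuration
#'
#' @param img_size input extent (square images `[in_ch, img_size, img_size]`).
#' @param in_ch image channels.
#' @param base base channel width.
#' @param mult per-level channel multipliers; `length(mult)` levels, each
#'   halving the extent (5 levels at full scale).
#' @param attn_max attention runs at stages with extent `<= attn_max`.
#' @param d_ctx conditioning vector dimension.
#' @param time_dim sinusoidal timestep embedding width.
#' @param groups preferred group-normalization group count.
#' @export
unet_config <- function(img_size, in_ch = 3L, base = 32L, mult = c(1, 1, 2, 2, 4),
                        attn_max = 16L, d_ctx = 128L, time_dim = 32L,
                        groups = 8L) {
  widths <- as.integer(base * mult)
  L <- length(widths)
  res <- img_size / 2^(seq_len(L) - 1L)     # extent entering each level
  if (img_size %% 2^L != 0L && img_size / 2^L < 1)
    stop("img_size too small for the level count")
  list(img_size = as.integer(img_size), in_ch = as.integer(in_ch),
       widths = widths, L = L, attn_max = as.integer(attn_max),
       d_ctx = as.integer(d_ctx), time_dim = as.integer(time_dim),
       groups = as.integer(groups),
       attn_at = res <= attn_max, attn_mid = img_size / 2^L <= attn_max)
}

#' Build an untrained conditional UNet
#' @param config a [unet_config()].
#' @param seed initialization seed.
#' @return an `rs_unet` model.
#' @export
build_unet <- function(config, seed = 1L) {
  w <- config$widths; L <- config$L
  params <- with_seed(seed, {
    p <- list()
    p <- init_linear(p, "tmlp.l1", config$time_dim, config$time_dim)
    p <- init_linear(p, "tmlp.l2", config$time_dim, config$time_dim)
    p <- init_conv(p, "stem", config$in_ch, w[1], 3L)
    for (l in seq_len(L)) {
      p <- init_resblock(p, paste0("d", l, ".r"), w[l], w[l], config$time_dim)
      if (config$attn_at[l]) {
        p <- init_attention(p, paste0("d", l, ".sa"), w[l])
        p <- init_attention(p, paste0("d", l, ".ca"), w[l], config$d_ctx)
      }
      p <- init_conv(p, paste0("d", l, ".down"), w[l], w[min(l + 1L, L)], 3L)
    }
    p <- init_resblock(p, "mid.r1", w[L], w[L], config$time_dim)
    if (config$attn_mid) {
      p <- init_attention(p, "mid.sa", w[L])
      p <- init_attention(p, "mid.ca", w[L], config$d_ctx)
    }
    p <- init_resblock(p, "mid.r2", w[L], w[L], config$time_dim)
    for (l in seq_len(L)) {
      p <- init_conv(p, paste0("u", l, ".up"), w[min(l + 1L, L)], w[l], 3L)
      p <- init_resblock(p, paste0("u", l, ".r"), 2L * w[l], w[l], config$time_dim)
      if (config$attn_at[l]) {
        p <- init_attention(p, paste0("u", l, ".sa"), w[l])
        p <- init_attention(p, paste0("u", l, ".ca"), w[l], config$d_ctx)
      }
    }
    p <- init_norm(p, "out.gn", w[1])
    p <- init_conv(p, "out.conv", w[1], config$in_ch, 3L)
    p
  })
  structure(list(params = params, config = config, trained = FALSE),
            class = "rs_unet")
}

# UNet forward pass. `trace`, when an environment, collects the spatial
# extents at which attention layers actually executed.
unet_fwd <- function(ctx, cfg, x, t, cond, trace = NULL) {
  w <- cfg$widths; L <- cfg$L; gp <- cfg$groups
  temb <- ad_const(time_embedding(t, cfg$time_dim))
  temb <- fwd_linear(ctx, "tmlp.l2", ad_silu(fwd_linear(ctx, "tmlp.l1", temb)))
  cond_nd <- as_ad(cond)
  note <- function(stage, ext) if (is.environment(trace))
    trace$log <- rbind(trace$log, data.frame(stage = stage, extent = ext))
  h <- fwd_conv(ctx, "stem", as_ad(x), stride = 1L, pad = 1L)
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    h <- fwd_resblock(ctx, paste0("d", l, ".r"), h, w[l], w[l], gp, temb)
    if (cfg$attn_at[l]) {
      note(paste0("down", l), dim(h$value)[2])
      h <- fwd_attention(ctx, paste0("d", l, ".sa"), h, w[l], NULL, gp)
      h <- fwd_attention(ctx, paste0("d", l, ".ca"), h, w[l], cond_nd, gp)
    }
    skips[[l]] <- h
    h <- fwd_conv(ctx, paste0("d", l, ".down"), h, stride = 2L, pad = 1L)
  }
  h <- fwd_resblock(ctx, "mid.r1", h, w[L], w[L], gp, temb)
  if (cfg$attn_mid) {
    note("mid", dim(h$value)[2])
    h <- fwd_attention(ctx, "mid.sa", h, w[L], NULL, gp)
    h <- fwd_attention(ctx, "mid.ca", h, w[L], cond_nd, gp)
  }
  h <- fwd_resblock(ctx, "mid.r2", h, w[L], w[L], gp, temb)
  for (l in rev(seq_len(L))) {
    h <- fwd_conv(ctx, paste0("u", l, ".up"), ad_upsample2(h), stride = 1L, pad = 1L)
    h <- ad_concat_chan(h, skips[[l]])
    h <- fwd_resblock(ctx, paste0("u", l, ".r"), h, 2L * w[l], w[l], gp, temb)
    if (cfg$attn_at[l]) {
      note(paste0("up", l), dim(h$value)[2])
      h <- fwd_attention(ctx, paste0("u", l, ".sa"), h, w[l], NULL, gp)
      h <- fwd_attention(ctx, paste0("u", l, ".ca"), h, w[l], cond_nd, gp)
    }
  }
  h <- fwd_groupnorm(ctx, "out.gn", h, norm_groups(w[1], gp))
  fwd_conv(ctx, "out.conv", ad_silu(h), stride = 1L, pad = 1L)
}

#' Train the diffusion model
#'
#' Noise-prediction MSE objective: at every sampled timestep the UNet,
#' conditioned on the K H&E targets of the tile's own class, predicts the
#' injected noise. One AdamW update per `accum` tiles; checkpoints are
#' written every `ckpt_every` epochs when `ckpt_dir` is given, and the
#' best-validation parameters are kept when validation tiles are supplied.
#'
#' @param model an `rs_unet`.
#' @param tiles list of `[in_ch, s, s]` arrays in `[-1, 1]`.
#' @param labels class index per tile.
#' @param he_targets H&E target bank `[n_classes, K, d_ctx]` from a trained
#'   alignment model (required: the class conditioning comes from it).
#' @param schedule a [noise_schedule()].
#' @param epochs training epochs (one pass over the tiles each).
#' @param lr,weight_decay,accum optimizer settings.
#' @param ckpt_every checkpoint cadence in epochs (25 at full scale).
#' @param ckpt_dir directory for periodic checkpoints (`NULL` = keep none).
#' @param val_tiles,val_labels optional held-out tiles for validation MSE.
#' @param seed RNG seed.
#' @return the model with `loss_history` (per epoch), `val_history`,
#'   `checkpoints` (epochs at which checkpoints were written).
#' @export
train_diffusion <- function(model, tiles, labels, he_targets, schedule,
                            epochs, lr = 1e-5, weight_decay = 1e-5,
                            accum = 1L, ckpt_every = 25L, ckpt_dir = NULL,
                            val_tiles = NULL, val_labels = NULL, seed = 1L) {
  if (is.null(he_targets)) stop("he_targets missing: train the alignment model first")
  cfg <- model$config
  params <- model$params
  opt <- adamw_new(lr = lr, weight_decay = weight_decay)
  history <- numeric(0)
  val_history <- numeric(0)
  ckpts <- integer(0)
  best <- list(loss = Inf, params = params)
  sample_loss <- function(ps, x, lab, t, noise) {
    ctx <- ad_ctx(ps, frozen = "")
    xt <- forward_noise(x, t, schedule, noise)
    cond <- conditioning_for_training(lab, he_targets)
    pred <- unet_fwd(ctx, cfg, xt, t, cond)
    mean((pred$value - noise)^2)
  }
  with_seed(seed, {
    gacc <- list(); acc_n <- 0L
    for (ep in seq_len(epochs)) {
      ep_loss <- 0
      ord <- sample.int(length(tiles))
      for (ix in ord) {
        x <- tiles[[ix]]
        t <- sample.int(schedule$T, 1L)
        noise <- array(stats::rnorm(length(x)), dim(x))
        xt <- forward_noise(x, t, schedule, noise)
        cond <- conditioning_for_training(labels[[ix]], he_targets)
        ctx <- ad_ctx(params)
        pred <- unet_fwd(ctx, cfg, xt, t, cond)
        loss <- ad_mse(pred, noise)
        gacc <- grad_accumulate(gacc, ad_backward(loss))
        acc_n <- acc_n + 1L
        ep_loss <- ep_loss + loss$value
        if (acc_n == accum) {
          st <- adamw_step(opt, params, grad_scale(gacc, 1 / acc_n))
          opt <- st$opt; params <- st$params
          gacc <- list(); acc_n <- 0L
        }
      }
      history[ep] <- ep_loss / length(tiles)
      if (length(val_tiles)) {
        vl <- mean(vapply(seq_along(val_tiles), function(j) {
          t <- 1L + ((j * 7L) %% schedule$T)  # fixed spread of timesteps
          noise <- with_seed(seed + j, array(stats::rnorm(length(val_tiles[[j]])),
                                             dim(val_tiles[[j]])))
          sample_loss(params, val_tiles[[j]], val_labels[[j]], t, noise)
        }, 0))
        val_history[ep] <- vl
        if (vl < best$loss) best <- list(loss = vl, params = params)
      }
      if (!is.null(ckpt_dir) && ep %% ckpt_every == 0L) {
        dir.create(ckpt_dir, recursive = TRUE, showWarnings = FALSE)
        m <- model; m$params <- params
        save_checkpoint(m, file.path(ckpt_dir, sprintf("unet_ep%04d.rds", ep)))
        ckpts <- c(ckpts, ep)
      }
    }
    if (acc_n > 0L) {
      st <- adamw_step(opt, params, grad_scale(gacc, 1 / acc_n))
      params <- st$params
    }
  })
  model$params <- if (length(val_tiles) && is.finite(best$loss)) best$params else params
  model$loss_history <- history
  model$val_history <- val_history
  model$checkpoints <- ckpts
  model$trained <- epochs > 0L
  model
}

#' Sample an image from the trained diffusion model
#'
#' Ancestral sampling from pure noise along a (sub)sequence of timesteps;
#' with `steps = T` this is the exact DDPM reverse chain.
#'
#' @param model a trained `rs_unet`.
#' @param schedule the [noise_schedule()] used in training.
#' @param cond conditioning matrix `[K, d_ctx]`.
#' @param steps number of reverse steps (`<= T`).
#' @param seed RNG seed; fixed seed + conditioning gives identical output.
#' @param clip_x0 clamp the implied clean-image estimate to `[-1, 1]` at
#'   every step (the standard stabilization for epsilon-parameterized
#'   samplers) before forming the posterior mean.
#' @return image array `[in_ch, s, s]`, clipped to `[-1, 1]`.
#' @export
sample_diffusion <- function(model, schedule, cond, steps = schedule$T,
                             seed = 1L, clip_x0 = TRUE) {
  if (!isTRUE(model$trained)) stop("model is untrained")
  if (steps > schedule$T) stop("steps exceeds schedule length")
  cfg <- model$config
  ts <- unique(round(seq(schedule$T, 1, length.out = steps)))
  with_seed(seed, {
    x <- array(stats::rnorm(cfg$in_ch * cfg$img_size^2),
               c(cfg$in_ch, cfg$img_size, cfg$img_size))
    for (j in seq_along(ts)) {
      t <- ts[j]
      ab_t <- schedule$alphabar[t]
      ab_prev <- if (j < length(ts)) schedule$alphabar[ts[j + 1]] else 1
      ratio <- ab_t / ab_prev
      beta_eff <- 1 - ratio
      ctx <- ad_ctx(model$params, frozen = "")
      eps_hat <- unet_fwd(ctx, cfg, x, t, cond)$value
      x0_hat <- (x - sqrt(1 - ab_t) * eps_hat) / sqrt(ab_t)
      if (clip_x0) x0_hat <- pmin(pmax(x0_hat, -1), 1)
      # posterior mean q(x_{t_prev} | x_t, x0_hat)
      mean_x <- (sqrt(ab_prev) * beta_eff / (1 - ab_t)) * x0_hat +
        (sqrt(ratio) * (1 - ab_prev) / (1 - ab_t)) * x
      x <- if (j < length(ts)) {
        var_eff <- beta_eff * (1 - ab_prev) / (1 - ab_t)
        mean_x + sqrt(var_eff) * array(stats::rnorm(length(x)), dim(x))
      } else mean_x
    }
    pmin(pmax(x, -1), 1)
  })
}

#' Generate an H&E sub-image from a Raman sub-cube
#'
#' Full inference composition: encode the cube with the alignment model's
#' Raman encoder, patchify and project, compute cosine distances to the
#' Raman targets, sparsify with the two-step top-K mask, mix the aligned
#' H&E targets into conditioning vectors, and run the reverse diffusion.
#'
#' @param cube Raman sub-cube `[bands, X, Y]`.
#' @param alignnet a trained `rs_alignnet`.
#' @param unet a trained `rs_unet`.
#' @param schedule the training [noise_schedule()].
#' @param k_patch,k_clstarget top-K mask parameters; defaults keep 8 along
#'   the patch axis and K along the combined class/target axis (so the
#'   weaker class's targets are filtered out of the conditioning).
#' @param steps reverse diffusion steps.
#' @param seed RNG seed (deterministic end to end).
#' @return image `[in_ch, s, s]` in `[-1, 1]`, with attribute
#'   `stage_shapes` logging the intermediate shapes.
#' @export
generate_from_raman <- function(cube, alignnet, unet, schedule,
                                k_patch = NULL, k_clstarget = NULL,
                                steps = schedule$T, seed = 1L) {
  cfg <- alignnet$config
  shapes <- list(cube = dim(cube))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  patches <- stage("encode+patchify", {
    ctx <- ad_ctx(alignnet$params, frozen = "")
    aln_patches_fwd(ctx, cfg, cube, "RA")$value
  })
  shapes$patches <- dim(patches)
  ra_targets <- stage("targets", generate_targets(alignnet, "RA"))
  he_targets <- stage("targets", generate_targets(alignnet, "HE"))
  dist <- stage("distances", compute_distances(patches, ra_targets))
  shapes$dist <- dim(dist)
  if (is.null(k_patch)) k_patch <- min(8L, dim(dist)[2])
  if (is.null(k_clstarget)) k_clstarget <- dim(dist)[3]
  mask <- stage("mask", compute_mask(dist, k_patch, k_clstarget))
  cond <- stage("conditioning",
                synthesize_conditioning(dist, mask, he_targets)$cond)
  shapes$cond <- dim(cond)
  img <- stage("sampling",
               sample_diffusion(unet, schedule, cond, steps, seed = seed))
  shapes$image <- dim(img)
  attr(img, "stage_shapes") <- shapes
  img
}
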