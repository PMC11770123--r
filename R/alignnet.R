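# Cross-modal alignment network.
#
# Raman and H&E sub-images are encoded by separate convolutional stacks,
# split into non-overlapping patches (ViT-style), flattened and linearly
# projected to a 128-dimensional latent. A single bank of trainable seed
# vectors is mapped through per-modality fully connected stacks into
# per-class "targets" in each latent space; because both stacks consume the
# same seeds, target index (cls, k) refers to the same latent concept in
# both modalities. Classification is a similarity vote: cosine distances
# between patches and targets are exponentiated under a trainable
# temperature and combined with trainable nonnegative weights into
# per-class logits, trained with label-smoothed cross-entropy.

#' Alignment-network configuration
#'
#' @param bands Raman cube band count.
#' @param img_ch H&E channel count.
#' @param width latent channel width of both encoders.
#' @param n_down downsampling blocks per encoder (each halves extents).
#' @param patch patch extent on the encoded feature map.
#' @param d_seed seed vector dimension.
#' @param d_proj shared latent dimension of patches and targets.
#' @param K number of targets per class.
#' @param classes class labels (first class is index 1).
#' @param groups preferred group-normalization group count.
#' @param smoothing label-smoothing value for the cross-entropy.
#' @param lr,weight_decay AdamW settings.
#' @param accum samples per optimizer update (gradient accumulation; the
#'   full-scale configuration uses an effective batch of 64).
#' @param epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping
#'   (the full-scale configuration stops after 300).
#' @return a configuration list.
#' @export
alignnet_config <- function(bands, img_ch = 3L, width = 64L, n_down = 2L,
                            patch = 4L, d_seed = 64L, d_proj = 128L, K = 16L,
                            classes = PHANTOM_CLASSES, groups = 8L,
                            smoothing = 0.15, lr = 1e-5, weight_decay = 1e-5,
                            accum = 64L, epochs = 300L, patience = 300L) {
  list(bands = as.integer(bands), img_ch = as.integer(img_ch),
       width = as.integer(width), n_down = as.integer(n_down),
       patch = as.integer(patch), d_seed = as.integer(d_seed),
       d_proj = as.integer(d_proj), K = as.integer(K), classes = classes,
       n_classes = length(classes), groups = as.integer(groups),
       smoothing = smoothing, lr = lr, weight_decay = weight_decay,
       accum = as.integer(accum), epochs = as.integer(epochs),
       patience = as.integer(patience))
}

#' Build an untrained alignment network
#'
#' @param frozen_he_encoder a frozen encoder from [freeze_encoder()]; its
#'   parameters are copied in under the `he.enc.` prefix and never updated.
#' @param config an [alignnet_config()]; `width`/`n_down` must match the
#'   frozen encoder.
#' @param seed initialization seed.
#' @return an `rs_alignnet` model.
#' @export
build_alignnet <- function(frozen_he_encoder, config, seed = 1L) {
  stopifnot(inherits(frozen_he_encoder, "rs_frozen_encoder"))
  ecfg <- frozen_he_encoder$config
  if (ecfg$width != config$width || ecfg$n_down != config$n_down)
    stop("frozen encoder geometry does not match the configuration")
  d_raw <- config$width * config$patch^2
  params <- with_seed(seed, {
    p <- list()
    p <- init_down_stack(p, "ra.enc", config$bands, config$width, config$n_down)
    p <- init_linear(p, "he.proj", d_raw, config$d_proj)
    p <- init_linear(p, "ra.proj", d_raw, config$d_proj)
    p$seeds <- array(stats::rnorm(config$n_classes * config$K * config$d_seed),
                     c(config$n_classes, config$K, config$d_seed))
    for (m in c("he", "ra")) {
      p <- init_linear(p, paste0(m, ".fcs.l1"), config$d_seed, config$d_proj)
      p <- init_norm(p, paste0(m, ".fcs.ln1"), config$d_proj)
      p <- init_linear(p, paste0(m, ".fcs.l2"), config$d_proj, config$d_proj)
      p <- init_norm(p, paste0(m, ".fcs.ln2"), config$d_proj)
      p <- init_linear(p, paste0(m, ".fcs.l3"), config$d_proj, config$d_proj)
      # softplus(raw) = 1 at init for the per-target weights
      p[[paste0(m, ".w")]] <- matrix(log(exp(1) - 1), config$n_classes, config$K)
    }
    p$lam <- 0  # softplus(0) = log(2), the temperature initialization
    p
  })
  he <- frozen_he_encoder$params
  names(he) <- sub("^enc\\.", "he.enc.", names(he))
  params <- c(params, he)
  structure(list(params = params, config = config,
                 frozen_prefixes = "he.enc."),
            class = "rs_alignnet")
}

mod_prefix <- function(modality) {
  switch(toupper(modality), HE = "he", RA = "ra", RAMAN = "ra",
         stop("unknown modality: ", modality))
}

## ---- patch extraction ----

.patch_cache <- new.env(parent = emptyenv())

patch_indices <- function(C, H, W, ph, pw) {
  key <- paste(C, H, W, ph, pw, sep = "_")
  got <- .patch_cache[[key]]
  if (!is.null(got)) return(got)
  nH <- H %/% ph; nW <- W %/% pw
  d <- C * ph * pw
  within_c <- rep(seq_len(C), times = ph * pw)
  within_y <- rep(rep(seq_len(ph), each = C), times = pw)
  within_x <- rep(seq_len(pw), each = C * ph)
  base <- within_c + C * (within_y - 1L) + C * H * (within_x - 1L)
  # row-major patch order: the column (x) block varies fastest
  offs <- as.vector(t(outer(C * ph * (seq_len(nH) - 1L),
                            C * H * pw * (seq_len(nW) - 1L), "+")))
  idx <- outer(base, offs, "+")
  out <- list(idx = idx, n = nH * nW, d = d)
  .patch_cache[[key]] <- out
  out
}

# Autodiff node op: [C,H,W] -> [n_patches, C*ph*pw] (non-overlapping).
ad_patchify <- function(x, ph, pw) {
  x <- as_ad(x)
  dm <- dim(x$value)
  if (any(dm[2:3] %% c(ph, pw) != 0L))
    stop("spatial extents must be divisible by the patch size")
  pi <- patch_indices(dm[1], dm[2], dm[3], ph, pw)
  v <- t(matrix(x$value[pi$idx], nrow = pi$d))
  ad_op(v, list(x), function(g) {
    gx <- numeric(prod(dm))
    gx[as.vector(pi$idx)] <- as.vector(t(g))
    dim(gx) <- dm
    list(gx)
  })
}

#' Split a feature map into flattened non-overlapping patches
#'
#' Patches are enumerated row-major over the feature map; each row of the
#' result is one patch flattened to length `C * ph * pw`.
#'
#' @param feature_map array `[C, H, W]` with extents divisible by the patch.
#' @param patch patch extent (scalar or length 2).
#' @return matrix `[n_patches, d]` with attribute `geom`.
#' @export
patchify <- function(feature_map, patch = 4L) {
  patch <- as.integer(rep(patch, length.out = 2L))
  nd <- ad_patchify(ad_const(feature_map), patch[1], patch[2])
  out <- nd$value
  dm <- dim(feature_map)
  attr(out, "geom") <- list(patch = patch, channels = dm[1],
                            grid = dm[2:3] %/% patch)
  out
}

## ---- targets, distances, logits, loss (plain vectorized surface) ----

# Forward of the seed -> target stacks for one modality, on an ad ctx.
aln_targets_fwd <- function(ctx, cfg, modality) {
  m <- mod_prefix(modality)
  s <- ad_reshape(ctx_param(ctx, "seeds"),
                  c(cfg$n_classes * cfg$K, cfg$d_seed))
  h <- fwd_linear(ctx, paste0(m, ".fcs.l1"), s)
  h <- ad_silu(fwd_layernorm(ctx, paste0(m, ".fcs.ln1"), h))
  h <- fwd_linear(ctx, paste0(m, ".fcs.l2"), h)
  h <- ad_silu(fwd_layernorm(ctx, paste0(m, ".fcs.ln2"), h))
  fwd_linear(ctx, paste0(m, ".fcs.l3"), h)  # [n_classes*K, d_proj], cls fastest
}

aln_patches_fwd <- function(ctx, cfg, x, modality) {
  m <- mod_prefix(modality)
  feat <- fwd_down_stack(ctx, paste0(m, ".enc"), as_ad(x), cfg$width,
                         cfg$n_down, cfg$groups)
  raw <- ad_patchify(feat, cfg$patch, cfg$patch)
  fwd_linear(ctx, paste0(m, ".proj"), raw)  # [n_patches, d_proj]
}

# Distance tensor node [n_classes, n_patches, K] from patch/target matrices.
aln_dist_fwd <- function(patches, targets, n_classes, K) {
  pn <- ad_l2norm_rows(patches)
  tn <- ad_l2norm_rows(targets)
  D <- ad_matmul(pn, ad_t(tn))             # [n, n_classes*K], cls fastest
  n <- nrow(D$value)
  ad_aperm(ad_reshape(ad_t(D), c(n_classes, K, n)), c(1, 3, 2))
}

aln_logits_fwd <- function(ctx, cfg, dist3, modality) {
  m <- mod_prefix(modality)
  lam <- ad_softplus(ctx_param(ctx, "lam"))
  E <- ad_exp(ad_scale(ad_addc(dist3, 1), lam))
  S <- ad_sum_axis3(E, 2L)                 # [n_classes, K]
  w <- ad_softplus(ctx_param(ctx, paste0(m, ".w")))
  ad_rowsums(ad_mul(w, S))                 # length n_classes
}

#' Generate per-class targets for one modality
#'
#' Deterministic map of the shared seed bank through the modality's fully
#' connected stack.
#'
#' @param model an `rs_alignnet`.
#' @param modality `"HE"` or `"RA"`.
#' @return array `[n_classes, K, d_proj]`.
#' @export
generate_targets <- function(model, modality) {
  cfg <- model$config
  ctx <- ad_ctx(model$params, frozen = "")
  tm <- aln_targets_fwd(ctx, cfg, modality)$value
  aperm(array(t(tm), c(cfg$d_proj, cfg$n_classes, cfg$K)), c(2, 3, 1))
}

#' Cosine similarities between patches and per-class targets
#'
#' @param patches matrix `[n_patches, d]`.
#' @param targets array `[n_classes, K, d]`.
#' @param eps norm guard; vectors with norm below `eps` are scaled by
#'   `1/eps` instead of normalized, so zero vectors never produce NaN.
#' @return distance tensor `[n_classes, n_patches, K]`, entries in [-1, 1].
#' @export
compute_distances <- function(patches, targets, eps = 1e-8) {
  dm <- dim(targets)
  n_classes <- dm[1]; K <- dm[2]; d <- dm[3]
  stopifnot(ncol(patches) == d)
  tm <- matrix(aperm(targets, c(3, 1, 2)), nrow = d)  # d x (cls*K), cls fastest
  normr <- function(m) m / pmax(sqrt(rowSums(m^2)), eps)
  pn <- normr(patches)
  tn <- normr(t(tm))
  D <- pn %*% t(tn)                                   # [n, cls*K]
  aperm(array(t(D), c(n_classes, K, nrow(patches))), c(1, 3, 2))
}

#' Per-class logits from a distance tensor
#'
#' `logits[cls] = sum_k w[cls,k] * sum_i exp(lambda * (1 + dist[cls,i,k]))`:
#' the temperature rescales similarities from [-1, 1] to [0, 2*lambda], the
#' exponential amplifies the large similarities across the patch axis, and
#' the nonnegative weights sum over the target axis.
#'
#' @param dist tensor `[n_classes, n_patches, K]`.
#' @param w nonnegative weights `[n_classes, K]`.
#' @param lambda nonnegative scalar temperature.
#' @return numeric vector of per-class logits.
#' @export
compute_logits <- function(dist, w, lambda) {
  if (lambda < 0 || any(w < 0)) stop("w and lambda must be nonnegative")
  if (lambda * 2 > 700) stop("temperature too large: exp overflow; reduce lambda")
  E <- exp(lambda * (1 + dist))
  S <- apply(E, c(1, 3), sum)              # [n_classes, K]
  rowSums(w * S)
}

#' Label-smoothed classification loss
#'
#' Cross-entropy of `softmax(logits)` against the smoothed one-hot target
#' `(1 - s) * onehot + s / n_classes`.
#'
#' @param logits per-class logits.
#' @param label class index (1-based) or class name.
#' @param smoothing label-smoothing value in [0, 1).
#' @param classes class names used when `label` is character.
#' @return nonnegative scalar loss.
#' @export
classification_loss <- function(logits, label, smoothing = 0.15,
                                classes = PHANTOM_CLASSES) {
  n <- length(logits)
  if (is.character(label)) label <- match(label, classes)
  if (is.na(label) || label < 1 || label > n) stop("label outside class set")
  tgt <- rep(smoothing / n, n)
  tgt[label] <- tgt[label] + 1 - smoothing
  m <- max(logits)
  logp <- logits - (m + log(sum(exp(logits - m))))
  -sum(tgt * logp)
}

## ---- training ----

# One-sample loss node on a ctx honoring the frozen H&E encoder.
aln_loss_fwd <- function(ctx, cfg, x, modality, label_idx) {
  patches <- aln_patches_fwd(ctx, cfg, x, modality)
  targets <- aln_targets_fwd(ctx, cfg, modality)
  dist3 <- aln_dist_fwd(patches, targets, cfg$n_classes, cfg$K)
  logits <- aln_logits_fwd(ctx, cfg, dist3, modality)
  ad_ce_smooth(logits, label_idx, cfg$smoothing, cfg$n_classes)
}

#' Predict the class of a sub-image
#'
#' @param model a (trained) `rs_alignnet`.
#' @param x image array (`[img_ch, H, W]` for `"HE"`, `[bands, X, Y]` for
#'   `"RA"`).
#' @param modality `"HE"` or `"RA"`.
#' @return list with `logits`, `probs` and predicted `class`.
#' @export
predict_alignnet <- function(model, x, modality) {
  cfg <- model$config
  ctx <- ad_ctx(model$params, frozen = "")
  patches <- aln_patches_fwd(ctx, cfg, x, modality)
  targets <- aln_targets_fwd(ctx, cfg, modality)
  dist3 <- aln_dist_fwd(patches, targets, cfg$n_classes, cfg$K)
  logits <- aln_logits_fwd(ctx, cfg, dist3, modality)$value
  p <- exp(logits - max(logits)); p <- p / sum(p)
  list(logits = logits, probs = p,
       class = cfg$classes[which.max(logits)])
}

#' Train the alignment network
#'
#' Multi-task training over both modalities: each epoch interleaves the
#' shuffled H&E and Raman items, accumulating gradients and applying one
#' AdamW update per `config$accum` samples (so the update count equals
#' `ceiling(samples_seen / accum)`). The frozen H&E encoder parameters are
#' treated as constants throughout. Early stopping monitors the validation
#' loss with `config$patience`; the best-validation parameters are kept.
#'
#' @param model an `rs_alignnet` from [build_alignnet()].
#' @param data list with `train` and optional `val` item lists; each item is
#'   `list(x = array, modality = "HE"|"RA", label = class index,
#'   sample_id = chr)`. Both modalities must be present in `train`.
#' @param epochs overrides `config$epochs` when given.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch metrics.
#' @return the model with trained parameters, `metrics` (data frame with
#'   epoch/split/loss/accuracy rows) and `updates` (optimizer step count).
#' @export
train_alignnet <- function(model, data, epochs = NULL, seed = 1L,
                           verbose = FALSE) {
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  train <- data$train
  val <- data$val
  mods <- vapply(train, function(it) mod_prefix(it$modality), "")
  if (length(train) && !all(c("he", "ra") %in% mods))
    stop("training data must contain both modalities")
  params <- model$params
  frozen <- model$frozen_prefixes
  opt <- adamw_new(lr = cfg$lr, weight_decay = cfg$weight_decay)
  metrics <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  updates <- 0L
  gacc <- list(); acc_n <- 0L
  eval_split <- function(items, ps) {
    if (length(items) == 0L) return(c(NA_real_, NA_real_))
    m <- vapply(items, function(it) {
      ctx <- ad_ctx(ps, frozen = "")
      patches <- aln_patches_fwd(ctx, cfg, it$x, it$modality)
      targets <- aln_targets_fwd(ctx, cfg, it$modality)
      dist3 <- aln_dist_fwd(patches, targets, cfg$n_classes, cfg$K)
      lg <- aln_logits_fwd(ctx, cfg, dist3, it$modality)$value
      c(classification_loss(lg, it$label, cfg$smoothing, cfg$classes),
        as.numeric(which.max(lg) == it$label))
    }, numeric(2))
    rowMeans(m)
  }
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      he_items <- sample(train[mods == "he"])
      ra_items <- sample(train[mods == "ra"])
      order_items <- list()
      nmax <- max(length(he_items), length(ra_items))
      for (i in seq_len(nmax)) {  # alternate modalities
        if (i <= length(he_items)) order_items <- c(order_items, he_items[i])
        if (i <= length(ra_items)) order_items <- c(order_items, ra_items[i])
      }
      tr_loss <- 0; tr_hit <- 0
      for (it in order_items) {
        ctx <- ad_ctx(params, frozen = frozen)
        loss <- aln_loss_fwd(ctx, cfg, it$x, it$modality, it$label)
        gacc <- grad_accumulate(gacc, ad_backward(loss))
        acc_n <- acc_n + 1L
        tr_loss <- tr_loss + loss$value
        if (acc_n == cfg$accum) {
          st <- adamw_step(opt, params, grad_scale(gacc, 1 / acc_n), skip = frozen)
          opt <- st$opt; params <- st$params
          gacc <- list(); acc_n <- 0L; updates <- updates + 1L
        }
      }
      tr <- eval_split(order_items, params)
      vl <- eval_split(val, params)
      metrics[[length(metrics) + 1L]] <- data.frame(
        epoch = ep, split = c("train", "val"),
        loss = c(tr[1], vl[1]), accuracy = c(tr[2], vl[2]))
      if (verbose)
        message(sprintf("epoch %d train loss %.4f acc %.3f val loss %.4f acc %.3f",
                        ep, tr[1], tr[2], vl[1], vl[2]))
      monitor <- if (!is.na(vl[1])) vl[1] else tr[1]
      if (monitor < best$loss) best <- list(loss = monitor, params = params, epoch = ep)
      if (ep - best$epoch >= cfg$patience) break
    }
    if (acc_n > 0L) {  # flush the last partial accumulation
      st <- adamw_step(opt, params, grad_scale(gacc, 1 / acc_n), skip = frozen)
      params <- st$params; updates <- updates + 1L
      if (best$loss == Inf) best$params <- params
    }
  })
  model$params <- if (length(val)) best$params else params
  model$metrics <- if (length(metrics)) do.call(rbind, metrics) else
    data.frame(epoch = integer(), split = character(),
               loss = numeric(), accuracy = numeric())
  model$updates <- updates
  model
}

## ---- target/patch overlay ----

#' Rank target/patch pairs and overlay the top-n on an image
#'
#' Pairs every H&E patch with every (class, target) and ranks all pairs by
#' cosine similarity in descending order; the windows of the patches in the
#' top `n` pairs are marked in a logical overlay mask at input resolution.
#'
#' @param model a trained `rs_alignnet`.
#' @param image H&E image `[img_ch, H, W]`.
#' @param top_n number of pairs to keep (at most `n_patches * n_classes * K`).
#' @return list with `mask` (`[H, W]` logical) and `pairs` (data frame with
#'   rank, class, target index, patch index, similarity, window offsets).
#' @export
highlight_regions <- function(model, image, top_n) {
  cfg <- model$config
  ctx <- ad_ctx(model$params, frozen = "")
  patches <- aln_patches_fwd(ctx, cfg, image, "HE")$value
  targets <- generate_targets(model, "HE")
  dist <- compute_distances(patches, targets)   # [cls, i, k]
  n_pairs <- length(dist)
  if (top_n > n_pairs) stop("top_n exceeds the number of target/patch pairs")
  dmf <- dim(image)
  scale <- 2L^cfg$n_down
  win <- cfg$patch * scale
  grid_w <- (dmf[3] %/% scale) %/% cfg$patch
  idx <- arrayInd(order(-as.vector(dist))[seq_len(top_n)], dim(dist))
  mask <- matrix(FALSE, dmf[2], dmf[3])
  pairs <- data.frame(rank = seq_len(top_n), class = cfg$classes[idx[, 1]],
                      target_k = idx[, 3], patch = idx[, 2],
                      similarity = dist[idx])
  pairs$y0 <- ((pairs$patch - 1L) %/% grid_w) * win
  pairs$x0 <- ((pairs$patch - 1L) %% grid_w) * win
  for (r in seq_len(top_n)) {
    mask[pairs$y0[r] + seq_len(win), pairs$x0[r] + seq_len(win)] <- TRUE
  }
  list(mask = mask, pairs = pairs)
}
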