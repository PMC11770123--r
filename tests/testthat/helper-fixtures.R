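# Shared fixtures and independent scalar oracles.
#
# The oracles deliberately re-derive every quantity with plain loops and
# direct formulas, so the vectorized implementations are checked against an
# independent computation path.

rs <- asNamespace("ramanstain")

## ---- scalar oracles for the similarity / logit / loss chain ----

oracle_cosine <- function(a, b, eps = 1e-8) {
  sum(a * b) / (max(sqrt(sum(a^2)), eps) * max(sqrt(sum(b^2)), eps))
}

oracle_distances <- function(patches, targets, eps = 1e-8) {
  n_classes <- dim(targets)[1]; K <- dim(targets)[2]
  n <- nrow(patches)
  out <- array(NA_real_, c(n_classes, n, K))
  for (cls in seq_len(n_classes))
    for (i in seq_len(n))
      for (k in seq_len(K))
        out[cls, i, k] <- oracle_cosine(patches[i, ], targets[cls, k, ], eps)
  out
}

oracle_logits <- function(dist, w, lambda) {
  n_classes <- dim(dist)[1]
  out <- numeric(n_classes)
  for (cls in seq_len(n_classes)) {
    acc <- 0
    for (k in seq_len(dim(dist)[3])) {
      inner <- 0
      for (i in seq_len(dim(dist)[2]))
        inner <- inner + exp(lambda * (1 + dist[cls, i, k]))
      acc <- acc + w[cls, k] * inner
    }
    out[cls] <- acc
  }
  out
}

oracle_ce <- function(logits, label, smoothing) {
  n <- length(logits)
  tgt <- rep(smoothing / n, n); tgt[label] <- tgt[label] + 1 - smoothing
  p <- exp(logits) / sum(exp(logits))
  -sum(tgt * log(p))
}

# Brute-force two-step top-K mask: explicit thresholds from sorted values,
# lowest-index tie resolution.
oracle_mask <- function(dist, k_patch, k_clstarget) {
  dm <- dim(dist)
  s1 <- array(FALSE, dm)
  for (cls in seq_len(dm[1])) for (k in seq_len(dm[3])) {
    v <- dist[cls, , k]
    r <- rank(-v, ties.method = "first")
    s1[cls, , k] <- r <= k_patch
  }
  s2 <- array(FALSE, dm)
  for (i in seq_len(dm[2])) {
    v <- as.vector(dist[, i, ])
    alive <- as.vector(s1[, i, ])
    v[!alive] <- -Inf
    r <- rank(-v, ties.method = "first")
    keep <- alive & r <= k_clstarget
    # rank counts dead -Inf entries too once alive ones are exhausted; keep
    # at most k_clstarget alive entries in rank order
    if (sum(keep) < min(k_clstarget, sum(alive))) {
      ord <- order(-v, seq_along(v))
      ord <- ord[alive[ord]]
      keep <- rep(FALSE, length(v))
      keep[ord[seq_len(min(k_clstarget, sum(alive)))]] <- TRUE
    }
    s2[, i, ] <- array(keep, c(dm[1], dm[3]))
  }
  m <- array(-Inf, dm); m[s2] <- 1
  m
}

oracle_conditioning <- function(dist, mask, he_targets) {
  dm <- dim(dist)
  K <- dm[3]; d <- dim(he_targets)[3]
  cond <- matrix(0, K, d)
  for (k in seq_len(K)) {
    num <- 0; den <- 0
    for (cls in seq_len(dm[1])) for (i in seq_len(dm[2]))
      if (mask[cls, i, k] == 1) den <- den + exp(dist[cls, i, k])
    for (cls in seq_len(dm[1])) for (i in seq_len(dm[2]))
      if (mask[cls, i, k] == 1)
        cond[k, ] <- cond[k, ] + exp(dist[cls, i, k]) / den * he_targets[cls, k, ]
  }
  cond
}

## ---- toy data ----

# Co-registered phantom items for alignment training; near-orthogonal class
# spectra make the problem separable by construction.
toy_align_items <- function(n_per_class, bands = 6L, seed0 = 1L,
                            noise = 0.03, canvas = 16, he_override = NULL,
                            signatures = NULL) {
  items <- list()
  for (ci in 1:2) {
    cls <- c("TSCC", "normal")[ci]
    for (i in seq_len(n_per_class)) {
      sp <- phantom_spec(cls, canvas_um = c(canvas, canvas), bands = bands,
                         spectral_signature =
                           if (is.null(signatures)) NULL else signatures[[ci]],
                         noise_sd = noise, n_texture_elements = 4L,
                         rng_seed = seed0 * 1000L + ci * 300L + i)
      sm <- generate_sample(sp)
      he <- if (is.null(he_override)) sm$rgb else he_override(ci, seed0 * 77L + ci * 13L + i)
      sid <- paste0(cls, "_", i)
      items <- c(items, list(
        list(x = he, modality = "HE", label = ci, sample_id = sid),
        list(x = sm$cube, modality = "RA", label = ci, sample_id = sid)))
    }
  }
  items
}

# Small pretrained-and-frozen H&E encoder + alignment model, shared by the
# training tests.
toy_alignnet <- function(items, bands = 6L, width = 8L, K = 4L,
                         epochs = 10L, lr = 2e-3, accum = 8L, seed = 3L,
                         ae_steps = 30L) {
  he_imgs <- lapply(Filter(function(i) i$modality == "HE", items), `[[`, "x")
  ae <- build_autoencoder(3L, width = width, n_down = 2L, seed = seed)
  ae <- pretrain_autoencoder(ae, he_imgs, steps = ae_steps, lr = 2e-3, seed = seed)
  cfg <- alignnet_config(bands = bands, width = width, n_down = 2L, patch = 4L,
                         K = K, lr = lr, accum = accum, epochs = epochs)
  build_alignnet(freeze_encoder(ae), cfg, seed = seed)
}
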