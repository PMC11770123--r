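# Layer builders on top of the autodiff primitives.
#
# Parameters live in a flat named list of arrays; `init_*` helpers append
# freshly initialized arrays under a dotted prefix and the matching `fwd_*`
# helpers pull them out of an `ad_ctx` during the forward pass.

init_conv <- function(params, name, in_ch, out_ch, k = 3L, gain = 2) {
  sd <- sqrt(gain / (in_ch * k * k))
  params[[paste0(name, ".W")]] <-
    array(stats::rnorm(out_ch * in_ch * k * k, sd = sd), c(out_ch, in_ch, k, k))
  params[[paste0(name, ".b")]] <- numeric(out_ch)
  params
}

init_linear <- function(params, name, d_in, d_out, gain = 2) {
  sd <- sqrt(gain / d_in)
  params[[paste0(name, ".W")]] <- matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out)
  params[[paste0(name, ".b")]] <- numeric(d_out)
  params
}

init_norm <- function(params, name, ch) {
  params[[paste0(name, ".g")]] <- rep(1, ch)
  params[[paste0(name, ".be")]] <- numeric(ch)
  params
}

fwd_conv <- function(ctx, name, x, stride = 1L, pad = 1L) {
  ad_conv2d(x, ctx_param(ctx, paste0(name, ".W")),
            ctx_param(ctx, paste0(name, ".b")), stride = stride, pad = pad)
}

fwd_linear <- function(ctx, name, x) {
  ad_add_rowvec(ad_matmul(x, ctx_param(ctx, paste0(name, ".W"))),
                ctx_param(ctx, paste0(name, ".b")))
}

fwd_groupnorm <- function(ctx, name, x, groups) {
  ad_groupnorm(x, ctx_param(ctx, paste0(name, ".g")),
               ctx_param(ctx, paste0(name, ".be")), groups = groups)
}

fwd_layernorm <- function(ctx, name, x) {
  ad_layernorm_rows(x, ctx_param(ctx, paste0(name, ".g")),
                    ctx_param(ctx, paste0(name, ".be")))
}

# Number of groups for group normalization: largest divisor of `ch` not
# exceeding the preferred count.
norm_groups <- function(ch, prefer = 8L) {
  g <- min(prefer, ch)
  while (ch %% g != 0L) g <- g - 1L
  g
}

## ---- residual CNN block ----
# Two (groupNorm -> SiLU -> conv3x3) stages with an additive shortcut from
# block input to the last convolution's output. When the channel count
# changes, the shortcut goes through a 1x1 convolution. With a timestep
# embedding, the second normalization is modulated scale-shift style
# (AdaGN): h <- gn(h) * (1 + scale(t)) + shift(t), so the denoiser can
# express timestep-dependent gains; the modulation projections start at
# zero, leaving the block time-agnostic at initialization.

init_resblock <- function(params, name, in_ch, out_ch, time_dim = 0L) {
  params <- init_norm(params, paste0(name, ".gn1"), in_ch)
  params <- init_conv(params, paste0(name, ".c1"), in_ch, out_ch, 3L)
  params <- init_norm(params, paste0(name, ".gn2"), out_ch)
  params <- init_conv(params, paste0(name, ".c2"), out_ch, out_ch, 3L)
  if (in_ch != out_ch) params <- init_conv(params, paste0(name, ".sc"), in_ch, out_ch, 1L)
  if (time_dim > 0L) {
    params[[paste0(name, ".ts.W")]] <- matrix(0, time_dim, out_ch)
    params[[paste0(name, ".ts.b")]] <- numeric(out_ch)
    params[[paste0(name, ".tb.W")]] <- matrix(0, time_dim, out_ch)
    params[[paste0(name, ".tb.b")]] <- numeric(out_ch)
  }
  params
}

fwd_resblock <- function(ctx, name, x, in_ch, out_ch, groups_pref = 8L, t_emb = NULL) {
  h <- fwd_groupnorm(ctx, paste0(name, ".gn1"), x, norm_groups(in_ch, groups_pref))
  h <- fwd_conv(ctx, paste0(name, ".c1"), ad_silu(h), stride = 1L, pad = 1L)
  h <- fwd_groupnorm(ctx, paste0(name, ".gn2"), h, norm_groups(out_ch, groups_pref))
  if (!is.null(t_emb)) {
    ts <- fwd_linear(ctx, paste0(name, ".ts"), t_emb)   # [1, out_ch] scale
    tb <- fwd_linear(ctx, paste0(name, ".tb"), t_emb)   # [1, out_ch] shift
    h <- ad_mul_chan(h, ad_addc(ad_reshape(ts, out_ch), 1))
    h <- ad_add_chan(h, ad_reshape(tb, out_ch))
  }
  h <- fwd_conv(ctx, paste0(name, ".c2"), ad_silu(h), stride = 1L, pad = 1L)
  sc <- if (in_ch != out_ch) fwd_conv(ctx, paste0(name, ".sc"), x, stride = 1L, pad = 0L) else x
  ad_add(sc, h)
}

## ---- downsampling / upsampling stacks ----
# One downsampling block = two residual blocks followed by a stride-2
# convolution; each block halves both spatial extents. The autoencoder
# decoder mirrors this with nearest-neighbour upsampling + convolution.

init_down_stack <- function(params, name, in_ch, width, n_down) {
  params <- init_conv(params, paste0(name, ".init"), in_ch, width, 3L)
  for (l in seq_len(n_down)) {
    params <- init_resblock(params, paste0(name, ".d", l, ".r1"), width, width)
    params <- init_resblock(params, paste0(name, ".d", l, ".r2"), width, width)
    params <- init_conv(params, paste0(name, ".d", l, ".down"), width, width, 3L)
  }
  params
}

fwd_down_stack <- function(ctx, name, x, width, n_down, groups_pref = 8L) {
  h <- fwd_conv(ctx, paste0(name, ".init"), x, stride = 1L, pad = 1L)
  for (l in seq_len(n_down)) {
    h <- fwd_resblock(ctx, paste0(name, ".d", l, ".r1"), h, width, width, groups_pref)
    h <- fwd_resblock(ctx, paste0(name, ".d", l, ".r2"), h, width, width, groups_pref)
    h <- fwd_conv(ctx, paste0(name, ".d", l, ".down"), h, stride = 2L, pad = 1L)
  }
  h
}

init_up_stack <- function(params, name, out_ch, width, n_down) {
  for (l in seq_len(n_down)) {
    params <- init_resblock(params, paste0(name, ".u", l, ".r1"), width, width)
    params <- init_resblock(params, paste0(name, ".u", l, ".r2"), width, width)
    params <- init_conv(params, paste0(name, ".u", l, ".up"), width, width, 3L)
  }
  params <- init_conv(params, paste0(name, ".out"), width, out_ch, 3L)
  params
}

fwd_up_stack <- function(ctx, name, h, out_ch, width, n_down, groups_pref = 8L) {
  for (l in seq_len(n_down)) {
    h <- fwd_resblock(ctx, paste0(name, ".u", l, ".r1"), h, width, width, groups_pref)
    h <- fwd_resblock(ctx, paste0(name, ".u", l, ".r2"), h, width, width, groups_pref)
    h <- fwd_conv(ctx, paste0(name, ".u", l, ".up"), ad_upsample2(h), stride = 1L, pad = 1L)
  }
  fwd_conv(ctx, paste0(name, ".out"), h, stride = 1L, pad = 1L)
}

## ---- attention ----
# Single-head scaled dot-product attention over spatial tokens. For
# self-attention the context is the token matrix itself; for cross-attention
# it is an external [n_ctx, d_ctx] matrix (e.g. conditioning vectors).

init_attention <- function(params, name, ch, d_ctx = ch) {
  params <- init_norm(params, paste0(name, ".gn"), ch)
  params <- init_linear(params, paste0(name, ".q"), ch, ch, gain = 1)
  params <- init_linear(params, paste0(name, ".k"), d_ctx, ch, gain = 1)
  params <- init_linear(params, paste0(name, ".v"), d_ctx, ch, gain = 1)
  # zero-initialized output projection: the block starts as the identity and
  # the (cross-)attention contribution is learned from zero
  params[[paste0(name, ".o.W")]] <- matrix(0, ch, ch)
  params[[paste0(name, ".o.b")]] <- numeric(ch)
  params
}

# x: [C,H,W] node; context: NULL for self-attention or [n_ctx, d_ctx] node.
fwd_attention <- function(ctx, name, x, ch, context = NULL, groups_pref = 8L) {
  dm <- dim(x$value)
  hn <- fwd_groupnorm(ctx, paste0(name, ".gn"), x, norm_groups(ch, groups_pref))
  tok <- ad_t(ad_reshape(hn, c(dm[1], dm[2] * dm[3])))  # [HW, C]
  kv_in <- if (is.null(context)) tok else context
  q <- fwd_linear(ctx, paste0(name, ".q"), tok)
  k <- fwd_linear(ctx, paste0(name, ".k"), kv_in)
  v <- fwd_linear(ctx, paste0(name, ".v"), kv_in)
  att <- ad_softmax_rows(ad_scale(ad_matmul(q, ad_t(k)), 1 / sqrt(ch)))
  o <- fwd_linear(ctx, paste0(name, ".o"), ad_matmul(att, v))
  ad_add(x, ad_reshape(ad_t(o), dm))
}

## ---- sinusoidal timestep embedding ----

time_embedding <- function(t, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- t * freqs
  matrix(c(sin(ang), cos(ang)), nrow = 1L)
}
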