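# Reverse-mode automatic differentiation on dense arrays.
#
# A forward pass builds a graph of `ad_node` environments; `ad_backward()`
# walks it in reverse topological order and accumulates gradients into the
# leaf nodes created from trainable parameters. Nodes whose ancestors contain
# no trainable parameter carry no backward closure, so frozen subgraphs
# (e.g. the frozen H&E encoder) cost nothing at backward time.

ad_node <- function(value, parents = list(), backward = NULL, needs = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$needs <- needs
  nd$grad <- NULL
  nd$pname <- NULL
  class(nd) <- "ad_node"
  nd
}

ad_const <- function(value) ad_node(value)

is_ad <- function(x) inherits(x, "ad_node")

as_ad <- function(x) if (is_ad(x)) x else ad_const(x)

ad_value <- function(x) if (is_ad(x)) x$value else x

# Construct an interior node; drops the backward closure when no parent
# requires gradients so dead subgraphs are pruned automatically.
ad_op <- function(value, parents, backward) {
  needs <- FALSE
  for (p in parents) if (is_ad(p) && isTRUE(p$needs)) { needs <- TRUE; break }
  if (!needs) backward <- NULL
  ad_node(value, parents = parents, backward = backward, needs = needs)
}

# Parameter context: wraps a named list of arrays into leaf nodes on demand,
# caching one node per parameter so gradient contributions accumulate.
# Parameters whose name starts with a `frozen` prefix become constants.
ad_ctx <- function(params, frozen = character()) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$frozen <- frozen
  ctx$cache <- new.env(parent = emptyenv())
  ctx
}

ctx_param <- function(ctx, name) {
  nd <- ctx$cache[[name]]
  if (is.null(nd)) {
    v <- ctx$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    frozen <- length(ctx$frozen) > 0L && any(startsWith(name, ctx$frozen))
    nd <- if (frozen) ad_const(v) else ad_node(v, needs = TRUE)
    if (!frozen) nd$pname <- name
    ctx$cache[[name]] <- nd
  }
  nd
}

ad_topo <- function(root) {
  acc <- new.env(parent = emptyenv())
  acc$lst <- vector("list", 64L)
  acc$n <- 0L
  visit <- function(nd) {
    if (!is.null(nd$.vis)) return(invisible(NULL))
    nd$.vis <- TRUE
    for (p in nd$parents) if (is_ad(p) && isTRUE(p$needs)) visit(p)
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$lst)) length(acc$lst) <- 2L * length(acc$lst)
    acc$lst[[acc$n]] <- nd
    invisible(NULL)
  }
  visit(root)
  acc$lst[seq_len(acc$n)]
}

# Backpropagate from a scalar root; returns named list of parameter grads.
ad_backward <- function(root) {
  stopifnot(is_ad(root), length(root$value) == 1L)
  if (!isTRUE(root$needs)) return(list())
  topo <- ad_topo(root)
  for (nd in topo) nd$grad <- NULL
  root$grad <- 1
  grads <- list()
  for (idx in rev(seq_along(topo))) {
    nd <- topo[[idx]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$pname)) grads[[nd$pname]] <- nd$grad
    if (!is.null(nd$backward)) {
      gs <- nd$backward(nd$grad)
      for (j in seq_along(nd$parents)) {
        p <- nd$parents[[j]]
        if (is_ad(p) && isTRUE(p$needs) && !is.null(gs[[j]])) {
          p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
        }
      }
    }
  }
  for (nd in topo) nd$.vis <- NULL
  grads
}

## ---- elementwise and linear-algebra primitives ----

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# Multiply by a scalar (plain numeric or scalar node).
ad_scale <- function(a, s) {
  a <- as_ad(a)
  if (is_ad(s)) {
    av <- a$value; sv <- s$value
    ad_op(av * sv, list(a, s), function(g) list(g * sv, sum(g * av)))
  } else {
    ad_op(a$value * s, list(a), function(g) list(g * s))
  }
}

ad_addc <- function(a, c) {
  a <- as_ad(a)
  ad_op(a$value + c, list(a), function(g) list(g))
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_op(av %*% bv, list(a, b),
        function(g) list(g %*% t(bv), t(av) %*% g))
}

ad_t <- function(a) {
  a <- as_ad(a)
  ad_op(t(a$value), list(a), function(g) list(t(g)))
}

ad_sum <- function(a) {
  a <- as_ad(a)
  dm <- dim(a$value); n <- length(a$value)
  ad_op(sum(a$value), list(a), function(g) {
    out <- rep(as.numeric(g), n)
    if (!is.null(dm)) dim(out) <- dm
    list(out)
  })
}

ad_mean <- function(a) {
  a <- as_ad(a)
  dm <- dim(a$value); n <- length(a$value)
  ad_op(mean(a$value), list(a), function(g) {
    out <- rep(as.numeric(g) / n, n)
    if (!is.null(dm)) dim(out) <- dm
    list(out)
  })
}

# Row sums of a matrix -> vector.
ad_rowsums <- function(a) {
  a <- as_ad(a)
  nr <- nrow(a$value); nc <- ncol(a$value)
  ad_op(rowSums(a$value), list(a),
        function(g) list(matrix(g, nr, nc)))
}

# Sum a 3D array over one axis, keeping the other two.
ad_sum_axis3 <- function(a, axis) {
  a <- as_ad(a)
  dm <- dim(a$value)
  stopifnot(length(dm) == 3L, axis %in% 1:3)
  keep <- setdiff(1:3, axis)
  ad_op(apply(a$value, keep, sum), list(a), function(g) {
    full <- array(g, c(dm[keep], dm[axis]))
    perm <- integer(3L)
    perm[keep] <- 1:2
    perm[axis] <- 3L
    list(aperm(full, perm))
  })
}

ad_exp <- function(a) {
  a <- as_ad(a)
  ev <- exp(a$value)
  ad_op(ev, list(a), function(g) list(g * ev))
}

ad_silu <- function(a) {
  a <- as_ad(a)
  av <- a$value
  s <- 1 / (1 + exp(-av))
  ad_op(av * s, list(a), function(g) list(g * s * (1 + av * (1 - s))))
}

ad_softplus <- function(a) {
  a <- as_ad(a)
  av <- a$value
  v <- ifelse(av > 30, av, log1p(exp(pmin(av, 30))))
  if (!is.null(dim(av))) dim(v) <- dim(av)
  s <- 1 / (1 + exp(-av))
  ad_op(v, list(a), function(g) list(g * s))
}

ad_reshape <- function(a, dims) {
  a <- as_ad(a)
  old <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  ad_op(v, list(a), function(g) {
    if (is.null(old)) dim(g) <- NULL else dim(g) <- old
    list(g)
  })
}

ad_aperm <- function(a, perm) {
  a <- as_ad(a)
  ad_op(aperm(a$value, perm), list(a),
        function(g) list(aperm(g, order(perm))))
}

# Add a length-ncol vector to every row of a matrix (bias on features).
ad_add_rowvec <- function(m, v) {
  m <- as_ad(m); v <- as_ad(v)
  ad_op(sweep(m$value, 2L, v$value, "+"), list(m, v),
        function(g) list(g, colSums(g)))
}

# Add a per-channel bias (length dim1) to a [C,H,W] array.
ad_add_chan <- function(x, v) {
  x <- as_ad(x); v <- as_ad(v)
  ad_op(x$value + as.vector(v$value), list(x, v),
        function(g) list(g, rowSums(g, dims = 1L)))
}

# Multiply a [C,H,W] array by a per-channel gain (length dim1).
ad_mul_chan <- function(x, v) {
  x <- as_ad(x); v <- as_ad(v)
  xv <- x$value; vv <- as.vector(v$value)
  ad_op(xv * vv, list(x, v),
        function(g) list(g * vv, rowSums(g * xv, dims = 1L)))
}

# Concatenate two [C,H,W] arrays along the channel axis.
ad_concat_chan <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[2:3] == db[2:3]))
  v <- array(0, c(da[1] + db[1], da[2], da[3]))
  v[seq_len(da[1]), , ] <- a$value
  v[da[1] + seq_len(db[1]), , ] <- b$value
  ad_op(v, list(a, b), function(g) {
    list(g[seq_len(da[1]), , , drop = FALSE],
         g[da[1] + seq_len(db[1]), , , drop = FALSE])
  })
}

## ---- row-wise normalizations and softmax ----

# L2-normalize each row of a matrix, guarding zero norms at `eps`.
ad_l2norm_rows <- function(a, eps = 1e-8) {
  a <- as_ad(a)
  av <- a$value
  nrm <- sqrt(rowSums(av^2))
  neff <- pmax(nrm, eps)
  y <- av / neff
  ad_op(y, list(a), function(g) {
    dots <- rowSums(g * y)
    gx <- (g - y * dots) / neff
    clipped <- nrm < eps
    if (any(clipped)) gx[clipped, ] <- g[clipped, , drop = FALSE] / eps
    list(gx)
  })
}

ad_softmax_rows <- function(a) {
  a <- as_ad(a)
  av <- a$value
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  p <- e / rowSums(e)
  ad_op(p, list(a), function(g) {
    list((g - rowSums(g * p)) * p)
  })
}

# Layer normalization over the feature (column) axis of [n, d] with affine
# per-feature gamma/beta.
ad_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ad_op(y, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gamma$value, "*")
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    dx <- (istd / d) * (d * dxhat - s1 - xhat * s2)
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# Group normalization on a [C,H,W] array; channels are split into `groups`
# contiguous groups, statistics taken per group over channels and space.
ad_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  xv <- x$value
  dm <- dim(xv)
  C <- dm[1]; HW <- dm[2] * dm[3]
  stopifnot(C %% groups == 0L)
  cg <- C %/% groups
  m <- cg * HW
  xr <- matrix(aperm(array(xv, c(cg, groups, HW)), c(1, 3, 2)), m, groups)
  mu <- colMeans(xr)
  va <- colMeans(xr^2) - mu^2
  istd_g <- 1 / sqrt(va + eps)
  mu_c <- rep(mu, each = cg)
  istd_c <- rep(istd_g, each = cg)
  xhat <- (xv - mu_c) * istd_c
  y <- xhat * as.vector(gamma$value) + as.vector(beta$value)
  ad_op(y, list(x, gamma, beta), function(g) {
    dxhat <- g * as.vector(gamma$value)
    per_group <- function(a) {
      colSums(matrix(aperm(array(a, c(cg, groups, HW)), c(1, 3, 2)), m, groups))
    }
    s1 <- per_group(dxhat)
    s2 <- per_group(dxhat * xhat)
    dx <- (istd_c / m) * (m * dxhat - rep(s1, each = cg) - xhat * rep(s2, each = cg))
    list(dx, rowSums(g * xhat, dims = 1L), rowSums(g, dims = 1L))
  })
}

## ---- convolution and resampling ----

# Cache of im2col index sets keyed by geometry.
.conv_cache <- new.env(parent = emptyenv())

conv_indices <- function(C, H, W, kh, kw, stride, pad) {
  key <- paste(C, H, W, kh, kw, stride, pad, sep = "_")
  got <- .conv_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  OH <- (Hp - kh) %/% stride + 1L
  OW <- (Wp - kw) %/% stride + 1L
  cc <- rep(seq_len(C), times = kh * kw)
  khr <- rep(rep(seq_len(kh), each = C), times = kw)
  kwr <- rep(seq_len(kw), each = C * kh)
  base <- cc + C * (khr - 1L) + C * Hp * (kwr - 1L)
  offh <- C * stride * (seq_len(OH) - 1L)
  offw <- C * Hp * stride * (seq_len(OW) - 1L)
  off <- as.vector(outer(offh, offw, "+"))
  idx <- outer(base, off, "+")
  out <- list(idx = idx, OH = OH, OW = OW, Hp = Hp, Wp = Wp)
  .conv_cache[[key]] <- out
  out
}

pad_chw <- function(x, pad) {
  if (pad == 0L) return(x)
  dm <- dim(x)
  xp <- array(0, c(dm[1], dm[2] + 2L * pad, dm[3] + 2L * pad))
  xp[, pad + seq_len(dm[2]), pad + seq_len(dm[3])] <- x
  xp
}

# 2D convolution on [C,H,W] with weight [outC,inC,kh,kw], bias length outC.
ad_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xv <- x$value; wv <- w$value
  dmx <- dim(xv); dmw <- dim(wv)
  C <- dmx[1]; H <- dmx[2]; W <- dmx[3]
  outC <- dmw[1]; kh <- dmw[3]; kw <- dmw[4]
  stopifnot(dmw[2] == C)
  ci <- conv_indices(C, H, W, kh, kw, as.integer(stride), as.integer(pad))
  xp <- pad_chw(xv, pad)
  patches <- matrix(xp[ci$idx], nrow = nrow(ci$idx))
  wmat <- matrix(wv, outC, C * kh * kw)
  out <- wmat %*% patches + as.vector(b$value)
  yv <- array(out, c(outC, ci$OH, ci$OW))
  ad_op(yv, list(x, w, b), function(g) {
    gmat <- matrix(g, outC, ci$OH * ci$OW)
    gw <- gmat %*% t(patches)
    dim(gw) <- dmw
    gb <- rowSums(gmat)
    gpatch <- t(wmat) %*% gmat
    gxp_flat <- numeric(C * ci$Hp * ci$Wp)
    acc <- rowsum(as.vector(gpatch), as.vector(ci$idx))
    gxp_flat[as.integer(rownames(acc))] <- acc
    gxp <- array(gxp_flat, c(C, ci$Hp, ci$Wp))
    gx <- if (pad > 0L) {
      gxp[, pad + seq_len(H), pad + seq_len(W), drop = FALSE]
    } else gxp
    list(gx, gw, gb)
  })
}

# Nearest-neighbour 2x spatial upsampling of [C,H,W].
ad_upsample2 <- function(x) {
  x <- as_ad(x)
  dm <- dim(x$value)
  ih <- rep(seq_len(dm[2]), each = 2L)
  iw <- rep(seq_len(dm[3]), each = 2L)
  yv <- x$value[, ih, iw, drop = FALSE]
  ad_op(yv, list(x), function(g) {
    o1 <- seq(1L, 2L * dm[2], by = 2L)
    o2 <- seq(1L, 2L * dm[3], by = 2L)
    gh <- g[, o1, , drop = FALSE] + g[, o1 + 1L, , drop = FALSE]
    list(gh[, , o2, drop = FALSE] + gh[, , o2 + 1L, drop = FALSE])
  })
}

## ---- losses ----

# Cross-entropy of softmax(logits) against a label-smoothed one-hot target.
ad_ce_smooth <- function(logits, label_idx, smoothing = 0, n_classes = NULL) {
  logits <- as_ad(logits)
  lv <- as.vector(logits$value)
  if (is.null(n_classes)) n_classes <- length(lv)
  stopifnot(label_idx >= 1L, label_idx <= n_classes)
  tgt <- rep(smoothing / n_classes, n_classes)
  tgt[label_idx] <- tgt[label_idx] + (1 - smoothing)
  m <- max(lv)
  lse <- m + log(sum(exp(lv - m)))
  logp <- lv - lse
  p <- exp(logp)
  ad_op(-sum(tgt * logp), list(logits), function(g) {
    gr <- as.numeric(g) * (p - tgt)
    if (!is.null(dim(logits$value))) dim(gr) <- dim(logits$value)
    list(gr)
  })
}

ad_mse <- function(a, b) {
  d <- ad_sub(as_ad(a), as_ad(b))
  ad_mean(ad_mul(d, d))
}
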