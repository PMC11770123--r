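# AdamW optimizer with decoupled weight decay, plus gradient accumulation
# and small reproducibility helpers shared by the training loops.

#' Create an AdamW optimizer state
#'
#' @param lr learning rate (default matches the training configuration used
#'   throughout the package, see [run_config()]).
#' @param weight_decay decoupled weight-decay coefficient.
#' @param beta1,beta2,eps Adam moment coefficients and stabilizer.
#' @return an optimizer state list, advanced by `adamw_step()`.
#' @keywords internal
adamw_new <- function(lr = 1e-5, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, wd = weight_decay, b1 = beta1, b2 = beta2, eps = eps,
       t = 0L, m = list(), v = list())
}

# Apply one AdamW update. `grads` is a named list (missing names = no grad);
# `skip` names (e.g. frozen encoder parameters) are never touched.
adamw_step <- function(opt, params, grads, skip = character()) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (nm in names(grads)) {
    if (length(skip) && any(startsWith(nm, skip))) next
    g <- grads[[nm]]
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- opt$b1 * m + (1 - opt$b1) * g
    v <- opt$b2 * v + (1 - opt$b2) * g * g
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + opt$eps)
    params[[nm]] <- params[[nm]] - opt$lr * (upd + opt$wd * params[[nm]])
  }
  list(opt = opt, params = params)
}

# Accumulate `new` gradients into running sums `acc` (both named lists).
grad_accumulate <- function(acc, new) {
  for (nm in names(new)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) new[[nm]] else acc[[nm]] + new[[nm]]
  }
  acc
}

grad_scale <- function(grads, s) {
  for (nm in names(grads)) grads[[nm]] <- grads[[nm]] * s
  grads
}

#' Fingerprint of a parameter set
#'
#' MD5 digest of the serialized parameter list, used to assert that frozen
#' weights stay bit-identical across downstream training.
#'
#' @param params a named list of numeric arrays (or a model with `$params`).
#' @return a character MD5 string.
#' @export
weight_fingerprint <- function(params) {
  if (!is.null(params$params)) params <- params$params
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(params, NULL, version = 2L), tmp)
  unname(tools::md5sum(tmp))
}

# Evaluate `expr` under a temporary RNG seed, restoring the global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Deterministic per-stage seed derived from one pipeline seed. Offsets are
# fixed per stage name; results stay below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, autoencoder = 211L, alignnet = 307L,
               diffusion = 401L, sampling = 503L, evaluate = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}
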