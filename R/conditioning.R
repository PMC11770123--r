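# Conditioning for the diffusion model.
#
# At inference, the distance tensor of a Raman sub-image is sparsified by a
# two-step top-K rule and turned, per target index k, into a softmax-
# weighted convex combination of the aligned H&E targets. During training,
# the conditioning is simply the K H&E targets of the image's own class.
#
# The mask is applied with additive semantics: surviving entries keep their
# distance as softmax score, masked entries score -Inf and therefore get
# weight exactly 0 — this is the reading under which the mask "filters out
# smaller distance values" (a literal product with -Inf would flip the sign
# of negative distances instead of removing them).

#' Two-step top-K mask over a distance tensor
#'
#' Step 1 keeps, independently for every (class, target) fiber, the
#' `k_patch` largest entries along the patch axis. Step 2 keeps, for every
#' patch, the `k_clstarget` largest surviving entries along the combined
#' (class, target) axis. Ties at the kth value are resolved
#' deterministically toward the lowest index.
#'
#' @param dist distance tensor `[n_classes, n_patches, K]`.
#' @param k_patch number kept along the patch axis (1..n_patches).
#' @param k_clstarget number kept along the combined class/target axis
#'   (1..n_classes*K).
#' @return mask of the same shape with entries `1` (kept) or `-Inf`.
#' @export
compute_mask <- function(dist, k_patch, k_clstarget) {
  dm <- dim(dist)
  stopifnot(length(dm) == 3L)
  n_classes <- dm[1]; n_patches <- dm[2]; K <- dm[3]
  if (k_patch < 1 || k_patch > n_patches) stop("k_patch out of range")
  if (k_clstarget < 1 || k_clstarget > n_classes * K)
    stop("k_clstarget out of range")
  keep1 <- array(FALSE, dm)
  for (cls in seq_len(n_classes)) {
    for (k in seq_len(K)) {
      v <- dist[cls, , k]
      top <- order(-v, seq_along(v))[seq_len(k_patch)]
      keep1[cls, top, k] <- TRUE
    }
  }
  keep2 <- array(FALSE, dm)
  for (i in seq_len(n_patches)) {
    v <- as.vector(dist[, i, ])        # combined (cls, k) axis, cls fastest
    alive <- as.vector(keep1[, i, ])
    v[!alive] <- -Inf
    ord <- order(-v, seq_along(v))
    ord <- ord[alive[ord]][seq_len(min(k_clstarget, sum(alive)))]
    sel <- array(FALSE, c(n_classes, K))
    sel[ord] <- TRUE
    keep2[, i, ] <- sel
  }
  mask <- array(-Inf, dm)
  mask[keep2] <- 1
  mask
}

#' Conditioning vectors from masked distances and aligned H&E targets
#'
#' For every target index k, a softmax over the surviving (class, patch)
#' entries of the distance tensor weights the per-class H&E targets:
#' `cond_k = sum_{cls,i} softmax(dist[cls,i,k]) * Target_HE[cls,k]`. Each
#' `cond_k` is therefore a convex combination of the H&E targets of index k
#' across classes; masked entries contribute exactly zero weight.
#'
#' @param dist distance tensor `[n_classes, n_patches, K]`.
#' @param mask mask from [compute_mask()] (same shape, 1 / -Inf).
#' @param he_targets H&E targets `[n_classes, K, d]`.
#' @param lambda optional nonnegative temperature applied to the distances
#'   before the softmax; `NULL` (default) uses the raw distances.
#' @return list with `cond` (`[K, d]`) and `weights`
#'   (`[n_classes, n_patches, K]`, summing to 1 over (cls, i) for each k).
#' @export
synthesize_conditioning <- function(dist, mask, he_targets, lambda = NULL) {
  dm <- dim(dist)
  stopifnot(identical(dim(mask), dm), dim(he_targets)[1] == dm[1],
            dim(he_targets)[2] == dm[3])
  n_classes <- dm[1]; K <- dm[3]; d <- dim(he_targets)[3]
  score <- ifelse(mask == 1, dist, -Inf)
  if (!is.null(lambda)) {
    if (lambda < 0) stop("lambda must be nonnegative")
    score <- ifelse(is.finite(score), lambda * score, score)
  }
  cond <- matrix(0, K, d)
  weights <- array(0, dm)
  for (k in seq_len(K)) {
    s <- score[, , k, drop = FALSE]
    if (!any(is.finite(s)))
      stop("no surviving entries for target index k = ", k)
    m <- max(s[is.finite(s)])
    e <- ifelse(is.finite(s), exp(s - m), 0)
    wk <- e / sum(e)
    weights[, , k] <- wk
    cls_w <- apply(array(wk, dm[1:2]), 1L, sum)     # weight mass per class
    cond[k, ] <- colSums(matrix(he_targets[, k, ], n_classes, d) * cls_w)
  }
  list(cond = cond, weights = weights)
}

#' Training-time conditioning: the labeled class's H&E targets
#'
#' @param class_label class name or index.
#' @param he_targets H&E targets `[n_classes, K, d]`.
#' @param classes class names used when `class_label` is character.
#' @return matrix `[K, d]`, the K targets of the class in order.
#' @export
conditioning_for_training <- function(class_label, he_targets,
                                      classes = PHANTOM_CLASSES) {
  cls <- if (is.character(class_label)) match(class_label, classes)
         else as.integer(class_label)
  if (is.na(cls) || cls < 1 || cls > dim(he_targets)[1])
    stop("unknown class: ", class_label)
  matrix(he_targets[cls, , ], dim(he_targets)[2], dim(he_targets)[3])
}
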