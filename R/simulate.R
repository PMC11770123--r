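# Synthetic co-registered phantom data.
#
# Each phantom is a pair (RGB "H&E-like" image, hyperspectral "Raman-like"
# cube) drawn on a shared canvas so that the same planted texture elements
# are visible in both modalities: class identity is encoded in RGB texture
# (irregular high-chroma blobs and ring structures for the carcinoma class,
# parallel striations with peripheral dots for normal muscle) and in the
# per-class spectral band signature of the cube. The vocabulary echoes the
# histology it stands in for (pleomorphic cells and keratin pearls versus
# striated fibers) without claiming visual realism.

PHANTOM_CLASSES <- c("TSCC", "normal")

#' Per-class mean spectral signature
#'
#' Smooth mixture-of-Gaussian band profiles over the configured number of
#' bands; the two classes peak in disjoint spectral regions.
#'
#' @param class_label `"TSCC"` or `"normal"`.
#' @param bands number of spectral bands.
#' @return numeric vector of length `bands`, values in (0, 0.7].
#' @export
class_signature <- function(class_label, bands) {
  class_label <- match.arg(class_label, PHANTOM_CLASSES)
  x <- seq(0, 1, length.out = bands)
  bump <- function(mu, s, a) a * exp(-0.5 * ((x - mu) / s)^2)
  base <- 0.08
  if (class_label == "TSCC") {
    base + bump(0.18, 0.05, 0.5) + bump(0.52, 0.04, 0.35) + bump(0.85, 0.06, 0.45)
  } else {
    base + bump(0.32, 0.05, 0.5) + bump(0.68, 0.04, 0.4) + bump(0.95, 0.05, 0.3)
  }
}

#' Specification of one synthetic phantom
#'
#' @param class_label tissue class, `"TSCC"` or `"normal"`.
#' @param canvas_um canvas width and height in micrometers (>= 8).
#' @param n_texture_elements number of planted texture elements.
#' @param bands number of spectral bands in the cube.
#' @param spectral_signature per-class mean band profile (length `bands`);
#'   defaults to [class_signature()].
#' @param noise_sd standard deviation of additive Gaussian noise applied to
#'   both modalities (>= 0).
#' @param um_per_px physical sampling, micrometers per pixel.
#' @param rng_seed integer seed making the phantom deterministic.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(class_label, canvas_um = c(32, 32),
                         n_texture_elements = 6L, bands = 64L,
                         spectral_signature = NULL, noise_sd = 0.02,
                         um_per_px = 1, rng_seed = 1L) {
  class_label <- match.arg(class_label, PHANTOM_CLASSES)
  if (any(canvas_um < 8)) stop("canvas dimensions must be at least 8 um")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (bands < 1) stop("band count must be positive")
  if (is.null(spectral_signature)) spectral_signature <- class_signature(class_label, bands)
  if (length(spectral_signature) != bands)
    stop("spectral_signature length (", length(spectral_signature),
         ") does not match band count (", bands, ")")
  structure(list(class_label = class_label, canvas_um = canvas_um,
                 n_texture_elements = as.integer(n_texture_elements),
                 bands = as.integer(bands),
                 spectral_signature = spectral_signature,
                 noise_sd = noise_sd, um_per_px = um_per_px,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Pixel-coordinate grids for a canvas (row = y, col = x).
.grid_xy <- function(H, W) {
  list(y = matrix(seq_len(H), H, W), x = matrix(seq_len(W), H, W, byrow = TRUE))
}

.ellipse_mask <- function(g, cx, cy, rx, ry, theta) {
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

.ring_mask <- function(g, cx, cy, r, width) {
  d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  abs(d - r) <= width / 2
}

.stripe_mask <- function(g, offset, slope, thickness) {
  abs(g$y - (offset + slope * g$x)) <= thickness / 2
}

#' Generate one co-registered phantom sample
#'
#' Draws the RGB image and the hyperspectral cube from the same latent
#' element placement, so masking either modality by the planted element
#' locations selects identical pixel sets.
#'
#' @param spec a [phantom_spec()].
#' @return list with `rgb` (`[3, H, W]`, values in `[0, 1]`), `cube`
#'   (`[bands, H, W]`), `label`, `element_mask` (`[H, W]` logical) and the
#'   generating `spec`. The cube carries a `wavenumbers` attribute.
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  W <- as.integer(round(spec$canvas_um[1] / spec$um_per_px))
  H <- as.integer(round(spec$canvas_um[2] / spec$um_per_px))
  with_seed(spec$rng_seed, {
    g <- .grid_xy(H, W)
    tscc <- spec$class_label == "TSCC"
    bg_col <- if (tscc) c(0.93, 0.80, 0.89) else c(0.96, 0.84, 0.86)
    el_cols <- if (tscc) list(c(0.45, 0.18, 0.55), c(0.60, 0.30, 0.62))
               else list(c(0.82, 0.42, 0.52), c(0.30, 0.18, 0.40))
    mask_all <- matrix(FALSE, H, W)
    rgb <- array(0, c(3, H, W))
    for (ch in 1:3) rgb[ch, , ] <- bg_col[ch]
    n_el <- spec$n_texture_elements
    slope <- stats::runif(1, -0.25, 0.25)  # shared orientation of striations
    el_col_of <- vector("list", n_el)
    masks <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      if (tscc) {
        if (e %% 2L == 1L) {  # pleomorphic blob
          m <- .ellipse_mask(g, stats::runif(1, 3, W - 2), stats::runif(1, 3, H - 2),
                             stats::runif(1, 1.5, 4.5), stats::runif(1, 1.5, 4.5),
                             stats::runif(1, 0, pi))
          cl <- el_cols[[1]]
        } else {              # pearl-like ring
          m <- .ring_mask(g, stats::runif(1, 4, W - 3), stats::runif(1, 4, H - 3),
                          stats::runif(1, 2.5, 5), 1.6)
          cl <- el_cols[[2]]
        }
      } else {
        if (e %% 2L == 1L) {  # parallel fiber striation
          m <- .stripe_mask(g, stats::runif(1, 2, H - 2), slope, 1.6)
          cl <- el_cols[[1]]
        } else {              # peripheral nucleus-like dot
          side <- sample(4L, 1L)
          cx <- switch(side, stats::runif(1, 2, 4), stats::runif(1, W - 4, W - 1),
                       stats::runif(1, 2, W - 1), stats::runif(1, 2, W - 1))
          cy <- switch(side, stats::runif(1, 2, H - 1), stats::runif(1, 2, H - 1),
                       stats::runif(1, 2, 4), stats::runif(1, H - 4, H - 1))
          m <- .ellipse_mask(g, cx, cy, 1.4, 1.4, 0)
          cl <- el_cols[[2]]
        }
      }
      masks[[e]] <- m
      el_col_of[[e]] <- cl
      mask_all <- mask_all | m
    }
    for (e in seq_len(n_el)) {
      m <- masks[[e]]
      for (ch in 1:3) {
        plane <- rgb[ch, , ]
        plane[m] <- el_col_of[[e]][ch]
        rgb[ch, , ] <- plane
      }
    }
    # Cube: background spectrum = class signature; planted elements carry an
    # amplified copy of the signature (same placement as the RGB elements).
    sig <- spec$spectral_signature
    cube <- array(sig, c(spec$bands, H, W))
    gain <- matrix(1, H, W)
    gain[mask_all] <- 1.45
    cube <- cube * rep(as.vector(gain), each = spec$bands)
    if (spec$noise_sd > 0) {
      rgb <- rgb + array(stats::rnorm(length(rgb), sd = spec$noise_sd), dim(rgb))
      cube <- cube + array(stats::rnorm(length(cube), sd = spec$noise_sd), dim(cube))
      rgb <- pmin(pmax(rgb, 0), 1)
      cube <- pmin(pmax(cube, 0), 1)
    }
    attr(cube, "wavenumbers") <- seq(600, 3100, length.out = spec$bands)
    attr(cube, "um_per_px") <- rep(spec$um_per_px, 2L)
    list(rgb = rgb, cube = cube, label = spec$class_label,
         element_mask = mask_all, spec = spec)
  })
}

# Allocate per-split counts from fractions; remainders go to the splits with
# the largest fractional part (ties broken by split order).
split_counts <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(fractions))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  if (any(fractions > 0 & base == 0))
    stop("n_per_class too small for the requested split fractions")
  as.integer(base)
}

#' Generate and write a synthetic dataset
#'
#' Writes one RGB PNG, one multi-page TIFF cube with a JSON sidecar per
#' sample, and a JSON manifest. Samples are split at the sample (patient)
#' level, so the train/val/test sets are disjoint by `sample_id`.
#'
#' @param n_per_class samples per class.
#' @param split_fractions train/val/test fractions summing to 1.
#' @param out_dir output directory (created if missing).
#' @param rng_seed integer seed; the whole dataset is reproducible from it.
#' @param ... further arguments forwarded to [phantom_spec()]
#'   (`canvas_um`, `bands`, `noise_sd`, `n_texture_elements`, ...).
#' @return the manifest (invisibly written to `manifest.json`).
#' @export
generate_dataset <- function(n_per_class, split_fractions = c(0.8, 0.1, 0.1),
                             out_dir = tempfile("phantoms"), rng_seed = 1L, ...) {
  counts <- split_counts(n_per_class, split_fractions)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  splits <- rep(c("train", "val", "test"), counts)
  records <- list()
  for (cls in PHANTOM_CLASSES) {
    for (i in seq_len(n_per_class)) {
      sid <- sprintf("%s_%02d", tolower(cls), i)
      seed_i <- (as.integer(rng_seed) %% 100000L) * 10000L +
        1000L * (match(cls, PHANTOM_CLASSES) - 1L) + i
      sp <- phantom_spec(cls, rng_seed = seed_i, ...)
      smp <- generate_sample(sp)
      rgb_path <- file.path(out_dir, paste0(sid, "_he.png"))
      cube_path <- file.path(out_dir, paste0(sid, "_raman.tiff"))
      write_rgb_image(smp$rgb, rgb_path)
      write_cube(smp$cube, cube_path)
      records[[length(records) + 1L]] <- list(
        sample_id = sid, class_label = cls,
        rgb_path = rgb_path, cube_path = cube_path,
        split = splits[i], um_per_px = sp$um_per_px)
    }
  }
  manifest <- list(records = do.call(rbind, lapply(records, function(r)
    data.frame(r, stringsAsFactors = FALSE))),
    rng_seed = as.integer(rng_seed))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}
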