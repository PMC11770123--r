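# Physical-resolution resizing and unfold-style sub-image extraction.
#
# Conventions, used everywhere: coordinates are 0-based, windows are
# half-open `[off, off + window)`, tiles are enumerated row-major (the
# height offset varies slowest), and the tile count per axis uses floor
# semantics: floor((extent - window) / stride) + 1, i.e. any remainder at
# the far edge is dropped.

#' Tile grid specification
#'
#' @param window window height and width in pixels (length-2 or scalar).
#' @param stride stride per axis in pixels (length-2 or scalar, >= 1).
#' @return a `tile_grid` list.
#' @export
tile_grid <- function(window, stride = window) {
  window <- as.integer(rep(window, length.out = 2L))
  stride <- as.integer(rep(stride, length.out = 2L))
  if (any(window < 1L)) stop("window must be positive")
  if (any(stride < 1L)) stop("stride must be at least 1")
  structure(list(window = window, stride = stride), class = "tile_grid")
}

#' Number of tiles per axis and in total
#'
#' @param extent image extent `(H, W)` in pixels.
#' @param grid a [tile_grid()].
#' @return list with `per_axis` (length 2) and `total`.
#' @export
tile_counts <- function(extent, grid) {
  extent <- as.integer(rep(extent, length.out = 2L))
  if (any(grid$window > extent)) stop("window exceeds image extent")
  per_axis <- (extent - grid$window) %/% grid$stride + 1L
  list(per_axis = per_axis, total = as.integer(prod(per_axis)))
}

#' Resize an RGB image to an explicit physical target shape
#'
#' Bilinear interpolation with antialiasing, used to bring all H&E images to
#' the common sampling of 1 pixel per square micrometer before tiling. The
#' per-axis targets are explicit because source scans may need different
#' factors per axis.
#'
#' @param image array `[3, H, W]`.
#' @param target_shape integer `(H, W)` target extents (>= 1).
#' @return array `[3, target H, target W]`.
#' @export
resize_to_physical <- function(image, target_shape) {
  stopifnot(length(dim(image)) == 3L)
  target_shape <- as.integer(target_shape)
  if (any(target_shape < 1L)) stop("target dimensions must be positive")
  dm <- dim(image)
  if (all(dm[2:3] == target_shape)) return(image)
  img <- aperm(image, c(2, 3, 1))  # [H, W, C] for EBImage
  out <- EBImage::resize(EBImage::Image(img, colormode = "Color"),
                         w = target_shape[1], h = target_shape[2],
                         filter = "bilinear", antialias = TRUE)
  aperm(EBImage::imageData(out), c(3, 1, 2))
}

#' Extract sub-images with an unfold-like sliding window
#'
#' @param image array `[C, H, W]`.
#' @param grid a [tile_grid()] valid for the image.
#' @return list of `[C, wh, ww]` arrays in row-major window order; each
#'   element carries an `offset` attribute (0-based `(y, x)`).
#' @export
extract_subimages <- function(image, grid) {
  dm <- dim(image)
  stopifnot(length(dm) == 3L)
  tc <- tile_counts(dm[2:3], grid)
  wh <- grid$window[1]; ww <- grid$window[2]
  out <- vector("list", tc$total)
  n <- 0L
  for (oy in seq_len(tc$per_axis[1]) - 1L) {
    y0 <- oy * grid$stride[1]
    for (ox in seq_len(tc$per_axis[2]) - 1L) {
      x0 <- ox * grid$stride[2]
      tile <- image[, y0 + seq_len(wh), x0 + seq_len(ww), drop = FALSE]
      attr(tile, "offset") <- c(y0, x0)
      n <- n + 1L
      out[[n]] <- tile
    }
  }
  out
}

#' Extract Raman sub-cubes (one per scanned region)
#'
#' A scanned region maps to exactly one sub-cube; the only spatial change is
#' a crop of the last spatial axis to `target_last` lines. The crop is
#' centered by default (for 50 -> 48 it drops the first and last line); an
#' explicit `offset` (0-based) overrides the centering.
#'
#' @param cube array `[bands, X, Y]`.
#' @param target_last desired extent of the last spatial axis.
#' @param offset optional 0-based crop offset into the last axis.
#' @return list with one `[bands, X, target_last]` sub-cube.
#' @export
extract_raman_subimages <- function(cube, target_last = dim(cube)[3],
                                    offset = NULL) {
  dm <- dim(cube)
  stopifnot(length(dm) == 3L)
  target_last <- as.integer(target_last)
  if (target_last > dm[3]) stop("window exceeds cube extent")
  if (is.null(offset)) offset <- (dm[3] - target_last) %/% 2L
  if (offset < 0L || offset + target_last > dm[3]) stop("invalid crop offset")
  sub <- cube[, , offset + seq_len(target_last), drop = FALSE]
  list(sub)
}

#' Spatial shape after the encoder's downsampling stack
#'
#' Each stride-2 convolution (kernel 3, padding 1) maps an extent `e` to
#' `ceiling(e / 2)`; the channel count becomes the configured latent width.
#'
#' @param in_shape input shape `(channels, H, W)`.
#' @param n_down number of downsampling blocks.
#' @param width latent channel width.
#' @return integer shape `(width, H', W')`.
#' @export
encoder_output_shape <- function(in_shape, n_down = 2L, width = 64L) {
  sp <- as.integer(in_shape[2:3])
  for (i in seq_len(n_down)) sp <- (sp + 1L) %/% 2L
  c(as.integer(width), sp)
}

#' Number of non-overlapping patches of a feature map
#'
#' @param feat_shape feature-map shape `(C, H, W)`.
#' @param patch patch extent per axis (scalar or length 2).
#' @return list with `n_patches` and the flattened dimension `d`.
#' @export
patch_count <- function(feat_shape, patch = 4L) {
  patch <- as.integer(rep(patch, length.out = 2L))
  sp <- as.integer(feat_shape[2:3])
  if (any(sp %% patch != 0L))
    stop("spatial extents must be divisible by the patch size")
  list(n_patches = as.integer(prod(sp %/% patch)),
       d = as.integer(as.integer(feat_shape[1]) * prod(patch)))
}

# Reassemble non-overlapping tiles (stride == window) into the cropped
# image; inverse of extract_subimages for that case.
reassemble_tiles <- function(tiles, per_axis, window) {
  C <- dim(tiles[[1]])[1]
  out <- array(0, c(C, per_axis[1] * window[1], per_axis[2] * window[2]))
  n <- 0L
  for (oy in seq_len(per_axis[1]) - 1L) {
    for (ox in seq_len(per_axis[2]) - 1L) {
      n <- n + 1L
      out[, oy * window[1] + seq_len(window[1]),
          ox * window[2] + seq_len(window[2])] <- tiles[[n]]
    }
  }
  out
}
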