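# Reading and writing the pipeline's on-disk formats:
#  - RGB images as PNG (or TIFF), arrays [3, H, W] in [0, 1];
#  - hyperspectral cubes as multi-page TIFF (one 32-bit float page per band)
#    with a JSON sidecar carrying the wavenumber axis and sampling;
#  - dataset manifests and run reports as JSON.

#' Write an RGB image
#'
#' @param rgb array `[3, H, W]`, values in `[0, 1]`.
#' @param path output path ending in `.png` or `.tif(f)`.
#' @export
write_rgb_image <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[1] == 3L)
  img <- aperm(pmin(pmax(rgb, 0), 1), c(2, 3, 1))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Read an RGB image into `[3, H, W]`
#' @param path a PNG or TIFF file.
#' @export
read_rgb_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  aperm(img, c(3, 1, 2))
}

#' Write a hyperspectral cube as multi-page TIFF + JSON sidecar
#'
#' One float page per band; the sidecar `<path>.json` stores the wavenumber
#' axis and micrometers-per-pixel so the container stays self-describing.
#'
#' @param cube array `[bands, H, W]`; `wavenumbers` / `um_per_px` attributes
#'   are used when the explicit arguments are `NULL`.
#' @param path output `.tiff` path.
#' @param wavenumbers,um_per_px metadata for the sidecar.
#' @export
write_cube <- function(cube, path, wavenumbers = NULL, um_per_px = NULL) {
  stopifnot(length(dim(cube)) == 3L)
  if (is.null(wavenumbers)) wavenumbers <- attr(cube, "wavenumbers")
  if (is.null(um_per_px)) um_per_px <- attr(cube, "um_per_px")
  if (is.null(wavenumbers)) wavenumbers <- seq(600, 3100, length.out = dim(cube)[1])
  if (is.null(um_per_px)) um_per_px <- c(1, 1)
  pages <- lapply(seq_len(dim(cube)[1]), function(b) cube[b, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(wavenumbers = wavenumbers, um_per_px = um_per_px),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF cube written by [write_cube()]
#' @param path the `.tiff` path; the `<path>.json` sidecar is read if present.
#' @return array `[bands, H, W]` with `wavenumbers` and `um_per_px` attributes.
#' @export
read_cube <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  cube <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (b in seq_along(pages)) cube[b, , ] <- pages[[b]]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(cube, "wavenumbers") <- meta$wavenumbers
    attr(cube, "um_per_px") <- meta$um_per_px
  }
  cube
}

#' Write / read a dataset manifest
#'
#' @param manifest list with a `records` data frame (sample_id, class_label,
#'   rgb_path, cube_path, split, um_per_px).
#' @param path JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$records <- as.data.frame(m$records, stringsAsFactors = FALSE)
  m
}

# Checkpoint helpers: a checkpoint is a named list of parameter arrays plus
# the building configuration, stored as a single RDS file.
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

load_checkpoint <- function(path) readRDS(path)
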