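#' Read an image tile from disk
#'
#' Reads PNG, TIFF or JPEG into an [rgb_image()]. The white level `i0` is
#' inferred from the file's bit depth (255 for 8-bit, 65535 for 16-bit)
#' unless overridden. Grayscale input is replicated to three channels and an
#' alpha channel is dropped, each with a warning.
#'
#' @param path file path; format chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @param i0 optional white-level override.
#' @return An [rgb_image()].
#' @export
read_tile <- function(path, i0 = NULL) {
  if (!file.exists(path)) stop("cannot read tile: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    bits <- png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path)
    info <- tiff::readTIFF(path, payload = FALSE)
    bits <- info$bits.per.sample[1]
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("package 'jpeg' is required for JPEG tiles", call. = FALSE)
    raw <- jpeg::readJPEG(path)
    bits <- 8L
  } else stop("unsupported tile format: .", ext, call. = FALSE)

  white <- if (is.null(i0)) {
    # float TIFFs carry densities/OD in [0,1]-ish; treat stored scale directly
    if (bits >= 16) 65535 else 255
  } else i0
  if (length(dim(raw)) == 2L) {
    warning("grayscale tile replicated to 3 channels")
    raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  } else if (dim(raw)[3] == 4L) {
    warning("alpha channel dropped")
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (dim(raw)[3] == 2L) {
    warning("gray+alpha tile: alpha dropped, gray replicated to 3 channels")
    raw <- array(rep(raw[, , 1], 3L), c(dim(raw)[1:2], 3L))
  }
  # codecs return [0, 1]; rescale to counts
  rgb_image(round(raw * white), i0 = white)
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  as.integer(hdr[25])  # IHDR bit-depth byte
}

#' Write an image tile to disk
#'
#' PNG and TIFF are lossless; JPEG is provided for convenience only.
#'
#' @param img an [rgb_image()].
#' @param path output path; format chosen by extension.
#' @export
write_tile <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- img$pixels / img$i0
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = if (img$i0 > 255) 16L else 8L)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("package 'jpeg' is required for JPEG tiles", call. = FALSE)
    jpeg::writeJPEG(norm, path, quality = 0.95)
  } else stop("unsupported tile format: .", ext, call. = FALSE)
  invisible(path)
}

# TIFF float samples are only well-defined in [0, 1]; densities are mapped
# through a fixed affine transfer function covering OD values in [-2, 8].
DENSITY_TIFF_OFFSET <- 2
DENSITY_TIFF_SCALE <- 10

#' Export one stain's density map as a 32-bit float TIFF
#'
#' Densities (optical-density units, possibly slightly negative from
#' estimation noise) are mapped through the fixed affine transfer function
#' `(x + 2) / 10` into the TIFF float range and inverted by
#' [read_density_tiff()], so any density in `[-2, 8]` round trips within
#' 32-bit float precision.
#'
#' @param nmaps a [density_maps()] object.
#' @param stain_index row of the density matrix to export (1 = first stain).
#' @param path output `.tif` path.
#' @export
write_density_tiff <- function(nmaps, stain_index, path) {
  stopifnot(inherits(nmaps, "density_maps"))
  plane <- unflatten_plane(nmaps$n[stain_index, ], nmaps$shape)
  enc <- (plane + DENSITY_TIFF_OFFSET) / DENSITY_TIFF_SCALE
  if (min(enc) < 0 || max(enc) > 1) {
    warning("densities outside [-2, 8] clipped in TIFF export")
    enc <- pmin(pmax(enc, 0), 1)
  }
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a float-TIFF density map back as a matrix
#' @param path `.tif` path written by [write_density_tiff()].
#' @return numeric matrix (tile-shaped density plane, OD units).
#' @export
read_density_tiff <- function(path) {
  tiff::readTIFF(path) * DENSITY_TIFF_SCALE - DENSITY_TIFF_OFFSET
}
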