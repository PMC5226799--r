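#' RGB tile container
#'
#' Wraps an `H x W x 3` array of transmitted-light intensities together with
#' the incident-light intensity `i0`. Intensities are dimensionless counts in
#' `[0, i0]`; for an 8-bit scanner `i0 = 255`, for 16-bit `i0 = 65535`.
#'
#' @param pixels numeric `H x W x 3` array, values in `[0, i0]`.
#' @param i0 incident-light intensity (white level), a positive scalar.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, i0 = 255) {
  if (!is.numeric(i0) || length(i0) != 1L || !is.finite(i0) || i0 <= 0)
    stop("`i0` must be a positive finite scalar", call. = FALSE)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array (RGB)", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > i0)
    stop("pixel values must be finite and lie in [0, i0]", call. = FALSE)
  structure(list(pixels = pixels, i0 = i0), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d, i0 = %g, range [%.1f, %.1f]\n",
              d[1], d[2], x$i0, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Optical-density image container
#'
#' A `3 x P` matrix of optical densities (rows = red, green, blue channels;
#' columns = pixels in row-major scan order, i.e. pixel `p` sits at row
#' `(p - 1) %/% W + 1`, column `(p - 1) %% W + 1` of the tile) plus the
#' original `(H, W)` shape so density maps can be reshaped deterministically.
#'
#' @param d numeric `3 x P` matrix of non-negative optical densities.
#' @param shape integer vector `c(H, W)` with `H * W == P`.
#' @return An object of class `od_image`.
#' @export
od_image <- function(d, shape) {
  if (!is.matrix(d) || nrow(d) != 3L)
    stop("`d` must be a 3 x P matrix", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 2L || prod(shape) != ncol(d))
    stop("`shape` must be c(H, W) with H * W == ncol(d)", call. = FALSE)
  if (anyNA(d) || any(!is.finite(d)) || min(d) < 0)
    stop("optical densities must be finite and >= 0", call. = FALSE)
  rownames(d) <- c("r", "g", "b")
  structure(list(d = d, shape = shape), class = "od_image")
}

#' @export
print.od_image <- function(x, ...) {
  cat(sprintf("<od_image> 3 x %d (tile %d x %d), OD range [%.3f, %.3f]\n",
              ncol(x$d), x$shape[1], x$shape[2], min(x$d), max(x$d)))
  invisible(x)
}

# row-major flatten / unflatten of one channel plane
flatten_plane <- function(plane) as.vector(t(plane))
unflatten_plane <- function(v, shape) matrix(v, nrow = shape[1], byrow = TRUE)

#' Convert transmitted-light RGB to optical density
#'
#' Applies the Beer-Lambert relation `D = -log(I / i0)` (natural log) per
#' channel. Stain mixing is linear in this space: `D = M N` for stain matrix
#' `M` and density maps `N`. Intensities are clamped below at `eps` counts so
#' saturated-black pixels map to a large finite density rather than `Inf`.
#'
#' @param img an [rgb_image()].
#' @param eps clamp floor in counts (default 1, the smallest resolvable
#'   intensity step of an integer sensor).
#' @return An [od_image()] with the tile shape retained.
#' @export
rgb_to_od <- function(img, eps = 1) {
  stopifnot(inherits(img, "rgb_image"))
  d <- rbind(
    flatten_plane(img$pixels[, , 1]),
    flatten_plane(img$pixels[, , 2]),
    flatten_plane(img$pixels[, , 3])
  )
  d <- -log(pmin(pmax(d, eps), img$i0) / img$i0)
  od_image(d, dim(img$pixels)[1:2])
}

#' Convert optical density back to transmitted-light RGB
#'
#' Inverts [rgb_to_od()]: `I = i0 * exp(-D)`, clipped to `[0, i0]`. Negative
#' densities (brighter than the incident light, which is unphysical) are
#' clipped to zero with a warning.
#'
#' @param od an [od_image()].
#' @param i0 incident-light intensity for the reconstruction (default 255).
#' @return An [rgb_image()].
#' @export
od_to_rgb <- function(od, i0 = 255) {
  stopifnot(inherits(od, "od_image"))
  d <- od$d
  if (min(d) < 0) {
    warning("negative optical densities clipped to 0 (brighter than incident light)")
    d <- pmax(d, 0)
  }
  inten <- pmin(pmax(i0 * exp(-d), 0), i0)
  h <- od$shape[1]; w <- od$shape[2]
  px <- array(0, c(h, w, 3))
  for (k in 1:3) px[, , k] <- unflatten_plane(inten[k, ], od$shape)
  rgb_image(px, i0 = i0)
}
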