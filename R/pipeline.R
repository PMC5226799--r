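#' Deconvolve a histology tile end to end
#'
#' The full method: convert the tile to optical density, decompose each
#' channel into decimated wavelet sub-bands, keep the `n_subbands` least
#' Gaussian composed bands (largest absolute excess kurtosis), estimate the
#' stain mixing matrix by fixed-point ICA on the concatenated bands, and
#' invert it on the raw OD image to recover per-stain density maps.
#'
#' @param x an [rgb_image()], a `phantom`, or a file path readable by
#'   [read_tile()].
#' @param wavelet wavelet name (default `"db2"`).
#' @param levels decomposition depth (default 5).
#' @param n_subbands number of sub-bands kept (default 20 = all at depth 5).
#' @param seed ICA seed (deterministic result per seed).
#' @param i0 white-level override for file input.
#' @param matrix optional precomputed [stain_matrix()]; skips estimation and
#'   only deconvolves.
#' @return Object of class `stain_fit`: list with `stain_matrix`,
#'   `densities`, `od`, `subbands` (kurtosis ranking tibble), `selected`
#'   (selection order tibble) and the call parameters. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
stain_deconvolve <- function(x, wavelet = "db2", levels = 5, n_subbands = 20,
                             seed = 0, i0 = NULL, matrix = NULL) {
  img <- if (is.character(x)) read_tile(x, i0 = i0)
         else if (inherits(x, "phantom")) x$image
         else x
  stopifnot(inherits(img, "rgb_image"))
  od <- rgb_to_od(img)
  stack <- decompose(od, wavelet = wavelet, levels = levels)
  obs <- select_subbands(stack, n = min(n_subbands, length(stack$bands)))
  m <- if (is.null(matrix)) {
    estimate_mixing_matrix(obs, seed = seed)
  } else {
    stopifnot(inherits(matrix, "stain_matrix"))
    matrix
  }
  nmaps <- deconvolve(od, m)
  structure(list(
    stain_matrix = m,
    densities = nmaps,
    od = od,
    subbands = kurtosis_table(stack),
    selected = obs$selected_ids,
    params = list(wavelet = wavelet, levels = stack$levels,
                  n_subbands = nrow(obs$selected_ids), seed = seed,
                  estimated = is.null(matrix))
  ), class = "stain_fit")
}

#' @export
print.stain_fit <- function(x, ...) {
  cat(sprintf("<stain_fit> %d x %d tile, %s wavelet, %d/%d sub-bands, seed %d\n",
              x$od$shape[1], x$od$shape[2], x$params$wavelet,
              x$params$n_subbands, nrow(x$subbands), x$params$seed))
  print(x$stain_matrix)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the estimated stain vectors
#'
#' @param x a `stain_fit`.
#' @param ... unused.
#' @return tibble with one row per component: `stain`, `r`, `g`, `b` (the
#'   unit OD stain vector).
#' @export
tidy.stain_fit <- function(x, ...) {
  m <- x$stain_matrix$m
  tibble::tibble(stain = colnames(m), r = m[1, ], g = m[2, ], b = m[3, ])
}

#' One-row summary of a stain deconvolution fit
#'
#' @param x a `stain_fit`.
#' @param ... unused.
#' @return tibble: pixels, sub-bands used, total selected coefficients,
#'   ICA iterations/convergence (NA when a precomputed matrix was applied),
#'   condition number of the stain matrix.
#' @export
glance.stain_fit <- function(x, ...) {
  it <- attr(x$stain_matrix, "ica_iterations")
  cv <- attr(x$stain_matrix, "ica_converged")
  tibble::tibble(
    n_pixels = ncol(x$od$d),
    n_subbands = x$params$n_subbands,
    n_coefficients = sum(x$subbands$n_coef[!is.na(x$subbands$rank) &
                                           x$subbands$rank <= x$params$n_subbands]),
    ica_iterations = if (is.null(it)) NA_integer_ else it,
    ica_converged = if (is.null(cv)) NA else cv,
    condition_number = x$stain_matrix$condition
  )
}

#' Sub-band count sweep on a set of phantoms
#'
#' Re-estimates the stain matrix for each phantom at several sub-band counts
#' (reusing one wavelet decomposition per phantom) and measures the angular
#' error and Euclidean distance of the recovered H and E vectors against the
#' phantom's true matrix.
#'
#' @param phantoms list of `phantom` objects (or a single one).
#' @param n_values sub-band counts to test (default `c(5, 10, 15, 20)`).
#' @param wavelet,levels,seed passed to the decomposition / ICA.
#' @return tibble with columns `n_subbands`, `seed`, `stain`, `angle_deg`,
#'   `distance`.
#' @export
subband_sweep <- function(phantoms, n_values = c(5, 10, 15, 20),
                          wavelet = "db2", levels = 5, seed = 0) {
  if (inherits(phantoms, "phantom")) phantoms <- list(phantoms)
  rows <- list()
  for (ph in phantoms) {
    od <- rgb_to_od(ph$image)
    stack <- decompose(od, wavelet = wavelet, levels = levels)
    for (n in n_values) {
      obs <- select_subbands(stack, n = n)
      m <- estimate_mixing_matrix(obs, seed = seed)
      ang <- stain_angle_errors(m, ph$m_true, match = "angle")
      dst <- stain_vector_distance(m, ph$m_true)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_subbands = n, seed = ph$spec$seed,
        stain = ang$stain, angle_deg = ang$angle_deg, distance = dst$distance
      )
    }
  }
  do.call(rbind, rows)
}

#' Export a fit's stain matrix as a labelled CSV
#'
#' @param fit a `stain_fit` or [stain_matrix()].
#' @param path output CSV path.
#' @export
write_stain_matrix <- function(fit, path) {
  m <- if (inherits(fit, "stain_fit")) fit$stain_matrix else fit
  stopifnot(inherits(m, "stain_matrix"))
  utils::write.csv(format(m$m, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a stain matrix from CSV written by [write_stain_matrix()]
#' @param path CSV path.
#' @return A [stain_matrix()].
#' @export
read_stain_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  m <- as.matrix(df)
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")   # guard against rounding drift
  stain_matrix(m, labels = colnames(df))
}
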