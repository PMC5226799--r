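#' Orthonormal wavelet filter coefficients
#'
#' Returns the scaling (low-pass) and wavelet (high-pass) analysis filters of
#' a compactly supported orthonormal Daubechies wavelet. The high-pass filter
#' is the conjugate quadrature mirror `g[n] = (-1)^n h[L-1-n]`.
#'
#' @param name one of `"haar"` (= `"db1"`), `"db2"`, `"db4"`.
#' @return list with elements `lo` and `hi` (numeric filter taps).
#' @export
wavelet_filter <- function(name = "db2") {
  h <- switch(tolower(name),
    haar = ,
    db1  = c(1, 1) / sqrt(2),
    db2  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4  = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
             -0.027983769416984, -0.187034811718881, 0.030841381835987,
             0.032883011666983, -0.010597401784997),
    stop("unknown wavelet: ", name, call. = FALSE)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(lo = h, hi = g, name = tolower(name))
}

# One analysis step along the ROWS of X (i.e. down each column), with
# periodization: y[k] = sum_m f[m] X[(2k + m) mod N, ], k = 0..N/2-1.
# Odd N is periodized by repeating the last row. With orthonormal CQF filters
# and even N this transform is exactly orthogonal, so energy is conserved.
dwt_step_rows <- function(X, f) {
  N <- nrow(X)
  if (N %% 2L == 1L) { X <- rbind(X, X[N, , drop = FALSE]); N <- N + 1L }
  base <- seq.int(0L, N - 2L, by = 2L)
  Y <- matrix(0, N %/% 2L, ncol(X))
  for (m in seq_along(f)) {
    Y <- Y + f[m] * X[((base + m - 1L) %% N) + 1L, , drop = FALSE]
  }
  Y
}

# Single-level 2-D decimated transform: rows then columns.
# a = lo/lo, h = lo rows & hi cols (horizontal detail), v = hi rows & lo cols
# (vertical detail), o = hi/hi (diagonal).
dwt2_level <- function(X, filt) {
  lo_r <- dwt_step_rows(X, filt$lo)
  hi_r <- dwt_step_rows(X, filt$hi)
  list(
    a = t(dwt_step_rows(t(lo_r), filt$lo)),
    h = t(dwt_step_rows(t(lo_r), filt$hi)),
    v = t(dwt_step_rows(t(hi_r), filt$lo)),
    o = t(dwt_step_rows(t(hi_r), filt$hi))
  )
}

subband_orientations <- c("a", "h", "v", "o")

#' Multi-level sub-band decomposition of an optical-density image
#'
#' Runs a decimated 2-D wavelet cascade on each OD colour channel: at every
#' level the running approximation is split into approximation (`a`),
#' horizontal (`h`), vertical (`v`) and diagonal (`o`) blocks, all four are
#' retained as that level's sub-bands, and the approximation feeds the next
#' level. The three colour channels' coefficients of each (level,
#' orientation) pair are stacked as the rows of one composed 3-channel band,
#' giving `4 * levels` bands (20 at the default depth 5). Each composed band
#' is normalised to pooled zero mean / unit variance (one scalar mean and one
#' scalar s.d. over all `3 * p` coefficients, so the relative scaling between
#' channels — and hence the stain mixing — is untouched) and scored by
#' pooled excess kurtosis as a non-Gaussianity measure.
#'
#' @param od an [od_image()].
#' @param wavelet wavelet name, see [wavelet_filter()] (default `"db2"`).
#' @param levels decomposition depth (default 5). If the tile is too small
#'   for the requested depth it is reduced to the maximum feasible with a
#'   warning.
#' @return A `subband_stack`: list with `bands` (list of normalised `3 x p_l`
#'   matrices), `band_ids` (tibble of level/orientation), `kurtosis` (|K| is
#'   the selection score; signed K stored), `degenerate` (zero-variance
#'   flags), plus `wavelet`, `levels`, `shape`.
#' @export
decompose <- function(od, wavelet = "db2", levels = 5) {
  stopifnot(inherits(od, "od_image"))
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  # deepest level must still hold at least 2 x 2 coefficients
  max_feasible <- floor(log2(min(od$shape))) - 1L
  if (levels > max_feasible) {
    warning(sprintf("tile %d x %d too small for %d levels; using %d",
                    od$shape[1], od$shape[2], levels, max_feasible))
    levels <- as.integer(max_feasible)
  }
  filt <- wavelet_filter(wavelet)

  planes <- lapply(1:3, function(k) unflatten_plane(od$d[k, ], od$shape))
  bands <- vector("list", 4L * levels)
  ids_level <- integer(4L * levels)
  ids_orient <- character(4L * levels)
  i <- 0L
  for (l in seq_len(levels)) {
    dec <- lapply(planes, dwt2_level, filt = filt)
    for (orient in subband_orientations) {
      i <- i + 1L
      bands[[i]] <- do.call(rbind, lapply(dec, function(ch) as.vector(t(ch[[orient]]))))
      ids_level[i] <- l
      ids_orient[i] <- orient
    }
    planes <- lapply(dec, `[[`, "a")
  }

  normed <- lapply(bands, normalise_band)
  degenerate <- vapply(normed, function(b) isTRUE(attr(b, "degenerate")), logical(1))
  kurt <- vapply(seq_along(normed), function(j) {
    if (degenerate[j]) NA_real_ else band_kurtosis(normed[[j]])
  }, numeric(1))

  structure(list(
    bands = normed,
    band_ids = tibble::tibble(level = ids_level, orientation = ids_orient),
    kurtosis = kurt,
    degenerate = degenerate,
    wavelet = filt$name,
    levels = levels,
    shape = od$shape
  ), class = "subband_stack")
}

#' @export
print.subband_stack <- function(x, ...) {
  cat(sprintf("<subband_stack> %d bands (%s, %d levels) on a %d x %d tile\n",
              length(x$bands), x$wavelet, x$levels, x$shape[1], x$shape[2]))
  print(kurtosis_table(x), n = 8)
  invisible(x)
}

#' Kurtosis ranking table of a sub-band stack
#'
#' @param stack a `subband_stack` from [decompose()].
#' @return tibble with one row per composed band: level, orientation,
#'   coefficient count per channel, excess kurtosis `k`, `abs_k`, degenerate
#'   flag and selection rank (1 = least Gaussian; ties broken by level then
#'   orientation a, h, v, o).
#' @export
kurtosis_table <- function(stack) {
  stopifnot(inherits(stack, "subband_stack"))
  p <- vapply(stack$bands, ncol, integer(1))
  tb <- tibble::tibble(
    level = stack$band_ids$level,
    orientation = stack$band_ids$orientation,
    n_coef = p,
    k = stack$kurtosis,
    abs_k = abs(stack$kurtosis),
    degenerate = stack$degenerate
  )
  ord <- band_selection_order(stack)
  tb$rank <- NA_integer_
  tb$rank[ord] <- seq_along(ord)
  tb[order(tb$rank, tb$level, match(tb$orientation, subband_orientations)), ]
}

#' Normalise a composed 3-channel sub-band
#'
#' Subtracts one pooled scalar mean and divides by one pooled scalar standard
#' deviation computed over all `3 * p` coefficients. Pooling is essential:
#' standardising each channel row separately would rescale the rows
#' independently and destroy the mixing matrix the method estimates.
#' Zero-variance bands come back as all zeros with attribute
#' `degenerate = TRUE` so they are never selected.
#'
#' @param band numeric `3 x p` matrix.
#' @return normalised `3 x p` matrix (population variance 1 over the pool).
#' @export
normalise_band <- function(band) {
  stopifnot(is.matrix(band), nrow(band) == 3L, ncol(band) >= 2L)
  mu <- mean(band)
  s2 <- mean((band - mu)^2)
  if (s2 < .Machine$double.eps) {
    out <- band * 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (band - mu) / sqrt(s2)
  attr(out, "degenerate") <- FALSE
  out
}

#' Pooled excess kurtosis of a sub-band
#'
#' Fourth standardised moment minus 3 over all coefficients pooled; zero for
#' a Gaussian, negative for flatter distributions (uniform: -1.2), positive
#' for heavy tails (Laplace: +3). `|K|` is the non-Gaussianity score used to
#' rank sub-bands.
#'
#' @param band numeric matrix or vector of coefficients.
#' @return scalar excess kurtosis.
#' @export
band_kurtosis <- function(band) {
  x <- as.vector(band)
  if (length(x) < 4L) stop("kurtosis undefined for fewer than 4 coefficients", call. = FALSE)
  e1071::kurtosis(x, type = 1)
}

# Selection order: by descending |K| over non-degenerate bands, ties broken
# by level (ascending) then orientation in the fixed order a, h, v, o.
band_selection_order <- function(stack) {
  ok <- which(!stack$degenerate)
  ok[order(-abs(stack$kurtosis[ok]),
           stack$band_ids$level[ok],
           match(stack$band_ids$orientation[ok], subband_orientations))]
}

#' Select the least-Gaussian sub-bands and build the filtered observations
#'
#' Ranks composed bands by `|K|` (descending), takes the top `n`, and
#' concatenates their normalised `3 x p_l` blocks horizontally into the
#' filtered observation matrix `D'` on which the mixing matrix is estimated.
#' Degenerate (zero-variance) bands are excluded before ranking; ties are
#' broken deterministically by level then orientation.
#'
#' @param stack a `subband_stack` from [decompose()].
#' @param n number of bands to keep (default all `4 * levels`). If `n`
#'   exceeds the available non-degenerate bands, all are used with a warning.
#' @return A `filtered_observations`: list with `dprime` (`3 x p`),
#'   `selected_ids` (tibble of level/orientation/kurtosis in selection
#'   order) and `p`.
#' @export
select_subbands <- function(stack, n = length(stack$bands)) {
  stopifnot(inherits(stack, "subband_stack"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  ord <- band_selection_order(stack)
  if (n > length(ord)) {
    warning(sprintf("only %d non-degenerate sub-bands available; using all", length(ord)))
    n <- length(ord)
  }
  keep <- ord[seq_len(n)]
  dprime <- do.call(cbind, stack$bands[keep])
  structure(list(
    dprime = dprime,
    selected_ids = tibble::tibble(
      level = stack$band_ids$level[keep],
      orientation = stack$band_ids$orientation[keep],
      k = stack$kurtosis[keep]
    ),
    p = ncol(dprime)
  ), class = "filtered_observations")
}

#' @export
print.filtered_observations <- function(x, ...) {
  cat(sprintf("<filtered_observations> 3 x %d from %d sub-bands\n",
              x$p, nrow(x$selected_ids)))
  invisible(x)
}
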