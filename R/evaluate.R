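#' Ground-truth stain matrix from annotated pixels
#'
#' Builds a reference stain matrix from pixel annotations chosen by
#' biological structure (nuclei for haematoxylin, cytoplasm for eosin): per
#' stain, the per-channel median of the annotated pixels' optical densities,
#' unit-normalised, becomes that stain's vector. With two annotated stains
#' the residual column is completed as the normalised elementwise absolute
#' value of their cross product — the absolute value keeps the column in the
#' physically admissible non-negative octant (absorption cannot be negative),
#' at the cost of exact orthogonality.
#'
#' @param od an [od_image()].
#' @param annots data frame with columns `stain`, `row`, `col` (1-based tile
#'   coordinates), or a named list of `n x 2` row/col matrices. Exactly the
#'   stains present are used; each must have at least one pixel.
#' @return A [stain_matrix()] with the annotated stains in columns 1-2.
#' @export
ground_truth_stain_matrix <- function(od, annots) {
  stopifnot(inherits(od, "od_image"))
  if (is.data.frame(annots)) {
    stopifnot(all(c("stain", "row", "col") %in% names(annots)))
    annots <- split(annots[c("row", "col")], annots$stain)
    annots <- lapply(annots, as.matrix)
  }
  stains <- names(annots)
  if (length(stains) < 2L) stop("need annotations for at least 2 stains", call. = FALSE)
  h <- od$shape[1]; w <- od$shape[2]
  vecs <- lapply(stains, function(s) {
    xy <- annots[[s]]
    if (is.null(xy) || nrow(xy) == 0L)
      stop("no annotated pixels for stain: ", s, call. = FALSE)
    if (any(xy[, 1] < 1 | xy[, 1] > h | xy[, 2] < 1 | xy[, 2] > w))
      stop("annotation out of bounds for stain: ", s, call. = FALSE)
    p <- (xy[, 1] - 1L) * w + xy[, 2]          # row-major pixel index
    v <- apply(od$d[, p, drop = FALSE], 1, stats::median)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("annotated pixels for stain ", s, " have zero OD", call. = FALSE)
    v / nv
  })
  m <- do.call(cbind, vecs[1:2])
  res <- c(m[2, 1] * m[3, 2] - m[3, 1] * m[2, 2],
           m[3, 1] * m[1, 2] - m[1, 1] * m[3, 2],
           m[1, 1] * m[2, 2] - m[2, 1] * m[1, 2])
  res <- abs(res)                               # OD components are non-negative
  res <- res / sqrt(sum(res^2))
  stain_matrix(cbind(m, res), labels = c(stains[1:2], "residual"))
}

#' Read stain annotations from CSV
#'
#' Expected columns: `tile, stain, row, col` with 0-based pixel coordinates
#' (converted to 1-based on read).
#'
#' @param path CSV path.
#' @return tibble with 1-based `row`/`col`.
#' @export
read_annotations <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("tile", "stain", "row", "col") %in% names(tb)))
  tb$row <- tb$row + 1L
  tb$col <- tb$col + 1L
  tb
}

#' Euclidean distance between matching stain vectors
#'
#' Both matrices' columns are unit-norm, so the distance per stain is the
#' chord length `2 sin(theta / 2)` of the angle between the vectors; it is
#' bounded by 2 and equals 1 at a 60 degree separation.
#'
#' @param m_est,m_gt [stain_matrix()] objects with matching stain order.
#' @return tibble with columns `stain`, `distance`.
#' @export
stain_vector_distance <- function(m_est, m_gt) {
  stopifnot(inherits(m_est, "stain_matrix"), inherits(m_gt, "stain_matrix"))
  tibble::tibble(
    stain = m_gt$labels[1:2],
    distance = unname(sqrt(colSums((m_est$m[, 1:2] - m_gt$m[, 1:2])^2)))
  )
}

#' Pearson correlation between estimated and ground-truth density maps
#'
#' @param n_est,n_gt [density_maps()] of equal shape.
#' @param stains which rows to compare (default the two stains).
#' @param clip clip both maps at zero before correlating (default FALSE:
#'   correlation on the un-clipped densities).
#' @return tibble with `stain`, `r`, `p_value`; zero-variance maps yield NA
#'   with a warning.
#' @export
density_correlation <- function(n_est, n_gt, stains = 1:2, clip = FALSE) {
  stopifnot(inherits(n_est, "density_maps"), inherits(n_gt, "density_maps"))
  if (!all(n_est$shape == n_gt$shape)) stop("density maps differ in shape", call. = FALSE)
  rows <- lapply(stains, function(k) {
    a <- n_est$n[k, ]; b <- n_gt$n[k, ]
    if (clip) { a <- pmax(a, 0); b <- pmax(b, 0) }
    if (stats::var(a) < .Machine$double.eps || stats::var(b) < .Machine$double.eps) {
      warning("zero-variance density map for stain ", k, "; correlation undefined")
      return(tibble::tibble(stain = n_gt$labels[k], r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(a, b)
    tibble::tibble(stain = n_gt$labels[k], r = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Bland-Altman agreement between estimated and ground-truth densities
#'
#' Classic agreement analysis on per-pixel differences (estimate minus
#' truth): bias is the mean difference and the limits of agreement are
#' `bias +/- 1.96 sd`. Pixels are pooled over the requested stains and
#' optionally subsampled (seeded) as one would for a scatter of randomly
#' selected pixels.
#'
#' @param n_est,n_gt [density_maps()] of equal shape.
#' @param stains rows to pool (default both stains).
#' @param n_sample subsample size (default 5000; `Inf` uses every pixel).
#' @param seed subsampling seed.
#' @return Object of class `bland_altman`: list with `bias`, `loa_low`,
#'   `loa_high`, `differences`, `means`, `n`.
#' @export
bland_altman <- function(n_est, n_gt, stains = 1:2, n_sample = 5000, seed = 0) {
  stopifnot(inherits(n_est, "density_maps"), inherits(n_gt, "density_maps"))
  if (!all(n_est$shape == n_gt$shape)) stop("density maps differ in shape", call. = FALSE)
  a <- as.vector(n_est$n[stains, , drop = FALSE])
  b <- as.vector(n_gt$n[stains, , drop = FALSE])
  if (is.finite(n_sample) && n_sample < length(a)) {
    set.seed(seed)
    idx <- sample.int(length(a), n_sample)
    a <- a[idx]; b <- b[idx]
  }
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    bias = bias,
    loa_low = bias - 1.96 * s,
    loa_high = bias + 1.96 * s,
    differences = d,
    means = (a + b) / 2,
    n = length(d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.4f, limits [%.4f, %.4f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Full evaluation report against a ground truth
#'
#' Convenience wrapper combining [stain_vector_distance()],
#' [density_correlation()] and [bland_altman()] for one tile.
#'
#' @param m_est estimated [stain_matrix()].
#' @param n_est estimated [density_maps()].
#' @param m_gt ground-truth [stain_matrix()].
#' @param n_gt ground-truth [density_maps()].
#' @param seed subsampling seed for the Bland-Altman arm.
#' @return tibble with one row per stain: distance, r, p_value, plus
#'   Bland-Altman bias/limits (pooled over stains, repeated per row).
#' @export
evaluation_report <- function(m_est, n_est, m_gt, n_gt, seed = 0) {
  dist <- stain_vector_distance(m_est, m_gt)
  corr <- density_correlation(n_est, n_gt)
  ba <- bland_altman(n_est, n_gt, seed = seed)
  out <- merge(dist, corr, by = "stain", sort = FALSE)
  out$ba_bias <- ba$bias
  out$ba_loa_low <- ba$loa_low
  out$ba_loa_high <- ba$loa_high
  tibble::as_tibble(out)
}
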