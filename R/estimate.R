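#' Stain mixing matrix container
#'
#' A `3 x 3` matrix whose columns are unit-norm, non-negative optical-density
#' stain vectors (RGB rows): column 1 haematoxylin-like, column 2 eosin-like,
#' column 3 the residual/background direction. Under Beer-Lambert the OD
#' image factorises as `D = M N`.
#'
#' @param m numeric `3 x 3` matrix of unit-norm non-negative columns.
#' @param labels column labels (default haematoxylin, eosin, residual).
#' @return Object of class `stain_matrix`.
#' @export
stain_matrix <- function(m, labels = c("haematoxylin", "eosin", "residual")) {
  if (!is.matrix(m) || any(dim(m) != 3L))
    stop("`m` must be a 3 x 3 matrix", call. = FALSE)
  if (anyNA(m) || min(m) < -1e-12)
    stop("stain vectors must have non-negative components", call. = FALSE)
  m <- pmax(m, 0)
  norms <- sqrt(colSums(m^2))
  if (any(norms < 1e-12)) stop("zero stain vector", call. = FALSE)
  if (any(abs(norms - 1) > 1e-8))
    stop("stain vectors must be unit-norm (normalise before constructing)", call. = FALSE)
  kap <- kappa(m, exact = TRUE)
  if (!is.finite(kap)) stop("stain matrix is singular", call. = FALSE)
  if (kap > 1e4)
    warning(sprintf("stain matrix is ill-conditioned (condition number %.3g)", kap))
  dimnames(m) <- list(c("r", "g", "b"), labels)
  structure(list(m = m, labels = labels, condition = kap), class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("<stain_matrix> columns = OD stain vectors\n")
  print(round(x$m, 4))
  invisible(x)
}

#' Reference OD directions used to label ICA components
#'
#' Classical haematoxylin and eosin absorption directions from the colour
#' deconvolution literature, used ONLY to decide which recovered component
#' is called "haematoxylin" and which "eosin" — never in the estimation
#' itself.
#'
#' @return `3 x 2` matrix of unit vectors (columns H, E).
#' @export
stain_references <- function() {
  ref <- cbind(h = c(0.650, 0.704, 0.286), e = c(0.072, 0.990, 0.105))
  sweep(ref, 2, sqrt(colSums(ref^2)), "/")
}

angle_deg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(max(cs, -1), 1)) * 180 / pi
}

#' Resolve ICA sign/scale/permutation ambiguities into a canonical stain matrix
#'
#' ICA recovers mixing columns only up to sign, scale and order. The canon:
#' each column is sign-flipped so its entry sum is non-negative, residual
#' negative entries are clipped to zero, each column is scaled to unit norm,
#' and columns are permuted so that column 1 is the candidate closest in
#' angle to the reference haematoxylin direction and column 2 closest to the
#' reference eosin direction ([stain_references()]); the assignment minimises
#' the total H + E angle over all ordered column pairs, with near-ties broken
#' towards the more blue-weighted column as haematoxylin.
#'
#' @param m_raw invertible `3 x 3` matrix (raw ICA mixing estimate).
#' @return A [stain_matrix()] in (H, E, residual) column order.
#' @export
resolve_ambiguities <- function(m_raw) {
  if (!is.matrix(m_raw) || any(dim(m_raw) != 3L))
    stop("`m_raw` must be 3 x 3", call. = FALSE)
  if (abs(det(m_raw)) < 1e-12) stop("`m_raw` must be invertible", call. = FALSE)
  m <- m_raw
  for (j in 1:3) {
    s <- sum(m[, j])
    if (s < 0) m[, j] <- -m[, j]
  }
  m <- pmax(m, 0)
  norms <- sqrt(colSums(m^2))
  norms[norms < 1e-12] <- 1
  m <- sweep(m, 2, norms, "/")

  ref <- stain_references()
  pairs <- expand.grid(h = 1:3, e = 1:3)
  pairs <- pairs[pairs$h != pairs$e, ]
  total <- apply(pairs, 1, function(pr) {
    angle_deg(m[, pr[1]], ref[, "h"]) + angle_deg(m[, pr[2]], ref[, "e"])
  })
  best <- total <= min(total) + 1e-9
  cand <- pairs[best, , drop = FALSE]
  if (nrow(cand) > 1L) {
    # tie: haematoxylin is the more blue-weighted candidate
    cand <- cand[order(-m[3, cand$h]), , drop = FALSE]
  }
  hi <- cand$h[1]; ei <- cand$e[1]
  ri <- setdiff(1:3, c(hi, ei))
  stain_matrix(m[, c(hi, ei, ri)])
}

# deterministic random orthogonal 3x3 for FastICA restarts
random_rotation <- function(seed, nc = 3L) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))
}

# Fixed-point ICA with the kurtosis contrast. The kurtosis contrast matches
# the non-Gaussianity measure used for sub-band selection and, unlike
# logcosh, is unbiased in the presence of the sub-Gaussian quantisation
# residual of 8-bit tiles.
run_fastica <- function(X, n_components, seed, maxit, tol) {
  for (attempt in 0:2) {
    fit <- suppressWarnings(
      ica::icafast(X, nc = n_components, center = TRUE, maxit = maxit,
                   tol = tol, alg = "par", fun = "kur",
                   Rmat = random_rotation(seed + attempt * 10007L, n_components))
    )
    if (isTRUE(fit$converged)) return(fit)
  }
  stop(sprintf("FastICA did not converge within %d iterations after 3 restarts", maxit),
       call. = FALSE)
}

check_rank <- function(X, n_components, what) {
  rv <- apply(X, 2, stats::var)
  if (any(rv < .Machine$double.eps)) {
    stop(sprintf("channel %s of %s has zero variance; cannot estimate %d components",
                 paste(c("red", "green", "blue")[rv < .Machine$double.eps], collapse = ", "),
                 what, n_components), call. = FALSE)
  }
  r <- qr(scale(X, center = TRUE, scale = FALSE), tol = 1e-10)$rank
  if (r < n_components)
    stop(sprintf("%s is rank-deficient (rank %d < %d components); channels are collinear",
                 what, r, n_components), call. = FALSE)
}

#' Estimate the stain mixing matrix by ICA on filtered observations
#'
#' Runs fixed-point ICA (logcosh contrast, whitening on) on the concatenated
#' least-Gaussian sub-bands `D'`. Because sub-band filtering is linear, the
#' mixing matrix of the filtered observations equals that of the raw OD
#' image, so the recovered mixing columns are the stain vectors. The raw ICA
#' mixing estimate is passed through [resolve_ambiguities()].
#'
#' @param obs a `filtered_observations` from [select_subbands()].
#' @param n_components number of components (default 3: two stains plus a
#'   residual/background direction).
#' @param seed integer seed controlling the ICA initial rotation; the result
#'   is deterministic for a fixed seed. Non-convergence triggers up to two
#'   deterministic re-seeded restarts before erroring.
#' @param maxit,tol fixed-point iteration cap and convergence tolerance.
#' @return A [stain_matrix()] with attributes `ica_iterations` and
#'   `ica_converged`.
#' @export
estimate_mixing_matrix <- function(obs, n_components = 3, seed = 0,
                                   maxit = 400, tol = 1e-4) {
  stopifnot(inherits(obs, "filtered_observations"))
  X <- t(obs$dprime)
  if (nrow(X) < 10 * n_components)
    stop("too few coefficients for ICA (need >= 10 per component)", call. = FALSE)
  check_rank(X, n_components, "D'")
  fit <- run_fastica(X, n_components, seed, maxit, tol)
  out <- resolve_ambiguities(fit$M)
  attr(out, "ica_iterations") <- fit$iter
  attr(out, "ica_converged") <- fit$converged
  out
}

#' Plain-ICA baseline on the raw OD image
#'
#' The comparison arm: identical ICA settings and ambiguity resolution, but
#' applied to the centred raw OD matrix with no sub-band filtering. When the
#' stain density maps are spatially correlated this baseline degrades, which
#' is exactly the failure mode sub-band selection mitigates.
#'
#' @param od an [od_image()].
#' @inheritParams estimate_mixing_matrix
#' @return A [stain_matrix()].
#' @export
plain_ica_baseline <- function(od, n_components = 3, seed = 0,
                               maxit = 400, tol = 1e-4) {
  stopifnot(inherits(od, "od_image"))
  X <- t(od$d)
  check_rank(X, n_components, "OD matrix")
  fit <- run_fastica(X, n_components, seed, maxit, tol)
  out <- resolve_ambiguities(fit$M)
  attr(out, "ica_iterations") <- fit$iter
  attr(out, "ica_converged") <- fit$converged
  out
}

#' Per-pixel stain density maps container
#'
#' `3 x P` matrix: rows are the per-pixel amounts of stain 1, stain 2 and the
#' residual component; columns follow the same row-major pixel order as
#' [od_image()]. Densities may be negative (estimation noise); they are kept
#' as-is and only clipped at zero for rendering.
#'
#' @param n numeric `3 x P` matrix.
#' @param shape `c(H, W)` tile shape.
#' @param labels row labels.
#' @return Object of class `density_maps`.
#' @export
density_maps <- function(n, shape, labels = c("haematoxylin", "eosin", "residual")) {
  if (!is.matrix(n) || nrow(n) != 3L) stop("`n` must be 3 x P", call. = FALSE)
  shape <- as.integer(shape)
  if (prod(shape) != ncol(n)) stop("shape does not match P", call. = FALSE)
  if (anyNA(n) || any(!is.finite(n))) stop("densities must be finite", call. = FALSE)
  rownames(n) <- labels
  structure(list(n = n, shape = shape, labels = labels), class = "density_maps")
}

#' @export
print.density_maps <- function(x, ...) {
  cat(sprintf("<density_maps> 3 x %d (tile %d x %d)\n",
              ncol(x$n), x$shape[1], x$shape[2]))
  invisible(x)
}

#' Extract one stain's density map as a tile-shaped matrix
#' @param nmaps a [density_maps()].
#' @param stain_index 1, 2 or 3.
#' @param clip clip negatives to zero.
#' @return `H x W` numeric matrix.
#' @export
density_plane <- function(nmaps, stain_index, clip = FALSE) {
  stopifnot(inherits(nmaps, "density_maps"))
  v <- nmaps$n[stain_index, ]
  if (clip) v <- pmax(v, 0)
  unflatten_plane(v, nmaps$shape)
}

#' Deconvolve an OD image into per-stain density maps
#'
#' Computes `N = M^-1 D`. Before any clipping the reconstruction `M N`
#' reproduces `D` to machine precision. An ill-conditioned matrix (condition
#' number above 1e4) falls back to the Moore-Penrose pseudo-inverse with a
#' warning.
#'
#' @param od an [od_image()].
#' @param m a [stain_matrix()].
#' @return A [density_maps()].
#' @export
deconvolve <- function(od, m) {
  stopifnot(inherits(od, "od_image"), inherits(m, "stain_matrix"))
  minv <- if (m$condition > 1e4) {
    warning("ill-conditioned stain matrix; using pseudo-inverse")
    MASS::ginv(m$m)
  } else solve(m$m)
  density_maps(minv %*% od$d, od$shape, m$labels)
}

#' Render a single-stain RGB reconstruction
#'
#' The visual deconvolution output: `I_k = i0 * exp(-m_k n_k)` for stain
#' vector `m_k` and its density map `n_k` (clipped at zero for rendering).
#' A stain with zero density everywhere renders pure white.
#'
#' @param nmaps a [density_maps()].
#' @param m the [stain_matrix()] used for deconvolution.
#' @param stain_index which stain to render (1, 2 or 3).
#' @param i0 white level of the output tile.
#' @return An [rgb_image()].
#' @export
stain_channel_image <- function(nmaps, m, stain_index, i0 = 255) {
  stopifnot(inherits(nmaps, "density_maps"), inherits(m, "stain_matrix"),
            stain_index %in% 1:3)
  nk <- pmax(nmaps$n[stain_index, ], 0)
  dk <- m$m[, stain_index] %o% nk
  od_to_rgb(od_image(dk, nmaps$shape), i0 = i0)
}

#' Angular error between matching stain vectors of two stain matrices
#'
#' @param m_est,m_ref [stain_matrix()] objects.
#' @param match `"label"` compares same-position columns; `"angle"` first
#'   matches the two stain columns (H, E) by the minimum-total-angle
#'   assignment, which is the right choice against a ground-truth matrix
#'   whose labelling convention may differ.
#' @return tibble with columns `stain` and `angle_deg` for the two stains.
#' @export
stain_angle_errors <- function(m_est, m_ref, match = c("angle", "label")) {
  stopifnot(inherits(m_est, "stain_matrix"), inherits(m_ref, "stain_matrix"))
  match <- match.arg(match)
  if (match == "label") {
    idx <- 1:2
  } else {
    straight <- angle_deg(m_est$m[, 1], m_ref$m[, 1]) + angle_deg(m_est$m[, 2], m_ref$m[, 2])
    crossed  <- angle_deg(m_est$m[, 1], m_ref$m[, 2]) + angle_deg(m_est$m[, 2], m_ref$m[, 1])
    idx <- if (straight <= crossed) 1:2 else 2:1
  }
  tibble::tibble(
    stain = m_ref$labels[1:2],
    angle_deg = c(angle_deg(m_est$m[, idx[1]], m_ref$m[, 1]),
                  angle_deg(m_est$m[, idx[2]], m_ref$m[, 2]))
  )
}
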