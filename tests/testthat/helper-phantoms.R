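# shared fixture builders; everything is generated in code at test time

# small random 8-bit tile
random_tile <- function(h = 32, w = 32, seed = 1, i0 = 255) {
  set.seed(seed)
  rgb_image(array(sample(0:i0, h * w * 3, replace = TRUE), c(h, w, 3)), i0 = i0)
}

# OD image with arbitrary non-negative entries
od_from_matrix <- function(d, shape) od_image(d, shape)

# filtered_observations built directly from a 3 x p matrix (for ICA tests
# that bypass the wavelet stage)
obs_from_matrix <- function(x) {
  structure(list(dprime = x,
                 selected_ids = tibble::tibble(level = 1L, orientation = "a",
                                               k = NA_real_),
                 p = ncol(x)),
            class = "filtered_observations")
}

# fabricated subband_stack with chosen kurtosis values (for tie-rule tests)
fake_stack <- function(kurt, levels = 1L, degenerate = rep(FALSE, length(kurt))) {
  nb <- length(kurt)
  orients <- rep(c("a", "h", "v", "o"), length.out = nb)
  lvl <- rep(seq_len(ceiling(nb / 4)), each = 4)[seq_len(nb)]
  bands <- lapply(seq_len(nb), function(i) matrix(stats::rnorm(3 * 8), 3, 8))
  structure(list(bands = bands,
                 band_ids = tibble::tibble(level = lvl, orientation = orients),
                 kurtosis = kurt, degenerate = degenerate,
                 wavelet = "db2", levels = max(lvl), shape = c(8L, 8L)),
            class = "subband_stack")
}

median_angle_errors <- function(seeds, rho = 0, noise_sigma = 0, seed_ica = 0,
                                estimator = c("subband", "plain")) {
  estimator <- match.arg(estimator)
  out <- lapply(seeds, function(s) {
    ph <- render_phantom(phantom_spec(seed = s, rho = rho,
                                      noise_sigma = noise_sigma))
    m <- if (estimator == "subband") {
      stain_deconvolve(ph, seed = seed_ica)$stain_matrix
    } else {
      plain_ica_baseline(rgb_to_od(ph$image), seed = seed_ica)
    }
    stain_angle_errors(m, ph$m_true)$angle_deg
  })
  do.call(rbind, out)  # one row per seed: H, E
}
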