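test_that("detail bands annihilate constant tiles and sizes follow decimation", {
  px <- array(128, c(64, 64, 3))
  od <- rgb_to_od(rgb_image(px))
  st <- decompose(od, wavelet = "db2", levels = 1)
  expect_equal(length(st$bands), 4L)
  expect_true(all(vapply(st$bands, ncol, integer(1)) == 32 * 32))
  ids <- st$band_ids$orientation
  for (o in c("h", "v", "o")) {
    raw_zero <- st$degenerate[ids == o]
    expect_true(raw_zero)              # flagged degenerate, never selected
  }
})

test_that("one orthogonal decomposition level conserves channel energy", {
  set.seed(11)
  X <- matrix(runif(16 * 16, 0, 2), 16, 16)
  for (wav in c("haar", "db2", "db4")) {
    filt <- wavelet_filter(wav)
    dec <- stainwave:::dwt2_level(X, filt)
    e_bands <- sum(vapply(dec, function(b) sum(b^2), numeric(1)))
    expect_equal(e_bands, sum(X^2), tolerance = 1e-10)
  }
})

test_that("the cascade yields 4 bands per level with quartered counts", {
  od <- rgb_to_od(random_tile(64, 64, seed = 2))
  st <- decompose(od, levels = 3)
  expect_equal(nrow(st$band_ids), 12L)
  p <- vapply(st$bands, ncol, integer(1))
  expect_equal(unique(p[st$band_ids$level == 1]), 1024L)
  expect_equal(unique(p[st$band_ids$level == 2]), 256L)
  expect_equal(unique(p[st$band_ids$level == 3]), 64L)
})

test_that("requesting too deep a decomposition reduces depth with a warning", {
  od <- rgb_to_od(random_tile(16, 16, seed = 4))
  expect_warning(st <- decompose(od, levels = 5), "too small")
  expect_equal(st$levels, 3L)
})

test_that("band normalisation pools one mean and one variance over channels", {
  set.seed(5)
  b <- matrix(rnorm(3 * 50, mean = 2, sd = 3), 3)
  nb <- normalise_band(b)
  expect_equal(mean(nb), 0, tolerance = 1e-12)
  expect_equal(mean(nb^2), 1, tolerance = 1e-12)
  # relative channel scaling survives: rows (2u, u, 0) built from centred u
  u <- rnorm(100); u <- u - mean(u)
  nb2 <- normalise_band(rbind(2 * u, u, 0 * u))
  ratio <- unname(sqrt(rowSums(nb2^2)))
  expect_equal(ratio / ratio[2], c(2, 1, 0), tolerance = 1e-10)
  # all-zero band flagged degenerate
  z <- normalise_band(matrix(0, 3, 10))
  expect_true(attr(z, "degenerate"))
  expect_true(all(z == 0))
})

test_that("excess kurtosis is calibrated on known distributions", {
  set.seed(9)
  expect_lt(abs(band_kurtosis(rnorm(1e6))), 0.02)
  expect_equal(band_kurtosis(runif(1e6, -1, 1)), -1.2, tolerance = 0.02)
  lap <- stats::rexp(1e6) * sample(c(-1, 1), 1e6, TRUE)
  expect_equal(band_kurtosis(lap), 3, tolerance = 0.2)
  expect_error(band_kurtosis(c(1, 2, 3)), "fewer than 4")
})

test_that("selection ranks by |K|, breaks ties deterministically, conserves columns", {
  st <- fake_stack(kurt = c(5, -7, 2, 7, 1, 0.5, -0.25, 0.25))
  ord <- stainwave:::band_selection_order(st)
  # |K| = 7 tie between band 2 (L1 h) and band 4 (L1 o): h precedes o
  expect_equal(ord[1:2], c(2L, 4L))
  # |K| = 0.25 tie between band 7 (L2 v) and band 8 (L2 o): v precedes o
  expect_equal(ord[7:8], c(7L, 8L))
  obs <- select_subbands(st, n = 8)
  expect_equal(obs$p, sum(vapply(st$bands, ncol, integer(1))))
  obs1 <- select_subbands(st, n = 1)
  expect_identical(obs1$dprime, st$bands[[2]])
  # ranking is invariant to the order bands are stored in
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  st2 <- st
  st2$bands <- st$bands[perm]
  st2$band_ids <- st$band_ids[perm, ]
  st2$kurtosis <- st$kurtosis[perm]
  st2$degenerate <- st$degenerate[perm]
  expect_identical(select_subbands(st2, 8)$selected_ids,
                   select_subbands(st, 8)$selected_ids)
})

test_that("degenerate bands are excluded and over-asking warns", {
  st <- fake_stack(kurt = c(4, NA, 2, 1), degenerate = c(FALSE, TRUE, FALSE, FALSE))
  expect_warning(obs <- select_subbands(st, 4), "non-degenerate")
  expect_equal(nrow(obs$selected_ids), 3L)
})

test_that("linear sub-band filtering commutes with stain mixing", {
  set.seed(21)
  m <- default_phantom_matrix()$m
  n <- matrix(runif(3 * 256), 3)        # 16 x 16 source planes
  d <- m %*% n
  filt <- wavelet_filter("db2")
  for (k in c("a", "h", "v", "o")) {
    fd <- lapply(1:3, function(i) stainwave:::dwt2_level(matrix(d[i, ], 16, byrow = TRUE), filt)[[k]])
    fn <- lapply(1:3, function(i) stainwave:::dwt2_level(matrix(n[i, ], 16, byrow = TRUE), filt)[[k]])
    lhs <- do.call(rbind, lapply(fd, as.vector))
    rhs <- m %*% do.call(rbind, lapply(fn, as.vector))
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("Gaussian-noise tiles score near zero kurtosis, textured tiles score high", {
  set.seed(30)
  # pure 3-channel Gaussian noise (equal channel variance): every sub-band of
  # an orthogonal transform stays Gaussian, so pooled |K| stays near zero and
  # selection falls back to the deterministic tie rule
  d <- matrix(abs(rnorm(3 * 128 * 128, mean = 1, sd = 0.15)), 3)
  st_white <- decompose(od_image(d, c(128, 128)), levels = 3)
  det_white <- abs(st_white$kurtosis[st_white$band_ids$orientation != "a"])
  expect_lt(max(det_white), 0.5)
  s1 <- select_subbands(st_white, 12)
  s2 <- select_subbands(st_white, 12)
  expect_identical(s1$selected_ids, s2$selected_ids)
  # a textured phantom concentrates edge energy in sparse coefficients
  ph <- render_phantom(phantom_spec(size = c(128, 128), seed = 1))
  st_tex <- decompose(rgb_to_od(ph$image), levels = 3)
  det_tex <- abs(st_tex$kurtosis[st_tex$band_ids$orientation != "a"])
  expect_gt(max(det_tex), 10)
})
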