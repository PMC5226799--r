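test_that("ground-truth stain vectors are per-channel medians in OD space", {
  # 4 x 4 tile with known OD values planted at annotated pixels
  d <- matrix(0.05, 3, 16)
  # stain A pixels (row-major indices 1, 2, 3): red ODs 0.2, 0.5, 0.9
  d[, 1] <- c(0.2, 0.6, 0.1); d[, 2] <- c(0.5, 0.4, 0.3); d[, 3] <- c(0.9, 0.5, 0.2)
  # stain B pixels (indices 5, 6): red ODs 0.2, 0.4
  d[, 5] <- c(0.2, 0.8, 0.1); d[, 6] <- c(0.4, 0.6, 0.3)
  od <- od_image(d, c(4, 4))
  ann <- data.frame(stain = c("A", "A", "A", "B", "B"),
                    row = c(1, 1, 1, 2, 2), col = c(1, 2, 3, 1, 2))
  m <- ground_truth_stain_matrix(od, ann)
  # odd count: middle value; even count: mean of middle two (sort-based oracle)
  med_a <- apply(d[, 1:3], 1, function(x) { s <- sort(x); s[2] })
  med_b <- apply(d[, 5:6], 1, function(x) mean(sort(x)))
  expect_equal(unname(m$m[, 1]), med_a / sqrt(sum(med_a^2)), tolerance = 1e-12)
  expect_equal(unname(m$m[, 2]), med_b / sqrt(sum(med_b^2)), tolerance = 1e-12)
  expect_equal(unname(m$m[1, 2] / m$m[2, 2]), 0.3 / 0.7, tolerance = 1e-12)
  # residual column: unit-norm absolute cross product (non-negative octant)
  expect_equal(unname(sum(m$m[, 3]^2)), 1, tolerance = 1e-12)
  cr <- c(med_a[2] * med_b[3] - med_a[3] * med_b[2],
          med_a[3] * med_b[1] - med_a[1] * med_b[3],
          med_a[1] * med_b[2] - med_a[2] * med_b[1])
  expect_equal(unname(m$m[, 3]), abs(cr) / sqrt(sum(cr^2)), tolerance = 1e-12)
  # single annotated pixel returns that pixel's direction
  m1 <- ground_truth_stain_matrix(od, data.frame(stain = c("A", "B"),
                                                 row = c(1, 2), col = c(1, 1)))
  expect_equal(unname(m1$m[, 1]), d[, 1] / sqrt(sum(d[, 1]^2)), tolerance = 1e-12)
  expect_error(ground_truth_stain_matrix(od, data.frame(stain = "A", row = 1, col = 1)),
               "2 stains")
})

test_that("stain-vector distance is the chord between unit vectors", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  ma <- stain_matrix(cbind(e1, e2, c(0, 0, 1)))
  expect_equal(stain_vector_distance(ma, ma)$distance, c(0, 0))
  mb <- stain_matrix(cbind(e2, e1, c(0, 0, 1)))
  expect_equal(stain_vector_distance(ma, mb)$distance, rep(sqrt(2), 2),
               tolerance = 1e-12)
  # 60 degree separation has chord length exactly 1
  v60 <- c(cos(pi / 3), sin(pi / 3), 0)
  mc <- stain_matrix(cbind(v60, e2, c(0, 0, 1)))
  expect_equal(stain_vector_distance(ma, mc)$distance[1], 1, tolerance = 1e-12)
  # symmetry and the unit-vector bound
  expect_equal(stain_vector_distance(mc, ma)$distance,
               stain_vector_distance(ma, mc)$distance)
  expect_true(all(stain_vector_distance(ma, mb)$distance <= 2))
})

test_that("density correlation matches closed forms and affine invariance", {
  set.seed(17)
  base <- matrix(runif(3 * 4096), 3)
  nm <- density_maps(base, c(64, 64))
  expect_equal(density_correlation(nm, nm)$r, c(1, 1), tolerance = 1e-12)
  neg <- density_maps(-base + 2, c(64, 64))
  expect_equal(density_correlation(neg, nm)$r, c(-1, -1), tolerance = 1e-12)
  scaled <- density_maps(3 * base + 1, c(64, 64))
  expect_equal(density_correlation(scaled, nm)$r, c(1, 1), tolerance = 1e-12)
  # attenuation by independent noise: r -> s / sqrt(s^2 + sigma^2)
  s <- 1; sigma <- 1; P <- 1e5
  set.seed(18)
  x <- rnorm(P, sd = s)
  noisy <- density_maps(rbind(x + rnorm(P, sd = sigma), x, 0 * x), c(P / 100, 100))
  truth <- density_maps(rbind(x, x, 0 * x), c(P / 100, 100))
  r <- density_correlation(noisy, truth, stains = 1)$r
  expect_equal(r, s / sqrt(s^2 + sigma^2), tolerance = 0.01)
  # zero-variance map is reported as undefined
  flat <- density_maps(matrix(0, 3, 4096), c(64, 64))
  expect_warning(rc <- density_correlation(flat, nm, stains = 1), "zero-variance")
  expect_true(is.na(rc$r))
})

test_that("Bland-Altman limits bracket the bias and match the Gaussian form", {
  set.seed(19)
  base <- matrix(runif(3 * 2500), 3)
  nm <- density_maps(base, c(50, 50))
  ba0 <- bland_altman(nm, nm, n_sample = Inf)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  off <- density_maps(base + 0.7, c(50, 50))
  bac <- bland_altman(off, nm, n_sample = Inf)
  expect_equal(bac$bias, 0.7, tolerance = 1e-12)
  expect_equal(bac$loa_low, 0.7, tolerance = 1e-9)
  expect_equal(bac$loa_high, 0.7, tolerance = 1e-9)
  # standard-normal differences at n = 1e5: limits near +/- 1.96, ~95% inside
  set.seed(20)
  P <- 1e5
  diffs <- rnorm(P)
  a <- density_maps(rbind(diffs, 0 * diffs, 0 * diffs), c(1000, 100))
  b <- density_maps(matrix(0, 3, P), c(1000, 100))
  ba <- bland_altman(a, b, stains = 1, n_sample = Inf)
  expect_lt(ba$loa_low, ba$bias); expect_gt(ba$loa_high, ba$bias)
  expect_equal(ba$loa_low, -1.96, tolerance = 0.02)
  expect_equal(ba$loa_high, 1.96, tolerance = 0.02)
  inside <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.005)
  # subsampling is seeded and reproducible
  s1 <- bland_altman(a, b, stains = 1, n_sample = 500, seed = 3)
  s2 <- bland_altman(a, b, stains = 1, n_sample = 500, seed = 3)
  expect_identical(s1$differences, s2$differences)
})

test_that("evaluation_report combines the three metrics per stain", {
  ph <- render_phantom(phantom_spec(size = c(64, 64), seed = 12))
  od <- rgb_to_od(ph$image)
  n_est <- deconvolve(od, ph$m_true)
  rep <- evaluation_report(ph$m_true, n_est, ph$m_true, ph$n_true, seed = 1)
  expect_s3_class(rep, "tbl_df")
  expect_equal(rep$stain, c("haematoxylin", "eosin"))
  expect_equal(rep$distance, c(0, 0))
  expect_true(all(rep$r > 0.999))
  expect_true(all(rep$ba_loa_low <= rep$ba_bias & rep$ba_bias <= rep$ba_loa_high))
})

test_that("annotation CSVs convert 0-based coordinates", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(tile = "t", stain = "haematoxylin", row = 0, col = 2),
            p, row.names = FALSE)
  ann <- read_annotations(p)
  expect_equal(ann$row, 1L)
  expect_equal(ann$col, 3L)
})
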