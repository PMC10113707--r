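test_that("GLCM reproduces the two-level hand-counted case", {
  img <- matrix(c(0, 1, 0, 1), 2, 2)  # rows: (0,0) and (1,1)
  cfgg <- glcm_config(n_gray_levels = 2, angles = 0, symmetric = TRUE)
  P <- glcm(img, matrix(1, 2, 2), cfgg)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(glcm_energy(P), 0.5)
  expect_equal(glcm_correlation(P), 1.0)
})

test_that("GLCM handles degenerate and symmetric cases", {
  cfgg <- glcm_config(n_gray_levels = 8, angles = 0)
  # constant ROI: single entry 1, energy 1, correlation 1 by convention
  P <- glcm(matrix(0.4, 5, 5), matrix(1, 5, 5), cfgg)
  expect_equal(sum(P), 1)
  expect_equal(max(P), 1)
  expect_equal(glcm_energy(P), 1)
  expect_equal(glcm_correlation(P), 1)
  # uniform P over k^2 cells: energy 1/k^2
  k <- 4
  expect_equal(glcm_energy(matrix(1 / k^2, k, k)), 1 / k^2)
  # rotating the image by 90 degrees with the perpendicular angle
  set.seed(60)
  img <- matrix(runif(64), 8, 8)
  P0 <- glcm(img, matrix(1, 8, 8), glcm_config(8, angles = 0))
  rot <- t(img)[, 8:1]  # 90-degree rotation
  P90 <- glcm(rot, matrix(1, 8, 8), glcm_config(8, angles = pi / 2))
  expect_equal(P0, P90, tolerance = 1e-12)
  expect_error(glcm(img, matrix(0, 8, 8)), "2 pixels")
})

test_that("GLCM agrees with the brute-force pair-counting oracle", {
  set.seed(61)
  for (t in 1:100) {
    img <- matrix(runif(64), 8, 8)
    roi <- matrix(rbinom(64, 1, 0.7), 8, 8)
    if (sum(roi) < 4) next
    cfgg <- glcm_config(n_gray_levels = 4,
                        angles = c(0, pi / 4, pi / 2, 3 * pi / 4))
    offsets <- cbind(round(sin(cfgg$angles)), round(cos(cfgg$angles)))
    got <- tryCatch(glcm(img, roi, cfgg), error = function(e) NULL)
    if (is.null(got)) next
    want <- brute_glcm(img, roi, 4, offsets, symmetric = TRUE)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("GLCM of any ROI is a valid symmetric distribution", {
  set.seed(62)
  for (t in 1:20) {
    s <- generate_phantom_slice(64, 64, 1, seed = 900 + t)
    les <- (s$lesion_label_map == 1) * 1L
    if (sum(les) < 12) next
    P <- glcm(s$image, les, glcm_config(16))
    expect_true(all(P >= 0))
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_lt(max(abs(P - t(P))), 1e-12)
    e <- glcm_energy(P)
    expect_true(e > 0 && e <= 1)
    expect_true(abs(glcm_correlation(P)) <= 1 + 1e-9)
  }
})

test_that("feature histograms normalise, clip and bin correctly", {
  h <- feature_histogram(rep(0.3, 10), 5, c(0, 1))
  expect_equal(sum(h$heights), 1)
  expect_equal(max(h$heights), 1)
  h2 <- feature_histogram(c(0.1, 0.9), 2, c(0, 1))
  expect_equal(h2$heights, c(0.5, 0.5))
  # out-of-range values clip into end bins
  h3 <- feature_histogram(c(-5, 10), 4, c(0, 1))
  expect_equal(h3$heights, c(0.5, 0, 0, 0.5))
  set.seed(63)
  h4 <- feature_histogram(rnorm(1000), 30, c(-3, 3))
  expect_lt(abs(sum(h4$heights) - 1), 1e-12)
  expect_error(feature_histogram(numeric(0), 5, c(0, 1)), "empty")
  expect_error(feature_histogram(1, 5, c(1, 0)), "lo < hi")
})

test_that("KL divergence matches its closed form and is asymmetric", {
  h1 <- feature_histogram(c(0.2, 0.8), 2, c(0, 1))   # (0.5, 0.5)
  h2 <- feature_histogram(c(0.2, 0.8, 0.8, 0.9), 2, c(0, 1))  # (0.25, 0.75)
  want <- 0.5 * log(2) + 0.5 * log(2 / 3)
  expect_equal(kl_divergence(h1, h2, eps = 1e-12), want, tolerance = 1e-6)
  expect_equal(round(want, 4), 0.1438)
  expect_false(isTRUE(all.equal(kl_divergence(h1, h2), kl_divergence(h2, h1))))
  expect_equal(kl_divergence(h1, h1), 0)
  expect_gte(kl_divergence(h2, h1), 0)
  expect_error(kl_divergence(h1, feature_histogram(0.5, 3, c(0, 1))), "mismatch")
})

test_that("realism report separates texture families and is near zero on itself", {
  real <- lapply(1:24, function(i) generate_phantom_slice(64, 64, 2, seed = 1000 + i))
  rois <- lesionsynth:::lesion_rois(real)
  cfgg <- glcm_config(n_gray_levels = 16)
  self <- realism_report(rois, rois, cfgg, n_bins = 20, eps = 1e-10)
  expect_equal(nrow(self), 2L)
  expect_true(all(self$kl < 1e-6))
  expect_named(self, c("feature", "n_real", "n_syn", "kl"))
  same <- lapply(1:24, function(i) generate_phantom_slice(64, 64, 2, seed = 2000 + i))
  shifted <- lapply(1:24, function(i)
    generate_phantom_slice(64, 64, 2, seed = 3000 + i, lesion_noise_sigma = 2.0))
  kl_same <- realism_report(rois, lesionsynth:::lesion_rois(same), cfgg, n_bins = 20)
  kl_diff <- realism_report(rois, lesionsynth:::lesion_rois(shifted), cfgg, n_bins = 20)
  expect_lt(kl_same$kl[kl_same$feature == "glcm_correlation"],
            kl_diff$kl[kl_diff$feature == "glcm_correlation"])
  # csv output
  p <- tempfile(fileext = ".csv")
  realism_report(rois, rois, cfgg, n_bins = 20, out_csv = p)
  expect_true(file.exists(p))
  expect_equal(nrow(read.csv(p)), 2L)
})
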