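test_that("boundary landmarks of a disk lie on the circle, equally spaced", {
  m <- disk_mask(64, 32, 32, 20)
  v <- extract_boundary_points(m, 200)
  xy <- cbind(v[1:200], v[201:400])
  d <- sqrt((xy[, 1] - mean(xy[, 1]))^2 + (xy[, 2] - mean(xy[, 2]))^2)
  expect_true(all(abs(d - 20) <= 1))
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  expect_lt(max(seg) - min(seg), 1)
})

test_that("boundary landmarks of a square recover its perimeter", {
  q <- matrix(0L, 40, 40); q[10:30, 10:30] <- 1L
  v <- extract_boundary_points(q, 200)
  xy <- cbind(v[1:200], v[201:400])
  per <- sum(sqrt(diff(c(xy[, 1], xy[1, 1]))^2 + diff(c(xy[, 2], xy[1, 2]))^2))
  expect_lt(abs(per - 80), 4)
})

test_that("boundary extraction rejects invalid masks", {
  expect_error(extract_boundary_points(matrix(0L, 10, 10)), "empty")
  two <- matrix(0L, 20, 20)
  two[2:7, 2:7] <- 1L; two[12:18, 12:18] <- 1L
  expect_error(extract_boundary_points(two), "component")
  tiny <- matrix(0L, 10, 10); tiny[4:5, 4:5] <- 1L
  expect_error(extract_boundary_points(tiny), "area")
})

test_that("Procrustes alignment removes rotation and scale", {
  m <- phantom_lesion_masks(1, seed0 = 700L)[[1]]
  sh <- extract_boundary_points(m, 100)
  xy <- cbind(sh[1:100], sh[101:200])
  th <- pi / 3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sh2 <- c((xy %*% t(R))[, 1] * 3 + 7, (xy %*% t(R))[, 2] * 3 - 4)
  al <- procrustes_align(list(sh, sh2))
  expect_lt(max(abs(al$aligned[[1]] - al$aligned[[2]])), 1e-6)
  # idempotence: aligning aligned shapes changes nothing
  al2 <- procrustes_align(al$aligned)
  for (i in 1:2) expect_lt(max(abs(al2$aligned[[i]] - al$aligned[[i]])), 1e-6)
  # objective never increases across iterations
  masks <- phantom_lesion_masks(8, seed0 = 710L)
  shapes <- lapply(masks, extract_boundary_points, n_points = 100)
  alr <- procrustes_align(shapes)
  expect_true(all(diff(alr$objective) <= 1e-10))
  expect_error(procrustes_align(list(sh, rep(0, 200))), "degenerate")
})

test_that("shape PCA recovers rank-1 structure and round-trips at full rank", {
  base <- extract_boundary_points(disk_mask(64, 32, 32, 15), 100)
  al0 <- procrustes_align(list(base, base * 1.0))$mean_shape
  dir <- sin(seq_len(200)) / sqrt(sum(sin(seq_len(200))^2))
  shapes <- lapply(seq(-6, 6), function(w) al0 + 0.01 * w * dir)
  mod <- fit_shape_pca(shapes, n_components = 3)
  expect_gt(mod$mode_variances[1] / sum(mod$mode_variances), 1 - 1e-8)
  expect_gt(abs(sum(mod$D[1, ] * dir)), 1 - 1e-8)
  # full-rank reconstruction
  masks <- phantom_lesion_masks(15, seed0 = 720L)
  alg <- procrustes_align(lapply(masks, extract_boundary_points, n_points = 100))$aligned
  mf <- fit_shape_pca(alg, n_components = 14)
  X <- do.call(rbind, alg)
  ctr <- sweep(X, 2, mf$mean_shape)
  rec <- sweep(ctr %*% t(mf$D) %*% mf$D, 2, mf$mean_shape, `+`)
  expect_lt(max(abs(rec - X)), 1e-8)
  expect_true(all(diff(mf$mode_variances) <= 1e-12))
  expect_true(all(abs(mf$D %*% t(mf$D) - diag(14)) < 1e-8))
  expect_error(fit_shape_pca(alg[1:5], n_components = 10), "at least")
})

test_that("shape model is invariant to training order up to mode signs", {
  masks <- phantom_lesion_masks(12, seed0 = 730L)
  shapes <- lapply(masks, extract_boundary_points, n_points = 80)
  m1 <- fit_shape_pca(procrustes_align(shapes)$aligned, 5)
  perm <- rev(seq_along(shapes))
  m2 <- fit_shape_pca(procrustes_align(shapes[perm])$aligned, 5)
  expect_equal(m1$mode_variances, m2$mode_variances, tolerance = 1e-6)
  for (i in 1:5) {
    expect_lt(min(max(abs(m1$D[i, ] - m2$D[i, ])),
                  max(abs(m1$D[i, ] + m2$D[i, ]))), 1e-6)
  }
})

test_that("sampled shapes follow the per-mode weight distribution", {
  masks <- phantom_lesion_masks(20, seed0 = 740L)
  model <- fit_shape_model(masks, n_points = 80, n_components = 5)
  expect_identical(sample_shape(model, 4, weight_scale = 0), model$mean_shape)
  expect_identical(sample_shape(model, 9), sample_shape(model, 9))
  # project 500 samples back onto the modes: sample variance within 20%
  W <- t(vapply(1:500, function(s)
    as.numeric((sample_shape(model, s) - model$mean_shape) %*% t(model$D)),
    numeric(5)))
  v <- apply(W, 2, var)
  expect_true(all(abs(v / model$mode_variances - 1) < 0.2))
})

test_that("similarity transform controls area, rotation and translation", {
  sh <- extract_boundary_points(disk_mask(64, 32, 32, 12), 100)
  a0 <- lesionsynth:::polygon_area(sh[1:100], sh[101:200])
  expect_lt(max(abs(transform_shape(sh, a0) - sh)), 1e-6)
  big <- transform_shape(sh, a0 * 100)
  xy <- cbind(big[1:100], big[101:200])
  d_big <- sqrt((xy[, 1] - mean(xy[, 1]))^2 + (xy[, 2] - mean(xy[, 2]))^2)
  xy0 <- cbind(sh[1:100], sh[101:200])
  d0 <- sqrt((xy0[, 1] - mean(xy0[, 1]))^2 + (xy0[, 2] - mean(xy0[, 2]))^2)
  expect_equal(d_big, d0 * 10, tolerance = 1e-9)
  expect_lt(max(abs(transform_shape(sh, a0, rotation = 2 * pi) -
                    transform_shape(sh, a0, rotation = 0))), 1e-9)
  ar <- lesionsynth:::polygon_area(big[1:100], big[101:200])
  expect_lt(abs(ar / (a0 * 100) - 1), 0.02)
  expect_error(transform_shape(sh, -5), "target_area")
})

test_that("sampled areas stay in the jitter band and above the area floor", {
  model <- structure(list(mean_shape = numeric(4), D = diag(4)[1:2, ],
                          mode_variances = c(1, 0.5), area_sample = 100,
                          n_points = 2, n_components = 2),
                     class = "shape_model")
  draws <- vapply(1:1000, function(s) sample_area(model, s), 0)
  expect_gt(mean(draws >= 74 & draws <= 135), 0.99)
  expect_true(all(draws >= 11))
  expect_identical(sample_area(model, 3), sample_area(model, 3))
  model$area_sample <- 10.5
  expect_true(all(vapply(1:200, function(s) sample_area(model, s), 0) >= 11))
})

test_that("rasterisation matches analytic area and round-trips masks", {
  tt <- seq(0, 2 * pi, length.out = 201)[1:200]
  circ <- c(30 + 20 * cos(tt), 30 + 20 * sin(tt))
  r <- rasterize_shape(circ, c(64, 64))
  expect_lt(abs(sum(r) / (pi * 400) - 1), 0.05)
  # round trip on a convex mask
  m <- disk_mask(64, 30, 34, 11)
  v <- extract_boundary_points(m, 200)
  r2 <- rasterize_shape(v, c(64, 64))
  iou <- sum(r2 & m) / sum(r2 | m)
  expect_gte(iou, 0.95)
  # degenerate polygon: empty result or error, never a crash
  degen <- c(rep(5, 100), rep(5, 100))
  res <- tryCatch(rasterize_shape(degen, c(20, 20)), error = function(e) "err")
  expect_true(identical(res, "err") || sum(res) == 0)
  expect_error(rasterize_shape(circ, c(20, 20)), "bounds")
})

test_that("mask placement respects organ and existing lesions", {
  s <- generate_phantom_slice(64, 64, 2, seed = 17)
  masks <- phantom_lesion_masks(15, seed0 = 750L)
  model <- fit_shape_model(masks, n_points = 80, n_components = 5)
  existing <- (s$lesion_label_map > 0) * 1L
  constraint <- list(organ_mask = s$organ_mask, existing_lesions = existing,
                     max_tries = 300)
  for (k in 1:100) {
    sh <- transform_shape(sample_shape(model, k), sample_area(model, k))
    m <- place_mask(sh, constraint, seed = k)
    expect_equal(sum(m & existing), 0)
    expect_equal(sum(m & !s$organ_mask), 0)
    expect_gt(sum(m), 10)
    expect_equal(max(lesionsynth:::label_components(m)), 1L)
  }
  # infeasible case: organ fully covered
  full <- list(organ_mask = s$organ_mask, existing_lesions = s$organ_mask,
               max_tries = 20)
  sh <- transform_shape(sample_shape(model, 1), 50)
  expect_error(place_mask(sh, full, seed = 1), "max|tries|crowded")
})

test_that("shape model serialisation round-trips", {
  masks <- phantom_lesion_masks(12, seed0 = 760L)
  model <- fit_shape_model(masks, n_points = 60, n_components = 5)
  p <- tempfile(fileext = ".yaml")
  save_shape_model(model, p)
  m2 <- load_shape_model(p)
  expect_equal(m2$mean_shape, model$mean_shape, tolerance = 1e-9)
  expect_equal(m2$D, model$D, tolerance = 1e-9)
  expect_equal(m2$area_sample, model$area_sample)
  expect_equal(sample_shape(m2, 5), sample_shape(model, 5), tolerance = 1e-9)
  expect_output(print(model), "Point-distribution")
})
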