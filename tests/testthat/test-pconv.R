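test_that("partial convolution matches the per-window brute-force oracle", {
  set.seed(41)
  for (t in 1:30) {
    Cin <- sample(1:3, 1); Cout <- sample(1:3, 1)
    X <- array(runif(8 * 8 * Cin), c(8, 8, Cin))
    M <- matrix(rbinom(64, 1, runif(1, 0.3, 0.9)), 8, 8)
    W <- array(rnorm(3 * 3 * Cin * Cout), c(3, 3, Cin, Cout))
    b <- rnorm(Cout)
    got <- partial_conv2d(X, M, W, b, stride = 1, pad = 1)
    want <- brute_partial_conv(X, M, W, b, 1L, 1L)
    expect_lt(max(abs(got$output - want)), 1e-6)
  }
})

test_that("full-validity partial convolution reduces to standard convolution", {
  set.seed(42)
  for (t in 1:10) {
    X <- array(runif(8 * 8 * 2), c(8, 8, 2))
    W <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
    b <- rnorm(3)
    M <- matrix(1, 8, 8)
    # without zero padding the two operators coincide exactly everywhere
    got <- partial_conv2d(X, M, W, b, stride = 1, pad = 0)
    Wm <- t(matrix(W, 18, 3))
    std <- lesionsynth:::conv2d_fwd(X, Wm, b, 3L, 1L, 0L)
    expect_lt(max(abs(got$output - std)), 1e-12)
    # with zero padding they coincide on the interior (borders renormalise)
    gp <- partial_conv2d(X, M, W, b, stride = 1, pad = 1)
    sp <- lesionsynth:::conv2d_fwd(X, Wm, b, 3L, 1L, 1L)
    expect_lt(max(abs(gp$output[2:7, 2:7, ] - sp[2:7, 2:7, ])), 1e-12)
  }
  # all-ones image and filter: interior outputs equal the window size
  r <- partial_conv2d(array(1, c(6, 6, 1)), matrix(1, 6, 6),
                      array(1, c(3, 3, 1, 1)), 0, 1, 1)
  expect_true(all(abs(r$output[2:5, 2:5, 1] - 9) < 1e-12))
})

test_that("windows with no valid pixel output exactly zero, without bias", {
  X <- array(runif(36), c(6, 6, 1))
  M <- matrix(0, 6, 6); M[1, 1] <- 1
  W <- array(rnorm(9), c(3, 3, 1, 1))
  r <- partial_conv2d(X, M, W, b = 5, stride = 1, pad = 1)
  far <- r$output[4:6, 4:6, 1]   # windows never touching the valid pixel
  expect_true(all(far == 0))
  expect_equal(r$mask[4:6, 4:6], matrix(0, 3, 3))
})

test_that("masked-out pixel values cannot influence any output", {
  set.seed(43)
  X <- array(runif(64), c(8, 8, 1))
  M <- matrix(rbinom(64, 1, 0.5), 8, 8)
  W <- array(rnorm(9), c(3, 3, 1, 1))
  X2 <- X
  X2[, , 1][M == 0] <- 1e6 * runif(sum(M == 0))
  r1 <- partial_conv2d(X, M, W, 0.3, 1, 1)
  r2 <- partial_conv2d(X2, M, W, 0.3, 1, 1)
  expect_identical(r1$output, r2$output)
  # and through the whole generator
  gen <- build_generator(generator_config(4, 4, 32), seed = 2)
  img <- matrix(runif(32 * 32), 32, 32)
  Mg <- matrix(1, 32, 32); Mg[8:20, 10:22] <- 0
  img2 <- img; img2[Mg == 0] <- 100
  o1 <- generator_forward(gen, list(image = img, mask = Mg))
  o2 <- generator_forward(gen, list(image = img2, mask = Mg))
  expect_identical(o1, o2)
})

test_that("mask update equals square-element dilation and saturates", {
  set.seed(44)
  for (t in 1:200) {
    M <- matrix(rbinom(256, 1, runif(1, 0.05, 0.5)), 16, 16)
    got <- update_mask(M, 3)
    expect_identical(got, ebimage_dilate(M, 3))
  }
  # all-ones fixed point, single-seed growth
  expect_identical(update_mask(matrix(1, 5, 5), 3), matrix(1, 5, 5))
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  up <- update_mask(single, 3)
  expect_equal(sum(up), 9)
  expect_true(all(up[2:4, 2:4] == 1))
  # iteration count to saturation matches the dilation oracle
  for (t in 1:20) {
    M <- matrix(0, 16, 16)
    M[sample(256, 2)] <- 1
    a <- M; b <- M; ka <- 0; kb <- 0
    while (!all(a == 1)) { a <- update_mask(a, 3); ka <- ka + 1 }
    while (!all(b == 1)) { b <- ebimage_dilate(b, 3); kb <- kb + 1 }
    expect_identical(ka, kb)
  }
  expect_error(update_mask(matrix(0.5, 4, 4), 3), "binary")
})

test_that("generator architecture honours its configuration", {
  cfg <- generator_config(4, 8, 32)
  g1 <- build_generator(cfg, seed = 5)
  g2 <- build_generator(cfg, seed = 5)
  expect_identical(g1$params, g2$params)
  expect_equal(lesionsynth:::n_params(g1$params), lesionsynth:::n_params(g2$params))
  # channel plan doubles and caps at 8x base
  expect_equal(generator_config(8, 64, 256)$channels,
               c(64, 128, 256, 512, 512, 512, 512, 512))
  expect_error(generator_config(8, 8, 100), "divisible")
  img <- matrix(runif(32 * 32), 32, 32)
  out <- generator_forward(g1, list(image = img, mask = matrix(1, 32, 32)))
  expect_equal(dim(out), c(32L, 32L))
  expect_true(all(is.finite(out)))
  expect_true(all(out >= 0 & out <= 1))
  # full-scale shape check: 256 in, 256 out
  g8 <- build_generator(generator_config(8, 2, 256), seed = 1)
  o8 <- generator_forward(g8, list(image = matrix(runif(256^2), 256, 256),
                                   mask = matrix(1, 256, 256)))
  expect_equal(dim(o8), c(256L, 256L))
  expect_true(all(is.finite(o8)))
  # deterministic inference
  Mh <- matrix(1, 32, 32); Mh[5:12, 5:12] <- 0
  expect_identical(generator_forward(g1, list(image = img, mask = Mh)),
                   generator_forward(g1, list(image = img, mask = Mh)))
  expect_error(lesionsynth:::gen_forward_batch(
    g1, list(matrix(0, 30, 30)), list(matrix(1, 30, 30))), "incompatible")
})

test_that("composite selects real context and synthesized hole per pixel", {
  x <- matrix(1:16 / 16, 4, 4)
  xh <- -matrix(1:16 / 16, 4, 4)
  expect_identical(composite(x, xh, matrix(1, 4, 4)), x)
  expect_identical(composite(x, xh, matrix(0, 4, 4)), xh)
  for (code in 0:15) {  # exhaustive over 4x4-block patterns
    M <- matrix(as.numeric(bitwAnd(code, 2^(0:3)) > 0)[c(1, 2, 3, 4)], 2, 2)
    M4 <- M[rep(1:2, each = 2), rep(1:2, each = 2)]
    z <- composite(x, xh, M4)
    expect_identical(z[M4 == 1], x[M4 == 1])
    expect_identical(z[M4 == 0], xh[M4 == 0])
  }
  expect_error(composite(x, xh[1:3, 1:3], matrix(1, 4, 4)), "mismatch")
})

test_that("lesion patch cropping centres, clamps and selects uniformly", {
  img <- matrix(runif(128 * 128), 128, 128)
  les <- matrix(0L, 128, 128); les[60:68, 62:70] <- 1L
  cp <- crop_lesion_patch(img, les, 64, seed = 1)
  expect_equal(dim(cp$patch), c(64L, 64L))
  expect_equal(sum(cp$lesion), sum(les))
  ctr <- c(mean(row(les)[les == 1]), mean(col(les)[les == 1]))
  expect_lt(abs(cp$r0 + 32 - ctr[1]), 2)
  # corner lesion: window clamped, still full size
  les2 <- matrix(0L, 128, 128); les2[1:6, 1:6] <- 1L
  cp2 <- crop_lesion_patch(img, les2, 64, seed = 1)
  expect_equal(cp2$r0, 0)
  expect_equal(dim(cp2$patch), c(64L, 64L))
  expect_error(crop_lesion_patch(img, matrix(0L, 128, 128), 64, 1), "empty")
  # uniform component selection
  les3 <- matrix(0L, 128, 128)
  les3[10:14, 10:14] <- 1L; les3[60:64, 60:64] <- 1L; les3[100:104, 100:104] <- 1L
  picks <- vapply(1:1000, function(s) crop_lesion_patch(img, les3, 64, s)$component, 0)
  expect_true(all(abs(tabulate(picks, 3) / 1000 - 1 / 3) < 0.05))
})

test_that("critic has the stated layer geometry and spectral normalisation", {
  cfg <- discriminator_config(input_size = 64, base_channels = 8)
  D <- build_discriminator(cfg, seed = 3)
  p <- matrix(runif(64 * 64), 64, 64)
  s <- discriminator_forward(D, p)
  expect_length(s, 1)
  expect_true(is.finite(s))
  expect_identical(s, discriminator_forward(D, p))
  # spatial plan 64 -> 32 -> 16 -> 8 -> scalar
  eff <- lesionsynth:::disc_effective_weights(D, update = FALSE)
  fc <- lesionsynth:::disc_forward_cached(D, array(p, c(64, 64, 1)), eff)
  expect_equal(dim(fc$acts[[2]])[1:2], c(32L, 32L))
  expect_equal(dim(fc$acts[[3]])[1:2], c(16L, 16L))
  expect_equal(dim(fc$acts[[4]])[1:2], c(8L, 8L))
  # normalised intermediate kernels have largest singular value ~ 1
  for (l in cfg$sn_layers) {
    expect_lt(abs(svd(eff[[l]]$Wbar)$d[1] - 1), 0.05)
  }
  expect_error(discriminator_forward(D, matrix(0, 63, 63)), "64")
  expect_error(discriminator_config(input_size = 63), "divisible")
})

test_that("checkpoints embed config and restore behaviour exactly", {
  gen <- build_generator(generator_config(4, 4, 32), seed = 9)
  img <- matrix(runif(32 * 32), 32, 32)
  M <- matrix(1, 32, 32); M[10:15, 10:15] <- 0
  out <- generator_forward(gen, list(image = img, mask = M))
  p <- tempfile(fileext = ".rds")
  save_checkpoint(gen, p)
  gen2 <- load_checkpoint(p)
  expect_identical(generator_forward(gen2, list(image = img, mask = M)), out)
  expect_equal(gen2$cfg$n_stages, 4L)
})
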