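test_that("reconstruction loss reproduces the worked 2x2 case", {
  x <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  xh <- matrix(c(0.5, 0, 0, 0), 2, 2, byrow = TRUE)
  M <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(reconstruction_loss(x, xh, M, w1 = 1, w2 = 5, reduction = "sum"), 5.5)
  expect_equal(reconstruction_loss(x, xh, M, w1 = 1, w2 = 5, reduction = "mean"), 5.5 / 4)
  expect_equal(reconstruction_loss(x, x, M), 0)
  # doubling w2 doubles only the lesion term
  l1 <- reconstruction_loss(x, xh, M, 1, 5, "sum")
  l2 <- reconstruction_loss(x, xh, M, 1, 10, "sum")
  lesion_term <- sum((1 - M) * abs(x - xh))
  expect_equal(l2 - l1, 5 * lesion_term)
  expect_error(reconstruction_loss(x, xh[1, , drop = FALSE], M), "mismatch")
})

test_that("Gram matrices match the double-loop oracle and are symmetric PSD", {
  set.seed(50)
  for (t in 1:20) {
    C <- sample(1:4, 1)
    Fc <- array(rnorm(6 * 5 * C), c(6, 5, C))
    G <- gram_matrix(Fc)
    # independent double loop
    Go <- matrix(0, C, C)
    for (i in seq_len(C)) for (j in seq_len(C)) {
      Go[i, j] <- sum(Fc[, , i] * Fc[, , j]) / (6 * 5 * C)
    }
    expect_lt(max(abs(G - Go)), 1e-6)
    expect_lt(max(abs(G - t(G))), 1e-12)
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  # single constant channel: scalar v^2
  v <- 0.7
  expect_equal(as.numeric(gram_matrix(matrix(v, 4, 4))), v^2)
  # orthogonal channels: zero off-diagonals
  Fo <- array(0, c(2, 2, 2)); Fo[1, 1, 1] <- 1; Fo[2, 2, 2] <- 1
  expect_equal(gram_matrix(Fo)[1, 2], 0)
})

test_that("perceptual loss matches hand evaluation with the identity extractor", {
  phi <- identity_extractor()
  x <- matrix(runif(64), 8, 8)
  expect_equal(perceptual_loss(x, x, x, phi), 0)
  expect_equal(texture_loss(x, x, x, phi), 0)
  # xhat = x + 1, z = x: per-layer term (1/N)(N*1 + 0) = 1
  expect_equal(perceptual_loss(x + 1, x, x, phi), 1)
  expect_gte(perceptual_loss(matrix(runif(64), 8, 8), x, x, phi), 0)
})

test_that("texture loss ignores pixel positions but sees texture changes", {
  phi <- identity_extractor()
  x <- matrix(runif(64), 8, 8)
  perm <- matrix(sample(as.numeric(x)), 8, 8)
  # spatial permutation leaves the Gram matrix unchanged -> loss 0
  expect_lt(texture_loss(perm, x, x, phi), 1e-12)
  # hand-computed 2-channel case with a stub 2-channel "extractor"
  f_of <- function(img) array(c(img, 2 * img), c(dim(img), 2))
  xh <- x * 1.5
  Gh <- gram_matrix(f_of(xh)); Gx <- gram_matrix(f_of(x))
  manual <- (sum(abs(Gh - Gx)) + sum(abs(Gx - Gx))) / length(f_of(x))
  # replicate via the package's random_conv_extractor interface contract:
  # texture_loss with identity extractor on the raw images
  expect_equal(texture_loss(xh, x, x, phi),
               (sum(abs(gram_matrix(xh) - gram_matrix(x)))) / 64)
  expect_gt(manual, 0)
})

test_that("WGAN-GP losses behave as designed", {
  cfg <- discriminator_config(input_size = 32, base_channels = 4)
  D <- build_discriminator(cfg, seed = 2)
  set.seed(51)
  real <- lapply(1:4, function(i) matrix(runif(1024), 32, 32))
  fake <- lapply(1:4, function(i) matrix(runif(1024), 32, 32))
  gl <- gan_losses(D, real, fake, lambda_gp = 10, seed = 3)
  expect_true(all(is.finite(unlist(gl))))
  expect_equal(gl$gen_adv_loss, -gl$fake_score)
  # constant critic: zero weights -> scores 0, gradient norm 0, Gp = 1
  Dz <- build_discriminator(cfg, seed = 2)
  for (nm in names(Dz$params)) {
    Dz$params[[nm]]$W[] <- 0
    Dz$params[[nm]]$b[] <- 0
  }
  glz <- gan_losses(Dz, real, fake, lambda_gp = 10, seed = 3)
  expect_equal(glz$real_score, 0)
  expect_equal(glz$fake_score, 0)
  expect_equal(glz$gp, 1)
  expect_equal(glz$critic_loss, 10)  # -(0 - 0 - 10*1)
  # identical real and fake batches: score difference exactly 0
  gls <- gan_losses(D, real, real, lambda_gp = 10, seed = 3)
  expect_equal(gls$real_score, gls$fake_score)
})

test_that("critic input gradients match finite differences", {
  D <- build_discriminator(discriminator_config(input_size = 32,
                                                base_channels = 4), seed = 6)
  eff <- lesionsynth:::disc_effective_weights(D, update = FALSE)
  p <- matrix(runif(1024), 32, 32)
  fc <- lesionsynth:::disc_forward_cached(D, array(p, c(32, 32, 1)), eff)
  g <- lesionsynth:::disc_backward_cached(D, fc, eff, 1)$dInput
  set.seed(52)
  for (r in 1:5) {
    i <- sample(1024, 1)
    pp <- p; pp[i] <- pp[i] + 1e-6
    pm <- p; pm[i] <- pm[i] - 1e-6
    fd <- (lesionsynth:::disc_forward_cached(D, array(pp, c(32, 32, 1)), eff)$score -
           lesionsynth:::disc_forward_cached(D, array(pm, c(32, 32, 1)), eff)$score) / 2e-6
    an <- g[(i - 1) %% 32 + 1, (i - 1) %/% 32 + 1, 1]
    expect_lt(abs(fd - an), 1e-5 * max(1, abs(fd)))
  }
})

test_that("total loss combines components with the configured weights", {
  lw <- loss_weights()
  expect_equal(lw$reconstruction, 1)
  expect_equal(lw$perceptual, 0.05)
  expect_equal(lw$texture, 100)
  expect_equal(lw$w1, 1)
  expect_equal(lw$w2, 5)
  expect_equal(total_loss(list(gan = 0, reconstruction = 0, perceptual = 0,
                               texture = 0), lw), 0)
  expect_equal(total_loss(list(gan = 1, reconstruction = 1, perceptual = 1,
                               texture = 1), lw), 102.05)
  base <- total_loss(list(gan = 0.3, reconstruction = 0.2, perceptual = 0.1,
                          texture = 0.4), lw)
  lw2 <- loss_weights(texture = 200)
  expect_equal(total_loss(list(gan = 0.3, reconstruction = 0.2, perceptual = 0.1,
                               texture = 0.4), lw2) - base, 100 * 0.4)
  expect_error(total_loss(list(gan = NaN, reconstruction = 0, perceptual = 0,
                               texture = 0), lw), "gan")
  expect_error(loss_weights(texture = -1), "non-negative")
})
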