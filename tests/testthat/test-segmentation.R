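test_that("CE+Dice loss matches hand arithmetic and boundary conventions", {
  z <- matrix(0, 4, 4)
  # empty prediction and label: Dice term is 1 - 1/1 = 0
  expect_equal(ce_dice_loss(z, z, lambda_ce = 0, lambda_dice = 1), 0)
  # perfect hard prediction: both terms ~ 0
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_lt(ce_dice_loss(y, y), 1e-5)
  # 2x2 worked case: y has one positive pixel, yhat = 0.5 everywhere;
  # L_Dice = 1 - (2*0.5+1)/(1+2+1) = 0.5, L_CE = ln 2
  y1 <- matrix(c(1, 0, 0, 0), 2, 2)
  yh <- matrix(0.5, 2, 2)
  expect_equal(ce_dice_loss(yh, y1, lambda_ce = 0, lambda_dice = 1), 0.5)
  expect_equal(ce_dice_loss(yh, y1, lambda_ce = 1, lambda_dice = 0), log(2))
  expect_equal(ce_dice_loss(yh, y1, lambda_ce = 0.5, lambda_dice = 1),
               0.5 + 0.5 * log(2))
  expect_error(ce_dice_loss(yh, matrix(0, 3, 3)), "mismatch")
})

test_that("CE+Dice loss decreases monotonically toward the label", {
  set.seed(70)
  for (t in 1:20) {
    y <- matrix(rbinom(64, 1, 0.3), 8, 8)
    ls <- vapply(seq(0, 1, length.out = 11), function(tt)
      ce_dice_loss((1 - tt) * 0.5 + tt * pmin(pmax(y, 0.02), 0.98), y), 0)
    expect_true(all(diff(ls) <= 1e-10))
  }
})

test_that("the CE+Dice gradient matches finite differences", {
  set.seed(71)
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  yh <- matrix(runif(64, 0.1, 0.9), 8, 8)
  g <- lesionsynth:::ce_dice_grad(yh, y)
  for (r in 1:5) {
    i <- sample(64, 1)
    up <- yh; up[i] <- up[i] + 1e-6
    dn <- yh; dn[i] <- dn[i] - 1e-6
    fd <- (ce_dice_loss(up, y) - ce_dice_loss(dn, y)) / 2e-6
    expect_lt(abs(fd - g[i]), 1e-5 * max(1, abs(fd)))
  }
})

test_that("segmentation U-Net has the contracted interface", {
  net <- build_unet(1, 4, 3, seed = 2)
  net2 <- build_unet(1, 4, 3, seed = 2)
  expect_identical(net$params, net2$params)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- unet_forward(net, img)
  expect_equal(dim(p), c(32L, 32L))
  expect_true(all(is.finite(p)))
  expect_true(all(p > 0 & p < 1))
  expect_error(unet_forward(net, matrix(0, 30, 30)), "divisible")
  # 256 -> 256 at full scale
  n8 <- build_unet(1, 2, 4, seed = 1)
  p8 <- unet_forward(n8, matrix(runif(256^2), 256, 256))
  expect_equal(dim(p8), c(256L, 256L))
})

test_that("volumetric metrics reproduce the worked cases", {
  a <- matrix(0, 4, 4); a[1, 1:2] <- 1
  expect_equal(segmentation_metrics(a, a), list(dsc = 100, vpsc = 100, vsen = 100))
  pred <- matrix(0, 4, 4); pred[1, 1:4] <- 1   # 4 px
  gt <- matrix(0, 4, 4); gt[1, 1:2] <- 1       # 2 px, overlap 2
  m <- segmentation_metrics(pred, gt)
  expect_equal(m$vpsc, 50)
  expect_equal(m$vsen, 100)
  expect_equal(m$dsc, 200 * 2 / 6, tolerance = 1e-9)  # 66.67%
  disj <- matrix(0, 4, 4); disj[4, 4] <- 1
  expect_equal(segmentation_metrics(disj, gt), list(dsc = 0, vpsc = 0, vsen = 0))
  z <- matrix(0, 4, 4)
  expect_equal(segmentation_metrics(z, z), list(dsc = 100, vpsc = 100, vsen = 100))
  expect_equal(segmentation_metrics(z, gt)$dsc, 0)
  expect_equal(segmentation_metrics(gt, z)$dsc, 0)
})

test_that("DSC is the harmonic mean of precision and sensitivity", {
  set.seed(72)
  for (t in 1:200) {
    pred <- matrix(rbinom(64, 1, runif(1, 0.2, 0.7)), 8, 8)
    gt <- matrix(rbinom(64, 1, runif(1, 0.2, 0.7)), 8, 8)
    if (sum(pred * gt) == 0) next
    m <- segmentation_metrics(pred, gt)
    expect_equal(m$dsc, 2 * m$vpsc * m$vsen / (m$vpsc + m$vsen), tolerance = 1e-9)
  }
})

test_that("cross-validation partitions subjects exactly once, never synthetics", {
  ds <- generate_phantom_dataset(30, c(1, 2), seed = 8, height = 32, width = 32)
  syn_src <- lapply(1:6, function(i) generate_phantom_slice(32, 32, 1, seed = 860 + i))
  syn <- lapply(syn_src, function(s)
    list(image = s$image, label = (s$lesion_label_map > 0) * 1))
  cfg <- seg_config(batch_size = 8, epochs = 1, n_folds = 3, depth = 3,
                    base_width = 2, seed = 4)
  r <- train_segmentation(ds, syn, cfg)
  # every real subject evaluated exactly once
  expect_identical(sort(unique(r$per_subject$subject)), sort(unique(ds$subject)))
  expect_identical(nrow(r$per_subject), length(unique(ds$subject)))
  counts <- table(r$per_subject$subject)
  expect_true(all(counts == 1))
  expect_equal(nrow(r$per_fold), 3L)
  expect_true(all(r$per_subject$dsc >= 0 & r$per_subject$dsc <= 100))
  # baseline mode runs without synthetic data
  r0 <- train_segmentation(ds, NULL, cfg)
  expect_equal(nrow(r0$per_subject), length(unique(ds$subject)))
  expect_error(train_segmentation(list(), NULL, cfg), "empty")
})
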