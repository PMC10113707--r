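# Shared fixtures and independent oracles, all built in code.

# Brute-force partial convolution: explicit per-window loop, independent of
# the im2col implementation under test.
brute_partial_conv <- function(X, M, W, b, stride = 1L, pad = 1L) {
  k <- dim(W)[1L]; Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  H <- dim(X)[1L]; Wd <- dim(X)[2L]
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (Wd + 2 * pad - k) %/% stride + 1L
  Xp <- array(0, c(H + 2 * pad, Wd + 2 * pad, Cin))
  Mp <- array(0, c(H + 2 * pad, Wd + 2 * pad, Cin))
  Xp[pad + seq_len(H), pad + seq_len(Wd), ] <- X
  Mp[pad + seq_len(H), pad + seq_len(Wd), ] <- array(M, c(H, Wd, Cin))
  out <- array(0, c(Ho, Wo, Cout))
  K <- k * k * Cin
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    xr <- (i - 1L) * stride + seq_len(k); xc <- (j - 1L) * stride + seq_len(k)
    xw <- Xp[xr, xc, , drop = FALSE]; mw <- Mp[xr, xc, , drop = FALSE]
    sm <- sum(mw)
    for (co in seq_len(Cout)) {
      wk <- array(W[, , , co], c(k, k, Cin))
      out[i, j, co] <- if (sm > 0) sum(wk * xw * mw) * K / sm + b[co] else 0
    }
  }
  out
}

# Brute-force GLCM by explicit pair counting.
brute_glcm <- function(image, roi, n_levels, offsets, symmetric = TRUE) {
  idx <- which(roi == 1)
  vals <- image[idx]
  lo <- min(vals); hi <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  q[idx] <- if (hi - lo < 1e-12) 1L else
    pmin(pmax(floor((image[idx] - lo) / (hi - lo) * n_levels) + 1L, 1L), n_levels)
  P <- matrix(0, n_levels, n_levels)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1L]; dc <- offsets[o, 2L]
    for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(image) || c2 < 1 || c2 > ncol(image)) next
      if (is.na(q[r, c]) || is.na(q[r2, c2])) next
      P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
      if (symmetric) P[q[r2, c2], q[r, c]] <- P[q[r2, c2], q[r, c]] + 1
    }
  }
  P / sum(P)
}

# EBImage box dilation as a plain numeric matrix.
ebimage_dilate <- function(M, k = 3L) {
  d <- EBImage::dilate(EBImage::Image(M), EBImage::makeBrush(k, "box"))
  matrix(as.numeric(EBImage::imageData(d)), nrow(M), ncol(M))
}

disk_mask <- function(side, cr, cc, radius) {
  m <- matrix(0L, side, side)
  rr <- row(m) - 1; cc2 <- col(m) - 1
  m[(rr - cr)^2 + (cc2 - cc)^2 <= radius^2] <- 1L
  m
}

# Small training-lesion mask bank built from seeded phantoms.
phantom_lesion_masks <- function(n = 25L, side = 64L, seed0 = 600L) {
  masks <- list()
  i <- 0L
  while (length(masks) < n) {
    i <- i + 1L
    s <- generate_phantom_slice(side, side, 1L, seed = seed0 + i)
    m <- (s$lesion_label_map == 1L) * 1L
    if (sum(m) > 10) masks[[length(masks) + 1L]] <- m
  }
  masks
}

# Desk-scale synthesis configuration shared by the training tests.
tiny_synthesis_config <- function(steps, seed, batch_size = 6L) {
  synthesis_config(
    gen = generator_config(4L, 8L, 32L),
    disc = discriminator_config(input_size = 32L, base_channels = 8L),
    extractor = random_conv_extractor(channels = c(8L, 16L), strides = c(1L, 2L)),
    batch_size = batch_size, steps = steps, seed = seed)
}
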