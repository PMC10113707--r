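# Minimal CPU convolutional-network engine used by the generator, the
# Wasserstein critic and the segmentation U-Net.
#
# Representation conventions:
#   sample tensor   array dim c(H, W, C)         ("cube", channel-last)
#   batch           list of cubes
#   conv weights    matrix Cout x (k*k*Cin), row c = flattened kernel of
#                   output channel c; matches matrix(w, k*k*Cin, Cout) of an
#                   R array dim c(k, k, Cin, Cout)
#   validity masks  "mask groups": list of list(mask = H x W matrix,
#                   n = number of consecutive channels sharing that mask)
#
# All forward functions return caches sufficient for their backward pass;
# nothing here uses global state except the RNG (always inside with_seed).

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# ---- parameter initialisation -------------------------------------------

# He/Kaiming normal: sd = sqrt(2 / fan_in), fan_in = k*k*Cin.
he_conv <- function(Cin, Cout, k) {
  sd <- sqrt(2 / (k * k * Cin))
  list(W = matrix(rnorm(Cout * k * k * Cin, 0, sd), Cout, k * k * Cin),
       b = numeric(Cout))
}

bn_param <- function(C) list(gamma = rep(1, C), beta = numeric(C))

n_params <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, n_params, 0)) else length(tree)
}

zero_like <- function(tree) {
  if (is.list(tree)) lapply(tree, zero_like) else tree * 0
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_add(a[[i]], b[[i]])
    a
  } else a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, tree_scale, s = s) else a * s
}

tree_finite <- function(a) {
  if (is.list(a)) all(vapply(a, tree_finite, TRUE)) else all(is.finite(a))
}

# ---- plain convolution layer --------------------------------------------

conv_f <- function(X, p) {
  conv2d_fwd(X, p$W, p$b, p$k, p$stride, p$pad)
}

conv_b <- function(dY, X, p) {
  gw <- conv2d_bwd_weight(X, dY, p$k, p$stride, p$pad)
  dX <- conv2d_bwd_input(dY, p$W, dim(X)[1L], dim(X)[2L], dim(X)[3L],
                         p$k, p$stride, p$pad)
  list(dX = dX, dW = gw$dW, db = as.numeric(gw$db))
}

conv_f_batch <- function(Xs, p) {
  conv2d_fwd_batch(Xs, p$W, p$b, p$k, p$stride, p$pad)
}

conv_b_batch <- function(Xs, dYs, p) {
  conv2d_bwd_batch(Xs, dYs, p$W, p$k, p$stride, p$pad)
}

# ---- partial convolution layer ------------------------------------------

# X: cube H x W x Cin; groups: mask groups covering the Cin channels.
# Renormalisation follows the ratio-of-window-size convention: the valid
# window sum is rescaled by K / sum(M), K = k*k*Cin, so a fully valid
# window reduces exactly to the standard convolution. Windows with no
# valid pixel output exactly 0 (no bias).
pconv_f <- function(X, groups, p) {
  k <- p$k; s <- p$stride; pad <- p$pad
  Cin <- dim(X)[3L]
  Xm <- X
  ones_row <- matrix(1, 1L, k * k)
  S <- NULL
  at <- 0L
  for (g in groups) {
    idx <- at + seq_len(g$n)
    for (c in idx) Xm[, , c] <- Xm[, , c] * g$mask
    Sg <- conv2d_fwd(as_cube(g$mask), ones_row, 0, k, s, pad)
    Sg <- matrix(Sg, dim(Sg)[1L], dim(Sg)[2L])  # keep 1x1 outputs as matrices
    S <- if (is.null(S)) g$n * Sg else S + g$n * Sg
    at <- at + g$n
  }
  K <- k * k * Cin
  valid <- S > 1e-9
  sc <- ifelse(valid, K / pmax(S, 1e-9), 0)
  Y <- conv2d_fwd(Xm, p$W, numeric(nrow(p$W)), k, s, pad)
  for (c in seq_len(dim(Y)[3L])) Y[, , c] <- Y[, , c] * sc + p$b[c] * valid
  list(Y = Y, mask_out = list(list(mask = valid * 1, n = dim(Y)[3L])),
       cache = list(Xm = Xm, sc = sc, valid = valid, groups = groups,
                    dimX = dim(X)))
}

pconv_b <- function(dY, cache, p) {
  sc <- cache$sc
  dYs <- dY
  Cout <- dim(dY)[3L]
  db <- numeric(Cout)
  for (c in seq_len(Cout)) {
    db[c] <- sum(dY[, , c] * cache$valid)
    dYs[, , c] <- dY[, , c] * sc
  }
  gw <- conv2d_bwd_weight(cache$Xm, dYs, p$k, p$stride, p$pad)
  dXm <- conv2d_bwd_input(dYs, p$W, cache$dimX[1L], cache$dimX[2L],
                          cache$dimX[3L], p$k, p$stride, p$pad)
  at <- 0L
  for (g in cache$groups) {
    idx <- at + seq_len(g$n)
    for (c in idx) dXm[, , c] <- dXm[, , c] * g$mask
    at <- at + g$n
  }
  list(dX = dXm, dW = gw$dW, db = db)
}

# ---- activations ---------------------------------------------------------

relu_f <- function(X) list(Y = pmax(X, 0), cache = X > 0)
relu_b <- function(dY, cache) dY * cache
lrelu_f <- function(X, slope = 0.2) {
  pos <- X > 0
  list(Y = X * ifelse(pos, 1, slope), cache = ifelse(pos, 1, slope))
}
lrelu_b <- function(dY, cache) dY * cache
sigmoid_f <- function(X) {
  Y <- 1 / (1 + exp(-X))
  list(Y = Y, cache = Y)
}
sigmoid_b <- function(dY, cache) dY * cache * (1 - cache)

# ---- nearest-neighbour 2x upsampling ------------------------------------

up2_f <- function(X) {
  X[rep(seq_len(dim(X)[1L]), each = 2L), rep(seq_len(dim(X)[2L]), each = 2L), ,
    drop = FALSE]
}
up2_b <- function(dY) {
  h <- dim(dY)[1L] / 2L; w <- dim(dY)[2L] / 2L
  out <- array(0, dim = c(h, w, dim(dY)[3L]))
  for (a in 1:2) for (b in 1:2) {
    out <- out + dY[seq(a, by = 2L, length.out = h),
                    seq(b, by = 2L, length.out = w), , drop = FALSE]
  }
  out
}
up2_mask <- function(groups) {
  lapply(groups, function(g) list(mask = up2_f(as_cube(g$mask))[, , 1L], n = g$n))
}

# ---- batch normalisation (over batch x H x W per channel) ----------------

bn_f <- function(Xs, p, state, name, training, momentum = 0.1, eps = 1e-5) {
  C <- dim(Xs[[1L]])[3L]
  hw <- dim(Xs[[1L]])[1L] * dim(Xs[[1L]])[2L]
  N <- length(Xs) * hw
  if (training) {
    mu <- numeric(C); m2 <- numeric(C)
    for (X in Xs) {
      Xm <- matrix(X, hw, C)
      mu <- mu + colSums(Xm)
      m2 <- m2 + colSums(Xm^2)
    }
    mu <- mu / N
    var <- pmax(m2 / N - mu^2, 0)
    key_m <- paste0(name, ".mean"); key_v <- paste0(name, ".var")
    old_m <- state[[key_m]] %||% numeric(C)
    old_v <- state[[key_v]] %||% rep(1, C)
    state[[key_m]] <- (1 - momentum) * old_m + momentum * mu
    state[[key_v]] <- (1 - momentum) * old_v + momentum * var
  } else {
    mu <- state[[paste0(name, ".mean")]] %||% numeric(C)
    var <- state[[paste0(name, ".var")]] %||% rep(1, C)
  }
  invstd <- 1 / sqrt(var + eps)
  d <- dim(Xs[[1L]])
  mu_e <- rep(mu, each = hw); is_e <- rep(invstd, each = hw)
  ga_e <- rep(p$gamma, each = hw); be_e <- rep(p$beta, each = hw)
  xhat <- vector("list", length(Xs))
  Ys <- vector("list", length(Xs))
  for (i in seq_along(Xs)) {
    xh <- (as.numeric(Xs[[i]]) - mu_e) * is_e
    xhat[[i]] <- array(xh, d)
    Ys[[i]] <- array(xh * ga_e + be_e, d)
  }
  list(Ys = Ys, cache = list(xhat = xhat, invstd = invstd, N = N))
}

bn_b <- function(dYs, cache, p) {
  C <- length(p$gamma)
  hw <- dim(dYs[[1L]])[1L] * dim(dYs[[1L]])[2L]
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (i in seq_along(dYs)) {
    dm <- matrix(dYs[[i]], hw, C)
    xm <- matrix(cache$xhat[[i]], hw, C)
    dgamma <- dgamma + colSums(dm * xm)
    dbeta <- dbeta + colSums(dm)
  }
  dXs <- vector("list", length(dYs))
  d <- dim(dYs[[1L]])
  db_e <- rep(dbeta / cache$N, each = hw)
  dg_e <- rep(dgamma / cache$N, each = hw)
  gi_e <- rep(p$gamma * cache$invstd, each = hw)
  for (i in seq_along(dYs)) {
    # dX = gamma*invstd*(dY - mean(dY) - xhat * mean(dY*xhat))
    dX <- (as.numeric(dYs[[i]]) - db_e - as.numeric(cache$xhat[[i]]) * dg_e) * gi_e
    dXs[[i]] <- array(dX, d)
  }
  list(dXs = dXs, dgamma = dgamma, dbeta = dbeta)
}

# ---- spectral normalisation ---------------------------------------------

# Power iteration on the Cout x (k*k*Cin) weight matrix. u is persistent
# across steps; sigma is the estimated largest singular value.
sn_power <- function(W, u = NULL, iters = 1L) {
  if (is.null(u)) u <- rnorm(nrow(W))
  for (i in seq_len(iters)) {
    v <- as.numeric(crossprod(W, u)); v <- v / sqrt(sum(v^2) + 1e-12)
    u <- as.numeric(W %*% v); u <- u / sqrt(sum(u^2) + 1e-12)
  }
  sigma <- as.numeric(t(u) %*% W %*% v)
  list(u = u, v = v, sigma = sigma)
}

# Gradient through W_bar = W / sigma with sigma = u' W v (u, v fixed):
# dW = (G - <G, W_bar> u v') / sigma.
sn_grad <- function(G, Wbar, u, v, sigma) {
  (G - sum(G * Wbar) * (u %o% v)) / sigma
}

# ---- AMSGrad optimiser ---------------------------------------------------

# AMSGrad keeps the running maximum of the second-moment estimate; no bias
# correction, following the original formulation.
amsgrad_new <- function(params, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$m <- zero_like(params)
  e$v <- zero_like(params)
  e$vhat <- zero_like(params)
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e
}

amsgrad_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  step1 <- function(p, g, m, v, vh) {
    m2 <- opt$beta1 * m + (1 - opt$beta1) * g
    v2 <- opt$beta2 * v + (1 - opt$beta2) * g^2
    vh2 <- pmax(vh, v2)
    list(p = p - opt$lr * m2 / (sqrt(vh2) + opt$eps), m = m2, v = v2, vh = vh2)
  }
  rec <- function(p, g, m, v, vh) {
    if (is.list(p)) {
      out_p <- p
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]], vh[[i]])
        out_p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v; vh[[i]] <- r$vh
      }
      list(p = out_p, m = m, v = v, vh = vh)
    } else step1(p, g, m, v, vh)
  }
  r <- rec(params, grads, opt$m, opt$v, opt$vhat)
  opt$m <- r$m; opt$v <- r$v; opt$vhat <- r$vh
  r$p
}
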