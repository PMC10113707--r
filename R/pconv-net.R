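# Partial-convolution operator, mask update, the partial-convolution U-Net
# generator and the spectrally normalised Wasserstein critic.

cube_cat <- function(A, B) {
  array(c(A, B), dim = c(dim(A)[1L], dim(A)[2L], dim(A)[3L] + dim(B)[3L]))
}

#' Partial convolution with validity renormalisation
#'
#' Convolution whose output at each window depends only on valid pixels:
#' \code{x' = W'(X * M) * K / sum(M) + b} where the window has any valid
#' pixel (\code{K} is the window element count, so a fully valid window
#' reduces exactly to the standard convolution), and exactly 0 — without
#' bias — where the window contains no valid pixel.
#'
#' @param X Input features: H x W matrix or H x W x Cin array.
#' @param M Validity mask (1 = known pixel): H x W matrix shared by all
#'   channels, or an H x W x Cin array.
#' @param W Filter weights: array \code{dim c(k, k, Cin, Cout)}.
#' @param b Bias vector of length Cout.
#' @param stride,pad Convolution stride and zero padding.
#' @return List with \code{output} (H' x W' x Cout array) and \code{mask}
#'   (H' x W' updated validity mask, 1 where any input window pixel was
#'   valid).
#' @export
partial_conv2d <- function(X, M, W, b = NULL, stride = 1L, pad = NULL) {
  X <- as_cube(X)
  k <- dim(W)[1L]
  if (dim(W)[2L] != k) stop("kernel must be square")
  Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  if (dim(X)[3L] != Cin) stop("input has ", dim(X)[3L], " channels, weights expect ", Cin)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  if (is.null(b)) b <- numeric(Cout)
  if (is.matrix(M)) {
    if (!all(dim(M) == dim(X)[1:2])) stop("mask shape mismatch")
    stopifnot_binary(M)
    groups <- list(list(mask = M, n = Cin))
  } else {
    if (!all(dim(M) == dim(X))) stop("mask shape mismatch")
    stopifnot_binary(M)
    groups <- lapply(seq_len(Cin), function(c) list(mask = M[, , c], n = 1L))
  }
  p <- list(W = t(matrix(W, k * k * Cin, Cout)), b = b, k = k,
            stride = as.integer(stride), pad = as.integer(pad))
  r <- pconv_f(X, groups, p)
  list(output = r$Y, mask = r$mask_out[[1L]]$mask)
}

#' Update a validity mask alongside a convolution
#'
#' An output pixel is valid (1) iff any input pixel covered by its
#' \code{kernel_size} x \code{kernel_size} window is valid — a binary
#' dilation with a square structuring element (for stride 1). Repeated
#' application saturates to the all-ones mask.
#'
#' @param M Binary validity mask matrix.
#' @param kernel_size Window side length.
#' @param stride,pad Stride and padding of the paired convolution; defaults
#'   keep the mask size unchanged.
#' @return The updated binary mask.
#' @export
update_mask <- function(M, kernel_size, stride = 1L,
                        pad = (kernel_size - 1L) %/% 2L) {
  stopifnot_binary(M)
  ones <- matrix(1, 1L, kernel_size * kernel_size)
  S <- conv2d_fwd(as_cube(M), ones, 0, as.integer(kernel_size),
                  as.integer(stride), as.integer(pad))
  matrix((S > 1e-9) * 1, dim(S)[1L], dim(S)[2L])
}

#' Composite a synthesized image with its real context
#'
#' \code{z = M * x + (1 - M) * xhat}: real pixels are kept wherever the
#' validity mask is 1 and generator output fills the hole.
#'
#' @param x Real image matrix.
#' @param xhat Synthesized image matrix.
#' @param M Binary validity mask.
#' @return The composite matrix.
#' @export
composite <- function(x, xhat, M) {
  if (!all(dim(x) == dim(xhat)) || !all(dim(x) == dim(M))) {
    stop("shape mismatch between image, synthesis and mask")
  }
  M * x + (1 - M) * xhat
}

# ---- generator -----------------------------------------------------------

#' Generator architecture configuration
#'
#' The generator is a U-Net of partial convolutions: \code{n_stages}
#' stride-2 encoder stages (kernel 4, padding 1, ReLU) and \code{n_stages}
#' decoder stages (nearest-neighbour 2x upsampling, skip concatenation of
#' encoder features and masks, kernel-3 partial convolution, LeakyReLU slope
#' 0.2), with batch normalisation on every convolution except the first and
#' the last, and a final sigmoid keeping outputs in [0, 1]. Channel widths
#' double per stage from \code{base_channels}, capped at
#' \code{8 * base_channels}.
#'
#' @param n_stages Encoder/decoder depth (default 8).
#' @param base_channels First-stage channel width (default 64).
#' @param input_size Expected square input side; must be divisible by
#'   \code{2^n_stages}.
#' @return A list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_stages = 8L, base_channels = 64L,
                             input_size = 256L) {
  if (n_stages < 1) stop("n_stages must be >= 1")
  if (input_size %% (2^n_stages) != 0) {
    stop("input_size ", input_size, " is not divisible by 2^", n_stages)
  }
  structure(list(n_stages = as.integer(n_stages),
                 base_channels = as.integer(base_channels),
                 input_size = as.integer(input_size),
                 channels = pmin(base_channels * 2^(seq_len(n_stages) - 1L),
                                 8L * base_channels)),
            class = "generator_config")
}

#' Build a partial-convolution U-Net generator
#'
#' @param cfg A \code{\link{generator_config}}.
#' @param seed Integer seed for He/Kaiming weight initialisation; two builds
#'   with the same config and seed are identical.
#' @return A generator object (environment with \code{cfg}, \code{params},
#'   \code{state}).
#' @export
build_generator <- function(cfg = generator_config(), seed = 1L) {
  n <- cfg$n_stages; ch <- cfg$channels
  params <- list()
  with_seed(seed, {
    for (i in seq_len(n)) {
      cin <- if (i == 1L) 1L else ch[i - 1L]
      params[[paste0("enc", i)]] <- c(he_conv(cin, ch[i], 4L),
                                      list(k = 4L, stride = 2L, pad = 1L))
      if (i > 1L) params[[paste0("encbn", i)]] <- bn_param(ch[i])
    }
    for (i in seq(n - 1L, 0L)) {
      cin <- (if (i == n - 1L) ch[n] else ch[i + 1L]) +
        (if (i == 0L) 1L else ch[i])
      cout <- if (i == 0L) 1L else ch[i]
      params[[paste0("dec", i)]] <- c(he_conv(cin, cout, 3L),
                                      list(k = 3L, stride = 1L, pad = 1L))
      if (i > 0L) params[[paste0("decbn", i)]] <- bn_param(cout)
    }
  })
  net <- new.env(parent = emptyenv())
  net$kind <- "generator"
  net$cfg <- cfg
  net$params <- params
  net$state <- new.env(parent = emptyenv())
  class(net) <- "pconv_generator"
  net
}

# Batched generator forward pass. imgs/masks: lists of H x W matrices; the
# image is multiplied by the mask on entry so masked-out pixel values can
# never influence the output. Returns outputs and (if keep_cache) all layer
# caches needed for gen_backward_batch.
gen_forward_batch <- function(net, imgs, masks, training = FALSE,
                              keep_cache = FALSE) {
  cfg <- net$cfg; n <- cfg$n_stages
  B <- length(imgs)
  hw <- dim(imgs[[1L]])
  if (hw[1L] %% (2^n) != 0 || hw[2L] %% (2^n) != 0) {
    stop("input size ", hw[1L], "x", hw[2L], " incompatible with ", n, " downsamplings")
  }
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  Xs <- vector("list", B); Gs <- vector("list", B)
  for (b in seq_len(B)) {
    Xs[[b]] <- as_cube(imgs[[b]] * masks[[b]])
    Gs[[b]] <- list(list(mask = masks[[b]], n = 1L))
  }
  E_X <- list(); E_G <- list()
  E_X[["0"]] <- Xs; E_G[["0"]] <- Gs
  for (i in seq_len(n)) {
    p <- net$params[[paste0("enc", i)]]
    pc <- lapply(seq_len(B), function(b) pconv_f(Xs[[b]], Gs[[b]], p))
    Xs <- lapply(pc, `[[`, "Y"); Gs <- lapply(pc, `[[`, "mask_out")
    if (keep_cache) cache[[paste0("enc", i, ".pc")]] <- lapply(pc, `[[`, "cache")
    if (i > 1L) {
      bn <- bn_f(Xs, net$params[[paste0("encbn", i)]], net$state,
                 paste0("encbn", i), training)
      Xs <- bn$Ys
      if (keep_cache) cache[[paste0("enc", i, ".bn")]] <- bn$cache
    }
    ac <- lapply(Xs, relu_f)
    Xs <- lapply(ac, `[[`, "Y")
    if (keep_cache) cache[[paste0("enc", i, ".act")]] <- lapply(ac, `[[`, "cache")
    E_X[[as.character(i)]] <- Xs; E_G[[as.character(i)]] <- Gs
  }
  for (i in seq(n - 1L, 0L)) {
    Xs <- lapply(Xs, up2_f); Gs <- lapply(Gs, up2_mask)
    skX <- E_X[[as.character(i)]]; skG <- E_G[[as.character(i)]]
    if (keep_cache) cache[[paste0("dec", i, ".upch")]] <- dim(Xs[[1L]])[3L]
    Xs <- lapply(seq_len(B), function(b) cube_cat(Xs[[b]], skX[[b]]))
    Gs <- lapply(seq_len(B), function(b) c(Gs[[b]], skG[[b]]))
    p <- net$params[[paste0("dec", i)]]
    pc <- lapply(seq_len(B), function(b) pconv_f(Xs[[b]], Gs[[b]], p))
    Xs <- lapply(pc, `[[`, "Y"); Gs <- lapply(pc, `[[`, "mask_out")
    if (keep_cache) cache[[paste0("dec", i, ".pc")]] <- lapply(pc, `[[`, "cache")
    if (i > 0L) {
      bn <- bn_f(Xs, net$params[[paste0("decbn", i)]], net$state,
                 paste0("decbn", i), training)
      Xs <- bn$Ys
      if (keep_cache) cache[[paste0("dec", i, ".bn")]] <- bn$cache
      ac <- lapply(Xs, lrelu_f)
      Xs <- lapply(ac, `[[`, "Y")
      if (keep_cache) cache[[paste0("dec", i, ".act")]] <- lapply(ac, `[[`, "cache")
    } else {
      ac <- lapply(Xs, sigmoid_f)
      Xs <- lapply(ac, `[[`, "Y")
      if (keep_cache) cache[[paste0("dec0.act")]] <- lapply(ac, `[[`, "cache")
    }
  }
  list(outputs = lapply(Xs, function(X) matrix(X, dim(X)[1L], dim(X)[2L])),
       cache = cache)
}

# Backward pass matching gen_forward_batch. dOuts: list of H x W gradient
# matrices. Returns grads (named list parallel to net$params).
gen_backward_batch <- function(net, cache, dOuts) {
  cfg <- net$cfg; n <- cfg$n_stages
  B <- length(dOuts)
  grads <- zero_like(net$params)
  dE <- list()  # per-stage skip gradient accumulators (lists of cubes)
  dY <- lapply(seq_len(B), function(b)
    sigmoid_b(as_cube(dOuts[[b]]), cache[["dec0.act"]][[b]]))
  for (i in seq(0L, n - 1L)) {
    nm <- paste0("dec", i)
    if (i > 0L) {
      dY <- lapply(seq_len(B), function(b)
        lrelu_b(dY[[b]], cache[[paste0(nm, ".act")]][[b]]))
      bnb <- bn_b(dY, cache[[paste0(nm, ".bn")]], net$params[[paste0("decbn", i)]])
      dY <- bnb$dXs
      grads[[paste0("decbn", i)]]$gamma <- grads[[paste0("decbn", i)]]$gamma + bnb$dgamma
      grads[[paste0("decbn", i)]]$beta <- grads[[paste0("decbn", i)]]$beta + bnb$dbeta
    }
    p <- net$params[[nm]]
    upch <- cache[[paste0(nm, ".upch")]]
    dUp <- vector("list", B); dSkip <- vector("list", B)
    for (b in seq_len(B)) {
      pb <- pconv_b(dY[[b]], cache[[paste0(nm, ".pc")]][[b]], p)
      grads[[nm]]$W <- grads[[nm]]$W + pb$dW
      grads[[nm]]$b <- grads[[nm]]$b + pb$db
      dUp[[b]] <- up2_b(pb$dX[, , seq_len(upch), drop = FALSE])
      dSkip[[b]] <- pb$dX[, , -seq_len(upch), drop = FALSE]
    }
    dE[[as.character(i)]] <- dSkip
    dY <- dUp  # gradient at the activation output of the next-deeper stage
  }
  # dY now holds the gradient at encoder stage n's activation output
  dCur <- dY
  for (i in seq(n, 1L)) {
    if (!is.null(dE[[as.character(i)]])) {
      dCur <- lapply(seq_len(B), function(b) dCur[[b]] + dE[[as.character(i)]][[b]])
    }
    dCur <- lapply(seq_len(B), function(b)
      relu_b(dCur[[b]], cache[[paste0("enc", i, ".act")]][[b]]))
    if (i > 1L) {
      bnb <- bn_b(dCur, cache[[paste0("enc", i, ".bn")]], net$params[[paste0("encbn", i)]])
      dCur <- bnb$dXs
      grads[[paste0("encbn", i)]]$gamma <- grads[[paste0("encbn", i)]]$gamma + bnb$dgamma
      grads[[paste0("encbn", i)]]$beta <- grads[[paste0("encbn", i)]]$beta + bnb$dbeta
    }
    p <- net$params[[paste0("enc", i)]]
    dPrev <- vector("list", B)
    for (b in seq_len(B)) {
      pb <- pconv_b(dCur[[b]], cache[[paste0("enc", i, ".pc")]][[b]], p)
      grads[[paste0("enc", i)]]$W <- grads[[paste0("enc", i)]]$W + pb$dW
      grads[[paste0("enc", i)]]$b <- grads[[paste0("enc", i)]]$b + pb$db
      dPrev[[b]] <- pb$dX
    }
    dCur <- dPrev
  }
  grads
}

#' Run the generator on a masked slice
#'
#' @param gen A generator from \code{\link{build_generator}}.
#' @param masked List with \code{image} (H x W matrix, hole pixels are
#'   ignored — the image is multiplied by the mask internally) and
#'   \code{mask} (binary validity matrix, 0 marks the lesion hole).
#' @return The synthesized H x W image matrix.
#' @export
generator_forward <- function(gen, masked) {
  r <- gen_forward_batch(gen, list(masked$image), list(masked$mask),
                         training = FALSE)
  r$outputs[[1L]]
}

# ---- lesion patch cropping ----------------------------------------------

#' Crop a patch centred on a randomly selected lesion
#'
#' Selects one connected lesion component uniformly at random and crops a
#' \code{size} x \code{size} window centred on its centroid, clamped to the
#' image bounds (zero-padded if the image is smaller than the window).
#'
#' @param image H x W matrix.
#' @param lesion_mask Nonempty binary matrix of lesion pixels.
#' @param size Patch side length (default 64).
#' @param seed Integer seed for the component selection.
#' @return List with \code{patch}, \code{lesion} (patch-level lesion mask),
#'   and the window origin \code{r0}, \code{c0} (0-based, in image
#'   coordinates) plus index maps used to paste gradients back.
#' @export
crop_lesion_patch <- function(image, lesion_mask, size = 64L, seed = 1L) {
  if (!any(lesion_mask == 1)) stop("lesion mask is empty")
  lab <- label_components((lesion_mask > 0) * 1L)
  k <- max(lab)
  pick <- with_seed(seed, sample.int(k, 1L))
  h <- nrow(image); w <- ncol(image)
  rows <- row(lab)[lab == pick]; cols <- col(lab)[lab == pick]
  cr <- mean(rows); cc <- mean(cols)
  r0 <- round(cr - size / 2); c0 <- round(cc - size / 2)
  r0 <- min(max(r0, 0L), max(h - size, 0L))
  c0 <- min(max(c0, 0L), max(w - size, 0L))
  patch <- matrix(0, size, size)
  lpatch <- matrix(0, size, size)
  rs <- seq_len(min(size, h - r0)); cs <- seq_len(min(size, w - c0))
  patch[rs, cs] <- image[r0 + rs, c0 + cs]
  lpatch[rs, cs] <- (lab[r0 + rs, c0 + cs] == pick) * 1
  list(patch = patch, lesion = lpatch, r0 = r0, c0 = c0,
       rows = rs, cols = cs, component = pick)
}

# ---- discriminator (Wasserstein critic) ---------------------------------

#' Critic architecture configuration
#'
#' Four convolutional layers: the first three have kernel 4, stride 2,
#' padding 1 (64 -> 32 -> 16 -> 8) with LeakyReLU(0.2); the last maps the
#' 8 x 8 field to a single scalar score (no sigmoid — Wasserstein critic).
#' Spectral normalisation is applied to the intermediate convolutional
#' layers. \code{mask_input} multiplies the input patch by its lesion
#' indicator so the critic scores the lesion region only.
#'
#' @param input_size Patch side length (default 64; must be divisible by 8).
#' @param base_channels First-layer channel width.
#' @param sn_layers Indices of layers receiving spectral normalisation.
#' @param mask_input Whether patches are multiplied by the lesion indicator.
#' @return A list of class \code{"discriminator_config"}.
#' @export
discriminator_config <- function(input_size = 64L, base_channels = 64L,
                                 sn_layers = 1:3, mask_input = TRUE) {
  if (input_size %% 8L != 0L) stop("input_size must be divisible by 8")
  structure(list(input_size = as.integer(input_size), n_layers = 4L,
                 kernel = 4L, stride = 2L, pad = 1L,
                 base_channels = as.integer(base_channels),
                 sn_layers = sn_layers, mask_input = mask_input),
            class = "discriminator_config")
}

#' Build the critic network
#'
#' @param cfg A \code{\link{discriminator_config}}.
#' @param seed Integer seed for weight initialisation.
#' @return A critic object (environment).
#' @export
build_discriminator <- function(cfg = discriminator_config(), seed = 1L) {
  ch <- cfg$base_channels * c(1L, 2L, 4L)
  params <- list()
  state <- new.env(parent = emptyenv())
  with_seed(seed, {
    cin <- 1L
    for (l in 1:3) {
      params[[paste0("conv", l)]] <- c(he_conv(cin, ch[l], 4L),
                                       list(k = 4L, stride = 2L, pad = 1L))
      cin <- ch[l]
    }
    kf <- cfg$input_size %/% 8L
    params[["conv4"]] <- c(he_conv(cin, 1L, kf),
                           list(k = kf, stride = 1L, pad = 0L))
    for (l in cfg$sn_layers) {
      u0 <- rnorm(nrow(params[[paste0("conv", l)]]$W))
      state[[paste0("snu", l)]] <- u0 / sqrt(sum(u0^2))
    }
  })
  net <- new.env(parent = emptyenv())
  net$kind <- "discriminator"
  net$cfg <- cfg
  net$params <- params
  net$state <- state
  class(net) <- "pconv_discriminator"
  # settle the power-iteration vectors on the initial weights
  for (i in 1:30) disc_effective_weights(net, update = TRUE)
  net
}

# Spectral-norm effective weights for each layer; update = TRUE runs one
# power iteration (training); update = FALSE reuses the stored u (inference,
# deterministic).
disc_effective_weights <- function(net, update = FALSE) {
  eff <- vector("list", 4L)
  for (l in 1:4) {
    p <- net$params[[paste0("conv", l)]]
    if (l %in% net$cfg$sn_layers) {
      u <- net$state[[paste0("snu", l)]]
      sp <- sn_power(p$W, u, iters = 1L)
      if (update) net$state[[paste0("snu", l)]] <- sp$u
      if (abs(sp$sigma) < 1e-12) {
        eff[[l]] <- list(Wbar = p$W, sn = NULL, p = p)  # degenerate zero layer
      } else {
        eff[[l]] <- list(Wbar = p$W / sp$sigma, sn = sp, p = p)
      }
    } else {
      eff[[l]] <- list(Wbar = p$W, sn = NULL, p = p)
    }
  }
  eff
}

# Forward pass of one patch cube (input_size^2 x 1). Returns score and the
# caches needed for both parameter gradients and input gradients.
disc_forward_cached <- function(net, X, eff) {
  acts <- list(X)   # inputs to each layer
  lmask <- list()   # LeakyReLU derivative multipliers
  for (l in 1:3) {
    p <- eff[[l]]$p
    Z <- conv2d_fwd(acts[[l]], eff[[l]]$Wbar, p$b, p$k, p$stride, p$pad)
    a <- lrelu_f(Z)
    lmask[[l]] <- a$cache
    acts[[l + 1L]] <- a$Y
  }
  p4 <- eff[[4L]]$p
  out <- conv2d_fwd(acts[[4L]], eff[[4L]]$Wbar, p4$b, p4$k, p4$stride, p4$pad)
  list(score = as.numeric(out)[1L], acts = acts, lmask = lmask)
}

# Backprop a scalar cotangent through the critic: returns per-layer
# gradients on the *effective* weights plus the input gradient.
disc_backward_cached <- function(net, fc, eff, dscore) {
  dWbar <- vector("list", 4L); db <- vector("list", 4L)
  dY <- array(dscore, dim = c(1L, 1L, 1L))
  p4 <- eff[[4L]]$p
  gw <- conv2d_bwd_weight(fc$acts[[4L]], dY, p4$k, p4$stride, p4$pad)
  dWbar[[4L]] <- gw$dW; db[[4L]] <- as.numeric(gw$db)
  dX <- conv2d_bwd_input(dY, eff[[4L]]$Wbar, dim(fc$acts[[4L]])[1L],
                         dim(fc$acts[[4L]])[2L], dim(fc$acts[[4L]])[3L],
                         p4$k, p4$stride, p4$pad)
  for (l in 3:1) {
    dX <- lrelu_b(dX, fc$lmask[[l]])
    p <- eff[[l]]$p
    gw <- conv2d_bwd_weight(fc$acts[[l]], dX, p$k, p$stride, p$pad)
    dWbar[[l]] <- gw$dW; db[[l]] <- as.numeric(gw$db)
    dX <- conv2d_bwd_input(dX, eff[[l]]$Wbar, dim(fc$acts[[l]])[1L],
                           dim(fc$acts[[l]])[2L], dim(fc$acts[[l]])[3L],
                           p$k, p$stride, p$pad)
  }
  list(dWbar = dWbar, db = db, dInput = dX)
}

# Gradient of s = <g, v> with respect to the effective weights, where
# g = d score / d input. Because the critic is piecewise linear, s equals
# the forward pass of v through the linearised network (activation
# multipliers frozen), in which each weight appears exactly once; its
# weight gradients follow from a standard backward pass over that chain.
# Biases do not enter g. Used for the WGAN-GP penalty gradient.
disc_gp_weight_grad <- function(net, fc, eff, v) {
  ts <- list(v)
  for (l in 1:3) {
    p <- eff[[l]]$p
    U <- conv2d_fwd(ts[[l]], eff[[l]]$Wbar, numeric(nrow(eff[[l]]$Wbar)),
                    p$k, p$stride, p$pad)
    ts[[l + 1L]] <- U * fc$lmask[[l]]
  }
  p4 <- eff[[4L]]$p
  s <- as.numeric(conv2d_fwd(ts[[4L]], eff[[4L]]$Wbar, numeric(1L),
                             p4$k, p4$stride, p4$pad))[1L]
  dWbar <- vector("list", 4L)
  dY <- array(1, dim = c(1L, 1L, 1L))
  gw <- conv2d_bwd_weight(ts[[4L]], dY, p4$k, p4$stride, p4$pad)
  dWbar[[4L]] <- gw$dW
  dX <- conv2d_bwd_input(dY, eff[[4L]]$Wbar, dim(ts[[4L]])[1L], dim(ts[[4L]])[2L],
                         dim(ts[[4L]])[3L], p4$k, p4$stride, p4$pad)
  for (l in 3:1) {
    dX <- dX * fc$lmask[[l]]
    p <- eff[[l]]$p
    gw <- conv2d_bwd_weight(ts[[l]], dX, p$k, p$stride, p$pad)
    dWbar[[l]] <- gw$dW
    dX <- conv2d_bwd_input(dX, eff[[l]]$Wbar, dim(ts[[l]])[1L], dim(ts[[l]])[2L],
                           dim(ts[[l]])[3L], p$k, p$stride, p$pad)
  }
  list(dWbar = dWbar, s = s)
}

# Map effective-weight gradients back through spectral normalisation and
# accumulate into a grads tree parallel to net$params.
disc_accumulate_grads <- function(net, eff, grads, dWbar, db = NULL) {
  for (l in 1:4) {
    nm <- paste0("conv", l)
    g <- dWbar[[l]]
    if (!is.null(eff[[l]]$sn)) {
      sp <- eff[[l]]$sn
      g <- sn_grad(g, eff[[l]]$Wbar, sp$u, sp$v, sp$sigma)
    }
    grads[[nm]]$W <- grads[[nm]]$W + g
    if (!is.null(db)) grads[[nm]]$b <- grads[[nm]]$b + db[[l]]
  }
  grads
}

#' Score a patch with the critic
#'
#' @param disc A critic from \code{\link{build_discriminator}}.
#' @param patch \code{input_size} x \code{input_size} matrix (multiply by
#'   the lesion indicator beforehand if \code{mask_input} semantics are
#'   wanted; \code{\link{gan_losses}} does this for you).
#' @return A single numeric score (unbounded; no sigmoid).
#' @export
discriminator_forward <- function(disc, patch) {
  sz <- disc$cfg$input_size
  if (!is.matrix(patch) || nrow(patch) != sz || ncol(patch) != sz) {
    stop("patch must be ", sz, " x ", sz)
  }
  eff <- disc_effective_weights(disc, update = FALSE)
  disc_forward_cached(disc, as_cube(patch), eff)$score
}

# ---- checkpointing -------------------------------------------------------

#' Save or load a network checkpoint
#'
#' A single-file checkpoint embedding the architecture config, all
#' parameters and persistent state (batch-norm running statistics, spectral
#' norm power-iteration vectors).
#'
#' @param net A generator, critic, or segmentation network.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(kind = net$kind, cfg = net$cfg, params = net$params,
               state = as.list(net$state)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  d <- readRDS(path)
  net <- new.env(parent = emptyenv())
  net$kind <- d$kind
  net$cfg <- d$cfg
  net$params <- d$params
  net$state <- list2env(d$state, new.env(parent = emptyenv()))
  class(net) <- switch(d$kind,
                       generator = "pconv_generator",
                       discriminator = "pconv_discriminator",
                       unet = "seg_unet")
  net
}
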