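# Loss terms for adversarial lesion-texture synthesis: weighted L1
# reconstruction, Wasserstein GAN with gradient penalty, perceptual and
# Gram-matrix texture losses, and their weighted total.

#' Loss weights for synthesis training
#'
#' Defaults follow the tuned values: reconstruction 1, perceptual 0.05,
#' texture 100; healthy-tissue weight \code{w1 = 1} versus lesion weight
#' \code{w2 = 5} inside the reconstruction term; gradient-penalty
#' coefficient 10 (the WGAN-GP standard).
#'
#' @param reconstruction,perceptual,texture Term weights in the total loss.
#' @param w1,w2 Healthy/lesion pixel weights inside the reconstruction loss.
#' @param gp Gradient-penalty coefficient.
#' @return A list of class \code{"loss_weights"}.
#' @export
loss_weights <- function(reconstruction = 1, perceptual = 0.05, texture = 100,
                         w1 = 1, w2 = 5, gp = 10) {
  w <- list(reconstruction = reconstruction, perceptual = perceptual,
            texture = texture, w1 = w1, w2 = w2, gp = gp)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' Weighted L1 reconstruction loss
#'
#' \code{w1 * |M (x - xhat)|_1 + w2 * |(1 - M)(x - xhat)|_1}: the lesion
#' hole (\code{M = 0}) is weighted \code{w2}, healthy context \code{w1}.
#'
#' @param x Real image matrix.
#' @param xhat Synthesized image matrix.
#' @param M Binary validity mask (1 = healthy).
#' @param w1,w2 Healthy/lesion weights.
#' @param reduction \code{"mean"} (default; L1 sums divided by the pixel
#'   count) or \code{"sum"}.
#' @return A single non-negative number.
#' @export
reconstruction_loss <- function(x, xhat, M, w1 = 1, w2 = 5,
                                reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!all(dim(x) == dim(xhat)) || !all(dim(x) == dim(M))) stop("shape mismatch")
  stopifnot_binary(M)
  d <- abs(x - xhat)
  val <- w1 * sum(M * d) + w2 * sum((1 - M) * d)
  if (reduction == "mean") val / length(x) else val
}

# Gradient of the reconstruction loss with respect to xhat.
reconstruction_loss_grad <- function(x, xhat, M, w1 = 1, w2 = 5,
                                     reduction = "mean") {
  g <- -(w1 * M + w2 * (1 - M)) * sign(x - xhat)
  if (reduction == "mean") g / length(x) else g
}

#' Gram matrix of a feature map
#'
#' \code{G = F F' / (C * H * W)} where \code{F} is the C x (H*W) unfolding
#' of the feature cube; symmetric positive semidefinite.
#'
#' @param feature H x W x C array (a matrix is treated as C = 1).
#' @return A C x C matrix.
#' @export
gram_matrix <- function(feature) {
  feature <- as_cube(feature)
  d <- dim(feature)
  F <- t(matrix(feature, d[1L] * d[2L], d[3L]))  # C x (H*W)
  (F %*% t(F)) / prod(d)
}

# d(loss)/dF given d(loss)/dG: dF = (dG + dG') F / (C*H*W), reshaped back.
gram_matrix_grad <- function(feature, dG) {
  d <- dim(feature)
  F <- t(matrix(feature, d[1L] * d[2L], d[3L]))
  dF <- (dG + t(dG)) %*% F / prod(d)
  array(t(dF), dim = d)
}

#' Perceptual loss over extractor feature maps
#'
#' Sum over the selected layers of
#' \code{(1/N_i) * (|Phi_i(xhat) - Phi_i(x)|_1 + |Phi_i(z) - Phi_i(x)|_1)},
#' averaged over the batch, where \code{z} is the composite of real context
#' and synthesized hole and \code{N_i} the element count of layer i's
#' feature map.
#'
#' @param xhat,x,z Image matrices (or lists of matrices for a batch).
#' @param phi A \code{"feature_extractor"}.
#' @return A single non-negative number.
#' @export
perceptual_loss <- function(xhat, x, z, phi = identity_extractor()) {
  if (!is.list(xhat)) { xhat <- list(xhat); x <- list(x); z <- list(z) }
  tot <- 0
  for (b in seq_along(xhat)) {
    fh <- fx_forward(phi, xhat[[b]])$feats
    fx <- fx_forward(phi, x[[b]])$feats
    fz <- fx_forward(phi, z[[b]])$feats
    for (i in seq_along(fh)) {
      Ni <- length(fh[[i]])
      tot <- tot + (sum(abs(fh[[i]] - fx[[i]])) + sum(abs(fz[[i]] - fx[[i]]))) / Ni
    }
  }
  tot / length(xhat)
}

#' Texture loss over Gram matrices of feature maps
#'
#' Same structure as \code{\link{perceptual_loss}} but distances are taken
#' between Gram matrices of each selected layer's features, making the loss
#' invariant to pixel position and sensitive only to feature
#' autocorrelation.
#'
#' @inheritParams perceptual_loss
#' @return A single non-negative number.
#' @export
texture_loss <- function(xhat, x, z, phi = identity_extractor()) {
  if (!is.list(xhat)) { xhat <- list(xhat); x <- list(x); z <- list(z) }
  tot <- 0
  for (b in seq_along(xhat)) {
    fh <- fx_forward(phi, xhat[[b]])$feats
    fx <- fx_forward(phi, x[[b]])$feats
    fz <- fx_forward(phi, z[[b]])$feats
    for (i in seq_along(fh)) {
      Ni <- length(fh[[i]])
      Gh <- gram_matrix(fh[[i]]); Gx <- gram_matrix(fx[[i]]); Gz <- gram_matrix(fz[[i]])
      tot <- tot + (sum(abs(Gh - Gx)) + sum(abs(Gz - Gx))) / Ni
    }
  }
  tot / length(xhat)
}

# Gradients of perceptual + texture losses (jointly, for one sample) with
# respect to xhat and z. Weighted by lambda_p and lambda_t. Returns the two
# image-gradient matrices and the two loss values.
perc_tex_grads <- function(xhat, x, z, phi, lambda_p, lambda_t) {
  ch <- fx_forward(phi, xhat, keep_cache = TRUE)
  cz <- fx_forward(phi, z, keep_cache = TRUE)
  fx <- fx_forward(phi, x)$feats
  dFh <- vector("list", length(ch$feats))
  dFz <- vector("list", length(ch$feats))
  lp <- 0; lt <- 0
  for (i in seq_along(ch$feats)) {
    Ni <- length(ch$feats[[i]])
    dh <- ch$feats[[i]] - fx[[i]]
    dz <- cz$feats[[i]] - fx[[i]]
    lp <- lp + (sum(abs(dh)) + sum(abs(dz))) / Ni
    gh <- lambda_p * sign(dh) / Ni
    gz <- lambda_p * sign(dz) / Ni
    Gh <- gram_matrix(ch$feats[[i]]); Gx <- gram_matrix(fx[[i]])
    Gz <- gram_matrix(cz$feats[[i]])
    lt <- lt + (sum(abs(Gh - Gx)) + sum(abs(Gz - Gx))) / Ni
    gh <- gh + lambda_t * gram_matrix_grad(ch$feats[[i]], sign(Gh - Gx) / Ni)
    gz <- gz + lambda_t * gram_matrix_grad(cz$feats[[i]], sign(Gz - Gx) / Ni)
    dFh[[i]] <- gh
    dFz[[i]] <- gz
  }
  list(dxhat = fx_backward(phi, ch$cache, dFh),
       dz = fx_backward(phi, cz$cache, dFz),
       perceptual = lp, texture = lt)
}

#' Wasserstein GAN losses with gradient penalty
#'
#' The critic maximises \code{E[D(real)] - E[D(fake)] - gp * Gp}; the
#' generator minimises \code{-E[D(fake)]}. The penalty
#' \code{Gp = E[(|grad_u D(u)|_2 - 1)^2]} is evaluated at per-sample random
#' interpolates \code{u = e*real + (1-e)*fake}, \code{e ~ U[0,1]}.
#'
#' @param disc A critic from \code{\link{build_discriminator}}.
#' @param real_patches,fake_patches Lists of patch matrices (already
#'   multiplied by the lesion indicator when \code{mask_input} semantics are
#'   in use).
#' @param lambda_gp Penalty coefficient.
#' @param seed Seed for the interpolation draws.
#' @return List with \code{critic_loss} (to minimise),
#'   \code{gen_adv_loss}, \code{gp} (mean penalty), and the mean real/fake
#'   scores.
#' @export
gan_losses <- function(disc, real_patches, fake_patches, lambda_gp = 10,
                       seed = 1L) {
  if (!length(real_patches) || !length(fake_patches)) stop("empty patch batch")
  eff <- disc_effective_weights(disc, update = FALSE)
  sr <- vapply(real_patches, function(p)
    disc_forward_cached(disc, as_cube(p), eff)$score, 0)
  sf <- vapply(fake_patches, function(p)
    disc_forward_cached(disc, as_cube(p), eff)$score, 0)
  if (!all(is.finite(c(sr, sf)))) stop("non-finite critic scores")
  gp <- gradient_penalty(disc, real_patches, fake_patches, seed = seed)
  obj <- mean(sr) - mean(sf) - lambda_gp * gp
  list(critic_loss = -obj, gen_adv_loss = -mean(sf), gp = gp,
       real_score = mean(sr), fake_score = mean(sf))
}

#' Gradient penalty of the critic
#'
#' @inheritParams gan_losses
#' @return The mean squared deviation of the critic's input-gradient norm
#'   from 1 at random interpolates.
#' @export
gradient_penalty <- function(disc, real_patches, fake_patches, seed = 1L) {
  n <- min(length(real_patches), length(fake_patches))
  eff <- disc_effective_weights(disc, update = FALSE)
  eps <- with_seed(seed, runif(n))
  gp <- 0
  for (i in seq_len(n)) {
    u <- eps[i] * real_patches[[i]] + (1 - eps[i]) * fake_patches[[i]]
    fc <- disc_forward_cached(disc, as_cube(u), eff)
    g <- disc_backward_cached(disc, fc, eff, 1)$dInput
    gp <- gp + (sqrt(sum(g^2)) - 1)^2
  }
  gp / n
}

#' Total synthesis loss
#'
#' \code{L = L_GAN + lambda_rec * L_rec + lambda_perc * L_perc +
#' lambda_tex * L_tex} with the default weights (1, 0.05, 100).
#'
#' @param components List with \code{gan}, \code{reconstruction},
#'   \code{perceptual}, \code{texture}.
#' @param weights A \code{\link{loss_weights}}.
#' @return The weighted sum.
#' @export
total_loss <- function(components, weights = loss_weights()) {
  v <- c(components$gan, components$reconstruction, components$perceptual,
         components$texture)
  if (!all(is.finite(v))) {
    bad <- c("gan", "reconstruction", "perceptual", "texture")[!is.finite(v)]
    stop("non-finite loss component: ", paste(bad, collapse = ", "))
  }
  components$gan + weights$reconstruction * components$reconstruction +
    weights$perceptual * components$perceptual +
    weights$texture * components$texture
}
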