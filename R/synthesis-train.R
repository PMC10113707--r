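# Adversarial training of the lesion-texture generator and inference-time
# synthesis of new labelled lesions.

#' Synthesis training configuration
#'
#' Defaults follow the tuned protocol: AMSGrad with beta1 = 0.5,
#' beta2 = 0.999, generator learning rate 1e-4, critic learning rate 1e-5,
#' batch size 6. The epoch default is deliberately small — pass
#' \code{epochs = 800} to reproduce a full-scale run — and \code{steps}
#' overrides epochs for step-budgeted experiments. One critic step is taken
#' per generator step (both are updated from the same forward pass);
#' \code{d_steps_per_g} raises the ratio.
#'
#' @param gen A \code{\link{generator_config}}.
#' @param disc A \code{\link{discriminator_config}}.
#' @param weights A \code{\link{loss_weights}}.
#' @param extractor A \code{"feature_extractor"} for the perceptual and
#'   texture losses.
#' @param batch_size,epochs,steps Training budget; \code{steps} wins if set.
#' @param lr_generator,lr_discriminator,beta1,beta2 AMSGrad hyperparameters.
#' @param d_steps_per_g Critic updates per generator update.
#' @param composite_fake Whether critic fake patches are cropped from the
#'   composite \code{z} (real context, synthesized hole) rather than the
#'   raw generator output.
#' @param checkpoint_every,checkpoint_dir Checkpoint cadence (steps) and
#'   target directory (NULL disables checkpoints).
#' @param seed Root seed; every random draw in training derives from it.
#' @return A list of class \code{"synthesis_config"}.
#' @export
synthesis_config <- function(gen = generator_config(),
                             disc = discriminator_config(),
                             weights = loss_weights(),
                             extractor = random_conv_extractor(),
                             batch_size = 6L, epochs = 5L, steps = NULL,
                             lr_generator = 1e-4, lr_discriminator = 1e-5,
                             beta1 = 0.5, beta2 = 0.999,
                             d_steps_per_g = 1L, composite_fake = TRUE,
                             checkpoint_every = Inf, checkpoint_dir = NULL,
                             seed = 1L) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (lr_generator <= 0 || lr_discriminator <= 0) stop("learning rates must be positive")
  structure(list(gen = gen, disc = disc, weights = weights,
                 extractor = extractor, batch_size = as.integer(batch_size),
                 epochs = epochs, steps = steps,
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 beta1 = beta1, beta2 = beta2,
                 d_steps_per_g = as.integer(d_steps_per_g),
                 composite_fake = composite_fake,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir, seed = seed),
            class = "synthesis_config")
}

# Normalise dataset entries to list(image, lesion_mask).
as_masked_slice <- function(s) {
  if (inherits(s, "phantom_slice")) {
    list(image = s$image, lesion_mask = (s$lesion_label_map > 0) * 1)
  } else {
    list(image = s$image, lesion_mask = (s$lesion_mask > 0) * 1)
  }
}

#' Train the lesion-texture synthesis GAN
#'
#' Per step: a batch of slices is drawn; the real lesion regions are masked
#' out; the generator inpaints them; the critic scores real versus
#' synthesized lesion patches (64 x 64 windows centred on a randomly chosen
#' lesion, multiplied by the lesion indicator); and both networks are
#' updated from the same forward pass with their own AMSGrad optimisers.
#' The full loss trajectory is recorded per step.
#'
#' @param dataset List of slices, each a \code{phantom_slice} or a list
#'   with \code{image} and \code{lesion_mask}; every slice must contain at
#'   least one lesion (training masks are the ground-truth delineations).
#' @param cfg A \code{\link{synthesis_config}}.
#' @return List with \code{generator}, \code{discriminator} and
#'   \code{history} (one row per step: total, adversarial, reconstruction,
#'   perceptual, texture, critic).
#' @export
train_synthesis <- function(dataset, cfg = synthesis_config()) {
  slices <- lapply(dataset, as_masked_slice)
  if (!length(slices)) stop("empty dataset")
  for (i in seq_along(slices)) {
    if (!any(slices[[i]]$lesion_mask == 1)) {
      stop("slice ", i, " has no lesion; synthesis training requires lesion masks")
    }
  }
  n <- length(slices)
  n_steps <- if (!is.null(cfg$steps)) cfg$steps
             else max(1L, ceiling(cfg$epochs * n / cfg$batch_size))
  gen <- build_generator(cfg$gen, seed = substream_seed(cfg$seed, "gen-init"))
  disc <- build_discriminator(cfg$disc, seed = substream_seed(cfg$seed, "disc-init"))
  opt_g <- amsgrad_new(gen$params, cfg$lr_generator, cfg$beta1, cfg$beta2)
  opt_d <- amsgrad_new(disc$params, cfg$lr_discriminator, cfg$beta1, cfg$beta2)
  lw <- cfg$weights
  psz <- disc$cfg$input_size
  hist <- matrix(NA_real_, n_steps, 6L,
                 dimnames = list(NULL, c("total", "adversarial", "reconstruction",
                                         "perceptual", "texture", "critic")))
  for (t in seq_len(n_steps)) {
    st_seed <- substream_seed(cfg$seed, paste0("step", t))
    idx <- with_seed(st_seed, sample.int(n, cfg$batch_size, replace = cfg$batch_size > n))
    xs <- lapply(slices[idx], `[[`, "image")
    Ls <- lapply(slices[idx], `[[`, "lesion_mask")
    Ms <- lapply(Ls, function(L) 1 - L)
    B <- length(xs)

    fw <- gen_forward_batch(gen, xs, Ms, training = TRUE, keep_cache = TRUE)
    xhat <- fw$outputs
    zs <- lapply(seq_len(B), function(b) composite(xs[[b]], xhat[[b]], Ms[[b]]))

    crops <- lapply(seq_len(B), function(b)
      crop_lesion_patch(xs[[b]], Ls[[b]], psz, seed = substream_seed(st_seed, paste0("crop", b))))
    srcs <- if (cfg$composite_fake) zs else xhat
    real_p <- vector("list", B); fake_p <- vector("list", B)
    for (b in seq_len(B)) {
      cp <- crops[[b]]
      ind <- if (disc$cfg$mask_input) cp$lesion else 1
      real_p[[b]] <- cp$patch * ind
      fp <- matrix(0, psz, psz)
      fp[cp$rows, cp$cols] <- srcs[[b]][cp$r0 + cp$rows, cp$c0 + cp$cols]
      fake_p[[b]] <- fp * ind
    }

    # ---- critic gradients (WGAN-GP) ----
    for (dstep in seq_len(cfg$d_steps_per_g)) {
      eff <- disc_effective_weights(disc, update = TRUE)
      gd <- zero_like(disc$params)
      sr <- numeric(B); sf <- numeric(B); gp <- 0
      eps <- with_seed(substream_seed(st_seed, paste0("gp", dstep)), runif(B))
      for (b in seq_len(B)) {
        fc_r <- disc_forward_cached(disc, as_cube(real_p[[b]]), eff)
        bk_r <- disc_backward_cached(disc, fc_r, eff, -1 / B)
        gd <- disc_accumulate_grads(disc, eff, gd, bk_r$dWbar, bk_r$db)
        sr[b] <- fc_r$score
        fc_f <- disc_forward_cached(disc, as_cube(fake_p[[b]]), eff)
        bk_f <- disc_backward_cached(disc, fc_f, eff, 1 / B)
        gd <- disc_accumulate_grads(disc, eff, gd, bk_f$dWbar, bk_f$db)
        sf[b] <- fc_f$score
        u <- eps[b] * real_p[[b]] + (1 - eps[b]) * fake_p[[b]]
        fc_u <- disc_forward_cached(disc, as_cube(u), eff)
        g <- disc_backward_cached(disc, fc_u, eff, 1)$dInput
        gn <- sqrt(sum(g^2))
        gp <- gp + (gn - 1)^2 / B
        coef <- lw$gp * 2 * (gn - 1) / max(gn, 1e-12) / B
        jg <- disc_gp_weight_grad(disc, fc_u, eff, g)
        gd <- disc_accumulate_grads(disc, eff, gd,
                                    lapply(jg$dWbar, function(w) coef * w))
      }
      critic_loss <- mean(sf) - mean(sr) + lw$gp * gp
      if (!is.finite(critic_loss)) stop("non-finite loss component: critic (step ", t, ")")
      disc$params <- amsgrad_step(opt_d, disc$params, gd)
    }

    # ---- generator gradients ----
    eff <- disc_effective_weights(disc, update = FALSE)
    dxhat <- vector("list", B)
    rec <- 0; perc <- 0; tex <- 0; adv <- 0
    for (b in seq_len(B)) {
      rec <- rec + reconstruction_loss(xs[[b]], xhat[[b]], Ms[[b]], lw$w1, lw$w2) / B
      dx <- lw$reconstruction *
        reconstruction_loss_grad(xs[[b]], xhat[[b]], Ms[[b]], lw$w1, lw$w2) / B
      pt <- perc_tex_grads(xhat[[b]], xs[[b]], zs[[b]], cfg$extractor,
                           lw$perceptual, lw$texture)
      perc <- perc + pt$perceptual / B
      tex <- tex + pt$texture / B
      dz <- pt$dz / B
      dx <- dx + pt$dxhat / B
      # adversarial: d(-mean sf)/d fake patch -> paste back into z (or xhat)
      fc_f <- disc_forward_cached(disc, as_cube(fake_p[[b]]), eff)
      adv <- adv - fc_f$score / B
      dpatch <- disc_backward_cached(disc, fc_f, eff, -1 / B)$dInput
      dpm <- matrix(dpatch, psz, psz)
      if (disc$cfg$mask_input) dpm <- dpm * crops[[b]]$lesion
      cp <- crops[[b]]
      dsrc <- matrix(0, nrow(xs[[b]]), ncol(xs[[b]]))
      dsrc[cp$r0 + cp$rows, cp$c0 + cp$cols] <- dpm[cp$rows, cp$cols]
      if (cfg$composite_fake) dz <- dz + dsrc else dx <- dx + dsrc
      # chain z -> xhat through the composite
      dx <- dx + dz * (1 - Ms[[b]])
      dxhat[[b]] <- dx
    }
    comp <- list(gan = adv, reconstruction = rec, perceptual = perc, texture = tex)
    tot <- total_loss(comp, lw)
    gg <- gen_backward_batch(gen, fw$cache, dxhat)
    if (!tree_finite(gg)) stop("non-finite loss component: generator gradient (step ", t, ")")
    gen$params <- amsgrad_step(opt_g, gen$params, gg)

    hist[t, ] <- c(tot, adv, rec, perc, tex, critic_loss)
    if (is.finite(cfg$checkpoint_every) && !is.null(cfg$checkpoint_dir) &&
        t %% cfg$checkpoint_every == 0L) {
      save_checkpoint(gen, file.path(cfg$checkpoint_dir, sprintf("gen_%06d.rds", t)))
      save_checkpoint(disc, file.path(cfg$checkpoint_dir, sprintf("disc_%06d.rds", t)))
    }
  }
  list(generator = gen, discriminator = disc, history = as.data.frame(hist))
}

#' Paint synthetic lesions into healthy tissue
#'
#' For each slice, the supplied new-lesion mask is removed from the validity
#' mask, the generator inpaints the hole, and (by default) the output is
#' composited so every pixel outside the new lesion is bit-identical to the
#' input. The mask doubles as the segmentation label of the synthetic
#' lesion.
#'
#' @param generator A trained generator.
#' @param slices List of \code{phantom_slice} objects (or lists with
#'   \code{image} and optionally \code{lesion_mask} of existing lesions).
#' @param masks List of binary masks of new lesions, one per slice, each
#'   disjoint from the slice's existing lesions (see
#'   \code{\link{place_mask}}).
#' @param composite_output If TRUE (default) pixels outside the new lesion
#'   are exactly the input pixels.
#' @return List of lists with \code{image} (synthetic slice) and
#'   \code{label} (the new-lesion mask).
#' @export
synthesize_lesions <- function(generator, slices, masks,
                               composite_output = TRUE) {
  if (length(slices) != length(masks)) stop("need one mask per slice")
  out <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    s <- if (inherits(slices[[i]], "phantom_slice") ||
             !is.null(slices[[i]]$image)) slices[[i]] else list(image = slices[[i]])
    existing <- if (!is.null(s$lesion_label_map)) (s$lesion_label_map > 0) * 1
                else if (!is.null(s$lesion_mask)) (s$lesion_mask > 0) * 1
                else 0 * s$image
    L <- (masks[[i]] > 0) * 1
    if (any(L == 1 & existing == 1)) {
      stop("mask ", i, " overlaps an existing lesion")
    }
    if (!any(L == 1)) {
      out[[i]] <- list(image = s$image, label = L)
      next
    }
    M <- 1 - L
    xhat <- generator_forward(generator, list(image = s$image, mask = M))
    img <- if (composite_output) composite(s$image, xhat, M) else xhat
    out[[i]] <- list(image = img, label = L)
  }
  out
}
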