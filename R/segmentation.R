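# Lesion segmentation: compact U-Net, combined cross-entropy + Dice loss,
# subject-level cross-validation with synthetic-data augmentation, and
# volumetric overlap metrics.

#' Segmentation training configuration
#'
#' Defaults follow the stated protocol: batch size 16, 150 epochs, learning
#' rate 3e-4, \code{lambda_dice = 1}, \code{lambda_ce = 0.5}, five-fold
#' cross-validation by subject. Desk-scale experiments lower \code{epochs}
#' and the network size.
#'
#' @param batch_size,epochs,learning_rate Optimiser protocol.
#' @param lambda_dice,lambda_ce Loss term weights.
#' @param n_folds Cross-validation folds (>= 2).
#' @param depth,base_width U-Net depth and first-stage channel width.
#' @param threshold Probability binarisation threshold for evaluation.
#' @param eval_per \code{"subject"} (volumetric metrics over each subject's
#'   slice stack, mirroring per-volume evaluation) or \code{"slice"}.
#' @param seed Root seed.
#' @return A list of class \code{"seg_config"}.
#' @export
seg_config <- function(batch_size = 16L, epochs = 150L, learning_rate = 3e-4,
                       lambda_dice = 1, lambda_ce = 0.5, n_folds = 5L,
                       depth = 4L, base_width = 16L, threshold = 0.5,
                       eval_per = c("subject", "slice"), seed = 1L) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (batch_size < 1 || epochs < 1 || learning_rate <= 0) stop("invalid training budget")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 lambda_dice = lambda_dice, lambda_ce = lambda_ce,
                 n_folds = as.integer(n_folds), depth = as.integer(depth),
                 base_width = as.integer(base_width), threshold = threshold,
                 eval_per = match.arg(eval_per), seed = seed),
            class = "seg_config")
}

#' Combined cross-entropy and Dice loss
#'
#' \code{L = lambda_ce * L_CE + lambda_dice * L_Dice} with
#' \code{L_CE = -(1/N) sum(y log(yhat) + (1-y) log(1-yhat))} and
#' \code{L_Dice = 1 - (2 sum(y yhat) + 1) / (sum(y) + sum(yhat) + 1)}; the
#' added 1 in numerator and denominator keeps the Dice term defined (and
#' zero) when prediction and label are both empty.
#'
#' @param yhat Probability grid (clipped into \code{[1e-7, 1 - 1e-7]}).
#' @param y Binary label grid.
#' @param lambda_ce,lambda_dice Term weights.
#' @return A single non-negative number.
#' @export
ce_dice_loss <- function(yhat, y, lambda_ce = 0.5, lambda_dice = 1) {
  if (!all(dim(yhat) == dim(y))) stop("shape mismatch")
  p <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
  ce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  # the Dice term uses the raw probabilities: with y = yhat = 0 the +1
  # smoothing gives exactly 1 - 1/1 = 0
  dice <- 1 - (2 * sum(y * yhat) + 1) / (sum(y) + sum(yhat) + 1)
  lambda_ce * ce + lambda_dice * dice
}

# Gradient of ce_dice_loss with respect to yhat.
ce_dice_grad <- function(yhat, y, lambda_ce = 0.5, lambda_dice = 1) {
  p <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
  n <- length(p)
  dce <- -(y / p - (1 - y) / (1 - p)) / n
  S <- sum(y) + sum(yhat) + 1
  I <- 2 * sum(y * yhat) + 1
  ddice <- -(2 * y * S - I) / S^2
  lambda_ce * dce + lambda_dice * ddice
}

#' Build a compact segmentation U-Net
#'
#' Encoder stages of 3x3 convolutions (batch norm + ReLU) with stride-2
#' downsampling convolutions, a bottleneck, decoder stages of
#' nearest-neighbour upsampling + skip concatenation + 3x3 convolution, and
#' a final sigmoid producing a per-pixel lesion probability. Channel widths
#' double per stage from \code{base_width}.
#'
#' @param in_channels Input channels (1 for grayscale slices).
#' @param base_width First-stage channel width.
#' @param depth Number of down/upsampling stages; the input side must be
#'   divisible by \code{2^depth}.
#' @param seed Integer seed for He initialisation.
#' @return A segmentation network object (environment).
#' @export
build_unet <- function(in_channels = 1L, base_width = 16L, depth = 4L,
                       seed = 1L) {
  ch <- base_width * 2^(seq_len(depth) - 1L)
  params <- list()
  with_seed(seed, {
    cin <- in_channels
    for (i in seq_len(depth)) {
      params[[paste0("enc", i)]] <- c(he_conv(cin, ch[i], 3L),
                                      list(k = 3L, stride = 1L, pad = 1L))
      params[[paste0("encbn", i)]] <- bn_param(ch[i])
      params[[paste0("down", i)]] <- c(he_conv(ch[i], ch[i], 4L),
                                       list(k = 4L, stride = 2L, pad = 1L))
      cin <- ch[i]
    }
    params[["bott"]] <- c(he_conv(ch[depth], 2L * ch[depth], 3L),
                          list(k = 3L, stride = 1L, pad = 1L))
    params[["bottbn"]] <- bn_param(2L * ch[depth])
    cprev <- 2L * ch[depth]
    for (i in seq(depth, 1L)) {
      params[[paste0("dec", i)]] <- c(he_conv(cprev + ch[i], ch[i], 3L),
                                      list(k = 3L, stride = 1L, pad = 1L))
      params[[paste0("decbn", i)]] <- bn_param(ch[i])
      cprev <- ch[i]
    }
    params[["final"]] <- c(he_conv(ch[1L], 1L, 3L),
                           list(k = 3L, stride = 1L, pad = 1L))
  })
  net <- new.env(parent = emptyenv())
  net$kind <- "unet"
  net$cfg <- list(in_channels = in_channels, base_width = base_width,
                  depth = depth)
  net$params <- params
  net$state <- new.env(parent = emptyenv())
  class(net) <- "seg_unet"
  net
}

unet_forward_batch <- function(net, imgs, training = FALSE, keep_cache = FALSE) {
  d <- net$cfg$depth
  B <- length(imgs)
  if (nrow(imgs[[1L]]) %% (2^d) != 0) {
    stop("input side must be divisible by 2^", d)
  }
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  ck <- function(nm, val) if (keep_cache) cache[[nm]] <- val
  Xs <- lapply(imgs, as_cube)
  skips <- list()
  for (i in seq_len(d)) {
    p <- net$params[[paste0("enc", i)]]
    ck(paste0("enc", i, ".in"), Xs)
    Xs <- conv_f_batch(Xs, p)
    bn <- bn_f(Xs, net$params[[paste0("encbn", i)]], net$state,
               paste0("encbn", i), training)
    Xs <- bn$Ys; ck(paste0("enc", i, ".bn"), bn$cache)
    ac <- lapply(Xs, relu_f)
    Xs <- lapply(ac, `[[`, "Y"); ck(paste0("enc", i, ".act"), lapply(ac, `[[`, "cache"))
    skips[[i]] <- Xs
    p <- net$params[[paste0("down", i)]]
    ck(paste0("down", i, ".in"), Xs)
    Xs <- conv_f_batch(Xs, p)
    ac <- lapply(Xs, lrelu_f)
    Xs <- lapply(ac, `[[`, "Y"); ck(paste0("down", i, ".act"), lapply(ac, `[[`, "cache"))
  }
  p <- net$params[["bott"]]
  ck("bott.in", Xs)
  Xs <- conv_f_batch(Xs, p)
  bn <- bn_f(Xs, net$params[["bottbn"]], net$state, "bottbn", training)
  Xs <- bn$Ys; ck("bott.bn", bn$cache)
  ac <- lapply(Xs, relu_f)
  Xs <- lapply(ac, `[[`, "Y"); ck("bott.act", lapply(ac, `[[`, "cache"))
  for (i in seq(d, 1L)) {
    Xs <- lapply(Xs, up2_f)
    ck(paste0("dec", i, ".upch"), dim(Xs[[1L]])[3L])
    Xs <- lapply(seq_len(B), function(b) cube_cat(Xs[[b]], skips[[i]][[b]]))
    p <- net$params[[paste0("dec", i)]]
    ck(paste0("dec", i, ".in"), Xs)
    Xs <- conv_f_batch(Xs, p)
    bn <- bn_f(Xs, net$params[[paste0("decbn", i)]], net$state,
               paste0("decbn", i), training)
    Xs <- bn$Ys; ck(paste0("dec", i, ".bn"), bn$cache)
    ac <- lapply(Xs, relu_f)
    Xs <- lapply(ac, `[[`, "Y"); ck(paste0("dec", i, ".act"), lapply(ac, `[[`, "cache"))
  }
  p <- net$params[["final"]]
  ck("final.in", Xs)
  Xs <- conv_f_batch(Xs, p)
  ac <- lapply(Xs, sigmoid_f)
  Xs <- lapply(ac, `[[`, "Y"); ck("final.act", lapply(ac, `[[`, "cache"))
  list(outputs = lapply(Xs, function(X) matrix(X, dim(X)[1L], dim(X)[2L])),
       cache = cache)
}

unet_backward_batch <- function(net, cache, dOuts) {
  d <- net$cfg$depth
  B <- length(dOuts)
  grads <- zero_like(net$params)
  addWb <- function(nm, Xs, dYs, p) {
    r <- conv_b_batch(Xs, dYs, p)
    grads[[nm]]$W <<- grads[[nm]]$W + r$dW
    grads[[nm]]$b <<- grads[[nm]]$b + as.numeric(r$db)
    r$dXs
  }
  dY <- lapply(seq_len(B), function(b)
    sigmoid_b(as_cube(dOuts[[b]]), cache[["final.act"]][[b]]))
  p <- net$params[["final"]]
  dY <- addWb("final", cache[["final.in"]], dY, p)
  dSkips <- vector("list", d)
  for (i in seq_len(d)) {
    nm <- paste0("dec", i)
    dY <- lapply(seq_len(B), function(b) relu_b(dY[[b]], cache[[paste0(nm, ".act")]][[b]]))
    bnb <- bn_b(dY, cache[[paste0(nm, ".bn")]], net$params[[paste0("decbn", i)]])
    dY <- bnb$dXs
    grads[[paste0("decbn", i)]]$gamma <- grads[[paste0("decbn", i)]]$gamma + bnb$dgamma
    grads[[paste0("decbn", i)]]$beta <- grads[[paste0("decbn", i)]]$beta + bnb$dbeta
    p <- net$params[[nm]]
    dY <- addWb(nm, cache[[paste0(nm, ".in")]], dY, p)
    upch <- cache[[paste0(nm, ".upch")]]
    dSkips[[i]] <- lapply(dY, function(g) g[, , -seq_len(upch), drop = FALSE])
    dY <- lapply(dY, function(g) up2_b(g[, , seq_len(upch), drop = FALSE]))
  }
  dY <- lapply(seq_len(B), function(b) relu_b(dY[[b]], cache[["bott.act"]][[b]]))
  bnb <- bn_b(dY, cache[["bott.bn"]], net$params[["bottbn"]])
  dY <- bnb$dXs
  grads[["bottbn"]]$gamma <- grads[["bottbn"]]$gamma + bnb$dgamma
  grads[["bottbn"]]$beta <- grads[["bottbn"]]$beta + bnb$dbeta
  p <- net$params[["bott"]]
  dY <- addWb("bott", cache[["bott.in"]], dY, p)
  for (i in seq(d, 1L)) {
    nm <- paste0("down", i)
    dY <- lapply(seq_len(B), function(b) lrelu_b(dY[[b]], cache[[paste0(nm, ".act")]][[b]]))
    p <- net$params[[nm]]
    dY <- addWb(nm, cache[[paste0(nm, ".in")]], dY, p)
    dY <- lapply(seq_len(B), function(b) dY[[b]] + dSkips[[i]][[b]])
    nm <- paste0("enc", i)
    dY <- lapply(seq_len(B), function(b) relu_b(dY[[b]], cache[[paste0(nm, ".act")]][[b]]))
    bnb <- bn_b(dY, cache[[paste0(nm, ".bn")]], net$params[[paste0("encbn", i)]])
    dY <- bnb$dXs
    grads[[paste0("encbn", i)]]$gamma <- grads[[paste0("encbn", i)]]$gamma + bnb$dgamma
    grads[[paste0("encbn", i)]]$beta <- grads[[paste0("encbn", i)]]$beta + bnb$dbeta
    p <- net$params[[nm]]
    dY <- addWb(nm, cache[[paste0(nm, ".in")]], dY, p)
  }
  grads
}

#' Per-pixel lesion probability map
#'
#' @param net A network from \code{\link{build_unet}}.
#' @param image H x W matrix with sides divisible by \code{2^depth}.
#' @return H x W probability matrix.
#' @export
unet_forward <- function(net, image) {
  unet_forward_batch(net, list(image), training = FALSE)$outputs[[1L]]
}

#' Volumetric segmentation metrics
#'
#' Dice similarity coefficient, volume precision and volume sensitivity in
#' percent: \code{DSC = 2|P n G| / (|P| + |G|)}, \code{vPSC = |P n G|/|P|},
#' \code{vSEN = |P n G|/|G|}. Convention for degenerate volumes: both empty
#' gives 100 everywhere; exactly one empty gives 0.
#'
#' @param pred_mask,gt_mask Binary matrices/arrays, or lists of them
#'   (treated as one volume).
#' @return Named list with \code{dsc}, \code{vpsc}, \code{vsen} (percent).
#' @export
segmentation_metrics <- function(pred_mask, gt_mask) {
  tot <- function(x) if (is.list(x)) sum(vapply(x, sum, 0)) else sum(x)
  inter <- if (is.list(pred_mask)) {
    sum(vapply(seq_along(pred_mask), function(i) sum(pred_mask[[i]] * gt_mask[[i]]), 0))
  } else {
    if (!all(dim(pred_mask) == dim(gt_mask))) stop("shape mismatch")
    sum(pred_mask * gt_mask)
  }
  vp <- tot(pred_mask); vg <- tot(gt_mask)
  if (vp == 0 && vg == 0) return(list(dsc = 100, vpsc = 100, vsen = 100))
  if (vp == 0 || vg == 0) return(list(dsc = 0, vpsc = 0, vsen = 0))
  list(dsc = 200 * inter / (vp + vg), vpsc = 100 * inter / vp,
       vsen = 100 * inter / vg)
}

# Normalise a labelled set to list(images, labels, subject).
as_seg_set <- function(x) {
  if (is.null(x) || !length(x)) return(list(images = list(), labels = list(), subject = integer(0)))
  if (!is.null(x$slices)) {
    list(images = lapply(x$slices, `[[`, "image"),
         labels = lapply(x$slices, function(s)
           if (!is.null(s$lesion_label_map)) (s$lesion_label_map > 0) * 1 else (s$label > 0) * 1),
         subject = x$subject %||% seq_along(x$slices))
  } else {
    list(images = lapply(x, `[[`, "image"),
         labels = lapply(x, function(s)
           if (!is.null(s$label)) (s$label > 0) * 1
           else if (!is.null(s$lesion_label_map)) (s$lesion_label_map > 0) * 1
           else (s$lesion_mask > 0) * 1),
         subject = vapply(seq_along(x), function(i) x[[i]]$subject %||% i, 0))
  }
}

# Train one U-Net on the given slices for cfg$epochs.
train_unet_once <- function(images, labels, cfg, seed) {
  net <- build_unet(1L, cfg$base_width, cfg$depth,
                    seed = substream_seed(seed, "unet-init"))
  opt <- amsgrad_new(net$params, cfg$learning_rate, 0.9, 0.999)
  n <- length(images)
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  t <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(substream_seed(seed, paste0("epoch", ep)), sample.int(n))
    for (s in seq_len(steps_per_epoch)) {
      t <- t + 1L
      idx <- ord[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
      fw <- unet_forward_batch(net, images[idx], training = TRUE, keep_cache = TRUE)
      dOuts <- lapply(seq_along(idx), function(b)
        ce_dice_grad(fw$outputs[[b]], labels[[idx[b]]], cfg$lambda_ce, cfg$lambda_dice) /
          length(idx))
      g <- unet_backward_batch(net, fw$cache, dOuts)
      if (!tree_finite(g)) stop("non-finite segmentation gradient at step ", t)
      net$params <- amsgrad_step(opt, net$params, g)
    }
  }
  net
}

#' Train lesion segmentation with synthetic augmentation
#'
#' Cross-validation folds are formed over the subjects of the REAL set
#' only; the synthetic set joins every training fold and never any
#' evaluation fold (a structural guarantee, additionally asserted). Metrics
#' are computed per held-out subject volume and pooled.
#'
#' @param real_set Real labelled slices: the output of
#'   \code{\link{generate_phantom_dataset}}, or a list of slices each with
#'   \code{image}, a label field, and optionally \code{subject}.
#' @param synthetic_set Synthetic labelled slices in the same formats (may
#'   be empty/NULL for the non-augmented baseline).
#' @param cfg A \code{\link{seg_config}}.
#' @return List with \code{per_subject} (data frame: fold, subject, dsc,
#'   vpsc, vsen), \code{per_fold} (fold means), \code{summary} (mean and sd
#'   over subjects and over folds), and \code{models}.
#' @export
train_segmentation <- function(real_set, synthetic_set = NULL,
                               cfg = seg_config()) {
  real <- as_seg_set(real_set)
  syn <- as_seg_set(synthetic_set)
  n_real <- length(real$images)
  if (!n_real) stop("real set is empty")
  subs <- unique(real$subject)
  if (length(subs) < cfg$n_folds) {
    stop("need at least n_folds = ", cfg$n_folds, " subjects, got ", length(subs))
  }
  perm <- with_seed(substream_seed(cfg$seed, "folds"), sample(subs))
  fold_assign <- rep(seq_len(cfg$n_folds), length.out = length(subs))
  rows <- list(); models <- list()
  for (f in seq_len(cfg$n_folds)) {
    eval_subs <- perm[fold_assign == f]
    eval_idx <- which(real$subject %in% eval_subs)
    train_idx <- setdiff(seq_len(n_real), eval_idx)
    if (length(intersect(eval_idx, n_real + seq_along(syn$images)))) {
      stop("synthetic image leaked into an evaluation fold")  # unreachable
    }
    tr_imgs <- c(real$images[train_idx], syn$images)
    tr_labs <- c(real$labels[train_idx], syn$labels)
    net <- train_unet_once(tr_imgs, tr_labs, cfg,
                           seed = substream_seed(cfg$seed, paste0("fold", f)))
    models[[f]] <- net
    for (s in eval_subs) {
      sl <- which(real$subject == s)
      preds <- lapply(sl, function(i)
        (unet_forward(net, real$images[[i]]) >= cfg$threshold) * 1)
      gts <- real$labels[sl]
      m <- if (cfg$eval_per == "subject") segmentation_metrics(preds, gts)
           else {
             ms <- lapply(seq_along(sl), function(j)
               segmentation_metrics(preds[[j]], gts[[j]]))
             list(dsc = mean(vapply(ms, `[[`, 0, "dsc")),
                  vpsc = mean(vapply(ms, `[[`, 0, "vpsc")),
                  vsen = mean(vapply(ms, `[[`, 0, "vsen")))
           }
      rows[[length(rows) + 1L]] <- data.frame(fold = f, subject = s,
                                              dsc = m$dsc, vpsc = m$vpsc,
                                              vsen = m$vsen)
    }
  }
  per_subject <- do.call(rbind, rows)
  per_fold <- do.call(rbind, lapply(split(per_subject, per_subject$fold),
    function(d) data.frame(fold = d$fold[1L], dsc = mean(d$dsc),
                           vpsc = mean(d$vpsc), vsen = mean(d$vsen))))
  summ <- list(
    by_subject = c(dsc = mean(per_subject$dsc), dsc_sd = sd(per_subject$dsc),
                   vpsc = mean(per_subject$vpsc), vpsc_sd = sd(per_subject$vpsc),
                   vsen = mean(per_subject$vsen), vsen_sd = sd(per_subject$vsen)),
    by_fold = c(dsc = mean(per_fold$dsc), dsc_sd = sd(per_fold$dsc),
                vpsc = mean(per_fold$vpsc), vpsc_sd = sd(per_fold$vpsc),
                vsen = mean(per_fold$vsen), vsen_sd = sd(per_fold$vsen)))
  list(per_subject = per_subject, per_fold = per_fold, summary = summ,
       models = models)
}
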