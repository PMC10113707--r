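# Feature extractors for the perceptual and texture losses.
#
# The losses are defined against any fixed multi-layer feature map Phi with
# layer groups (low/mid/high). The package ships two extractors: an identity
# extractor (one "layer", the image itself) and a frozen random-convolution
# network — fixed He-initialised kernels are a standard randomised basis for
# perceptual distances and require no external weight file. Any object
# implementing the same interface (a forward returning per-layer feature
# cubes and a matching backward) can be substituted.

#' Identity feature extractor
#'
#' A single-layer extractor whose only feature map is the image itself.
#' Useful for tests and as the cheapest perceptual-loss backend.
#'
#' @return An object of class \code{"feature_extractor"}.
#' @export
identity_extractor <- function() {
  structure(list(type = "identity", n_layers = 1L, select = 1L,
                 groups = list(low = 1L)),
            class = "feature_extractor")
}

#' Frozen random-convolution feature extractor
#'
#' A stack of fixed (never trained) 3x3 He-initialised convolutions with
#' ReLU, deterministic given the seed. Layer groups mirror the low/mid/high
#' split used for perceptual and texture losses.
#'
#' @param channels Output channels per layer.
#' @param strides Stride per layer.
#' @param select Which layer outputs are used by the losses.
#' @param seed Seed fixing the kernels.
#' @return An object of class \code{"feature_extractor"}.
#' @export
random_conv_extractor <- function(channels = c(8L, 16L, 16L),
                                  strides = c(1L, 2L, 2L),
                                  select = seq_along(channels),
                                  seed = 42L) {
  n <- length(channels)
  params <- with_seed(seed, {
    cin <- 1L
    out <- vector("list", n)
    for (l in seq_len(n)) {
      out[[l]] <- c(he_conv(cin, channels[l], 3L),
                    list(k = 3L, stride = as.integer(strides[l]), pad = 1L))
      cin <- channels[l]
    }
    out
  })
  g <- split(seq_len(n), cut(seq_len(n), breaks = min(3L, n), labels = FALSE))
  names(g) <- c("low", "mid", "high")[seq_along(g)]
  structure(list(type = "conv", n_layers = n, params = params,
                 select = as.integer(select), groups = g),
            class = "feature_extractor")
}

fx_forward <- function(phi, img, keep_cache = FALSE) {
  X <- as_cube(img)
  if (phi$type == "identity") {
    return(list(feats = list(X), cache = list(dim0 = dim(X))))
  }
  acts <- list(X)
  rmask <- vector("list", phi$n_layers)
  feats <- vector("list", length(phi$select))
  for (l in seq_len(phi$n_layers)) {
    p <- phi$params[[l]]
    Z <- conv_f(acts[[l]], p)
    a <- relu_f(Z)
    rmask[[l]] <- a$cache
    acts[[l + 1L]] <- a$Y
  }
  for (i in seq_along(phi$select)) feats[[i]] <- acts[[phi$select[i] + 1L]]
  list(feats = feats,
       cache = if (keep_cache) list(acts = acts, rmask = rmask) else NULL)
}

# dFeats: list parallel to phi$select (NULL entries allowed). Returns the
# gradient with respect to the input image (H x W matrix).
fx_backward <- function(phi, cache, dFeats) {
  if (phi$type == "identity") {
    d <- dFeats[[1L]]
    return(d[, , 1L])
  }
  n <- phi$n_layers
  dA <- vector("list", n + 1L)  # gradient at each activation
  for (i in seq_along(phi$select)) {
    l <- phi$select[i]
    if (!is.null(dFeats[[i]])) {
      dA[[l + 1L]] <- if (is.null(dA[[l + 1L]])) dFeats[[i]] else dA[[l + 1L]] + dFeats[[i]]
    }
  }
  dX <- NULL
  for (l in seq(n, 1L)) {
    cur <- dA[[l + 1L]]
    if (!is.null(dX)) cur <- if (is.null(cur)) dX else cur + dX
    if (is.null(cur)) { dX <- NULL; next }
    cur <- relu_b(cur, cache$rmask[[l]])
    p <- phi$params[[l]]
    dX <- conv2d_bwd_input(cur, p$W, dim(cache$acts[[l]])[1L],
                           dim(cache$acts[[l]])[2L], dim(cache$acts[[l]])[3L],
                           p$k, p$stride, p$pad)
  }
  dX[, , 1L]
}

#' Extract feature maps from an image
#'
#' @param phi A \code{"feature_extractor"}.
#' @param image H x W matrix (grayscale).
#' @return A list of feature cubes (H_i x W_i x C_i arrays), one per
#'   selected layer.
#' @export
extract_features <- function(phi, image) {
  fx_forward(phi, image)$feats
}
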