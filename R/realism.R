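# Realism scoring of synthetic lesions: GLCM texture features over lesion
# ROIs and KL divergence between real and synthetic feature distributions.

#' GLCM computation configuration
#'
#' Gray-level co-occurrence parameters: intensities are quantised to
#' \code{n_gray_levels} equal-width bins over the ROI range; pixel pairs are
#' counted at the given \code{distances} along each angle (0, 45, 90, 135
#' degrees by default), symmetrised and averaged over angles, and
#' normalised to sum 1.
#'
#' @param n_gray_levels Number of gray levels (>= 2; default 32).
#' @param distances Integer pair offsets in pixels (default 1).
#' @param angles Offset angles in radians.
#' @param symmetric Count each pair in both directions.
#' @return A list of class \code{"glcm_config"}.
#' @export
glcm_config <- function(n_gray_levels = 32L, distances = 1L,
                        angles = c(0, pi / 4, pi / 2, 3 * pi / 4),
                        symmetric = TRUE) {
  if (n_gray_levels < 2) stop("n_gray_levels must be >= 2")
  if (any(distances < 1)) stop("distances must be >= 1")
  structure(list(n_gray_levels = as.integer(n_gray_levels),
                 distances = as.integer(distances), angles = angles,
                 symmetric = symmetric),
            class = "glcm_config")
}

#' Gray-level co-occurrence matrix of a lesion ROI
#'
#' Only pixel pairs with both ends inside \code{roi_mask} are counted;
#' pixels outside the mask never enter the matrix.
#'
#' @param image H x W matrix of intensities in \code{[0, 1]}.
#' @param roi_mask Binary matrix; the ROI needs at least one valid pair.
#' @param cfg A \code{\link{glcm_config}}.
#' @return \code{n_gray_levels} x \code{n_gray_levels} matrix summing to 1.
#' @export
glcm <- function(image, roi_mask, cfg = glcm_config()) {
  if (!all(dim(image) == dim(roi_mask))) stop("shape mismatch")
  idx <- which(roi_mask == 1)
  if (length(idx) < 2L) stop("ROI must contain at least 2 pixels")
  L <- cfg$n_gray_levels
  vals <- image[idx]
  lo <- min(vals); hi <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi - lo < 1e-12) {
    q[idx] <- 1L
  } else {
    q[idx] <- pmin(pmax(floor((image[idx] - lo) / (hi - lo) * L) + 1L, 1L), L)
  }
  h <- nrow(image); w <- ncol(image)
  P <- matrix(0, L, L)
  n_pairs <- 0
  for (d in cfg$distances) {
    for (a in cfg$angles) {
      dr <- round(d * sin(a)); dc <- round(d * cos(a))
      rr <- seq_len(h); cc <- seq_len(w)
      r1 <- rr[rr + dr >= 1 & rr + dr <= h]
      c1 <- cc[cc + dc >= 1 & cc + dc <= w]
      if (!length(r1) || !length(c1)) next
      a1 <- q[r1, c1, drop = FALSE]
      a2 <- q[r1 + dr, c1 + dc, drop = FALSE]
      ok <- !is.na(a1) & !is.na(a2)
      if (!any(ok)) next
      tab <- table(factor(a1[ok], levels = 1:L), factor(a2[ok], levels = 1:L))
      Pa <- unclass(tab)
      if (cfg$symmetric) Pa <- Pa + t(Pa)
      P <- P + Pa
      n_pairs <- n_pairs + sum(Pa)
    }
  }
  if (n_pairs == 0) stop("no valid pixel pairs in ROI at the configured offsets")
  P <- P / n_pairs
  dimnames(P) <- NULL
  P
}

#' GLCM energy and correlation
#'
#' Energy is the sum of squared entries (angular second moment).
#' Correlation is the normalised covariance of the paired gray levels,
#' \code{sum((i - mu_x)(j - mu_y) P(i,j)) / (sigma_x sigma_y)}; a constant
#' ROI (zero marginal variance) returns correlation 1 by convention.
#'
#' @param P A normalised co-occurrence matrix.
#' @return A single number.
#' @export
glcm_energy <- function(P) sum(P^2)

#' @rdname glcm_energy
#' @export
glcm_correlation <- function(P) {
  L <- nrow(P)
  i <- seq_len(L)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(i * px); my <- sum(i * py)
  sx <- sqrt(sum((i - mx)^2 * px)); sy <- sqrt(sum((i - my)^2 * py))
  if (sx < 1e-12 || sy < 1e-12) return(1)
  sum(outer(i - mx, i - my) * P) / (sx * sy)
}

#' Normalised feature histogram
#'
#' Equal-width bins over \code{range}; values outside the range are clipped
#' into the end bins; heights sum to 1.
#'
#' @param values Nonempty numeric vector.
#' @param n_bins Number of bins.
#' @param range Length-2 numeric \code{(lo, hi)}, \code{lo < hi}.
#' @return List of class \code{"feature_histogram"} with \code{bin_edges}
#'   (length \code{n_bins + 1}) and \code{heights}.
#' @export
feature_histogram <- function(values, n_bins, range) {
  if (!length(values)) stop("empty value vector")
  lo <- range[1L]; hi <- range[2L]
  if (lo >= hi) stop("range must satisfy lo < hi")
  bins <- pmin(pmax(floor((values - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  heights <- tabulate(bins, nbins = n_bins)
  structure(list(bin_edges = seq(lo, hi, length.out = n_bins + 1L),
                 heights = heights / sum(heights)),
            class = "feature_histogram")
}

#' Kullback-Leibler divergence between two histograms
#'
#' \code{KL(h1 || h2) = sum_i h1(i) ln(h1(i) / h2(i))}, with additive
#' epsilon smoothing (then renormalisation) applied to both histograms to
#' handle empty bins; asymmetric in its arguments by construction.
#'
#' @param h1,h2 \code{"feature_histogram"} objects on identical binning,
#'   or plain probability vectors of equal length.
#' @param eps Additive smoothing constant.
#' @return A non-negative number, 0 iff the histograms coincide.
#' @export
kl_divergence <- function(h1, h2, eps = 1e-8) {
  g <- function(h) if (inherits(h, "feature_histogram")) h else list(bin_edges = NULL, heights = h)
  a <- g(h1); b <- g(h2)
  if (length(a$heights) != length(b$heights)) stop("histogram binning mismatch")
  if (!is.null(a$bin_edges) && !is.null(b$bin_edges) &&
      max(abs(a$bin_edges - b$bin_edges)) > 1e-9) {
    stop("histogram binning mismatch")
  }
  p <- a$heights + eps; p <- p / sum(p)
  q <- b$heights + eps; q <- q / sum(q)
  sum(ifelse(p > 0, p * log(p / q), 0))
}

#' Realism report: KL divergence of GLCM feature distributions
#'
#' Computes GLCM-energy and GLCM-correlation for every real and synthetic
#' lesion ROI, builds normalised histograms per feature on the pooled
#' min-max range, and reports \code{KL(real || synthetic)} per feature
#' (direction configurable).
#'
#' @param real_rois,synthetic_rois Lists of ROIs, each a list with
#'   \code{image} and \code{mask} (the exact lesion mask).
#' @param cfg A \code{\link{glcm_config}}.
#' @param n_bins Histogram bins (default 50).
#' @param eps KL smoothing constant.
#' @param direction \code{"real_vs_syn"} (default) or \code{"syn_vs_real"}.
#' @param out_csv Optional path; if given the report is also written as CSV.
#' @return A data frame with columns \code{feature}, \code{n_real},
#'   \code{n_syn}, \code{kl}.
#' @export
realism_report <- function(real_rois, synthetic_rois, cfg = glcm_config(),
                           n_bins = 50L, eps = 1e-8,
                           direction = c("real_vs_syn", "syn_vs_real"),
                           out_csv = NULL) {
  direction <- match.arg(direction)
  if (length(real_rois) < 20L || length(synthetic_rois) < 20L) {
    warning("fewer than 20 ROIs on one side; KL estimates will be noisy")
  }
  feats <- function(rois) {
    vapply(rois, function(r) {
      P <- glcm(r$image, (r$mask > 0) * 1L, cfg)
      c(energy = glcm_energy(P), correlation = glcm_correlation(P))
    }, numeric(2L))
  }
  fr <- feats(real_rois); fs <- feats(synthetic_rois)
  rows <- lapply(c("energy", "correlation"), function(f) {
    vr <- fr[f, ]; vs <- fs[f, ]
    rng <- range(c(vr, vs))
    if (diff(rng) < 1e-12) rng <- rng + c(-1e-6, 1e-6)
    hr <- feature_histogram(vr, n_bins, rng)
    hs <- feature_histogram(vs, n_bins, rng)
    kl <- if (direction == "real_vs_syn") kl_divergence(hr, hs, eps)
          else kl_divergence(hs, hr, eps)
    data.frame(feature = paste0("glcm_", f), n_real = length(vr),
               n_syn = length(vs), kl = kl)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

# Extract lesion ROIs (image + per-lesion mask) from a list of slices.
lesion_rois <- function(slices) {
  rois <- list()
  for (s in slices) {
    lab <- if (!is.null(s$lesion_label_map)) s$lesion_label_map
           else label_components((s$label > 0) * 1L)
    if (max(lab) == 0) next
    for (k in seq_len(max(lab))) {
      m <- (lab == k) * 1L
      if (sum(m) < 2) next
      rois[[length(rois) + 1L]] <- list(image = s$image, mask = m)
    }
  }
  rois
}
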