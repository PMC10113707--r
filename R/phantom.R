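#' Preprocessing configuration for CT slices
#'
#' Intensity window and output size used when preparing abdominal CT slices
#' for the synthesis and segmentation networks. The defaults window the
#' soft-tissue range to \code{[-100, 200]} HU and resample to 256 x 256.
#'
#' @param window_low,window_high Hounsfield-unit window endpoints.
#' @param out_size Side length in pixels of the resampled square slice.
#' @return A list of class \code{"preprocess_config"}.
#' @export
preprocess_config <- function(window_low = -100, window_high = 200, out_size = 256L) {
  if (window_low >= window_high) stop("window_low must be < window_high")
  if (out_size <= 0) stop("out_size must be positive")
  structure(list(window_low = window_low, window_high = window_high,
                 out_size = as.integer(out_size)),
            class = "preprocess_config")
}

# Radial star-convex polygon r(theta) = r0 * (1 + sum_k a_k cos(k theta + phi_k)).
# Returns a function of theta; coefficients drawn from the current RNG stream.
random_radial_profile <- function(max_order = 5L, max_amp = 0.3) {
  ord <- seq_len(max_order)
  a <- runif(max_order, 0, max_amp) * sample(c(-1, 1), max_order, replace = TRUE)
  # taper high orders so shapes stay simple
  a <- a / (1 + 0.5 * (ord - 1))
  phi <- runif(max_order, 0, 2 * pi)
  function(theta) {
    s <- rep(1, length(theta))
    for (k in ord) s <- s + a[k] * cos(k * theta + phi[k])
    pmax(s, 0.2)
  }
}

# Binary mask of a star-convex region centred at (cr, cc) with radial profile
# prof and nominal radius r0, evaluated on an h x w grid.
rasterize_radial <- function(h, w, cr, cc, r0, prof) {
  rows <- matrix(seq_len(h) - 1, h, w)
  cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  dr <- rows - cr; dc <- cols - cc
  theta <- atan2(dc, dr)
  rad <- sqrt(dr^2 + dc^2)
  (rad <= r0 * prof(theta)) * 1L
}

#' Generate one synthetic CT-like phantom slice
#'
#' Produces a seeded phantom emulating a windowed, liver-extracted CT slice:
#' a smooth star-convex organ blob with Gaussian-correlated background
#' texture (correlation length about 3 px), and star-convex lesions with a
#' distinct mean intensity offset (at least 0.15) and a shorter texture
#' correlation length (about 1 px). Pixels outside the organ are exactly 0
#' and all intensities lie in \code{[0, 1]}. Lesion areas are drawn
#' log-uniformly between 15 px and 10\% of the organ area.
#'
#' @param height,width Slice dimensions in pixels (at least 32; 32 x 32 and
#'   64 x 64 are the desk-scale training profiles, 256 x 256 the full-scale
#'   one).
#' @param n_lesions Number of disjoint lesions to place (may be 0).
#' @param seed Integer seed; the slice is bit-reproducible given the seed.
#' @return A list of class \code{"phantom_slice"} with elements
#'   \code{image} (numeric matrix in \code{[0,1]}), \code{organ_mask}
#'   (binary matrix) and \code{lesion_label_map} (integer matrix, 0 =
#'   background, k = k-th lesion).
#' @param lesion_noise_sigma Gaussian correlation length (pixels) of the
#'   lesion texture; the default 0.5 gives the short-range speckle that
#'   distinguishes lesions from the smoother organ background
#'   (\code{sigma = 1.5}). Changing it defines a different texture family,
#'   which the realism evaluation should detect.
#' @param lesion_offset_range Range of the absolute mean-intensity offset
#'   between lesion and surrounding tissue.
#' @export
generate_phantom_slice <- function(height = 256L, width = 256L, n_lesions = 1L,
                                   seed = 1L, lesion_noise_sigma = 0.5,
                                   lesion_offset_range = c(0.15, 0.3)) {
  if (height < 32 || width < 32) stop("height and width must be >= 32")
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  with_seed(seed, {
    # organ: large smooth star-convex blob covering roughly 20-60% of frame
    cr <- height / 2 + runif(1, -0.04, 0.04) * height
    cc <- width / 2 + runif(1, -0.04, 0.04) * width
    prof <- random_radial_profile(max_order = 3L, max_amp = 0.15)
    r0 <- 0.38 * min(height, width)
    organ <- rasterize_radial(height, width, cr, cc, r0, prof)
    organ_area <- sum(organ)

    mu_organ <- runif(1, 0.45, 0.6)
    noise_bg <- gaussian_blur(matrix(rnorm(height * width), height, width), 1.5)
    noise_bg <- noise_bg / sd(noise_bg) * 0.05
    image <- (mu_organ + noise_bg) * organ

    lesion_label <- matrix(0L, height, width)
    if (n_lesions > 0) {
      organ_idx <- which(organ == 1)
      noise_le <- gaussian_blur(matrix(rnorm(height * width), height, width),
                                lesion_noise_sigma)
      noise_le <- noise_le / sd(noise_le) * 0.05
      for (k in seq_len(n_lesions)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          area <- exp(runif(1, log(15), log(max(16, 0.1 * organ_area))))
          lprof <- random_radial_profile(max_order = 5L, max_amp = 0.3)
          lr0 <- sqrt(area / pi)
          ctr <- organ_idx[sample.int(length(organ_idx), 1L)]
          lr <- (ctr - 1L) %% height
          lc <- (ctr - 1L) %/% height
          les <- rasterize_radial(height, width, lr, lc, lr0, lprof)
          if (sum(les) <= 10) next
          if (any(les == 1 & organ == 0)) next
          if (any(les == 1 & lesion_label != 0L)) next
          lesion_label[les == 1] <- k
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place lesion ", k,
                          " without overlap after bounded retries")
      }
      offset <- runif(1, lesion_offset_range[1], lesion_offset_range[2]) *
        sample(c(-1, 1), 1)
      inles <- lesion_label != 0L
      image[inles] <- mu_organ + offset + noise_le[inles]
    }
    structure(list(image = clamp01(image) * organ,
                   organ_mask = organ,
                   lesion_label_map = lesion_label),
              class = "phantom_slice")
  })
}

#' Generate a phantom dataset with subject-level train/val/test split
#'
#' Slices are grouped into synthetic "subjects" (about four slices each,
#' sharing a per-subject base-intensity trait) and the three-way split is
#' made over subjects, never over slices, so that no subject straddles two
#' splits.
#'
#' @param n_slices Number of slices to generate (at least 3).
#' @param n_lesion_range Length-2 integer vector; per-slice lesion counts are
#'   drawn uniformly from this closed range.
#' @param seed Integer seed.
#' @param height,width Slice dimensions (desk-scale default 64).
#' @param split Proportions for train/validation/test; defaults mirror a
#'   52/24/23 percent division.
#' @return A list with \code{slices} (list of \code{phantom_slice}),
#'   \code{subject} (integer vector, one entry per slice) and \code{split}
#'   (list of index vectors \code{train}, \code{val}, \code{test}).
#' @export
generate_phantom_dataset <- function(n_slices, n_lesion_range = c(1L, 2L),
                                     seed = 1L, height = 64L, width = 64L,
                                     split = c(0.52, 0.24, 0.23)) {
  if (n_slices < 3) stop("n_slices must be >= 3 for a three-way split")
  split <- split / sum(split)
  n_subj <- max(3L, as.integer(round(n_slices / 4)))
  subject <- sort(rep_len(seq_len(n_subj), n_slices))
  slices <- vector("list", n_slices)
  ds_seed <- substream_seed(seed, "phantom-dataset")
  subj_shift <- with_seed(ds_seed, runif(n_subj, -0.05, 0.05))
  for (i in seq_len(n_slices)) {
    nl <- with_seed(substream_seed(ds_seed, paste0("count", i)),
                    sample(seq(n_lesion_range[1], n_lesion_range[2]), 1L))
    sl <- generate_phantom_slice(height, width, nl,
                                 seed = substream_seed(ds_seed, paste0("slice", i)))
    shift <- subj_shift[subject[i]]
    sl$image <- clamp01(sl$image + shift * sl$organ_mask) * sl$organ_mask
    slices[[i]] <- sl
  }
  perm <- with_seed(substream_seed(ds_seed, "split"), sample.int(n_subj))
  n_train <- max(1L, round(split[1] * n_subj))
  n_val <- max(1L, round(split[2] * n_subj))
  if (n_train + n_val >= n_subj) {
    n_train <- n_subj - 2L
    n_val <- 1L
  }
  subj_split <- list(train = perm[seq_len(n_train)],
                     val = perm[n_train + seq_len(n_val)],
                     test = perm[(n_train + n_val + 1L):n_subj])
  list(slices = slices, subject = subject,
       split = lapply(subj_split, function(s) which(subject %in% s)))
}

#' Window, normalise and extract the organ from a raw HU slice
#'
#' Applies the linear intensity window
#' \code{clip((raw - low) / (high - low), 0, 1)}, zeroes everything outside
#' the organ mask, and resamples to \code{cfg$out_size} per side (bilinear
#' for the image, nearest-neighbour for the mask so it stays binary).
#'
#' @param raw Numeric matrix of Hounsfield units.
#' @param organ_mask Binary matrix delineating the organ (e.g. the liver
#'   contour drawn by a physician), same shape as \code{raw}.
#' @param cfg A \code{\link{preprocess_config}}.
#' @return List with \code{image} (windowed, organ-extracted, resized) and
#'   \code{organ_mask} (resized).
#' @export
preprocess_slice <- function(raw, organ_mask, cfg = preprocess_config()) {
  if (!all(is.finite(raw))) stop("raw slice contains non-finite values")
  if (!any(organ_mask == 1)) stop("organ mask is empty")
  if (!all(dim(raw) == dim(organ_mask))) stop("raw and organ_mask shapes differ")
  img <- clamp01((raw - cfg$window_low) / (cfg$window_high - cfg$window_low))
  img <- img * organ_mask
  list(image = resize_bilinear(img, cfg$out_size, cfg$out_size) *
         resize_nearest(organ_mask, cfg$out_size, cfg$out_size),
       organ_mask = resize_nearest(organ_mask, cfg$out_size, cfg$out_size))
}

#' Write a slice or mask as a grayscale PNG
#'
#' PNG output is 8-bit and intended for masks and previews; use
#' \code{\link{write_slice_nifti}} when full intensity precision matters.
#'
#' @param m Numeric matrix in \code{[0,1]}.
#' @param path Output file path.
#' @export
write_slice_png <- function(m, path) {
  png::writePNG(clamp01(m), path)
  invisible(path)
}

#' @rdname write_slice_png
#' @export
read_slice_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Write/read a slice as NIfTI
#' @param m Numeric matrix.
#' @param path Output \code{.nii} or \code{.nii.gz} path.
#' @export
write_slice_nifti <- function(m, path) {
  RNifti::writeNifti(RNifti::asNifti(array(m, dim = c(dim(m), 1L))), path)
  invisible(path)
}

#' @rdname write_slice_nifti
#' @export
read_slice_nifti <- function(path) {
  a <- RNifti::readNifti(path)
  matrix(as.numeric(a), dim(a)[1L], dim(a)[2L])
}
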