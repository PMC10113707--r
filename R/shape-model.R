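# Point-distribution model of lesion contours: boundary landmarking,
# generalised Procrustes alignment, PCA, and sampling of new placed masks.
#
# A ShapeVector is a numeric vector of length 2n laid out [x1..xn, y1..yn],
# where x is the column coordinate and y the row coordinate (0-based pixel
# centres). All shapes in one model share n (default 200 landmarks).

shape_xy <- function(shape) {
  n <- length(shape) / 2L
  cbind(x = shape[seq_len(n)], y = shape[n + seq_len(n)])
}

xy_shape <- function(xy) c(xy[, 1L], xy[, 2L])

# Moore-neighbour boundary tracing of the single foreground component.
# Returns ordered boundary pixel coordinates, one row per visited boundary
# pixel (pixels may repeat on one-pixel-wide necks). Terminates when a
# (pixel, backtrack-direction) state repeats.
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] == 1
  # clockwise Moore neighbourhood starting W: W NW N NE E SE S SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  # start: topmost, then leftmost foreground pixel; its W and N neighbours
  # are guaranteed background
  rows <- row(mask)[mask == 1]; cols <- col(mask)[mask == 1]
  sr <- min(rows); sc <- min(cols[rows == sr])
  cr <- sr; cc <- sc
  bdir <- 1L  # direction from current pixel to its backtrack neighbour
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- matrix(c(sr, sc), 1L, 2L)
  repeat {
    key <- paste(cr, cc, bdir)
    if (!is.null(seen[[key]])) break
    assign(key, TRUE, envir = seen)
    found <- FALSE
    for (i in seq_len(8L)) {
      d <- ((bdir - 1L + i - 1L) %% 8L) + 1L
      nr <- cr + dr[d]; nc <- cc + dc[d]
      if (fg(nr, nc)) {
        # new backtrack: the (background) ring cell scanned just before d
        pd <- ((d - 2L) %% 8L) + 1L
        prevr <- cr + dr[pd]; prevc <- cc + dc[pd]
        cr <- nr; cc <- nc
        bdir <- which(dr == (prevr - cr) & dc == (prevc - cc))[1L]
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    path <- rbind(path, c(cr, cc))
  }
  # drop the duplicated return-to-start row if present
  n <- nrow(path)
  if (n > 1L && path[n, 1L] == sr && path[n, 2L] == sc) path <- path[-n, , drop = FALSE]
  path
}

#' Extract equally spaced boundary landmarks from a lesion mask
#'
#' Traces the outer boundary of the single foreground component and resamples
#' it to \code{n_points} landmarks equally spaced in arc length, ordered
#' counter-clockwise and starting from the landmark at the smallest polar
#' angle about the centroid (ties broken by the smaller row coordinate).
#'
#' @param mask Binary matrix with exactly one connected foreground component
#'   of area greater than 10 pixels.
#' @param n_points Number of landmarks (default 200).
#' @return A shape vector of length \code{2 * n_points}, \code{[x..., y...]}
#'   with x = column and y = row, in 0-based pixel coordinates.
#' @export
extract_boundary_points <- function(mask, n_points = 200L) {
  stopifnot_binary(mask)
  if (!any(mask == 1)) stop("mask is empty")
  lab <- label_components(mask)
  if (max(lab) != 1L) stop("mask must have exactly one connected component, found ", max(lab))
  if (sum(mask) <= 10) stop("component area must exceed 10 pixels")
  bp <- trace_boundary(mask)
  # 0-based (x=col, y=row) polygon
  px <- bp[, 2L] - 1; py <- bp[, 1L] - 1
  # drop consecutive duplicates, close the loop
  keep <- c(TRUE, diff(px) != 0 | diff(py) != 0)
  px <- px[keep]; py <- py[keep]
  if (length(px) < 3L) {  # degenerate thin component; fall back to pixel box
    stop("boundary too short to landmark")
  }
  # enforce counter-clockwise orientation (positive signed area in (x, y))
  n <- length(px)
  jn <- c(n, seq_len(n - 1L))
  signed <- sum(px[jn] * py - px * py[jn]) / 2
  if (signed < 0) { px <- rev(px); py <- rev(py) }
  # rotate start to the vertex with smallest angle about the centroid
  cx <- mean(px); cy <- mean(py)
  theta <- atan2(py - cy, px - cx) %% (2 * pi)
  cand <- which(theta == min(theta))
  start <- cand[which.min(py[cand])]
  idx <- c(start:n, seq_len(start - 1L))[seq_len(n)]
  px <- px[idx]; py <- py[idx]
  # arc-length resampling of the closed polygon
  seg <- sqrt(diff(c(px, px[1L]))^2 + diff(c(py, py[1L]))^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_points + 1L)[seq_len(n_points)]
  xs <- c(px, px[1L]); ys <- c(py, py[1L])
  ox <- approx(s, xs, xout = target, ties = "ordered")$y
  oy <- approx(s, ys, xout = target, ties = "ordered")$y
  # traced vertices are boundary-pixel centres; push landmarks half a pixel
  # outward (radially from the centroid) so the polygon follows the
  # component's outer edge and rasterisation round-trips the mask area
  dx <- ox - mean(ox); dy <- oy - mean(oy)
  nr <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  c(ox + 0.5 * dx / nr, oy + 0.5 * dy / nr)
}

#' Generalised Procrustes alignment of landmark shapes
#'
#' Centres every shape at the origin, scales it to unit centroid size, and
#' iteratively rotates all shapes to the evolving mean shape (rotation only,
#' no reflection) until the mean changes by less than \code{tol} or
#' \code{max_iter} iterations are reached.
#'
#' @param shapes List of shape vectors of equal length.
#' @param tol Convergence tolerance on the mean-shape change (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return List with \code{aligned} (list of aligned shape vectors),
#'   \code{mean_shape}, \code{objective} (summed squared distance to the mean
#'   per iteration) and \code{iterations}.
#' @export
procrustes_align <- function(shapes, tol = 1e-8, max_iter = 100L) {
  if (length(shapes) < 2L) stop("need at least two shapes")
  n2 <- unique(lengths(shapes))
  if (length(n2) != 1L) stop("all shapes must have the same number of landmarks")
  norm_shape <- function(v) {
    xy <- shape_xy(v)
    xy <- sweep(xy, 2L, colMeans(xy))
    sz <- sqrt(sum(xy^2))
    if (sz < 1e-12) stop("degenerate zero-size shape")
    xy / sz
  }
  mats <- lapply(shapes, norm_shape)
  rotate_to <- function(X, Y) {
    M <- crossprod(X, Y)
    sv <- svd(M)
    R <- sv$u %*% diag(c(1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
    X %*% R
  }
  mean_xy <- mats[[1L]]
  objective <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mats <- lapply(mats, rotate_to, Y = mean_xy)
    new_mean <- Reduce(`+`, mats) / length(mats)
    new_mean <- sweep(new_mean, 2L, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    objective <- c(objective,
                   sum(vapply(mats, function(m) sum((m - new_mean)^2), 0)))
    if (sqrt(sum((new_mean - mean_xy)^2)) < tol || iter >= max_iter) {
      mean_xy <- new_mean
      break
    }
    mean_xy <- new_mean
  }
  # fix the rotational gauge: generalised alignment determines the common
  # frame only up to a global rotation (which would otherwise depend on the
  # input order through the initial mean). Rotate everything so the mean's
  # first landmark lies on the +x axis.
  th <- atan2(mean_xy[1L, 2L], mean_xy[1L, 1L])
  Rg <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  mats <- lapply(mats, function(m) m %*% Rg)
  mean_xy <- mean_xy %*% Rg
  list(aligned = lapply(mats, xy_shape), mean_shape = xy_shape(mean_xy),
       objective = objective, iterations = iter)
}

#' Fit the PCA stage of the point-distribution shape model
#'
#' Runs standard mean-centred PCA on the aligned \code{2n}-dimensional shape
#' vectors and keeps the top \code{n_components} modes. Mode signs are fixed
#' by forcing the largest-magnitude coordinate of each component positive so
#' the model is reproducible across eigen-solvers.
#'
#' @param aligned List of aligned shape vectors (see
#'   \code{\link{procrustes_align}}); at least \code{n_components + 1}.
#' @param n_components Number of principal modes kept (default 10).
#' @param areas Optional numeric vector of training lesion areas in pixels
#'   (all > 10) supporting \code{\link{sample_area}}.
#' @return An object of class \code{"shape_model"}: \code{mean_shape},
#'   component matrix \code{D} (\code{n_components x 2n}, orthonormal rows),
#'   \code{mode_variances} (non-increasing) and \code{area_sample}.
#' @export
fit_shape_pca <- function(aligned, n_components = 10L, areas = numeric(0)) {
  m <- length(aligned)
  if (m < n_components + 1L) {
    stop("need at least ", n_components + 1L, " shapes to fit ", n_components, " modes")
  }
  if (length(areas) && any(areas <= 10)) stop("training areas must all exceed 10 pixels")
  X <- do.call(rbind, aligned)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  D <- t(pc$rotation[, seq_len(k), drop = FALSE])
  dimnames(D) <- NULL
  vars <- pc$sdev[seq_len(k)]^2
  # deterministic mode signs
  for (i in seq_len(nrow(D))) {
    j <- which.max(abs(D[i, ]))
    if (D[i, j] < 0) D[i, ] <- -D[i, ]
  }
  structure(list(mean_shape = as.numeric(pc$center), D = D,
                 mode_variances = vars, area_sample = as.numeric(areas),
                 n_points = length(aligned[[1L]]) / 2L,
                 n_components = k),
            class = "shape_model")
}

#' Fit a shape model directly from lesion masks
#'
#' Convenience wrapper: landmarks every mask, Procrustes-aligns, fits the
#' PCA model and records the empirical lesion areas.
#'
#' @param masks List of single-lesion binary masks.
#' @inheritParams fit_shape_pca
#' @param n_points Landmarks per contour.
#' @return A \code{"shape_model"}.
#' @export
fit_shape_model <- function(masks, n_points = 200L, n_components = 10L) {
  shapes <- lapply(masks, extract_boundary_points, n_points = n_points)
  areas <- vapply(masks, sum, 0)
  fit_shape_pca(procrustes_align(shapes)$aligned, n_components, areas = areas)
}

#' @export
print.shape_model <- function(x, ...) {
  cat("Point-distribution shape model\n")
  cat(sprintf("  landmarks per contour : %d\n", x$n_points))
  cat(sprintf("  principal modes       : %d\n", x$n_components))
  cat(sprintf("  variance explained    : %s\n",
              paste(sprintf("%.3f", x$mode_variances / sum(x$mode_variances)),
                    collapse = " ")))
  cat(sprintf("  training areas        : n=%d, median=%.0f px\n",
              length(x$area_sample),
              if (length(x$area_sample)) median(x$area_sample) else NA))
  invisible(x)
}

#' @export
plot.shape_model <- function(x, modes = seq_len(min(4L, x$n_components)),
                             scale = 2, ...) {
  op <- par(mfrow = c(1, length(modes)), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  for (m in modes) {
    mu <- shape_xy(x$mean_shape)
    lo <- shape_xy(x$mean_shape - scale * sqrt(x$mode_variances[m]) * x$D[m, ])
    hi <- shape_xy(x$mean_shape + scale * sqrt(x$mode_variances[m]) * x$D[m, ])
    rng <- range(mu, lo, hi)
    plot(rbind(mu, mu[1L, ]), type = "l", asp = 1, axes = FALSE,
         xlab = "", ylab = "", xlim = rng, ylim = rng,
         main = paste0("mode ", m), ...)
    lines(rbind(lo, lo[1L, ]), lty = 2)
    lines(rbind(hi, hi[1L, ]), lty = 3)
  }
  invisible(x)
}

#' Sample a new lesion shape from the model
#'
#' Draws independent mode weights \code{w_i ~ N(0, weight_scale^2 * var_i)}
#' and returns \code{mean_shape + w \%*\% D}, resampling (up to 50 tries) if
#' the resulting polygon self-intersects.
#'
#' @param model A \code{"shape_model"}.
#' @param seed Integer seed.
#' @param weight_scale Multiplier on the per-mode standard deviations;
#'   0 returns the mean shape exactly.
#' @return A shape vector.
#' @export
sample_shape <- function(model, seed, weight_scale = 1.0) {
  with_seed(seed, {
    for (try in seq_len(50L)) {
      w <- rnorm(model$n_components, 0, weight_scale * sqrt(model$mode_variances))
      shape <- model$mean_shape + as.numeric(w %*% model$D)
      xy <- shape_xy(shape)
      if (!polygon_self_intersects(xy[, 1L], xy[, 2L])) return(shape)
    }
    stop("could not sample a simple (non-self-intersecting) shape in 50 tries")
  })
}

#' Similarity transform of a shape: area, rotation, translation
#'
#' Scales the polygon about its centroid to \code{target_area}, rotates it
#' about the centroid by \code{rotation} radians, then translates it by
#' \code{translation} (row, col).
#'
#' @param shape A shape vector.
#' @param target_area Target polygon area in pixels^2 (> 10).
#' @param rotation Rotation angle in radians.
#' @param translation Length-2 numeric \code{(row, col)} offset.
#' @return The transformed shape vector.
#' @export
transform_shape <- function(shape, target_area, rotation = 0,
                            translation = c(0, 0)) {
  if (target_area <= 10) stop("target_area must exceed 10")
  xy <- shape_xy(shape)
  ctr <- colMeans(xy)
  rel <- sweep(xy, 2L, ctr)
  cur <- polygon_area(xy[, 1L], xy[, 2L])
  if (cur <= 0) stop("shape has non-positive area")
  rel <- rel * sqrt(target_area / cur)
  R <- matrix(c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2L, 2L)
  rel <- rel %*% t(R)
  out <- sweep(rel, 2L, ctr + c(translation[2L], translation[1L]), `+`)
  xy_shape(out)
}

#' Draw a lesion area from the training-area distribution
#'
#' Resamples the empirical training areas with a small multiplicative
#' log-normal jitter (sigma = 0.1) and floors the result at 11 pixels, so
#' every sampled lesion clears the minimum-area filter.
#'
#' @param model A \code{"shape_model"} with a nonempty \code{area_sample}.
#' @param seed Integer seed.
#' @param jitter_sigma Log-scale jitter standard deviation.
#' @return A single area in pixels^2.
#' @export
sample_area <- function(model, seed, jitter_sigma = 0.1) {
  if (!length(model$area_sample)) stop("model has no training area sample")
  with_seed(seed, {
    pick <- model$area_sample[sample.int(length(model$area_sample), 1L)]
    max(pick * rlnorm(1L, 0, jitter_sigma), 11)
  })
}

#' Rasterise a shape polygon onto a pixel grid
#'
#' A pixel is foreground iff its centre lies inside the polygon under the
#' even-odd rule.
#'
#' @param shape A shape vector in 0-based \code{(x = col, y = row)} pixel
#'   coordinates.
#' @param grid_shape Integer \code{(H, W)}.
#' @return Binary H x W matrix (possibly empty for degenerate polygons).
#' @export
rasterize_shape <- function(shape, grid_shape) {
  h <- grid_shape[1L]; w <- grid_shape[2L]
  xy <- shape_xy(shape)
  if (min(xy[, 1L]) < -0.5 || max(xy[, 1L]) > w - 0.5 ||
      min(xy[, 2L]) < -0.5 || max(xy[, 2L]) > h - 0.5) {
    stop("polygon exits grid bounds")
  }
  out <- matrix(0L, h, w)
  r0 <- max(1L, floor(min(xy[, 2L])) + 1L); r1 <- min(h, ceiling(max(xy[, 2L])) + 1L)
  c0 <- max(1L, floor(min(xy[, 1L])) + 1L); c1 <- min(w, ceiling(max(xy[, 1L])) + 1L)
  if (r1 < r0 || c1 < c0) return(out)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  inside <- points_in_polygon(cc - 1, rr - 1, xy[, 1L], xy[, 2L])
  out[cbind(rr[inside], cc[inside])] <- 1L
  out
}

#' Place a sampled shape inside an organ, avoiding existing lesions
#'
#' Rejection-samples a rotation uniform on \code{[0, 2pi)} and a translation
#' uniform over organ pixels until the rasterised mask is a single connected
#' component of area > 10 lying entirely inside the organ and disjoint from
#' every existing lesion. Existing lesions are never modified.
#'
#' @param shape A shape vector (typically \code{\link{sample_shape}} output,
#'   already scaled via \code{\link{transform_shape}} /
#'   \code{\link{sample_area}}).
#' @param constraint List with \code{organ_mask} (binary, nonempty),
#'   \code{existing_lesions} (binary, same shape) and \code{max_tries}.
#' @param seed Integer seed.
#' @return Binary mask of the placed lesion.
#' @export
place_mask <- function(shape, constraint, seed) {
  organ <- constraint$organ_mask
  existing <- constraint$existing_lesions
  if (is.null(existing)) existing <- matrix(0L, nrow(organ), ncol(organ))
  max_tries <- constraint$max_tries %||% 100L
  if (!any(organ == 1)) stop("organ mask is empty")
  h <- nrow(organ); w <- ncol(organ)
  organ_idx <- which(organ == 1)
  xy <- shape_xy(shape)
  area <- polygon_area(xy[, 1L], xy[, 2L])
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      rot <- runif(1L, 0, 2 * pi)
      tgt <- organ_idx[sample.int(length(organ_idx), 1L)]
      tr <- (tgt - 1L) %% h; tc <- (tgt - 1L) %/% h
      cand <- transform_shape(shape, area, rot, translation = c(0, 0))
      cxy <- shape_xy(cand)
      ctr <- colMeans(cxy)
      cand <- xy_shape(sweep(cxy, 2L, c(tc, tr) - ctr, `+`))
      cxy <- shape_xy(cand)
      if (min(cxy[, 1L]) < -0.5 || max(cxy[, 1L]) > w - 0.5 ||
          min(cxy[, 2L]) < -0.5 || max(cxy[, 2L]) > h - 0.5) next
      m <- rasterize_shape(cand, c(h, w))
      if (sum(m) <= 10) next
      if (any(m == 1 & organ == 0)) next
      if (any(m == 1 & existing == 1)) next
      if (max(label_components(m)) != 1L) next
      return(m)
    }
    stop("could not place mask inside organ after ", max_tries,
         " tries (organ too small or crowded)")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save or load a shape model as portable YAML
#'
#' @param model A \code{"shape_model"}.
#' @param path File path.
#' @export
save_shape_model <- function(model, path) {
  yaml::write_yaml(list(mean_shape = model$mean_shape,
                        D = as.numeric(model$D), D_dim = dim(model$D),
                        mode_variances = model$mode_variances,
                        area_sample = model$area_sample,
                        n_points = model$n_points,
                        n_components = model$n_components),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname save_shape_model
#' @export
load_shape_model <- function(path) {
  d <- yaml::read_yaml(path)
  structure(list(mean_shape = as.numeric(d$mean_shape),
                 D = matrix(as.numeric(d$D), d$D_dim[1L], d$D_dim[2L]),
                 mode_variances = as.numeric(d$mode_variances),
                 area_sample = as.numeric(d$area_sample),
                 n_points = d$n_points, n_components = d$n_components),
            class = "shape_model")
}
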