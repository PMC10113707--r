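# Internal helpers shared across modules.
#
# Coordinate convention (used everywhere): 0-based (row, col) pixel indices;
# a pixel's centre is at its (row, col) coordinate; masks are {0,1} integer
# matrices.

# Deterministic sub-stream seed derived from a root seed and a stage name, so
# that every stage of a pipeline draws from its own reproducible stream.
substream_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (v in utf8ToInt(name)) h <- (h * 69069 + v) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1))) stop(what, " must be binary (values in {0,1})")
}

# Even-odd rule point-in-polygon test, vectorised over query points.
# (vx, vy) is an implicitly closed polygon.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, crosses & (px < xint))
    j <- i
  }
  inside
}

# Shoelace area of a closed polygon (absolute value).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Does the closed polygon self-intersect?  O(n^2) segment test; shapes here
# have a few hundred vertices at most.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  seg_cross <- function(i, j) {
    d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d1 <- d(x[i], y[i], x2[i], y2[i], x[j], y[j])
    d2 <- d(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- d(x[j], y[j], x2[j], y2[j], x[i], y[i])
    d4 <- d(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (seg_cross(i, j)) return(TRUE)
    }
  }
  FALSE
}

# Bilinear resize of a numeric matrix to out_h x out_w.
resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  # map output pixel centres into input pixel-centre coordinates
  ri <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  ci <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  r0 <- pmin(pmax(floor(ri), 0), h - 1); r1 <- pmin(r0 + 1, h - 1)
  c0 <- pmin(pmax(floor(ci), 0), w - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  a <- m[r0 + 1, c0 + 1, drop = FALSE]; b <- m[r0 + 1, c1 + 1, drop = FALSE]
  d <- m[r1 + 1, c0 + 1, drop = FALSE]; e <- m[r1 + 1, c1 + 1, drop = FALSE]
  top <- a * outer(rep(1, out_h), 1 - fc) + b * outer(rep(1, out_h), fc)
  bot <- d * outer(rep(1, out_h), 1 - fc) + e * outer(rep(1, out_h), fc)
  top * outer(1 - fr, rep(1, out_w)) + bot * outer(fr, rep(1, out_w))
}

# Nearest-neighbour resize; keeps binary masks binary.
resize_nearest <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(out_h) - 0.5) * h / out_h), 0), h - 1) + 1
  ci <- pmin(pmax(floor((seq_len(out_w) - 0.5) * w / out_w), 0), w - 1) + 1
  m[ri, ci, drop = FALSE]
}

# Gaussian blur of a matrix through the package's convolution kernel.
gaussian_blur <- function(m, sigma) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  half <- (k - 1L) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  ker <- outer(g1, g1); ker <- ker / sum(ker)
  X <- array(m, dim = c(nrow(m), ncol(m), 1L))
  Wmat <- matrix(as.numeric(ker), nrow = 1L)
  Y <- conv2d_fwd(X, Wmat, 0, k, 1L, as.integer(half))
  Y[, , 1L]
}

# Connected-component labelling of a binary matrix (4- or 8-connectivity),
# flood fill with an explicit stack.
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  if (connectivity == 8L) {
    nbr <- cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L), c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    nbr <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  }
  for (start in which(mask == 1 & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      pr <- (p - 1L) %% h + 1L; pc <- (p - 1L) %/% h + 1L
      rr <- pr + nbr[, 1L]; cc <- pc + nbr[, 2L]
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      idx <- (cc[ok] - 1L) * h + rr[ok]
      idx <- idx[mask[idx] == 1 & lab[idx] == 0L]
      if (length(idx)) {
        lab[idx] <- cur
        stack <- c(stack, idx)
      }
    }
  }
  lab
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
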