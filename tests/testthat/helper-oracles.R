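# Independent brute-force oracles used across the suite. These deliberately
# recompute quantities with explicit loops / enumeration so they share no code
# with the package implementation.

# Second-order moment ellipse by explicit double loops + eigen decomposition.
oracle_moments <- function(mask) {
  n <- 0
  sx <- 0
  sy <- 0
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        n <- n + 1
        sx <- sx + c
        sy <- sy + (-r)
      }
    }
  }
  cx <- sx / n
  cy <- sy / n
  sxx <- 0
  syy <- 0
  sxy <- 0
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        dx <- c - cx
        dy <- (-r) - cy
        sxx <- sxx + dx * dx
        syy <- syy + dy * dy
        sxy <- sxy + dx * dy
      }
    }
  }
  S <- matrix(c(sxx / n + 1 / 12, sxy / n, sxy / n, syy / n + 1 / 12), 2, 2)
  e <- eigen(S, symmetric = TRUE)
  lmax <- e$values[1]
  lmin <- e$values[2]
  # Orientation of the major eigenvector, mapped to (-90, 90].
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(
    area = n,
    major_axis_length = 4 * sqrt(lmax),
    eccentricity = sqrt(max(0, 1 - lmin / lmax)),
    orientation = ang,
    lmax = lmax,
    lmin = lmin
  )
}

# Brute-force convex-hull membership count: a pixel center is inside the hull
# iff it lies on the inner side of every hull edge (explicit loops).
oracle_convex_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 2) return(nrow(idx))
  x <- idx[, 2]
  y <- idx[, 1]
  h <- grDevices::chull(x, y)
  if (length(h) <= 2) {
    return(nrow(unique(idx)))
  }
  vx <- x[h]
  vy <- y[h]
  a2 <- 0
  nh <- length(h)
  for (e in seq_len(nh)) {
    j <- if (e == nh) 1 else e + 1
    a2 <- a2 + vx[e] * vy[j] - vx[j] * vy[e]
  }
  if (a2 < 0) {
    vx <- rev(vx)
    vy <- rev(vy)
  }
  count <- 0
  for (px in seq(min(vx), max(vx))) {
    for (py in seq(min(vy), max(vy))) {
      ok <- TRUE
      for (e in seq_len(nh)) {
        j <- if (e == nh) 1 else e + 1
        cross <- (vx[j] - vx[e]) * (py - vy[e]) - (vy[j] - vy[e]) * (px - vx[e])
        if (cross < -1e-7) {
          ok <- FALSE
          break
        }
      }
      if (ok) count <- count + 1
    }
  }
  count
}

# Random connected blob: grow a region by repeatedly attaching a random
# 4-neighbour of the current set.
random_blob <- function(size = 40, grid = 24, seed = 1) {
  set.seed(seed)
  mask <- matrix(FALSE, grid, grid)
  r <- sample(5:(grid - 4), 1)
  c <- sample(5:(grid - 4), 1)
  mask[r, c] <- TRUE
  cells <- matrix(c(r, c), ncol = 2)
  for (i in seq_len(size - 1)) {
    for (try in 1:50) {
      pick <- cells[sample(nrow(cells), 1), ]
      step <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample(4, 1), ]
      cand <- pick + step
      if (all(cand >= 1) && cand[1] <= grid && cand[2] <= grid &&
          !mask[cand[1], cand[2]]) {
        mask[cand[1], cand[2]] <- TRUE
        cells <- rbind(cells, cand)
        break
      }
    }
  }
  mask
}

# Exhaustive minimum energy over all labelings consistent with the seeds
# (free pixels enumerated; energy recomputed with explicit loops).
oracle_min_energy <- function(lum, fg, bg, lambda, sigma, neighborhood = 4) {
  H <- nrow(lum)
  W <- ncol(lum)
  fit <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1) s <- 1
    c(mean(v), s)
  }
  f <- fit(lum[fg])
  b <- fit(lum[bg])
  nll <- function(x, p) 0.5 * ((x - p[1]) / p[2])^2 + log(p[2]) + 0.5 * log(2 * pi)
  free <- which(!fg & !bg)
  nfree <- length(free)
  stopifnot(nfree <= 16)
  pairs <- list()
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      i <- (c - 1) * H + r
      if (c < W) pairs[[length(pairs) + 1]] <- c(i, i + H, 1)
      if (r < H) pairs[[length(pairs) + 1]] <- c(i, i + 1, 1)
      if (neighborhood == 8 && r < H && c < W) {
        pairs[[length(pairs) + 1]] <- c(i, i + H + 1, sqrt(2))
      }
      if (neighborhood == 8 && r > 1 && c < W) {
        pairs[[length(pairs) + 1]] <- c(i, i + H - 1, sqrt(2))
      }
    }
  }
  best <- Inf
  lab <- matrix(FALSE, H, W)
  lab[fg] <- TRUE
  for (bits in 0:(2^nfree - 1)) {
    l <- lab
    if (nfree > 0) {
      on <- as.logical(bitwAnd(bits, 2^(seq_len(nfree) - 1)))
      l[free[on]] <- TRUE
    }
    e <- 0
    for (i in seq_len(H * W)) {
      e <- e + if (l[i]) nll(lum[i], f) else nll(lum[i], b)
    }
    for (p in pairs) {
      if (l[p[1]] != l[p[2]]) {
        e <- e + lambda * exp(-(lum[p[1]] - lum[p[2]])^2 / (2 * sigma^2)) / p[3]
      }
    }
    if (e < best) best <- e
  }
  best
}

iou <- function(a, b) sum(a & b) / sum(a | b)

luminance_of <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Tiny flat RGB image helper.
flat_image <- function(H, W, rgb = c(128, 128, 128)) {
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}
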