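#' Area, centroid and second-order central moments of a binary region
#'
#' The moment machinery behind the ellipse-of-inertia descriptors. Coordinates
#' follow the regionprops convention: x is the column index, y is the row
#' index flipped to point up, and each pixel contributes the second moment of
#' a unit square (the +1/12 correction on the diagonal), so single-pixel and
#' one-pixel-wide regions still define a proper ellipse.
#'
#' @param region_mask Logical (or 0/1) matrix with at least one set pixel.
#' @return A list with `area` (pixel count), `centroid` (c(x, y-up)) and
#'   `covariance` (2 x 2 matrix of the corrected normalized central moments
#'   \eqn{\mu'_{20}, \mu'_{11}, \mu'_{02}}).
#' @export
#' @examples
#' region_moments(matrix(TRUE, 1, 1))$covariance  # diag(1/12, 1/12)
region_moments <- function(region_mask) {
  region_mask <- as_logical_mask(as.matrix(region_mask))
  idx <- which(region_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("region_mask has no set pixel")
  x <- idx[, 2]          # column
  y <- -idx[, 1]         # row, flipped so y points up
  n <- length(x)
  cx <- mean(x)
  cy <- mean(y)
  mu20 <- mean((x - cx)^2) + 1 / 12
  mu02 <- mean((y - cy)^2) + 1 / 12
  mu11 <- mean((x - cx) * (y - cy))
  list(area = n,
       centroid = c(x = cx, y = cy),
       covariance = matrix(c(mu20, mu11, mu11, mu02), 2, 2,
                           dimnames = list(c("x", "y"), c("x", "y"))))
}

# Closed outer-boundary walk of a region (Moore neighbourhood, clockwise),
# returning the walk length with unit steps for 4-neighbour moves and sqrt(2)
# for diagonal moves. A single pixel has no steps and perimeter 0.
#
# The tracer iterates the deterministic state (current pixel, backtrack
# neighbour); the state space is finite so the walk enters a cycle, and the
# perimeter is the length of that cycle (the closed boundary circuit).
boundary_perimeter <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 1L) return(0)
  H <- nrow(mask)
  W <- ncol(mask)
  p <- matrix(FALSE, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- mask
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1], ] + 1L  # padded coords; topmost then leftmost
  # Clockwise neighbours starting at W (image rows grow downwards).
  nb <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
               ncol = 2L, byrow = TRUE)
  step_len <- ifelse(abs(nb[, 1]) + abs(nb[, 2]) == 2L, sqrt(2), 1)

  cur <- start
  b_dir <- 1L  # backtrack = W neighbour of the start, empty by construction
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cum <- 0
  lens <- numeric(0)
  cap <- 8L * n + 16L
  for (it in seq_len(cap)) {
    key <- paste(cur[1], cur[2], b_dir, sep = ",")
    prev <- get0(key, envir = seen)
    if (!is.null(prev)) return(cum - prev)
    assign(key, cum, envir = seen)
    moved <- FALSE
    for (k in 1:8) {
      d <- ((b_dir - 1L + k) %% 8L) + 1L
      cand <- cur + nb[d, ]
      if (p[cand[1], cand[2]]) {
        # New backtrack: the last empty neighbour checked (direction d-1 from
        # `cur`, which is the old backtrack itself when k == 1), re-expressed
        # as a direction from the new current pixel `cand`.
        prev_empty <- cur + nb[((d - 2L) %% 8L) + 1L, ]
        off <- prev_empty - cand
        b_dir <- which(nb[, 1] == off[1] & nb[, 2] == off[2])
        cum <- cum + step_len[d]
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) return(0)  # isolated pixel (cannot happen for n > 1 connected)
  }
  cum
}

#' Six geometric descriptors of one superpixel region
#'
#' Computes the shape features used as the classifier input: area (pixel
#' count), perimeter (length of the closed 8-connected outer boundary walk,
#' with diagonal steps weighted \eqn{\sqrt 2}), and the ellipse-of-inertia
#' descriptors orientation (degrees in (-90, 90], measured counter-clockwise
#' from the +x/column axis with y pointing up), eccentricity
#' (\eqn{\sqrt{1 - \lambda_{min}/\lambda_{max}}}), major axis length
#' (\eqn{4\sqrt{\lambda_{max}}}), plus the convex area (pixels whose centers
#' fall inside the filled convex hull of the region's pixel centers).
#'
#' Regions with several 4-connected components (possible after mask
#' intersection) are reduced to their largest component first.
#'
#' @param region_mask Logical (or 0/1) matrix with at least one set pixel.
#' @return A one-row tibble with columns `area`, `perimeter`, `eccentricity`,
#'   `orientation`, `convex_area`, `major_axis_length`.
#' @export
#' @examples
#' sq <- matrix(FALSE, 12, 12); sq[2:11, 2:11] <- TRUE
#' compute_sp_features(sq)  # area 100, perimeter 36, eccentricity 0
compute_sp_features <- function(region_mask) {
  region_mask <- as_logical_mask(as.matrix(region_mask))
  if (!any(region_mask)) stopf("region_mask has no set pixel")
  cc <- label_components(region_mask)
  if (max(cc) > 1L) {
    sizes <- tabulate(cc[cc > 0L])
    region_mask <- cc == which.max(sizes)
  }
  m <- region_moments(region_mask)
  S <- m$covariance
  common <- (S[1, 1] + S[2, 2]) / 2
  delta <- sqrt(((S[1, 1] - S[2, 2]) / 2)^2 + S[1, 2]^2)
  lmax <- common + delta
  lmin <- max(common - delta, 0)
  orient <- 0.5 * atan2(2 * S[1, 2], S[1, 1] - S[2, 2]) * 180 / pi
  if (orient <= -90) orient <- orient + 180
  if (orient > 90) orient <- orient - 180
  tibble::tibble(
    area = m$area,
    perimeter = boundary_perimeter(region_mask),
    eccentricity = sqrt(max(0, 1 - lmin / lmax)),
    orientation = orient,
    convex_area = convex_area_px(region_mask),
    major_axis_length = 4 * sqrt(lmax)
  )
}

# Number of pixel centers inside (or on) the filled convex hull of the
# region's pixel centers. Hull vertices come from grDevices::chull; membership
# is a vectorized half-plane test over the hull's bounding box. Degenerate
# (collinear) regions count lattice centers lying on the segment.
convex_area_px <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n <= 2L) return(n)
  x <- idx[, 2]
  y <- idx[, 1]
  h <- grDevices::chull(x, y)
  if (length(h) <= 2L) {
    # Collinear: count lattice centers on the extreme segment.
    a <- c(x[h[1]], y[h[1]])
    b <- c(x[h[length(h)]], y[h[length(h)]])
    gx <- seq(min(x), max(x))
    gy <- seq(min(y), max(y))
    pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    d <- abs((b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1]))
    seg <- sqrt(sum((b - a)^2))
    on_line <- d / max(seg, 1) < 1e-9
    within <- (pts[, 1] - a[1]) * (b[1] - a[1]) + (pts[, 2] - a[2]) * (b[2] - a[2])
    return(sum(on_line & within >= -1e-9 & within <= seg^2 + 1e-9))
  }
  vx <- x[h]
  vy <- y[h]
  # Orient counter-clockwise (shoelace).
  a2 <- sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)
  if (a2 < 0) {
    vx <- rev(vx)
    vy <- rev(vy)
  }
  gx <- seq(min(vx), max(vx))
  gy <- seq(min(vy), max(vy))
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  nh <- length(vx)
  for (e in seq_len(nh)) {
    j <- if (e == nh) 1L else e + 1L
    cross <- (vx[j] - vx[e]) * (py - vy[e]) - (vy[j] - vy[e]) * (px - vx[e])
    inside <- inside & (cross >= -1e-7)
    if (!any(inside)) break
  }
  sum(inside)
}

#' Extract feature records for every kept superpixel
#'
#' Runs [compute_sp_features()] on the pixel set of each label kept after
#' background elimination and tags each record with the image id and the
#' image-level class.
#'
#' @param sp_set A [superpixel_set] as returned by
#'   [filter_background_superpixels()].
#' @param image_id Identifier copied into every record.
#' @param class_label `"nevus"`/`"melanoma"` or 0/1.
#' @return A tibble with one row per kept superpixel: `image_id`, `sp_label`,
#'   the six feature columns, `class` (0 = nevus, 1 = melanoma).
#' @export
extract_all <- function(sp_set, image_id, class_label) {
  if (!inherits(sp_set, "superpixel_set")) {
    stopf("`sp_set` must be a superpixel_set")
  }
  cls <- class_to_int(class_label)
  kept <- sp_set$kept_labels
  if (length(kept) == 0L) {
    return(tibble::tibble(image_id = character(), sp_label = integer(),
                          area = numeric(), perimeter = numeric(),
                          eccentricity = numeric(), orientation = numeric(),
                          convex_area = numeric(), major_axis_length = numeric(),
                          class = integer()))
  }
  lm <- sp_set$label_map
  rows <- purrr::map(kept, function(l) {
    compute_sp_features(lm == l)
  })
  dplyr::bind_cols(
    tibble::tibble(image_id = as.character(image_id), sp_label = as.integer(kept)),
    dplyr::bind_rows(rows),
    tibble::tibble(class = cls)
  )
}

class_to_int <- function(class_label) {
  if (is.numeric(class_label)) {
    cls <- as.integer(class_label)
    if (!cls %in% c(0L, 1L)) stopf("numeric class must be 0 (nevus) or 1 (melanoma)")
    return(cls)
  }
  switch(as.character(class_label),
         nevus = 0L, melanoma = 1L,
         stopf("unknown class label '%s'", class_label))
}
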