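#' Parameters for SLIC superpixel generation
#'
#' @param n_superpixels Target number of superpixels `n` (default 100, the
#'   value at which classification works best in this pipeline).
#' @param compactness SLIC compactness `m`: weight of the spatial distance
#'   against the CIELAB color distance (default 10).
#' @param max_iterations Number of assignment/update sweeps (default 10).
#' @param min_size_fraction Fragments smaller than
#'   `min_size_fraction * (H*W/n)` are merged into an adjacent superpixel
#'   during connectivity enforcement (default 1/4).
#' @return An object of class `slic_params`.
#' @export
slic_params <- function(n_superpixels = 100, compactness = 10,
                        max_iterations = 10, min_size_fraction = 0.25) {
  if (n_superpixels < 2) stopf("n_superpixels must be >= 2")
  if (compactness <= 0) stopf("compactness must be > 0")
  if (min_size_fraction <= 0 || min_size_fraction >= 1) {
    stopf("min_size_fraction must be in (0, 1)")
  }
  structure(list(n_superpixels = as.integer(n_superpixels),
                 compactness = as.numeric(compactness),
                 max_iterations = as.integer(max_iterations),
                 min_size_fraction = as.numeric(min_size_fraction)),
            class = "slic_params")
}

# sRGB (0-255) -> CIELAB, returned as three H x W matrices.
rgb_to_lab <- function(rgb_image) {
  H <- dim(rgb_image)[1]
  W <- dim(rgb_image)[2]
  m <- cbind(as.vector(rgb_image[, , 1]),
             as.vector(rgb_image[, , 2]),
             as.vector(rgb_image[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], H, W),
       a = matrix(lab[, 2], H, W),
       b = matrix(lab[, 3], H, W))
}

#' SLIC superpixel segmentation
#'
#' Localized k-means in the joint CIELAB + image-plane space. Cluster centers
#' start on a regular grid with step \eqn{S = \sqrt{HW/n}}, are nudged to the
#' lowest-gradient position in their 3x3 neighbourhood, and pixels within a
#' 2S x 2S window of each center are assigned by the distance
#' \deqn{D = \sqrt{d_{lab}^2 + (d_{xy}/S)^2 m^2}.}
#' After the iterations, connectivity is enforced
#' ([enforce_connectivity()]): every final label is a single 4-connected
#' region and fragments below the minimum size are absorbed by a neighbour.
#' The procedure is fully deterministic.
#'
#' @param rgb_image H x W x 3 array, 0-255.
#' @param params A [slic_params()].
#' @return An integer H x W label matrix with contiguous labels `1..L`.
#' @export
#' @examples
#' img <- array(128, dim = c(48, 48, 3))
#' table(slic_superpixels(img, slic_params(n_superpixels = 4)))
slic_superpixels <- function(rgb_image, params = slic_params()) {
  assert_image(rgb_image)
  H <- dim(rgb_image)[1]
  W <- dim(rgb_image)[2]
  n <- params$n_superpixels
  if (n > H * W) stopf("n_superpixels = %d exceeds the pixel count %d", n, H * W)
  lab <- rgb_to_lab(rgb_image)
  S <- sqrt(H * W / n)
  m <- params$compactness

  # Regular grid initialization: ny * nx ~ n with grid aspect following the
  # image aspect (guarantees >= 2 centers even for tiny n).
  ny <- max(1L, round(sqrt(n * H / W)))
  nx <- max(1L, round(n / ny))
  if (ny * nx < 2L) nx <- 2L
  cy <- (seq_len(ny) - 0.5) * H / ny
  cx <- (seq_len(nx) - 0.5) * W / nx
  centers <- expand.grid(y = cy, x = cx)
  cr <- pmin(pmax(round(centers$y), 1L), H)
  cc <- pmin(pmax(round(centers$x), 1L), W)

  # Perturb each center to the lowest-gradient pixel in its 3x3 window.
  grad <- lab_gradient(lab)
  for (i in seq_along(cr)) {
    rs <- max(1L, cr[i] - 1L):min(H, cr[i] + 1L)
    cs <- max(1L, cc[i] - 1L):min(W, cc[i] + 1L)
    wdw <- grad[rs, cs, drop = FALSE]
    best <- which(wdw == min(wdw), arr.ind = TRUE)[1, ]
    cr[i] <- rs[best[1]]
    cc[i] <- cs[best[2]]
  }

  k <- length(cr)
  cL <- lab$L[cbind(cr, cc)]
  ca <- lab$a[cbind(cr, cc)]
  cb <- lab$b[cbind(cr, cc)]
  cyf <- as.numeric(cr)
  cxf <- as.numeric(cc)

  rows_m <- matrix(rep(seq_len(H), times = W), H, W)
  cols_m <- matrix(rep(seq_len(W), each = H), H, W)
  labels <- matrix(0L, H, W)

  for (it in seq_len(params$max_iterations)) {
    dist_best <- matrix(Inf, H, W)
    labels_new <- matrix(0L, H, W)
    for (i in seq_len(k)) {
      rs <- max(1L, floor(cyf[i] - S)):min(H, ceiling(cyf[i] + S))
      cs <- max(1L, floor(cxf[i] - S)):min(W, ceiling(cxf[i] + S))
      dl <- lab$L[rs, cs, drop = FALSE] - cL[i]
      da <- lab$a[rs, cs, drop = FALSE] - ca[i]
      db <- lab$b[rs, cs, drop = FALSE] - cb[i]
      dy <- rows_m[rs, cs, drop = FALSE] - cyf[i]
      dx <- cols_m[rs, cs, drop = FALSE] - cxf[i]
      D <- dl^2 + da^2 + db^2 + (dy^2 + dx^2) / S^2 * m^2
      better <- D < dist_best[rs, cs]
      if (any(better)) {
        sub <- dist_best[rs, cs]
        sub[better] <- D[better]
        dist_best[rs, cs] <- sub
        subl <- labels_new[rs, cs]
        subl[better] <- i
        labels_new[rs, cs] <- subl
      }
    }
    # Orphans outside every search window (possible on ragged grids): nearest
    # center spatially.
    if (any(labels_new == 0L)) {
      orph <- which(labels_new == 0L, arr.ind = TRUE)
      for (j in seq_len(nrow(orph))) {
        d2 <- (cyf - orph[j, 1])^2 + (cxf - orph[j, 2])^2
        labels_new[orph[j, 1], orph[j, 2]] <- which.min(d2)
      }
    }
    labels <- labels_new
    # Center update.
    lv <- as.vector(labels)
    cnt <- tabulate(lv, nbins = k)
    nz <- cnt > 0L
    agg <- function(v) {
      a <- rowsum(v, lv)          # one row per label actually present
      out <- numeric(k)
      out[as.integer(rownames(a))] <- a[, 1]
      out
    }
    cL[nz] <- agg(as.vector(lab$L))[nz] / cnt[nz]
    ca[nz] <- agg(as.vector(lab$a))[nz] / cnt[nz]
    cb[nz] <- agg(as.vector(lab$b))[nz] / cnt[nz]
    cyf[nz] <- agg(as.vector(rows_m))[nz] / cnt[nz]
    cxf[nz] <- agg(as.vector(cols_m))[nz] / cnt[nz]
  }

  min_size <- max(1L, floor(params$min_size_fraction * H * W / n))
  enforce_connectivity(labels, min_size)
}

# Squared CIELAB gradient magnitude (central differences, replicated edges).
lab_gradient <- function(lab) {
  g <- matrix(0, nrow(lab$L), ncol(lab$L))
  for (ch in lab) {
    H <- nrow(ch)
    W <- ncol(ch)
    gx <- ch[, c(2:W, W)] - ch[, c(1, 1:(W - 1))]
    gy <- ch[c(2:H, H), ] - ch[c(1, 1:(H - 1)), ]
    g <- g + gx^2 + gy^2
  }
  g
}

#' Enforce one 4-connected component per superpixel label
#'
#' Splits every 4-connected component of the label map into its own label,
#' absorbs components smaller than `min_size` into the largest 4-adjacent
#' component, and compacts the surviving labels to `1..L` (ordered by first
#' pixel occurrence, so the result is deterministic).
#'
#' @param label_map Integer H x W label matrix.
#' @param min_size Minimum component size in pixels.
#' @return Integer H x W label matrix satisfying the connectivity invariant.
#' @export
enforce_connectivity <- function(label_map, min_size = 1L) {
  H <- nrow(label_map)
  W <- ncol(label_map)
  comp <- matrix(0L, H, W)
  nc <- 0L
  for (l in sort(unique(as.vector(label_map)))) {
    cc <- label_components(label_map == l)
    sel <- cc > 0L
    comp[sel] <- cc[sel] + nc
    nc <- nc + max(cc)
  }
  sizes <- tabulate(as.vector(comp), nbins = nc)

  # Absorb small components, smallest first, into their largest neighbour.
  repeat {
    small <- which(sizes > 0L & sizes < min_size)
    if (length(small) == 0L || nc <= 1L) break
    sm <- small[which.min(sizes[small])]
    px <- which(comp == sm, arr.ind = TRUE)
    nb <- integer(0)
    r <- px[, 1]
    c <- px[, 2]
    up <- r > 1L
    dn <- r < H
    lf <- c > 1L
    rt <- c < W
    nb <- c(comp[cbind(r[up] - 1L, c[up])], comp[cbind(r[dn] + 1L, c[dn])],
            comp[cbind(r[lf], c[lf] - 1L)], comp[cbind(r[rt], c[rt] + 1L)])
    nb <- nb[nb != sm]
    if (length(nb) == 0L) {  # isolated island smaller than min_size: keep it
      sizes[sm] <- min_size
      next
    }
    target <- unique(nb)[which.max(sizes[unique(nb)])]
    comp[comp == sm] <- target
    sizes[target] <- sizes[target] + sizes[sm]
    sizes[sm] <- 0L
  }

  # Compact to 1..L in order of first appearance (column-major scan).
  v <- as.vector(comp)
  first <- match(sort(unique(v)), v)
  ord <- sort(unique(v))[order(first)]
  lut <- integer(nc)
  lut[ord] <- seq_along(ord)
  matrix(lut[v], H, W)
}

#' Eliminate background superpixels against a lesion mask
#'
#' The background-elimination step of iSLIC: a superpixel is kept when the
#' fraction of its pixels lying inside the lesion mask reaches
#' `overlap_threshold` (majority rule at the default 0.5). Discarded labels
#' stay in the label map; only the kept set changes.
#'
#' @param label_map Integer H x W label matrix (labels `1..L`).
#' @param lesion_mask Logical H x W matrix (the black-mask foreground).
#' @param overlap_threshold Fraction in (0, 1] (default 0.5).
#' @param n_requested The `n` the label map was generated with (metadata).
#' @return A `superpixel_set`: list with `label_map`, `kept_labels`,
#'   `n_requested`, `n_kept` and `per_label_pixel_count`.
#' @export
filter_background_superpixels <- function(label_map, lesion_mask,
                                          overlap_threshold = 0.5,
                                          n_requested = NA_integer_) {
  assert_mask(lesion_mask, c(dim(label_map), 1), "lesion_mask")
  if (overlap_threshold <= 0 || overlap_threshold > 1) {
    stopf("overlap_threshold must be in (0, 1]")
  }
  keep <- as_logical_mask(lesion_mask)
  L <- max(label_map)
  total <- tabulate(as.vector(label_map), nbins = L)
  inside <- tabulate(as.vector(label_map)[as.vector(keep)], nbins = L)
  frac <- ifelse(total > 0L, inside / total, 0)
  kept <- which(total > 0L & frac >= overlap_threshold)
  structure(list(label_map = label_map,
                 kept_labels = as.integer(kept),
                 n_requested = as.integer(n_requested),
                 n_kept = length(kept),
                 per_label_pixel_count = stats::setNames(total, seq_len(L))),
            class = "superpixel_set")
}

#' @export
print.superpixel_set <- function(x, ...) {
  cat(sprintf("<superpixel_set> %d x %d map, %d labels, %d kept (n requested: %s)\n",
              nrow(x$label_map), ncol(x$label_map),
              length(x$per_label_pixel_count), x$n_kept,
              ifelse(is.na(x$n_requested), "?", x$n_requested)))
  invisible(x)
}
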