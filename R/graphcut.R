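#' Parameters for seeded graph-cut lesion segmentation
#'
#' The lesion mask is the minimum s-t cut of a pixel grid graph. Data terms
#' are negative Gaussian log-likelihoods of pixel luminance under models
#' estimated from the foreground/background seeds; pairwise terms are the
#' contrast-sensitive Potts weights
#' \eqn{\lambda \exp(-(I_i - I_j)^2 / 2\sigma^2) / dist(i,j)}.
#'
#' @param lambda_smooth Smoothness weight (> 0).
#' @param sigma_contrast Contrast scale in intensity units (> 0).
#' @param neighborhood 4 or 8.
#' @param border_margin Width (pixels) of the frame used as background seeds.
#' @param fg_quantile Luminance quantile below which central pixels become
#'   foreground seeds (lesions are darker than skin).
#' @return An object of class `graphcut_params`.
#' @export
graphcut_params <- function(lambda_smooth = 50,
                            sigma_contrast = 10,
                            neighborhood = 4,
                            border_margin = 8,
                            fg_quantile = 0.1) {
  if (lambda_smooth <= 0) stopf("lambda_smooth must be > 0")
  if (sigma_contrast <= 0) stopf("sigma_contrast must be > 0")
  if (!neighborhood %in% c(4, 8)) stopf("neighborhood must be 4 or 8")
  if (fg_quantile <= 0 || fg_quantile >= 1) stopf("fg_quantile must be in (0,1)")
  structure(list(lambda_smooth = as.numeric(lambda_smooth),
                 sigma_contrast = as.numeric(sigma_contrast),
                 neighborhood = as.integer(neighborhood),
                 border_margin = as.integer(border_margin),
                 fg_quantile = as.numeric(fg_quantile)),
            class = "graphcut_params")
}

#' Automatic foreground/background seeds for lesion segmentation
#'
#' Background seeds are the border frame of width `border_margin` (lesions sit
#' centrally in dermoscopy frames). Foreground seeds are the pixels strictly
#' darker than the `fg_quantile` luminance quantile, restricted to the central
#' half of the image, reduced to their largest connected component. A constant
#' image has no pixel strictly below its quantile and is rejected: there is no
#' darkness contrast to seed from.
#'
#' @param rgb_image H x W x 3 array, 0-255.
#' @param params A [graphcut_params()].
#' @return A list with logical matrices `fg_seed_mask` and `bg_seed_mask`
#'   (disjoint, both non-empty).
#' @export
auto_seeds <- function(rgb_image, params = graphcut_params()) {
  assert_image(rgb_image)
  H <- dim(rgb_image)[1]
  W <- dim(rgb_image)[2]
  m <- params$border_margin
  if (H <= 2 * m || W <= 2 * m) {
    stopf("image (%d x %d) is not larger than twice border_margin = %d", H, W, m)
  }
  bg <- matrix(FALSE, H, W)
  bg[c(seq_len(m), H - m + seq_len(m)), ] <- TRUE
  bg[, c(seq_len(m), W - m + seq_len(m))] <- TRUE

  lum <- luminance(rgb_image)
  thr <- stats::quantile(lum, params$fg_quantile, names = FALSE)
  central <- matrix(FALSE, H, W)
  central[(floor(H / 4) + 1):ceiling(3 * H / 4), (floor(W / 4) + 1):ceiling(3 * W / 4)] <- TRUE
  cand <- (lum < thr) & central
  if (!any(cand)) {
    stopf("no foreground seed: no central pixel is darker than the %.0f%% luminance quantile",
          100 * params$fg_quantile)
  }
  fg <- largest_component(cand)
  fg <- fg & !bg
  if (!any(fg)) stopf("no foreground seed after excluding the border frame")
  list(fg_seed_mask = fg, bg_seed_mask = bg)
}

# Build the n-link table for a grid of size H x W: columns (i, j, weight),
# one undirected pair per row.
grid_nlinks <- function(lum, params) {
  H <- nrow(lum)
  W <- ncol(lum)
  idx <- matrix(seq_len(H * W), H, W)
  lam <- params$lambda_smooth
  sig <- params$sigma_contrast
  pair <- function(i, j, d) {
    w <- lam * exp(-(lum[i] - lum[j])^2 / (2 * sig^2)) / d
    cbind(i = i, j = j, w = w)
  }
  links <- list(
    pair(as.vector(idx[, -W]), as.vector(idx[, -1]), 1),     # horizontal
    pair(as.vector(idx[-H, ]), as.vector(idx[-1, ]), 1)      # vertical
  )
  if (params$neighborhood == 8L) {
    links <- c(links, list(
      pair(as.vector(idx[-H, -W]), as.vector(idx[-1, -1]), sqrt(2)),
      pair(as.vector(idx[-1, -W]), as.vector(idx[-H, -1]), sqrt(2))
    ))
  }
  do.call(rbind, links)
}

# Gaussian negative log-likelihood data terms from seed statistics.
seed_data_terms <- function(lum, fg, bg) {
  fit <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1) s <- 1   # floor: near-constant seed regions
    c(mean(v), s)
  }
  f <- fit(lum[fg])
  b <- fit(lum[bg])
  nll <- function(mu_sd) {
    0.5 * ((lum - mu_sd[1]) / mu_sd[2])^2 + log(mu_sd[2]) + 0.5 * log(2 * pi)
  }
  list(fg = nll(f), bg = nll(b))
}

#' Lesion segmentation by minimum s-t cut
#'
#' Solves the seeded binary labeling exactly: source-side pixels after the
#' minimum cut are the lesion. Terminal capacities carry the data terms
#' (seeds get effectively infinite capacity on their side), neighbour edges
#' carry the contrast weights, so the cut value equals the labeling energy
#' \eqn{\sum_i D_i(x_i) + \sum_{ij} w_{ij}[x_i \ne x_j]} and the solver
#' (push-relabel max-flow) returns its global minimum.
#'
#' @param rgb_image H x W x 3 array, 0-255.
#' @param fg_seed_mask,bg_seed_mask Disjoint non-empty logical matrices.
#' @param params A [graphcut_params()].
#' @param postprocess If `TRUE` (the contract's default) the raw cut is
#'   reduced to the connected component(s) containing foreground seeds and
#'   holes are filled (holes containing background seeds stay open). Set to
#'   `FALSE` to obtain the untouched minimum-energy labeling.
#' @return Logical H x W lesion mask.
#' @export
graph_cut_segment <- function(rgb_image, fg_seed_mask, bg_seed_mask,
                              params = graphcut_params(), postprocess = TRUE) {
  assert_image(rgb_image)
  assert_mask(fg_seed_mask, dim(rgb_image), "fg_seed_mask")
  assert_mask(bg_seed_mask, dim(rgb_image), "bg_seed_mask")
  fg <- as_logical_mask(fg_seed_mask)
  bg <- as_logical_mask(bg_seed_mask)
  if (!any(fg) || !any(bg)) stopf("both seed masks must be non-empty")
  if (any(fg & bg)) stopf("infeasible seeds: foreground and background masks overlap")

  H <- dim(rgb_image)[1]
  W <- dim(rgb_image)[2]
  n <- H * W
  lum <- luminance(rgb_image)
  dt <- seed_data_terms(lum, fg, bg)

  INF <- sum(abs(dt$fg)) + sum(abs(dt$bg)) + n * params$lambda_smooth * 8 + 1e6

  cap_s <- dt$bg            # paid when a pixel is labeled background
  cap_t <- dt$fg            # paid when a pixel is labeled foreground/lesion
  off <- min(cap_s, cap_t, 0)
  cap_s <- cap_s - off      # igraph wants non-negative capacities; a common
  cap_t <- cap_t - off      # shift per pixel leaves the argmin unchanged
  cap_s[fg] <- INF
  cap_t[fg] <- 0
  cap_t[bg] <- INF
  cap_s[bg] <- 0

  nl <- grid_nlinks(lum, params)
  cap_s <- as.vector(cap_s)
  cap_t <- as.vector(cap_t)

  # Exact reduction: a pixel whose unary margin exceeds the total weight of
  # its incident neighbour edges takes the cheaper label in *every* optimal
  # labeling (flipping it changes the pairwise part by at most that total),
  # so only the uncertain band near the lesion boundary needs the flow
  # solver. Seeds are fixed through their infinite terminal capacities.
  wsum <- numeric(n)
  agg1 <- rowsum(nl[, 3], nl[, 1])
  agg2 <- rowsum(nl[, 3], nl[, 2])
  wsum[as.integer(rownames(agg1))] <- agg1[, 1]
  wsum[as.integer(rownames(agg2))] <- wsum[as.integer(rownames(agg2))] + agg2[, 1]
  fixed_fg <- cap_s - cap_t > wsum
  fixed_bg <- cap_t - cap_s > wsum
  free <- which(!fixed_fg & !fixed_bg)

  label <- fixed_fg  # logical over pixels; free entries decided below
  if (length(free) > 0L) {
    pos <- integer(n)
    pos[free] <- seq_along(free)
    fi <- pos[nl[, 1]]
    fj <- pos[nl[, 2]]
    both <- fi > 0L & fj > 0L
    # Neighbour edges between a free pixel and a fixed one turn into
    # terminal capacities on the free side.
    add_s <- rowsum(nl[fj == 0L & fi > 0L & fixed_fg[nl[, 2]], 3,
                       drop = FALSE],
                    fi[fj == 0L & fi > 0L & fixed_fg[nl[, 2]]])
    add_t <- rowsum(nl[fj == 0L & fi > 0L & fixed_bg[nl[, 2]], 3,
                       drop = FALSE],
                    fi[fj == 0L & fi > 0L & fixed_bg[nl[, 2]]])
    add_s2 <- rowsum(nl[fi == 0L & fj > 0L & fixed_fg[nl[, 1]], 3,
                        drop = FALSE],
                     fj[fi == 0L & fj > 0L & fixed_fg[nl[, 1]]])
    add_t2 <- rowsum(nl[fi == 0L & fj > 0L & fixed_bg[nl[, 1]], 3,
                        drop = FALSE],
                     fj[fi == 0L & fj > 0L & fixed_bg[nl[, 1]]])
    cs <- cap_s[free]
    ct <- cap_t[free]
    bump <- function(v, agg) {
      if (nrow(agg) > 0L) {
        id <- as.integer(rownames(agg))
        v[id] <- v[id] + agg[, 1]
      }
      v
    }
    cs <- bump(bump(cs, add_s), add_s2)
    ct <- bump(bump(ct, add_t), add_t2)

    nf <- length(free)
    s <- nf + 1L
    t <- nf + 2L
    ed <- rbind(
      cbind(s, seq_len(nf)),
      cbind(seq_len(nf), t),
      cbind(fi[both], fj[both]),
      cbind(fj[both], fi[both])
    )
    caps <- c(cs, ct, nl[both, 3], nl[both, 3])
    g <- igraph::graph_from_edgelist(ed, directed = TRUE)
    flow <- igraph::max_flow(g, source = s, target = t, capacity = caps)
    src_side <- as.integer(flow$partition1)
    label[free[src_side[src_side <= nf]]] <- TRUE
  }
  lesion <- matrix(label, H, W)

  if (any(fg & !lesion) || any(bg & lesion)) {
    stopf("internal error: min-cut labeling violates seeds")  # nocov
  }
  if (postprocess) lesion <- postprocess_lesion(lesion, fg, bg)
  lesion
}

# Keep the components holding fg seeds; fill holes unless a hole contains a
# background seed (seed compliance is part of the contract).
postprocess_lesion <- function(lesion, fg, bg) {
  cc <- label_components(lesion)
  keep_ids <- unique(cc[fg & cc > 0L])
  lesion <- matrix(cc %in% keep_ids, nrow(lesion), ncol(lesion))
  filled <- as_logical_mask(matrix(EBImage::imageData(
    EBImage::fillHull(ebi(matrix(as.numeric(lesion), nrow(lesion), ncol(lesion))))),
    nrow(lesion), ncol(lesion)))
  holes <- filled & !lesion
  if (any(holes)) {
    hc <- label_components(holes)
    bad <- unique(hc[bg & hc > 0L])
    fill_ok <- holes & !(hc %in% bad)
    lesion <- lesion | fill_ok
  }
  lesion
}

# Energy of a labeling under the graph-cut model; used by the optimality
# checks (exhaustive enumeration on miniatures).
graphcut_energy <- function(rgb_image, labeling, fg_seed_mask, bg_seed_mask,
                            params = graphcut_params()) {
  lum <- luminance(rgb_image)
  fg <- as_logical_mask(fg_seed_mask)
  bg <- as_logical_mask(bg_seed_mask)
  lab <- as_logical_mask(labeling)
  if (any(fg & !lab) || any(bg & lab)) return(Inf)
  dt <- seed_data_terms(lum, fg, bg)
  e <- sum(dt$fg[lab]) + sum(dt$bg[!lab])
  nl <- grid_nlinks(lum, params)
  cut <- lab[nl[, 1]] != lab[nl[, 2]]
  e + sum(nl[cut, 3])
}

#' Blacken everything outside the lesion mask
#'
#' @param rgb_image H x W x 3 array.
#' @param lesion_mask Logical H x W matrix.
#' @return The image with all background pixels set to (0, 0, 0).
#' @export
apply_black_mask <- function(rgb_image, lesion_mask) {
  assert_image(rgb_image)
  assert_mask(lesion_mask, dim(rgb_image), "lesion_mask")
  keep <- as_logical_mask(lesion_mask)
  out <- rgb_image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!keep] <- 0
    out[, , ch] <- plane
  }
  out
}
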