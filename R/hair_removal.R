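#' Parameters for Dull Razor hair removal
#'
#' Hair is detected as thin dark curvilinear structure: a grayscale
#' morphological closing with a linear structuring element brightens any dark
#' structure thinner than the element, so the closing residue
#' (closed - original), maximized over element orientations, is large exactly
#' on hair pixels. Detected pixels are dilated slightly and then filled in
#' from the nearest non-hair neighbours.
#'
#' @param se_length Length of the linear structuring element in pixels
#'   (odd, >= 3). Should exceed the hair width by a comfortable margin.
#' @param se_orientations Orientations of the linear element, degrees.
#' @param diff_threshold Closing-residue threshold in intensity units (0-255).
#' @param mask_dilation Radius (pixels) by which the detected mask is grown
#'   before interpolation, to catch soft hair edges.
#' @return An object of class `hair_removal_params`.
#' @export
hair_removal_params <- function(se_length = 11,
                                se_orientations = c(0, 45, 90, 135),
                                diff_threshold = 10,
                                mask_dilation = 1) {
  if (se_length < 3 || se_length %% 2 == 0) {
    stopf("se_length must be odd and >= 3")
  }
  if (diff_threshold <= 0) stopf("diff_threshold must be > 0")
  structure(list(se_length = as.integer(se_length),
                 se_orientations = as.numeric(se_orientations),
                 diff_threshold = as.numeric(diff_threshold),
                 mask_dilation = as.integer(mask_dilation)),
            class = "hair_removal_params")
}

# Binary line structuring element of given length and orientation (degrees,
# measured in x = column / y = row-down coordinates; the closing response is
# taken over a set of orientations so the angle convention cancels out).
line_kernel <- function(length, angle_deg) {
  half <- (length - 1) / 2
  a <- angle_deg * pi / 180
  ks <- -half:half
  rr <- round(ks * sin(a))
  cc <- round(ks * cos(a))
  half_r <- max(abs(rr))
  half_c <- max(abs(cc))
  k <- matrix(0, 2 * half_r + 1, 2 * half_c + 1)
  k[cbind(rr + half_r + 1, cc + half_c + 1)] <- 1
  k
}

#' Detect hair pixels by morphological closing residue
#'
#' @param rgb_image H x W x 3 array, intensities 0-255.
#' @param params A [hair_removal_params()].
#' @return Logical H x W matrix; `TRUE` marks hair pixels.
#' @export
#' @seealso [remove_hair()]
detect_hair_mask <- function(rgb_image, params = hair_removal_params()) {
  assert_image(rgb_image)
  gray <- luminance(rgb_image)
  g01 <- gray / 255  # EBImage grayscale morphology clamps to [0, 1]
  resp <- matrix(-Inf, nrow(gray), ncol(gray))
  for (a in params$se_orientations) {
    k <- line_kernel(params$se_length, a)
    closed <- EBImage::imageData(EBImage::closing(ebi(g01), k))
    resp <- pmax(resp, (matrix(closed, nrow(gray), ncol(gray)) - g01) * 255)
  }
  mask <- resp > params$diff_threshold
  if (params$mask_dilation > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * params$mask_dilation + 1L, shape = "disc")
    mask <- EBImage::imageData(EBImage::dilate(ebi(matrix(as.numeric(mask),
                                                          nrow(mask), ncol(mask))),
                                               brush)) > 0.5
    mask <- matrix(mask, nrow(gray), ncol(gray))
  }
  mask
}

#' Replace hair pixels by nearest-neighbour interpolation
#'
#' Masked pixels are filled channel-wise from the surrounding unmasked pixels
#' by iterative onion-peel averaging: each pass assigns every still-missing
#' pixel the mean of its already-known 8-neighbours, which converges inward
#' from the mask boundary (hairs are thin, so a handful of passes suffice).
#' Pixels outside the mask are returned bit-identical.
#'
#' @param rgb_image H x W x 3 array, intensities 0-255.
#' @param hair_mask Logical H x W matrix from [detect_hair_mask()].
#' @return The inpainted H x W x 3 array.
#' @export
remove_hair <- function(rgb_image, hair_mask) {
  assert_image(rgb_image)
  assert_mask(hair_mask, dim(rgb_image), "hair_mask")
  hair_mask <- as_logical_mask(hair_mask)
  if (!any(hair_mask)) return(rgb_image)
  if (all(hair_mask)) stopf("hair mask covers the whole image; nothing to interpolate from")
  H <- nrow(hair_mask)
  W <- ncol(hair_mask)
  out <- rgb_image
  known <- !hair_mask
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  planes <- lapply(1:3, function(ch) {
    p <- out[, , ch]
    p[hair_mask] <- 0
    p
  })
  while (!all(known)) {
    acc <- lapply(1:3, function(ch) matrix(0, H, W))
    cnt <- matrix(0, H, W)
    for (s in seq_len(nrow(shifts))) {
      dr <- shifts$dr[s]
      dc <- shifts$dc[s]
      rs <- max(1, 1 + dr):min(H, H + dr)
      cs <- max(1, 1 + dc):min(W, W + dc)
      rs0 <- rs - dr
      cs0 <- cs - dc
      k <- known[rs0, cs0, drop = FALSE]
      cnt[rs, cs] <- cnt[rs, cs] + k
      for (ch in 1:3) {
        acc[[ch]][rs, cs] <- acc[[ch]][rs, cs] + planes[[ch]][rs0, cs0] * k
      }
    }
    fill <- !known & cnt > 0
    if (!any(fill)) break  # disconnected unknown region; cannot happen with finite mask
    for (ch in 1:3) {
      planes[[ch]][fill] <- acc[[ch]][fill] / cnt[fill]
    }
    known <- known | fill
  }
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[hair_mask] <- planes[[ch]][hair_mask]
    out[, , ch] <- plane
  }
  out
}

#' Detect and remove hair in one call
#'
#' @inheritParams detect_hair_mask
#' @return A list with `image` (cleaned array) and `hair_mask`.
#' @export
dull_razor <- function(rgb_image, params = hair_removal_params()) {
  mask <- detect_hair_mask(rgb_image, params)
  list(image = remove_hair(rgb_image, mask), hair_mask = mask)
}
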