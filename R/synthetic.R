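#' Configuration for a synthetic dermoscopy-like image
#'
#' Describes one synthetic skin image: a textured skin background, a single
#' darker lesion whose boundary is a radially perturbed ellipse, and optional
#' curvilinear hair artifacts. The two diagnostic classes differ by their
#' default boundary geometry: melanoma lesions get a larger radial
#' irregularity (0.25 vs 0.05) and a smaller minor/major axis ratio
#' (0.55 vs 0.9) than nevi, so that the shape descriptors measured downstream
#' genuinely separate the classes.
#'
#' The lesion boundary is \eqn{r(\theta) = r_0 (1 + p(\theta))} where
#' \eqn{p} is a random Fourier series over the `border_harmonics` band,
#' rescaled so its root-mean-square amplitude equals `border_irregularity`
#' (and clamped to \eqn{\pm 0.5} so the lesion stays inside the frame),
#' followed by anisotropic scaling of the minor axis by `axis_ratio` and a
#' random rotation. Melanoma borders default to a band reaching the
#' superpixel scale (serrated); nevi stay locally smooth. Melanoma lesions
#' additionally get smooth random pigment blotches (`variegation_sd`),
#' emulating the color variegation of real melanomas; nevi stay homogeneous.
#'
#' @param class_label `"nevus"` or `"melanoma"`; picks the default geometry.
#' @param image_height,image_width Image size in pixels.
#' @param skin_mean_rgb,lesion_mean_rgb Mean RGB intensities (0-255) of the
#'   skin background and the lesion.
#' @param skin_noise_sd Standard deviation of the i.i.d. Gaussian pixel noise
#'   added over the whole image, in intensity units.
#' @param lesion_radius_px Unperturbed lesion radius \eqn{r_0} in pixels.
#' @param border_irregularity RMS amplitude of the radial Fourier
#'   perturbation (unitless, >= 0). `NULL` uses the class default.
#' @param axis_ratio Minor/major axis ratio in (0, 1]. `NULL` uses the class
#'   default.
#' @param variegation_sd Amplitude (intensity units) of smooth random pigment
#'   blotches inside the lesion. `NULL` uses the class default
#'   (melanoma 18, nevus 0).
#' @param border_harmonics Integer range of Fourier harmonics in the radial
#'   boundary perturbation. `NULL` uses the class default: nevi are
#'   macroscopically lobed but locally smooth (2:6); melanomas additionally
#'   carry fine serrations at the superpixel scale (2:16).
#' @param n_hairs Number of hair arcs drawn on top of the image.
#' @param hair_width_px Hair stroke width in pixels.
#' @param seed Integer seed; the same config is byte-reproducible.
#'
#' @return An object of class `synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synth_config("melanoma", seed = 1)
#' cfg$axis_ratio
synth_config <- function(class_label = c("nevus", "melanoma"),
                         image_height = 256, image_width = 256,
                         skin_mean_rgb = c(224, 172, 150),
                         skin_noise_sd = 2.5,
                         lesion_mean_rgb = c(122, 74, 62),
                         lesion_radius_px = 78,
                         border_irregularity = NULL,
                         axis_ratio = NULL,
                         variegation_sd = NULL,
                         border_harmonics = NULL,
                         n_hairs = 0,
                         hair_width_px = 3,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  if (is.null(border_irregularity)) {
    border_irregularity <- if (class_label == "melanoma") 0.25 else 0.05
  }
  if (is.null(axis_ratio)) {
    axis_ratio <- if (class_label == "melanoma") 0.55 else 0.9
  }
  if (is.null(variegation_sd)) {
    variegation_sd <- if (class_label == "melanoma") 18 else 0
  }
  if (is.null(border_harmonics)) {
    border_harmonics <- if (class_label == "melanoma") 2:16 else 2:6
  }
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    skin_mean_rgb = as.numeric(skin_mean_rgb),
    skin_noise_sd = as.numeric(skin_noise_sd),
    lesion_mean_rgb = as.numeric(lesion_mean_rgb),
    lesion_radius_px = as.numeric(lesion_radius_px),
    border_irregularity = as.numeric(border_irregularity),
    axis_ratio = as.numeric(axis_ratio),
    variegation_sd = as.numeric(variegation_sd),
    border_harmonics = as.integer(border_harmonics),
    n_hairs = as.integer(n_hairs),
    hair_width_px = as.numeric(hair_width_px),
    class_label = class_label,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (any(cfg$skin_mean_rgb < 0 | cfg$skin_mean_rgb > 255) ||
      any(cfg$lesion_mean_rgb < 0 | cfg$lesion_mean_rgb > 255)) {
    stopf("mean RGB intensities must lie in [0, 255]")
  }
  if (length(cfg$skin_mean_rgb) != 3L || length(cfg$lesion_mean_rgb) != 3L) {
    stopf("mean RGB values must have length 3")
  }
  if (cfg$image_height < 32L || cfg$image_width < 32L) {
    stopf("image must be at least 32 x 32 pixels")
  }
  if (cfg$lesion_radius_px >= min(cfg$image_height, cfg$image_width) / 2) {
    stopf("lesion_radius_px = %g does not fit a %d x %d frame",
          cfg$lesion_radius_px, cfg$image_height, cfg$image_width)
  }
  if (cfg$axis_ratio <= 0 || cfg$axis_ratio > 1) {
    stopf("axis_ratio must lie in (0, 1]")
  }
  if (cfg$border_irregularity < 0) stopf("border_irregularity must be >= 0")
  if (cfg$variegation_sd < 0) stopf("variegation_sd must be >= 0")
  if (cfg$n_hairs < 0L) stopf("n_hairs must be >= 0")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %s, %dx%d, r0=%g, irregularity=%g, axis_ratio=%g, hairs=%d, seed=%d\n",
              x$class_label, x$image_height, x$image_width, x$lesion_radius_px,
              x$border_irregularity, x$axis_ratio, x$n_hairs, x$seed))
  invisible(x)
}

# Radial boundary function r(theta)/r0 for a config, given RNG state.
# Coefficients over the given harmonic band are rescaled so the series has
# RMS = irregularity, clamped to +/-0.5 so the worst-case radius is 1.5 * r0.
# Melanoma defaults extend the band to the superpixel scale (2..16), so the
# irregularity knob is expressed in the superpixel shape descriptors; nevus
# borders stay locally smooth (2..6).
sample_radial_profile <- function(irregularity, harmonics = 2:6) {
  a <- stats::rnorm(length(harmonics))
  b <- stats::rnorm(length(harmonics))
  rms <- sqrt(sum(a^2 + b^2) / 2)
  if (rms < .Machine$double.eps || irregularity == 0) {
    a[] <- 0
    b[] <- 0
  } else {
    a <- a / rms * irregularity
    b <- b / rms * irregularity
  }
  function(theta) {
    p <- rep(0, length(theta))
    for (i in seq_along(harmonics)) {
      p <- p + a[i] * cos(harmonics[i] * theta) + b[i] * sin(harmonics[i] * theta)
    }
    1 + pmin(pmax(p, -0.5), 0.5)
  }
}

#' Generate a synthetic lesion image with its ground-truth mask
#'
#' Draws one skin-toned image containing a single connected, darker lesion
#' region, plus i.i.d. Gaussian pixel noise, and (if `n_hairs > 0`) dark hair
#' arcs on top. The exact lesion pixel set is returned as `truth_mask`, which
#' is what makes segmentation and feature extraction testable end to end.
#'
#' @param config A [synth_config()].
#' @return A list with elements
#'   `image` (H x W x 3 array, 0-255, hairs included if requested),
#'   `truth_mask` (logical H x W matrix of lesion pixels),
#'   `class_label`, `clean_image` (the image before hairs),
#'   `hair_mask` (logical matrix, all `FALSE` when `n_hairs = 0`) and
#'   `config`.
#' @export
#' @examples
#' img <- generate_lesion_image(synth_config("nevus", seed = 7))
#' mean(img$truth_mask)  # lesion area fraction
generate_lesion_image <- function(config) {
  if (!inherits(config, "synth_config")) {
    stopf("`config` must be a synth_config object")
  }
  validate_synth_config(config)
  H <- config$image_height
  W <- config$image_width
  with_seed(config$seed, {
    profile <- sample_radial_profile(config$border_irregularity,
                                     config$border_harmonics)
    phi <- stats::runif(1, 0, pi)  # lesion rotation

    # Pixel-center coordinates relative to the image center, x = column,
    # y = row (y sign is irrelevant for membership).
    cx <- (W + 1) / 2
    cy <- (H + 1) / 2
    xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
    ys <- matrix(rep(seq_len(H), times = W), H, W) - cy

    u <- cos(phi) * xs + sin(phi) * ys
    v <- -sin(phi) * xs + cos(phi) * ys
    # Undo the anisotropic scaling of the minor axis, then compare against
    # the radial profile at the point's angle.
    vs <- v / config$axis_ratio
    theta <- atan2(vs, u)
    rad <- sqrt(u^2 + vs^2)
    mask <- rad <= config$lesion_radius_px * profile(theta)

    if (!any(mask)) stopf("degenerate geometry: lesion region is empty")
    # Keep the largest 4-connected piece; extreme irregularity can pinch off
    # satellites, and the contract is a single connected lesion.
    mask <- largest_component(mask)
    mask <- as_logical_mask(matrix(EBImage::imageData(
      EBImage::fillHull(ebi(matrix(as.numeric(mask), H, W)))), H, W))

    border <- mask[c(1:2, H - 1, H), ] |> any() || mask[, c(1:2, W - 1, W)] |> any()
    if (border) {
      stopf("degenerate geometry: lesion touches the image border (radius %g too large)",
            config$lesion_radius_px)
    }

    # Smooth pigment blotches (melanoma color variegation): a sum of random
    # Gaussian bumps inside the lesion, rescaled to the requested pointwise
    # standard deviation and attenuated per channel like brown pigment.
    varieg <- matrix(0, H, W)
    if (config$variegation_sd > 0) {
      n_blobs <- max(3L, round(sum(mask) / 2500))
      les_px <- which(mask, arr.ind = TRUE)
      ctr <- les_px[sample.int(nrow(les_px), n_blobs, replace = TRUE), ,
                    drop = FALSE]
      amp <- stats::rnorm(n_blobs)
      sds <- stats::runif(n_blobs, 12, 25)
      for (j in seq_len(n_blobs)) {
        d2 <- (matrix(rep(seq_len(H), times = W), H, W) - ctr[j, 1])^2 +
              (matrix(rep(seq_len(W), each = H), H, W) - ctr[j, 2])^2
        varieg <- varieg + amp[j] * exp(-d2 / (2 * sds[j]^2))
      }
      s <- stats::sd(varieg[mask])
      if (is.finite(s) && s > 0) {
        varieg <- varieg / s * config$variegation_sd
      }
      varieg[!mask] <- 0
    }

    img <- array(0, dim = c(H, W, 3))
    pigment_weight <- c(1, 0.9, 0.8)
    for (ch in 1:3) {
      base <- ifelse(mask, config$lesion_mean_rgb[ch], config$skin_mean_rgb[ch])
      img[, , ch] <- clip01(base + pigment_weight[ch] * varieg +
                              stats::rnorm(H * W, sd = config$skin_noise_sd))
    }

    clean <- img
    hair_mask <- matrix(FALSE, H, W)
    if (config$n_hairs > 0L) {
      hairy <- add_hair_overlay(img, n_hairs = config$n_hairs,
                                hair_width_px = config$hair_width_px,
                                seed = derive_seed(config$seed, "hair"))
      img <- hairy$image
      hair_mask <- hairy$hair_mask
    }

    list(image = img, truth_mask = mask, class_label = config$class_label,
         clean_image = clean, hair_mask = hair_mask, config = config)
  })
}

#' Overlay dark hair-like arcs on an image
#'
#' Draws `n_hairs` smooth dark curves (random cubic Bezier arcs spanning the
#' frame) of width `hair_width_px`, emulating the hair artifacts that the
#' Dull Razor preprocessing stage is meant to remove. Pixels under the arcs
#' are replaced by a dark hair tone; all other pixels are untouched.
#'
#' @param rgb_image H x W x 3 array, intensities 0-255.
#' @param n_hairs Number of arcs (>= 0); 0 returns the input unchanged.
#' @param hair_width_px Stroke width in pixels.
#' @param seed Integer seed for the arc geometry.
#' @return A list with `image` (the overlaid array) and `hair_mask`
#'   (logical matrix of exactly the pixels that were painted).
#' @export
add_hair_overlay <- function(rgb_image, n_hairs, hair_width_px = 3, seed = 1L) {
  assert_image(rgb_image)
  if (n_hairs < 0) stopf("n_hairs must be >= 0")
  H <- dim(rgb_image)[1]
  W <- dim(rgb_image)[2]
  hair_mask <- matrix(FALSE, H, W)
  if (n_hairs == 0) {
    return(list(image = rgb_image, hair_mask = hair_mask))
  }
  with_seed(seed, {
    out <- rgb_image
    for (h in seq_len(n_hairs)) {
      # Random cubic Bezier whose endpoints sit on opposite-ish borders so
      # arcs cross a good part of the frame, like real hairs do.
      side <- sample(1:4, 1)
      p0 <- switch(side,
                   c(1, stats::runif(1, 1, W)),
                   c(H, stats::runif(1, 1, W)),
                   c(stats::runif(1, 1, H), 1),
                   c(stats::runif(1, 1, H), W))
      p3 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      p1 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      p2 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      tt <- seq(0, 1, length.out = 4L * max(H, W))
      b <- function(i) {
        (1 - tt)^3 * p0[i] + 3 * (1 - tt)^2 * tt * p1[i] +
          3 * (1 - tt) * tt^2 * p2[i] + tt^3 * p3[i]
      }
      rr <- b(1)
      cc <- b(2)
      hair_mask <- hair_mask | stamp_curve(rr, cc, hair_width_px, H, W)
    }
    tone <- c(35, 28, 22) + stats::runif(3, 0, 10)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[hair_mask] <- tone[ch]
      out[, , ch] <- plane
    }
    list(image = out, hair_mask = hair_mask)
  })
}

# Rasterize a sampled curve with a circular brush of the given width.
stamp_curve <- function(rr, cc, width, H, W) {
  rad <- max(width / 2, 0.5)
  ir <- floor(rad)
  off <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
  r0 <- round(rr)
  c0 <- round(cc)
  keep <- r0 >= 1 - ir & r0 <= H + ir & c0 >= 1 - ir & c0 <= W + ir
  r0 <- r0[keep]
  c0 <- c0[keep]
  mask <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(off))) {
    r <- r0 + off$dr[k]
    c <- c0 + off$dc[k]
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    mask[cbind(r[ok], c[ok])] <- TRUE
  }
  mask
}

#' Generate a synthetic superpixel feature table
#'
#' Draws balanced per-superpixel feature records from two 6-dimensional
#' Gaussians whose Mahalanobis distance equals `separation`, on scales typical
#' of the geometric descriptors the pipeline measures (area, perimeter,
#' eccentricity, orientation, convex area, major axis length). With
#' `separation = 0` the two classes are identically distributed by
#' construction; larger values make the classification task easier.
#'
#' @param n_per_class Records per class (>= 1).
#' @param separation Mahalanobis distance between the class means (>= 0).
#' @param seed Integer seed.
#' @return A tibble with columns `image_id`, `sp_label`, the six feature
#'   columns and `class` (0 = nevus, 1 = melanoma).
#' @export
#' @examples
#' generate_feature_table(3, separation = 2, seed = 1)
generate_feature_table <- function(n_per_class, separation = 2, seed = 1L) {
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  if (separation < 0) stopf("separation must be >= 0")
  mu0 <- c(area = 650, perimeter = 95, eccentricity = 0.55, orientation = 0,
           convex_area = 700, major_axis_length = 38)
  sd0 <- c(area = 180, perimeter = 20, eccentricity = 0.18, orientation = 50,
           convex_area = 200, major_axis_length = 8)
  # Equal standardized shift on every axis: Mahalanobis distance = separation.
  shift <- separation * sd0 / sqrt(6)
  with_seed(seed, {
    draw <- function(mu, n) {
      vapply(seq_along(mu), function(j) stats::rnorm(n, mu[j], sd0[j]),
             numeric(n))
    }
    x0 <- draw(mu0, n_per_class)
    x1 <- draw(mu0 + shift, n_per_class)
    x <- rbind(x0, x1)
    colnames(x) <- names(mu0)
    tibble::tibble(
      image_id = "synthetic",
      sp_label = seq_len(2L * n_per_class),
      as_tibble(x),
      class = rep(c(0L, 1L), each = n_per_class)
    )
  })
}

#' Names of the six superpixel feature columns
#' @return Character vector of the feature column names, in canonical order.
#' @export
sp_feature_names <- function() {
  c("area", "perimeter", "eccentricity", "orientation",
    "convex_area", "major_axis_length")
}
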