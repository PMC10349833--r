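test_that("moment machinery matches closed forms on canonical shapes", {
  # single pixel: point mass plus the 1/12 pixel-extent correction
  m1 <- region_moments(matrix(TRUE, 1, 1))
  expect_equal(m1$area, 1L)
  expect_equal(unname(diag(m1$covariance)), c(1 / 12, 1 / 12))
  expect_equal(m1$covariance[1, 2], 0)

  f1 <- compute_sp_features(matrix(TRUE, 1, 1))
  expect_equal(f1$area, 1L)
  expect_equal(f1$eccentricity, 0)
  expect_equal(f1$major_axis_length, 4 / sqrt(12), tolerance = 1e-12)
  expect_equal(f1$perimeter, 0)

  # 1x5 horizontal bar: x-variance of {-2..2} is 2, plus 1/12
  bar <- matrix(FALSE, 3, 7)
  bar[2, 2:6] <- TRUE
  mb <- region_moments(bar)
  expect_equal(mb$covariance[1, 1], 2 + 1 / 12, tolerance = 1e-12)
  expect_equal(mb$covariance[2, 2], 1 / 12, tolerance = 1e-12)
  expect_equal(mb$covariance[1, 2], 0)

  # 10x10 square
  sq <- matrix(FALSE, 12, 12)
  sq[2:11, 2:11] <- TRUE
  fs <- compute_sp_features(sq)
  expect_equal(fs$area, 100L)
  expect_equal(fs$convex_area, 100L)
  expect_equal(fs$eccentricity, 0)
  expect_equal(fs$perimeter, 36)
})

test_that("mirroring negates the cross moment and keeps the diagonals", {
  mask <- random_blob(60, 28, seed = 3)
  mm <- region_moments(mask)
  mirrored <- mask[, ncol(mask):1]
  mm2 <- region_moments(mirrored)
  expect_equal(diag(mm$covariance), diag(mm2$covariance))
  expect_equal(mm$covariance[1, 2], -mm2$covariance[1, 2])
})

test_that("digitized rotated ellipses recover the continuous parameters", {
  for (deg in c(0, 30, 60)) {
    H <- 64
    W <- 64
    th <- deg * pi / 180
    mask <- matrix(FALSE, H, W)
    for (r in 1:H) {
      for (c in 1:W) {
        x <- c - 32.5
        y <- -(r - 32.5)   # y up, so `deg` is the y-up orientation
        u <- cos(th) * x + sin(th) * y
        v <- -sin(th) * x + cos(th) * y
        mask[r, c] <- (u / 20)^2 + (v / 10)^2 <= 1
      }
    }
    f <- compute_sp_features(mask)
    expect_equal(f$eccentricity, sqrt(1 - 0.25), tolerance = 0.02)
    dd <- abs(f$orientation - deg) %% 180
    expect_lte(min(dd, 180 - dd), 2)
  }
})

test_that("features agree with brute-force moment and hull oracles", {
  for (s in 1:60) {
    mask <- random_blob(size = sample(3:80, 1), grid = 24, seed = 100 + s)
    f <- compute_sp_features(mask)
    o <- oracle_moments(mask)
    expect_equal(f$area, o$area)
    if (o$eccentricity > 1e-4) {  # orientation is numerically undefined near circles
      d <- abs(f$orientation - o$orientation) %% 180
      expect_lte(min(d, 180 - d), 1e-6)
    }
    expect_equal(f$eccentricity, o$eccentricity, tolerance = 1e-6)
    expect_equal(f$major_axis_length, o$major_axis_length, tolerance = 1e-6)
    expect_equal(f$convex_area, oracle_convex_area(mask))
  }
})

test_that("90-degree rotation permutes orientation and preserves the rest", {
  mask <- random_blob(70, 28, seed = 77)
  f <- compute_sp_features(mask)
  rot <- t(mask)[, nrow(mask):1, drop = FALSE]  # 90-degree rotation
  fr <- compute_sp_features(rot)
  expect_equal(fr$area, f$area)
  expect_equal(fr$eccentricity, f$eccentricity, tolerance = 1e-9)
  expect_equal(fr$convex_area, f$convex_area)
  expect_equal(fr$major_axis_length, f$major_axis_length, tolerance = 1e-9)
  if (f$eccentricity > 1e-6) {
    d <- (fr$orientation - f$orientation) %% 180
    expect_lt(min(abs(d - 90), abs(d - 90 + 180), abs(d - 90 - 180)), 1e-6)
  }
})

test_that("convex area exceeds area exactly for non-convex digitized regions", {
  # digitized disc is convex: equality
  disc <- matrix(FALSE, 21, 21)
  for (r in 1:21) for (c in 1:21) {
    if ((r - 11)^2 + (c - 11)^2 <= 8^2) disc[r, c] <- TRUE
  }
  fd <- compute_sp_features(disc)
  expect_equal(fd$convex_area, fd$area)

  # an L-shape is not
  ell <- matrix(FALSE, 10, 10)
  ell[1:9, 1:3] <- TRUE
  ell[7:9, 1:9] <- TRUE
  fe <- compute_sp_features(ell)
  expect_gt(fe$convex_area, fe$area)
})

test_that("extract_all yields one record per kept label with valid features", {
  lm <- matrix(0L, 8, 8)
  lm[1:4, 1:4] <- 1L
  lm[1:4, 5:8] <- 2L
  lm[5:8, 1:8] <- 3L
  mask <- matrix(FALSE, 8, 8)
  mask[1:4, ] <- TRUE
  sp <- filter_background_superpixels(lm, mask)
  recs <- extract_all(sp, "imgA", "melanoma")
  expect_equal(nrow(recs), 2L)
  expect_setequal(recs$sp_label, c(1L, 2L))
  expect_true(all(recs$class == 1L))

  none <- filter_background_superpixels(lm, matrix(FALSE, 8, 8))
  expect_equal(nrow(extract_all(none, "imgA", "nevus")), 0L)
})

test_that("an end-to-end image yields finite features satisfying the invariants", {
  g <- generate_lesion_image(synth_config("melanoma", seed = 31))
  lm <- slic_superpixels(apply_black_mask(g$image, g$truth_mask))
  sp <- filter_background_superpixels(lm, g$truth_mask, n_requested = 100)
  recs <- extract_all(sp, "e2e", "melanoma")
  expect_gt(nrow(recs), 5)
  expect_true(all(is.finite(as.matrix(recs[, sp_feature_names()]))))
  expect_true(all(recs$area >= 1))
  expect_true(all(recs$convex_area >= recs$area))
  expect_true(all(recs$eccentricity >= 0 & recs$eccentricity < 1))
  expect_true(all(recs$orientation > -90 & recs$orientation <= 90))
  expect_true(all(recs$major_axis_length > 0))
})
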