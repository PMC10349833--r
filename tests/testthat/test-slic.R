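test_that("constant image with n = 9 tiles into a near-regular 3x3 grid", {
  img <- flat_image(120, 120, c(128, 128, 128))
  lm <- slic_superpixels(img, slic_params(n_superpixels = 9))
  sizes <- table(lm)
  expect_equal(length(sizes), 9L)
  expect_true(all(abs(sizes - 1600) / 1600 <= 0.25))
})

test_that("SLIC is deterministic and partitions every pixel", {
  g <- generate_lesion_image(synth_config("nevus", seed = 3))
  a <- slic_superpixels(g$image)
  b <- slic_superpixels(g$image)
  expect_identical(a, b)
  expect_false(any(a == 0L))
  expect_identical(sort(unique(as.vector(a))), seq_len(max(a)))
})

test_that("two-tone edge is recovered by SP boundaries at 1-px tolerance", {
  img <- flat_image(64, 64, c(60, 60, 60))
  for (ch in 1:3) img[, 33:64, ch] <- 200
  lm <- slic_superpixels(img, slic_params(n_superpixels = 2))
  # true edge: between columns 32 and 33; SP boundary pixels:
  b <- lm[, -64] != lm[, -1]
  recall <- mean(vapply(1:64, function(r) {
    any(b[r, 31:33])
  }, logical(1)))
  expect_gte(recall, 0.9)
})

test_that("superpixel count stays within [n/2, 2n] on synthetic lesions", {
  for (s in c(5, 6)) {
    g <- generate_lesion_image(synth_config(ifelse(s %% 2 == 0, "melanoma",
                                                   "nevus"), seed = s))
    lm <- slic_superpixels(g$image)
    expect_gte(max(lm), 50)
    expect_lte(max(lm), 200)
  }
})

test_that("rejects more superpixels than pixels", {
  img <- flat_image(4, 4, c(10, 10, 10))
  expect_error(slic_superpixels(img, slic_params(n_superpixels = 17)),
               "exceeds")
})

test_that("connectivity enforcement yields one 4-connected component per label", {
  # already-connected map passes through (up to relabeling)
  lm <- matrix(1L, 8, 8)
  lm[, 5:8] <- 2L
  out <- enforce_connectivity(lm, min_size = 2)
  expect_equal(max(out), 2L)
  expect_identical(out == out[1, 1], lm == 1L)

  # a 2-pixel orphan below min_size gets absorbed
  lm2 <- matrix(1L, 6, 6)
  lm2[3, 3:4] <- 2L
  out2 <- enforce_connectivity(lm2, min_size = 5)
  expect_equal(max(out2), 1L)

  # random label noise ends up satisfying the invariant
  set.seed(9)
  noisy <- matrix(sample(1:5, 32 * 32, replace = TRUE), 32, 32)
  out3 <- enforce_connectivity(noisy, min_size = 1)
  for (l in seq_len(max(out3))) {
    cc <- dermsp:::label_components(out3 == l)
    expect_equal(max(cc), 1L)
  }
})

test_that("background filtering follows the overlap-threshold contract", {
  lm <- matrix(0L, 8, 8)
  lm[1:4, 1:4] <- 1L
  lm[1:4, 5:8] <- 2L
  lm[5:8, 1:4] <- 3L
  lm[5:8, 5:8] <- 4L

  full <- filter_background_superpixels(lm, matrix(TRUE, 8, 8))
  expect_setequal(full$kept_labels, 1:4)

  none <- filter_background_superpixels(lm, matrix(FALSE, 8, 8))
  expect_equal(none$n_kept, 0L)
  expect_length(none$kept_labels, 0L)

  # mask covering exactly quadrants 2 and 3
  q23 <- matrix(FALSE, 8, 8)
  q23[1:4, 5:8] <- TRUE
  q23[5:8, 1:4] <- TRUE
  sel <- filter_background_superpixels(lm, q23, overlap_threshold = 0.5)
  expect_setequal(sel$kept_labels, c(2L, 3L))

  # per-label pixel counts conserve the partition
  expect_equal(sum(sel$per_label_pixel_count), 64)
})

test_that("kept sets shrink weakly as the overlap threshold rises", {
  g <- generate_lesion_image(synth_config("nevus", seed = 12))
  lm <- slic_superpixels(apply_black_mask(g$image, g$truth_mask))
  kept <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    filter_background_superpixels(lm, g$truth_mask, th)$n_kept
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("superpixel areas stay near-uniform on constant images", {
  img <- flat_image(128, 128, c(90, 90, 90))
  lm <- slic_superpixels(img, slic_params(n_superpixels = 25))
  sizes <- as.numeric(table(lm))
  expect_lte(stats::sd(sizes) / mean(sizes), 0.3)
})
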