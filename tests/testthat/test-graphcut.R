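test_that("auto seeds: dark disc gives fg inside, bg frame outside the disc", {
  img <- flat_image(64, 64, c(200, 200, 200))
  disc <- matrix(FALSE, 64, 64)
  for (r in 1:64) for (c in 1:64) {
    if ((r - 32)^2 + (c - 32)^2 <= 12^2) disc[r, c] <- TRUE
  }
  for (ch in 1:3) {
    p <- img[, , ch]
    p[disc] <- 60
    img[, , ch] <- p
  }
  # the disc covers ~11% of the frame; a 20% darkness quantile lands in the
  # bright background so the strictly-darker candidate set is exactly the disc
  s <- auto_seeds(img, graphcut_params(border_margin = 4, fg_quantile = 0.2))
  expect_true(all(disc[s$fg_seed_mask]))
  expect_false(any(s$bg_seed_mask & disc))
  expect_false(any(s$fg_seed_mask & s$bg_seed_mask))
})

test_that("auto seeds reject a constant image (no darkness contrast)", {
  expect_error(auto_seeds(flat_image(64, 64, c(120, 120, 120))),
               "foreground seed")
})

test_that("border frame arithmetic: margin 8 on 256x256 gives 7936 bg seeds", {
  g <- generate_lesion_image(synth_config("nevus", seed = 2))
  s <- auto_seeds(g$image, graphcut_params(border_margin = 8))
  expect_equal(sum(s$bg_seed_mask), 256^2 - 240^2)
  expect_equal(sum(s$bg_seed_mask), 7936L)
})

test_that("fully seeded images come back exactly as seeded", {
  img <- flat_image(6, 6, c(100, 100, 100))
  img[, , 1] <- matrix(runif(36, 90, 110), 6, 6)
  fg <- matrix(FALSE, 6, 6)
  fg[2:4, 2:4] <- TRUE
  bg <- !fg
  out <- graph_cut_segment(img, fg, bg)
  expect_identical(out, fg)
})

test_that("overlapping seeds are rejected", {
  img <- flat_image(8, 8, c(100, 100, 100))
  fg <- matrix(FALSE, 8, 8)
  fg[4, 4] <- TRUE
  bg <- matrix(FALSE, 8, 8)
  bg[4, 4] <- TRUE
  bg[1, 1] <- TRUE
  expect_error(graph_cut_segment(img, fg, bg), "infeasible")
})

test_that("a strong two-tone image is cut exactly along the tone boundary", {
  img <- flat_image(12, 12, c(40, 40, 40))
  for (ch in 1:3) img[, 7:12, ch] <- 220
  fg <- matrix(FALSE, 12, 12)
  fg[6, 2] <- TRUE
  bg <- matrix(FALSE, 12, 12)
  bg[6, 11] <- TRUE
  out <- graph_cut_segment(img, fg, bg, postprocess = FALSE)
  expected <- matrix(FALSE, 12, 12)
  expected[, 1:6] <- TRUE
  expect_identical(out, expected)
})

test_that("min-cut labelings attain the exhaustively enumerated minimum energy", {
  set.seed(41)
  params <- graphcut_params(lambda_smooth = 2, sigma_contrast = 25)
  for (case in 1:12) {
    H <- sample(3:4, 1)
    W <- sample(3:4, 1)
    img <- flat_image(H, W)
    lum <- matrix(runif(H * W, 0, 255), H, W)
    for (ch in 1:3) img[, , ch] <- lum
    fg <- matrix(FALSE, H, W)
    bg <- matrix(FALSE, H, W)
    fg[sample(H * W, 1)] <- TRUE
    repeat {
      j <- sample(H * W, 1)
      if (!fg[j]) {
        bg[j] <- TRUE
        break
      }
    }
    lab <- graph_cut_segment(img, fg, bg, params, postprocess = FALSE)
    e_impl <- dermsp:::graphcut_energy(img, lab, fg, bg, params)
    e_best <- oracle_min_energy(luminance_of(img), fg, bg,
                                params$lambda_smooth, params$sigma_contrast)
    expect_equal(e_impl, e_best, tolerance = 1e-9)
  }
})

test_that("seed compliance holds on synthetic lesions and IoU is high", {
  g <- generate_lesion_image(synth_config("melanoma", seed = 55))
  s <- auto_seeds(g$image)
  les <- graph_cut_segment(g$image, s$fg_seed_mask, s$bg_seed_mask)
  expect_true(all(les[s$fg_seed_mask]))
  expect_false(any(les[s$bg_seed_mask]))
  expect_gte(iou(les, g$truth_mask), 0.85)
})

test_that("black masking zeroes exactly the background", {
  img <- flat_image(10, 10, c(50, 100, 150))
  expect_identical(apply_black_mask(img, matrix(TRUE, 10, 10)), img)
  allblack <- apply_black_mask(img, matrix(FALSE, 10, 10))
  expect_true(all(allblack == 0))
  disc <- matrix(FALSE, 10, 10)
  disc[3:7, 3:7] <- TRUE
  out <- apply_black_mask(img, disc)
  expect_true(all(out[rep(!disc, 3)] == 0))
  expect_identical(out[rep(disc, 3)], img[rep(disc, 3)])
})
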