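test_that("an unperturbed circular config digitizes to a disc of the right area", {
  cfg <- synth_config("nevus", border_irregularity = 0, axis_ratio = 1,
                      lesion_radius_px = 60, seed = 4)
  g <- generate_lesion_image(cfg)
  expect_equal(dim(g$image), c(256, 256, 3))
  area <- sum(g$truth_mask)
  expect_lt(abs(area - pi * 60^2) / (pi * 60^2), 0.05)
  # single 4-connected component
  cc <- dermsp:::label_components(g$truth_mask)
  expect_equal(max(cc), 1L)
})

test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- synth_config("melanoma", seed = 99, n_hairs = 3)
  a <- generate_lesion_image(cfg)
  b <- generate_lesion_image(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_identical(a$hair_mask, b$hair_mask)
})

test_that("truth masks are a single 4-connected component across configs", {
  for (s in 1:6) {
    cls <- if (s %% 2 == 0) "melanoma" else "nevus"
    g <- generate_lesion_image(synth_config(cls, seed = s))
    cc <- dermsp:::label_components(g$truth_mask)
    expect_equal(max(cc), 1L)
  }
})

test_that("oversized lesions are rejected as degenerate geometry", {
  expect_error(synth_config("nevus", lesion_radius_px = 130), "fit")
  expect_error(synth_config("nevus", axis_ratio = 0), "axis_ratio")
  expect_error(synth_config("nevus", border_irregularity = -1), "irregularity")
})

test_that("melanoma masks are on average more eccentric than nevus masks", {
  ecc_of <- function(cls, seeds) {
    vapply(seeds, function(s) {
      g <- generate_lesion_image(synth_config(cls, seed = s))
      compute_sp_features(g$truth_mask)$eccentricity
    }, numeric(1))
  }
  e_nev <- ecc_of("nevus", 1:30)
  e_mel <- ecc_of("melanoma", 101:130)
  expect_gt(mean(e_mel), mean(e_nev))
})

test_that("hair overlay touches exactly the raster it reports and is seeded", {
  img <- flat_image(128, 128, c(200, 160, 140))
  h0 <- add_hair_overlay(img, n_hairs = 0)
  expect_identical(h0$image, img)
  expect_false(any(h0$hair_mask))

  h5 <- add_hair_overlay(img, n_hairs = 5, seed = 7)
  diff <- apply(abs(h5$image - img), c(1, 2), max) > 0
  expect_identical(diff, h5$hair_mask)
  expect_gt(sum(h5$hair_mask), 0)

  h5b <- add_hair_overlay(img, n_hairs = 5, seed = 7)
  expect_identical(h5$image, h5b$image)
})

test_that("synthetic feature tables have the documented shape and balance", {
  tab <- generate_feature_table(3, separation = 1, seed = 1)
  expect_equal(nrow(tab), 6L)
  expect_setequal(names(tab),
                  c("image_id", "sp_label", sp_feature_names(), "class"))
  expect_equal(sum(tab$class == 0), 3L)

  # separation = 0: the two classes share one distribution by construction
  big <- generate_feature_table(4000, separation = 0, seed = 2)
  for (f in sp_feature_names()) {
    d <- abs(mean(big[[f]][big$class == 1]) - mean(big[[f]][big$class == 0]))
    expect_lt(d / stats::sd(big[[f]]), 0.08)
  }
})

test_that("feature-table separability is monotone in the separation knob", {
  acc_at <- function(sep) {
    mean(vapply(1:5, function(s) {
      tab <- generate_feature_table(250, separation = sep, seed = 10 + s)
      sp <- split_dataset(tab, 0.7, seed = s)
      nz <- zscore_fit_transform(sp$train, sp$test)
      m <- train_model(build_classifier("RF", seed = s), nz$train, cv_folds = 0)
      mean(predict(m, nz$test) == nz$test$class)
    }, numeric(1)))
  }
  accs <- vapply(c(0, 1, 2, 4), acc_at, numeric(1))
  expect_true(all(diff(accs) >= -0.02))  # non-decreasing up to MC noise
  expect_gt(accs[4], 0.95)
})
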