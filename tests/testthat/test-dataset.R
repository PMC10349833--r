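make_table <- function(n, frac_pos = 0.5, seed = 1) {
  tab <- generate_feature_table(n %/% 2, separation = 1, seed = seed)
  tab$class <- rep(c(0L, 1L), each = n %/% 2)
  tab
}

test_that("stratified splits follow exact rounding arithmetic", {
  tab <- make_table(100)
  sp <- split_dataset(tab, 0.7, seed = 4)
  expect_equal(nrow(sp$train), 70L)
  expect_equal(nrow(sp$test), 30L)
  expect_equal(sum(sp$train$class == 0), 35L)
  expect_equal(sum(sp$train$class == 1), 35L)

  tab2 <- make_table(200)
  sp2 <- split_dataset(tab2, 0.85, seed = 4)
  expect_equal(nrow(sp2$train), 170L)
  expect_equal(nrow(sp2$test), 30L)
})

test_that("splits are deterministic, disjoint and exhaustive", {
  tab <- make_table(120, seed = 7)
  a <- split_dataset(tab, 0.7, seed = 11)
  b <- split_dataset(tab, 0.7, seed = 11)
  expect_identical(a$train, b$train)
  expect_identical(a$test, b$test)
  key <- function(d) paste(d$sp_label, d$class)
  expect_length(intersect(key(a$train), key(a$test)), 0L)
  expect_setequal(c(key(a$train), key(a$test)), key(tab))
})

test_that("single-class tables are rejected", {
  tab <- make_table(40)
  tab$class <- 0L
  expect_error(split_dataset(tab, 0.7), "both classes")
})

test_that("z-score normalization reproduces the hand-computed example", {
  tr <- tibble::tibble(area = c(2, 4, 6))
  for (f in setdiff(sp_feature_names(), "area")) tr[[f]] <- c(1, 2, 3)
  te <- tr[3, ]
  nz <- zscore_fit_transform(tr, te)
  # population sd of (2,4,6) is 1.63299; (6-4)/1.63299 = 1.2247
  expect_equal(nz$test$area, 1.2247, tolerance = 1e-4)
  expect_equal(nz$train$area[2], 0)  # the mean maps to zero
})

test_that("train columns standardize exactly and round-trip to 1e-12", {
  tab <- generate_feature_table(80, separation = 2, seed = 5)
  sp <- split_dataset(tab, 0.7, seed = 6)
  nz <- zscore_fit_transform(sp$train, sp$test)
  for (f in sp_feature_names()) {
    expect_lt(abs(mean(nz$train[[f]])), 1e-9)
    sd_pop <- sqrt(mean((nz$train[[f]] - mean(nz$train[[f]]))^2))
    expect_lt(abs(sd_pop - 1), 1e-9)
  }
  back <- zscore_apply(nz$train, nz$params, inverse = TRUE)
  for (f in sp_feature_names()) {
    expect_equal(back[[f]], sp$train[[f]], tolerance = 1e-12)
  }
  # test records use train parameters and may exceed |1|
  wild <- sp$test[1, ]
  wild$area <- max(sp$train$area) * 10
  tz <- zscore_apply(wild, nz$params)
  expect_gt(abs(tz$area), 1)
})

test_that("zero-variance features are rejected by name", {
  tab <- generate_feature_table(20, separation = 1, seed = 2)
  tab$perimeter <- 5
  expect_error(zscore_fit_transform(tab), "perimeter")
})

test_that("k-fold indices partition with balanced sizes", {
  f10 <- kfold_indices(10, k = 5, seed = 1)
  sizes <- vapply(f10, function(f) length(f$val_idx), numeric(1))
  expect_true(all(sizes == 2))
  expect_setequal(unlist(lapply(f10, `[[`, "val_idx")), 1:10)

  f13 <- kfold_indices(13, k = 5, seed = 2)
  sizes13 <- sort(vapply(f13, function(f) length(f$val_idx), numeric(1)),
                  decreasing = TRUE)
  expect_equal(sizes13, c(3, 3, 3, 2, 2))
  for (f in f13) {
    expect_length(intersect(f$train_idx, f$val_idx), 0L)
    expect_setequal(c(f$train_idx, f$val_idx), 1:13)
  }
  expect_error(kfold_indices(4, k = 5), "smaller")
})

test_that("per-class proportions in train and test track the global mix", {
  tab <- generate_feature_table(60, separation = 1, seed = 9)  # 120 records
  sp <- split_dataset(tab, 0.7, seed = 10)
  p_global <- mean(tab$class == 1)
  expect_lte(abs(sum(sp$train$class == 1) - p_global * nrow(sp$train)), 1)
  expect_lte(abs(sum(sp$test$class == 1) - p_global * nrow(sp$test)), 1)
})

test_that("image-level grouping keeps whole images on one side", {
  tab <- dplyr::bind_rows(lapply(1:8, function(i) {
    t <- generate_feature_table(5, separation = 1, seed = i)
    t$image_id <- sprintf("img%02d", i)
    t$class <- as.integer(i %% 2 == 0)
    t
  }))
  sp <- split_dataset(tab, 0.7, seed = 3, by_image = TRUE)
  expect_length(intersect(unique(sp$train$image_id),
                          unique(sp$test$image_id)), 0L)
})
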