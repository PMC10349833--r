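norm_table <- function(n_per_class, separation, seed) {
  tab <- generate_feature_table(n_per_class, separation, seed)
  sp <- split_dataset(tab, 0.7, seed = seed + 1)
  nz <- zscore_fit_transform(sp$train, sp$test)
  list(train = nz$train, test = nz$test)
}

test_that("classifier specs carry the published defaults and accept overrides", {
  rf <- build_classifier("RF")
  expect_equal(rf$hyperparameters$n_estimators, 100L)
  expect_equal(rf$hyperparameters$criterion, "entropy")

  knn <- build_classifier("KNN")
  expect_equal(knn$hyperparameters$n_neighbors, 1L)
  expect_equal(knn$hyperparameters$metric, "euclidean")
  expect_equal(knn$hyperparameters$leaf_size, 20L)

  svm <- build_classifier("SVM")
  expect_equal(svm$hyperparameters$kernel, "linear")
  expect_equal(svm$hyperparameters$decision_function_shape, "ovo")

  ad <- build_classifier("AD")
  expect_equal(ad$hyperparameters$algorithm, "SAMME")
  expect_equal(ad$hyperparameters$random_state, 40L)

  dt <- build_classifier("DT")
  expect_equal(dt$hyperparameters$criterion, "entropy")
  expect_equal(dt$hyperparameters$max_depth, 100L)

  gnb <- build_classifier("GNB")
  expect_equal(gnb$hyperparameters$var_smoothing, 1e-9)

  ov <- build_classifier("RF", overrides = list(n_estimators = 10))
  expect_equal(ov$hyperparameters$n_estimators, 10)

  expect_error(build_classifier("XGB"), "RF, SVM, AD, KNN, DT, GNB")
  expect_error(build_network("MLP"), "PRNN, FNN, CNN1D")
})

test_that("network specs match the published architectures", {
  fnn <- build_network("FNN")
  expect_equal(fnn$hyperparameters$hidden_units, c(10L, 8L, 6L))
  expect_equal(fnn$hyperparameters$learning_rate, 0.001)
  expect_equal(fnn$hyperparameters$epochs, 100L)

  cnn <- build_network("CNN1D")
  expect_equal(cnn$hyperparameters$conv1_filters, 64L)
  expect_equal(cnn$hyperparameters$conv1_kernel, 2L)
  expect_equal(cnn$hyperparameters$dropout_rate, 0.2)

  prnn <- build_network("PRNN")
  expect_equal(prnn$hyperparameters$hidden_layer_sizes, 10L)
})

test_that("CNN1D parameter count equals the layer-shape arithmetic", {
  # conv1 (2*1+1)*64; conv2 (1*64+1)*32; dense1 (5*32)*32+32; dense2 32+1
  by_hand <- (2 * 1 + 1) * 64 + (1 * 64 + 1) * 32 + (5 * 32) * 32 + 32 + 33
  expect_equal(network_n_parameters(build_network("CNN1D")), by_hand)
  expect_equal(by_hand, 7457)
  # FNN: (6+1)*10 + (10+1)*8 + (8+1)*6 + (6+1)*1
  expect_equal(network_n_parameters(build_network("FNN")),
               7 * 10 + 11 * 8 + 9 * 6 + 7)
})

test_that("1-NN and an unpruned tree memorize their training set", {
  d <- norm_table(60, 2, seed = 3)
  knn <- train_model(build_classifier("KNN", seed = 1), d$train, cv_folds = 0)
  expect_equal(mean(predict(knn, d$train) == d$train$class), 1)

  dt <- train_model(build_classifier("DT", seed = 1), d$train, cv_folds = 0)
  expect_equal(mean(predict(dt, d$train) == d$train$class), 1)
})

test_that("RF cross-validation accuracy exceeds 0.95 on well-separated data", {
  accs <- vapply(1:5, function(s) {
    tab <- generate_feature_table(300, separation = 4, seed = 40 + s)
    sp <- split_dataset(tab, 0.7, seed = s)
    nz <- zscore_fit_transform(sp$train, sp$test)
    m <- train_model(build_classifier("RF", seed = s), nz$train, cv_folds = 5)
    m$cv_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("no model finds signal when there is none", {
  d <- norm_table(250, 0, seed = 17)
  for (nm in c("RF", "SVM", "KNN", "DT", "GNB", "AD", "PRNN", "FNN", "CNN1D")) {
    spec <- if (nm %in% c("PRNN", "FNN", "CNN1D")) {
      build_network(nm, seed = 5)
    } else {
      build_classifier(nm, seed = 5)
    }
    m <- train_model(spec, d$train, cv_folds = 0)
    acc <- mean(predict(m, d$test) == d$test$class)
    expect_gte(acc, 0.4)
    expect_lte(acc, 0.6)
  }
})

test_that("every model beats the majority baseline on separation-2 data", {
  models <- c("RF", "SVM", "KNN", "DT", "GNB", "AD", "PRNN", "FNN", "CNN1D")
  wins <- sapply(1:5, function(s) {
    d <- norm_table(150, 2, seed = 60 + s)
    baseline <- max(mean(d$test$class == 0), mean(d$test$class == 1))
    vapply(models, function(nm) {
      spec <- if (nm %in% c("PRNN", "FNN", "CNN1D")) {
        build_network(nm, seed = s)
      } else {
        build_classifier(nm, seed = s)
      }
      m <- train_model(spec, d$train, cv_folds = 0)
      mean(predict(m, d$test) == d$test$class) - baseline
    }, numeric(1))
  })
  expect_true(all(rowMeans(wins) > 0))
})

test_that("seeded learners give identical predictions across runs", {
  d <- norm_table(100, 2, seed = 9)
  for (nm in c("RF", "AD", "DT", "FNN", "CNN1D", "KNN", "GNB")) {
    spec <- if (nm %in% c("FNN", "CNN1D")) {
      build_network(nm, seed = 11)
    } else {
      build_classifier(nm, seed = 11)
    }
    p1 <- predict(train_model(spec, d$train, cv_folds = 0), d$test)
    p2 <- predict(train_model(spec, d$train, cv_folds = 0), d$test)
    expect_identical(p1, p2)
  }
})

test_that("prediction handles empty input and thresholds at 0.5", {
  d <- norm_table(60, 2, seed = 21)
  m <- train_model(build_network("FNN", seed = 2), d$train, cv_folds = 0)
  expect_identical(predict(m, d$test[0, ]), integer(0))
  prob <- dermsp:::nn_predict_prob(m$fit,
                                   as.matrix(d$test[, sp_feature_names()]))
  expect_identical(predict(m, d$test), as.integer(prob >= 0.5))
})

test_that("single-class training sets are rejected", {
  d <- norm_table(30, 1, seed = 2)
  one <- d$train[d$train$class == 0, ]
  expect_error(train_model(build_classifier("RF"), one), "both classes")
})

test_that("tidy and glance summarise trained models", {
  d <- norm_table(40, 2, seed = 13)
  m <- train_model(build_classifier("GNB", seed = 1), d$train, cv_folds = 2)
  td <- tidy(m)
  expect_true("var_smoothing" %in% td$hyperparameter)
  gl <- glance(m)
  expect_equal(gl$model, "GNB")
  expect_equal(gl$n_train, nrow(d$train))
  expect_true(is.finite(gl$cv_accuracy))
})
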