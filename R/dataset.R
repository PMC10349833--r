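#' Stratified train/test split of a superpixel feature table
#'
#' Splits at the record (superpixel) level. With `stratified = TRUE` the
#' split draws `round(train_fraction * n_c)` records per class, so the class
#' proportions of train and test stay within one record of the global
#' proportions. Deterministic under `seed`.
#'
#' @param data Tibble with a `class` column in \{0, 1\}.
#' @param train_fraction Fraction of records assigned to training
#'   (the study ratios are 0.70, 0.80 and 0.85; 0.7:0.3 works best).
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Integer seed.
#' @param by_image If `TRUE`, whole images are assigned to one side
#'   (leakage-safe grouping for correlated superpixels from the same image);
#'   the fraction then applies to images, stratified by image class.
#' @return A list with tibbles `train` and `test`; attributes record the
#'   fraction and seed.
#' @export
split_dataset <- function(data, train_fraction = 0.7, stratified = TRUE,
                          seed = 1L, by_image = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  if (!"class" %in% names(data)) stopf("`data` must have a `class` column")
  classes <- sort(unique(data$class))
  if (!all(classes %in% c(0L, 1L)) || length(classes) < 2L) {
    stopf("`data` must contain both classes 0 and 1")
  }
  n <- nrow(data)
  with_seed(seed, {
    if (by_image) {
      imgs <- dplyr::distinct(data, .data$image_id, .data$class)
      tr_imgs <- unlist(lapply(classes, function(cl) {
        ids <- imgs$image_id[imgs$class == cl]
        sample(ids, round(train_fraction * length(ids)))
      }))
      tr_idx <- which(data$image_id %in% tr_imgs)
    } else if (stratified) {
      tr_idx <- unlist(lapply(classes, function(cl) {
        ids <- which(data$class == cl)
        sample(ids, round(train_fraction * length(ids)))
      }))
    } else {
      tr_idx <- sample(n, round(train_fraction * n))
    }
    tr_idx <- sort(tr_idx)
    out <- list(train = data[tr_idx, , drop = FALSE],
                test = data[setdiff(seq_len(n), tr_idx), , drop = FALSE])
    attr(out, "train_fraction") <- train_fraction
    attr(out, "seed") <- as.integer(seed)
    attr(out, "train_idx") <- tr_idx
    out
  })
}

#' Z-score normalization fitted on the training split only
#'
#' Applies \eqn{a' = (a - \mu(A)) / \sigma(A)} per feature column, with the
#' mean and the population standard deviation estimated on the training
#' records and reused verbatim for the test records — normalizing after the
#' split avoids leaking test statistics into training.
#'
#' @param train,test Tibbles with the six feature columns (test may be
#'   `NULL`).
#' @param feature_cols Columns to normalize (default [sp_feature_names()]).
#' @return A list with `train`, `test` (transformed copies) and `params`, a
#'   tibble with columns `feature`, `mu`, `sigma`.
#' @export
zscore_fit_transform <- function(train, test = NULL,
                                 feature_cols = sp_feature_names()) {
  if (nrow(train) == 0L) stopf("training set is empty")
  missing_cols <- setdiff(feature_cols, names(train))
  if (length(missing_cols) > 0L) {
    stopf("missing feature columns: %s", paste(missing_cols, collapse = ", "))
  }
  mu <- vapply(feature_cols, function(f) mean(train[[f]]), numeric(1))
  sigma <- vapply(feature_cols, function(f) {
    sqrt(mean((train[[f]] - mean(train[[f]]))^2))  # population sd
  }, numeric(1))
  zero <- sigma <= 0
  if (any(zero)) {
    stopf("zero-variance feature(s) on the training split: %s",
          paste(feature_cols[zero], collapse = ", "))
  }
  params <- tibble::tibble(feature = feature_cols, mu = unname(mu),
                           sigma = unname(sigma))
  list(train = zscore_apply(train, params),
       test = if (!is.null(test)) zscore_apply(test, params),
       params = params)
}

#' Apply stored z-score parameters to a feature table
#' @param data Tibble with the feature columns.
#' @param params The `params` tibble from [zscore_fit_transform()].
#' @param inverse If `TRUE`, undo the normalization instead.
#' @return The transformed tibble.
#' @export
zscore_apply <- function(data, params, inverse = FALSE) {
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    data[[f]] <- if (inverse) {
      data[[f]] * params$sigma[i] + params$mu[i]
    } else {
      (data[[f]] - params$mu[i]) / params$sigma[i]
    }
  }
  data
}

#' Balanced k-fold cross-validation indices
#'
#' Shuffles `1..n` under the seed and deals the indices into `k` validation
#' folds whose sizes differ by at most one.
#'
#' @param n Number of records.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A list of `k` lists, each with `train_idx` and `val_idx`;
#'   validation folds partition `1..n`.
#' @export
kfold_indices <- function(n, k = 5L, seed = 1L) {
  if (n < k) stopf("n = %d is smaller than k = %d folds", n, k)
  if (k < 2L) stopf("k must be >= 2")
  with_seed(seed, {
    perm <- sample.int(n)
    base <- n %/% k
    extra <- n %% k
    sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    ends <- cumsum(sizes)
    starts <- c(1L, ends[-k] + 1L)
    lapply(seq_len(k), function(i) {
      val <- sort(perm[starts[i]:ends[i]])
      list(train_idx = setdiff(seq_len(n), val), val_idx = val)
    })
  })
}
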