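#' Configuration for an end-to-end pipeline run
#'
#' Bundles the per-stage parameters, the image source (synthetic by default)
#' and the global seed. All stage seeds are derived deterministically from
#' `seed`, so a config + seed pair reproduces every output byte for byte.
#'
#' @param n_images Number of synthetic images (balanced classes, alternating)
#'   when no adapter images are supplied.
#' @param models Character vector of model names to train (subset of
#'   `r paste(MODEL_NAMES, collapse = ", ")`).
#' @param seed Global integer seed.
#' @param output_dir Directory for the results bundle (`NULL` = keep results
#'   in memory only).
#' @param synth_overrides Named list applied to each [synth_config()]
#'   (e.g. `list(n_hairs = 5)`).
#' @param hair_params,graphcut_params,slic_params Stage parameter objects.
#' @param overlap_threshold Kept-superpixel overlap threshold.
#' @param train_fraction Train fraction for the record-level split.
#' @param cv_folds Cross-validation folds recorded during training.
#' @param images Optional list of `(image, class_label)` pairs or a tibble
#'   with `path`/`class_label` columns from [load_dataset_adapter()]; when
#'   given, `n_images` and `synth_overrides` are ignored.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_images = 10L,
                            models = "RF",
                            seed = 1L,
                            output_dir = NULL,
                            synth_overrides = list(),
                            hair_params = hair_removal_params(),
                            graphcut_params = dermsp::graphcut_params(),
                            slic_params = dermsp::slic_params(),
                            overlap_threshold = 0.5,
                            train_fraction = 0.7,
                            cv_folds = 5L,
                            images = NULL) {
  bad <- setdiff(models, MODEL_NAMES)
  if (length(bad) > 0L) {
    stopf("unknown model(s): %s (valid: %s)", paste(bad, collapse = ", "),
          paste(MODEL_NAMES, collapse = ", "))
  }
  structure(list(n_images = as.integer(n_images), models = models,
                 seed = as.integer(seed), output_dir = output_dir,
                 synth_overrides = synth_overrides,
                 hair_params = hair_params,
                 graphcut_params = graphcut_params,
                 slic_params = slic_params,
                 overlap_threshold = overlap_threshold,
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 images = images),
            class = "pipeline_config")
}

#' Run the full superpixel classification pipeline
#'
#' Executes, per image: hair removal -> graph-cut lesion segmentation ->
#' black-masking -> SLIC -> background-superpixel elimination -> geometric
#' feature extraction; then assembles the feature table, splits it
#' (stratified, record level), z-score-normalizes on the training part, and
#' trains and evaluates every requested model (with fivefold CV recorded).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A results bundle (class `sp_pipeline_result`): list with
#'   `features` (tibble), `split` (train/test tibbles), `normalization`,
#'   `models` (named list of `sp_model`), `metrics` (tibble, one row per
#'   model), `masks` (per-image lesion masks and truth masks when synthetic)
#'   and `timings`. When `config$output_dir` is set, writes `features.csv`,
#'   `split_manifest.json`, `metrics_<model>.json` and `run_log.txt`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stopf("`config` must be a pipeline_config")
  }
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage, t0) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  # ---- image source ----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  imgs <- pipeline_images(config)
  tick("images", t0)
  say("pipeline: %d images", length(imgs))

  # ---- per-image stages ------------------------------------------------
  feats <- vector("list", length(imgs))
  masks <- vector("list", length(imgs))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_along(imgs)) {
    item <- imgs[[i]]
    img <- item$image
    if (is.null(item$hair_mask) || any(item$hair_mask)) {
      hm <- detect_hair_mask(img, config$hair_params)
      img <- remove_hair(img, hm)
    }
    seeds <- auto_seeds(img, config$graphcut_params)
    lesion <- graph_cut_segment(img, seeds$fg_seed_mask, seeds$bg_seed_mask,
                                config$graphcut_params)
    masked <- apply_black_mask(img, lesion)
    lm <- slic_superpixels(masked, config$slic_params)
    sp <- filter_background_superpixels(lm, lesion,
                                        config$overlap_threshold,
                                        n_requested = config$slic_params$n_superpixels)
    feats[[i]] <- extract_all(sp, item$image_id, item$class_label)
    masks[[i]] <- list(image_id = item$image_id, lesion_mask = lesion,
                       truth_mask = item$truth_mask, n_kept = sp$n_kept)
    say("  [%d/%d] %s: %d superpixels kept", i, length(imgs), item$image_id,
        sp$n_kept)
  }
  tick("segmentation_features", t0)
  features <- dplyr::bind_rows(feats)
  if (nrow(features) == 0L) stopf("pipeline produced no superpixel records")

  # ---- dataset assembly ------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  split <- split_dataset(features, train_fraction = config$train_fraction,
                         stratified = TRUE,
                         seed = derive_seed(config$seed, "split"))
  norm <- zscore_fit_transform(split$train, split$test)
  tick("dataset", t0)

  # ---- models ----------------------------------------------------------
  models <- list()
  metrics <- list()
  for (name in config$models) {
    t0 <- proc.time()[["elapsed"]]
    spec <- if (name %in% NN_NAMES) {
      build_network(name, seed = derive_seed(config$seed, name))
    } else {
      build_classifier(name, seed = derive_seed(config$seed, name))
    }
    fitted <- train_model(spec, norm$train, cv_folds = config$cv_folds)
    pred <- stats::predict(fitted, norm$test)
    ev <- evaluate_predictions(norm$test$class, pred)
    metrics[[name]] <- dplyr::bind_cols(
      tibble::tibble(model = name, cv_accuracy = fitted$cv_accuracy), ev)
    models[[name]] <- fitted
    tick(paste0("model_", name), t0)
    say("  %s: test accuracy %.3f (CV %.3f)", name, ev$accuracy,
        fitted$cv_accuracy)
  }
  metrics <- dplyr::bind_rows(metrics)
  timings[["total"]] <- round(proc.time()[["elapsed"]] - t_start, 3)

  result <- structure(list(features = features, split = split,
                           normalization = norm, models = models,
                           metrics = metrics, masks = masks,
                           config = config, timings = timings),
                      class = "sp_pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(result)
  result
}

# Build the list of per-image work items (synthetic by default).
pipeline_images <- function(config) {
  if (!is.null(config$images)) {
    items <- config$images
    if (is.data.frame(items)) {
      items <- purrr::pmap(items, function(path, class_label, ...) {
        list(image = read_image(path), class_label = class_label,
             image_id = basename(path))
      })
    }
    return(lapply(items, function(it) {
      list(image = it$image, class_label = it$class_label,
           image_id = it$image_id %||% "image",
           truth_mask = it$truth_mask %||% NULL,
           hair_mask = it$hair_mask %||% NULL)
    }))
  }
  n <- config$n_images
  lapply(seq_len(n), function(i) {
    cls <- if (i %% 2L == 1L) "nevus" else "melanoma"
    args <- utils::modifyList(
      list(class_label = cls, seed = derive_seed(config$seed, paste0("img", i))),
      config$synth_overrides)
    g <- generate_lesion_image(do.call(synth_config, args))
    list(image = g$image, class_label = g$class_label,
         image_id = sprintf("synth_%03d_%s", i, cls),
         truth_mask = g$truth_mask, hair_mask = g$hair_mask)
  })
}

write_pipeline_outputs <- function(result) {
  dir.create(result$config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(result$config$output_dir, f)
  write_feature_csv(result$features, out("features.csv"))
  jsonlite::write_json(list(seed = result$config$seed,
                            train_fraction = result$config$train_fraction,
                            train_idx = attr(result$split, "train_idx")),
                       out("split_manifest.json"), auto_unbox = TRUE)
  for (name in names(result$models)) {
    row <- result$metrics[result$metrics$model == name, ]
    jsonlite::write_json(list(
      model = name,
      dataset = "synthetic",
      split = result$config$train_fraction,
      cv_mean_accuracy = row$cv_accuracy,
      test = list(accuracy = row$accuracy, precision = row$precision,
                  recall = row$recall, f1 = row$f1, mcc = row$mcc,
                  undefined = row$undefined[[1]],
                  confusion = list(tp = row$tp, tn = row$tn,
                                   fp = row$fp, fn = row$fn))),
      out(sprintf("metrics_%s.json", name)), auto_unbox = TRUE, digits = NA)
  }
  log_lines <- c(
    sprintf("dermsp %s | R %s", as.character(utils::packageVersion("dermsp")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", result$config$seed),
    sprintf("images: %d | records: %d", length(result$masks),
            nrow(result$features)),
    sprintf("stage timings (s): %s",
            paste(names(result$timings), unlist(result$timings),
                  sep = "=", collapse = ", "))
  )
  writeLines(log_lines, out("run_log.txt"))
  invisible(result)
}

#' @export
print.sp_pipeline_result <- function(x, ...) {
  cat(sprintf("<sp_pipeline_result> %d images, %d superpixel records, %d model(s)\n",
              length(x$masks), nrow(x$features), length(x$models)))
  if (nrow(x$metrics) > 0) print(x$metrics[, c("model", "cv_accuracy",
                                               "accuracy", "mcc")])
  invisible(x)
}

#' Load (image path, class label) pairs from a dataset folder layout
#'
#' Adapters for the public dermoscopy collections and a generic
#' `<root>/<class>/*.png|jpg` layout:
#' * `folder` — class labels from the sub-directory names;
#' * `mednode` — `<root>/melanoma` and `<root>/naevus` directories;
#' * `sevenpoint` — reads `meta/meta.csv` (columns `case_num`, `diagnosis`,
#'   `derm`); `atypical nevus` maps to nevus for the binary task and the raw
#'   three-class label is kept in `diagnosis`; an explicit `image_list` of
#'   `derm` paths restricts the selection;
#' * `padufes20` — reads `metadata.csv` (columns `img_id`, `diagnostic`),
#'   keeping MEL and NEV rows.
#'
#' @param name Adapter name.
#' @param root_path Dataset root directory.
#' @param image_list Optional character vector restricting the images
#'   (sevenpoint).
#' @return Tibble with `path`, `class_label` (nevus/melanoma) and, where
#'   available, the raw `diagnosis`.
#' @export
load_dataset_adapter <- function(name = c("folder", "mednode", "sevenpoint",
                                          "padufes20"),
                                 root_path, image_list = NULL) {
  name <- tryCatch(match.arg(name),
                   error = function(e) {
                     stopf("unknown adapter '%s'; valid adapters: folder, mednode, sevenpoint, padufes20",
                           name[1])
                   })
  if (!dir.exists(root_path)) stopf("dataset root not found: %s", root_path)
  exts <- "\\.(png|jpg|jpeg)$"
  if (name == "folder" || name == "mednode") {
    dirs <- if (name == "mednode") {
      c(melanoma = "melanoma", nevus = "naevus")
    } else {
      d <- list.dirs(root_path, recursive = FALSE, full.names = FALSE)
      stats::setNames(d, d)
    }
    rows <- purrr::imap(dirs, function(d, label) {
      p <- list.files(file.path(root_path, d), pattern = exts,
                      full.names = TRUE, ignore.case = TRUE)
      if (length(p) == 0L) return(NULL)
      tibble::tibble(path = p, class_label = label)
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0L) {
      warning("no images found under ", root_path, call. = FALSE)
      return(tibble::tibble(path = character(), class_label = character()))
    }
    if (name == "mednode") out$class_label <- ifelse(out$class_label == "melanoma",
                                                     "melanoma", "nevus")
    return(out)
  }
  if (name == "sevenpoint") {
    meta_path <- file.path(root_path, "meta", "meta.csv")
    if (!file.exists(meta_path)) stopf("missing metadata file: %s", meta_path)
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    need <- c("diagnosis", "derm")
    if (!all(need %in% names(meta))) {
      stopf("meta.csv must contain columns: %s", paste(need, collapse = ", "))
    }
    keep <- grepl("melanoma|nevus", meta$diagnosis, ignore.case = TRUE)
    meta <- meta[keep, , drop = FALSE]
    if (!is.null(image_list)) meta <- meta[meta$derm %in% image_list, , drop = FALSE]
    return(tibble::tibble(
      path = file.path(root_path, "images", meta$derm),
      class_label = ifelse(grepl("melanoma", meta$diagnosis, ignore.case = TRUE),
                           "melanoma", "nevus"),
      diagnosis = meta$diagnosis))
  }
  # padufes20
  meta_path <- file.path(root_path, "metadata.csv")
  if (!file.exists(meta_path)) stopf("missing metadata file: %s", meta_path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (!all(c("img_id", "diagnostic") %in% names(meta))) {
    stopf("metadata.csv must contain columns img_id, diagnostic")
  }
  meta <- meta[meta$diagnostic %in% c("MEL", "NEV"), , drop = FALSE]
  tibble::tibble(path = file.path(root_path, "images", meta$img_id),
                 class_label = ifelse(meta$diagnostic == "MEL",
                                      "melanoma", "nevus"),
                 diagnosis = meta$diagnostic)
}
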