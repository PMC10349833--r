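#' Read an RGB image as an H x W x 3 array on the 0-255 scale
#' @param path PNG file path.
#' @return Numeric H x W x 3 array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Write an RGB image (0-255 array) as PNG
#' @param rgb_image H x W x 3 array.
#' @param path Output path.
#' @export
write_image <- function(rgb_image, path) {
  assert_image(rgb_image)
  png::writePNG(clip01(rgb_image) / 255, path)
  invisible(path)
}

#' Write a binary mask as a 0/255 single-channel PNG
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(as_logical_mask(mask)), nrow(mask), ncol(mask)),
                path)
  invisible(path)
}

#' Read a 0/255 mask PNG as a logical matrix
#' @param path PNG file path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}

#' Write a label map as a tab-separated integer matrix
#' @param label_map Integer matrix.
#' @param path Output path (.tsv).
#' @export
write_label_map <- function(label_map, path) {
  utils::write.table(label_map, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path TSV file path.
#' @return Integer matrix.
#' @export
read_label_map <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE)) |>
    unname() |>
    (\(m) matrix(as.integer(m), nrow(m), ncol(m)))()
}

#' Write a superpixel feature table as CSV
#'
#' Schema: `image_id,sp_label,area,perimeter,eccentricity,orientation,`
#' `convex_area,major_axis_length,class`.
#' @param features Tibble from [extract_all()] or [generate_feature_table()].
#' @param path Output path.
#' @export
write_feature_csv <- function(features, path) {
  cols <- c("image_id", "sp_label", sp_feature_names(), "class")
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0L) {
    stopf("feature table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(features[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a superpixel feature CSV
#' @param path CSV path.
#' @return Tibble.
#' @export
read_feature_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
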