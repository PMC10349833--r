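#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats predict
NULL

# Run code with a temporarily fixed RNG state, restoring whatever state the
# caller had (including "no state yet"). All seeded operations in the package
# funnel through this so that user-level RNG is never disturbed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible sub-seed from a base seed and a stage tag, kept well
# inside 32-bit integer range.
derive_seed <- function(seed, tag) {
  tag_num <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + tag_num) %% 2147483587L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stopf("`%s` must be an H x W x 3 numeric array", arg)
  }
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) stopf("`%s` is empty", arg)
  invisible(img)
}

assert_mask <- function(mask, dims = NULL, arg = "mask") {
  if (!is.matrix(mask)) stopf("`%s` must be a logical/0-1 matrix", arg)
  if (!is.null(dims) && !all(dim(mask) == dims[1:2])) {
    stopf("`%s` (%d x %d) does not match the image size (%d x %d)",
          arg, nrow(mask), ncol(mask), dims[1], dims[2])
  }
  invisible(mask)
}

as_logical_mask <- function(mask) {
  m <- mask > 0.5
  storage.mode(m) <- "logical"
  m
}

# Rec.601 luminance of an H x W x 3 array on the 0..255 scale.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# EBImage works on plain matrices; keep a thin veneer so the (row = y, col = x)
# convention used throughout the package is explicit in one place.
ebi <- function(m) EBImage::as.Image(m)

# Connected components (4- or 8-connectivity) of a logical matrix; returns an
# integer matrix of component ids, 0 for background.
label_components <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- EBImage::bwlabel(m)
  matrix(as.integer(EBImage::imageData(out)), nrow(mask), ncol(mask))
}

largest_component <- function(mask) {
  cc <- label_components(mask)
  if (max(cc) == 0L) return(mask & FALSE)
  sizes <- tabulate(cc[cc > 0L])
  cc == which.max(sizes)
}
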