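#' Binary segmentation masks
#'
#' A `binary_mask` holds one source's segmentation of one image as a logical
#' matrix (`TRUE` = foreground), together with the identifiers needed to join
#' it back to a study catalog. Masks are strictly binary: any strictly
#' positive pixel value read from a raster file is foreground.
#'
#' @param mask A logical or numeric matrix; strictly positive entries are
#'   foreground.
#' @param image_id,source_id Opaque identifiers for the image and the
#'   annotation source (e.g. `"L1"`, `"L2"`, `"model"`).
#' @return An object of class `binary_mask`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2), "img1", "L1")
#' mask_area(m)
#' @export
binary_mask <- function(mask, image_id, source_id) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  if (length(mask) == 0L) abort("`mask` must have at least one pixel.")
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.logical(mask)) abort("`mask` must be logical or numeric.")
  mask[is.na(mask)] <- FALSE
  structure(
    list(image_id = as.character(image_id),
         source_id = as.character(source_id),
         mask = mask),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> image %s, source %s: %d x %d px, %d foreground\n",
              x$image_id, x$source_id, ncol(x$mask), nrow(x$mask),
              sum(x$mask)))
  invisible(x)
}

#' @rdname binary_mask
#' @param x A `binary_mask`.
#' @export
mask_area <- function(x) sum(x$mask)

#' Dice similarity coefficient between two masks
#'
#' The Dice similarity coefficient (DSC) is the standard spatial overlap
#' index for segmentation evaluation: `2|A n B| / (|A| + |B|)`, in `[0, 1]`.
#' Two empty masks score 1: two raters agreeing that there is no target
#' region is perfect agreement; an empty mask against a non-empty one scores
#' 0 by the formula.
#'
#' @param a,b `binary_mask` objects for the same image with identical
#'   dimensions.
#' @return A number in `[0, 1]`.
#' @examples
#' a <- binary_mask(matrix(c(1, 1, 0, 0), 2, 2), "i", "L1")
#' b <- binary_mask(matrix(c(1, 0, 1, 0), 2, 2), "i", "L2")
#' dice(a, b)
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$mask), dim(b$mask))) {
    abort("Masks have different dimensions; DSC is undefined.",
          class = "blindval_dim_mismatch")
  }
  if (!identical(a$image_id, b$image_id)) {
    abort("Masks belong to different images; refusing to compare.",
          class = "blindval_image_mismatch")
  }
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0L) return(1.0)
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' Mean of per-image closest DSC
#'
#' Given two DSC values per image (one against each of two reference
#' sources), selects the higher value for each image and averages the
#' per-image maxima. This is the "closest labeler" summary: how well a
#' segmentation agrees with whichever reference it happens to be nearest to.
#'
#' @param dsc_a,dsc_b Numeric vectors of per-image DSC values in `[0, 1]`,
#'   same length, at least one element.
#' @return The mean of `pmax(dsc_a, dsc_b)`.
#' @examples
#' closest_mean_dsc(c(0.2, 0.9), c(0.8, 0.1)) # 0.85
#' @export
closest_mean_dsc <- function(dsc_a, dsc_b) {
  if (length(dsc_a) == 0L) abort("Need at least one pair of DSC values.")
  if (length(dsc_a) != length(dsc_b)) {
    abort("`dsc_a` and `dsc_b` must have the same length.")
  }
  if (anyNA(dsc_a) || anyNA(dsc_b) ||
      any(dsc_a < 0 | dsc_a > 1 | dsc_b < 0 | dsc_b > 1)) {
    abort("DSC values must lie in [0, 1].")
  }
  mean(pmax(dsc_a, dsc_b))
}

#' Student-t confidence interval for a mean
#'
#' Interval `mean +/- t(1 - (1 - conf)/2, n - 1) * sd / sqrt(n)`, the form
#' used for all mean-DSC intervals reported by this package.
#'
#' @param mean,sd Sample mean and sample standard deviation (`n - 1`
#'   denominator).
#' @param n Sample size, at least 2.
#' @param conf_level Confidence level, default `0.95`.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @examples
#' mean_ci_t(0.636, 0.215, 55)
#' @export
mean_ci_t <- function(mean, sd, n, conf_level = 0.95) {
  if (n < 2) abort("`n` must be at least 2 for a t interval.")
  if (sd < 0) abort("`sd` must be nonnegative.")
  half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * sd / sqrt(n)
  c(ci_low = mean - half, ci_high = mean + half)
}

#' Summarise a collection of DSC values
#'
#' @param x Numeric vector of DSC values in `[0, 1]`.
#' @param conf_level Confidence level for the t interval.
#' @return A one-row tibble with `n`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `conf_level`. When `n < 2` the interval is `NA` and a warning is
#'   raised.
#' @export
dsc_summary <- function(x, conf_level = 0.95) {
  if (length(x) == 0L) abort("Need at least one DSC value.")
  m <- mean(x)
  if (length(x) < 2L) {
    warn("Fewer than 2 values: no confidence interval computed.")
    s <- NA_real_; ci <- c(ci_low = NA_real_, ci_high = NA_real_)
  } else {
    s <- sd(x)
    ci <- mean_ci_t(m, s, length(x), conf_level)
  }
  tibble::tibble(n = length(x), mean = m, sd = s,
                 ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
                 conf_level = conf_level)
}

#' Read and write binary masks as PNG
#'
#' `read_mask()` accepts any raster PNG: multi-channel images are reduced to
#' their first channel and any strictly positive value becomes foreground.
#' `write_mask()` stores the mask as a single-channel PNG with values 0/1, so
#' a write-read round trip reproduces the foreground set exactly.
#'
#' @param path Path to a PNG file.
#' @param image_id,source_id Identifiers to attach to the mask read.
#' @param mask A `binary_mask`.
#' @return `read_mask()` returns a `binary_mask`; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, image_id, source_id) {
  if (!file.exists(path)) abort(sprintf("No such mask file: %s", path))
  px <- tryCatch(png::readPNG(path),
                 error = function(e) abort(sprintf("Unreadable raster: %s", path)))
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (length(px) == 0L) abort(sprintf("Zero-size raster: %s", path))
  binary_mask(px > 0, image_id, source_id)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Read a mask manifest
#'
#' The manifest is the plain-text index of a mask catalog: a CSV with columns
#' `image_id`, `source_id`, `mask_path`, one row per mask.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with character columns `image_id`, `source_id`,
#'   `mask_path`.
#' @export
read_manifest <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("image_id", "source_id", "mask_path")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("Manifest must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  tbl[need]
}
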