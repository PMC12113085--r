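#' Annotation catalog
#'
#' The catalog is the complete grid of masks entering a study: every image
#' annotated by every source exactly once. It is stored as a tibble with one
#' row per (image, source) pair; a `mask` list-column (of [binary_mask()]
#' objects) and/or a `mask_path` column may be attached. Schedule building
#' needs only the grid; DSC computations and the review loop need the masks.
#'
#' @param grid A data frame with columns `image_id` and `source_id`, and
#'   optionally `mask` (list of `binary_mask`) and `mask_path`.
#' @return An `annotation_catalog` tibble.
#' @export
annotation_catalog <- function(grid) {
  grid <- tibble::as_tibble(grid)
  if (!all(c("image_id", "source_id") %in% names(grid))) {
    abort("Catalog needs `image_id` and `source_id` columns.")
  }
  grid$image_id <- as.character(grid$image_id)
  grid$source_id <- as.character(grid$source_id)
  images <- unique(grid$image_id)
  sources <- unique(grid$source_id)
  if (length(images) < 1L || length(sources) < 2L) {
    abort("Catalog needs at least 1 image and 2 sources.")
  }
  if (nrow(grid) != length(images) * length(sources) ||
      anyDuplicated(grid[c("image_id", "source_id")])) {
    abort("Catalog must be a complete grid: one mask per (image, source).",
          class = "blindval_incomplete_grid")
  }
  structure(grid, class = c("annotation_catalog", class(grid)),
            images = images, sources = sources)
}

#' @rdname annotation_catalog
#' @param x An `annotation_catalog`.
#' @export
catalog_images <- function(x) attr(x, "images")

#' @rdname annotation_catalog
#' @export
catalog_sources <- function(x) attr(x, "sources")

#' Load a catalog from a manifest, reading the mask files
#'
#' @param manifest A manifest tibble (see [read_manifest()]) or a path to
#'   one.
#' @param read_masks Whether to read the PNG files into a `mask`
#'   list-column. Set `FALSE` when only the grid is needed.
#' @return An `annotation_catalog`.
#' @export
load_catalog <- function(manifest, read_masks = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  grid <- tibble::as_tibble(manifest)
  if (read_masks) {
    grid$mask <- purrr::pmap(
      grid[c("image_id", "source_id", "mask_path")],
      function(image_id, source_id, mask_path) {
        read_mask(mask_path, image_id, source_id)
      }
    )
  }
  annotation_catalog(grid)
}

#' Per-image DSC for every pair of sources
#'
#' @param catalog An `annotation_catalog` carrying a `mask` list-column.
#' @return A tibble with one row per image and unordered source pair:
#'   `image_id`, `source_a`, `source_b`, `dsc`.
#' @export
pairwise_dsc <- function(catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (is.null(catalog$mask)) abort("Catalog has no `mask` column.")
  sources <- catalog_sources(catalog)
  pairs <- utils::combn(sources, 2L, simplify = FALSE)
  lookup <- stats::setNames(catalog$mask,
                            paste(catalog$image_id, catalog$source_id,
                                  sep = "\r"))
  purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(
      image_id = catalog_images(catalog),
      source_a = pr[[1L]],
      source_b = pr[[2L]],
      dsc = purrr::map_dbl(catalog_images(catalog), function(img) {
        dice(lookup[[paste(img, pr[[1L]], sep = "\r")]],
             lookup[[paste(img, pr[[2L]], sep = "\r")]])
      })
    )
  })
}
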