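#' Build a blinded presentation schedule
#'
#' Constructs the shuffled, anonymised presentation sequence at the heart of
#' a blinded validation study. Every (image, source) pair appears once; in
#' addition, for each source a requested number of images is covertly
#' included a second time (replicate 2) so the validator's intra-observer
#' consistency can be measured. Duplicated images are chosen uniformly
#' without replacement per source, and the final order is a uniform random
#' permutation of all items, driven solely by `seed`.
#'
#' The result splits into two files-worth of information: the *plan* (the
#' ordered presentation ids, all a review interface may ever see) and the
#' *provenance record* (the sealed map from presentation id back to image,
#' source and replicate), kept apart until analysis. Presentation ids are
#' random 128-bit hex tokens so they encode nothing about origin or
#' generation order.
#'
#' @param catalog An [annotation_catalog()].
#' @param duplicates Named integer vector: duplicate count per source id.
#'   Sources omitted get 0. Each count must not exceed the image count.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param min_gap Optional minimum number of positions between a duplicate
#'   and its original (0 = no constraint, the default).
#' @return A list with elements `plan` (tibble `position`,
#'   `presentation_id`, class `schedule_plan`) and `provenance` (tibble
#'   `presentation_id`, `image_id`, `source_id`, `replicate`, class
#'   `provenance_record`).
#' @examples
#' cat <- annotation_catalog(expand.grid(image_id = c("a", "b"),
#'                                       source_id = c("L1", "L2")))
#' sch <- build_schedule(cat, c(L1 = 1), seed = 7)
#' nrow(sch$plan) # 2 * 2 + 1
#' @export
build_schedule <- function(catalog, duplicates = integer(), seed,
                           min_gap = 0L) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  images <- catalog_images(catalog)
  sources <- catalog_sources(catalog)
  dup <- stats::setNames(rep(0L, length(sources)), sources)
  if (length(duplicates)) {
    if (is.null(names(duplicates)) ||
        !all(names(duplicates) %in% sources)) {
      abort("`duplicates` must be named by source ids in the catalog.")
    }
    if (any(duplicates < 0) || any(duplicates > length(images))) {
      abort("Duplicate counts must be between 0 and the image count.",
            class = "blindval_bad_duplicates")
    }
    dup[names(duplicates)] <- as.integer(duplicates)
  }

  withr::with_seed(seed, {
    rep1 <- tidyr::expand_grid(image_id = images, source_id = sources)
    rep1$replicate <- 1L
    rep2 <- purrr::map_dfr(sources, function(s) {
      k <- dup[[s]]
      if (k == 0L) return(NULL)
      tibble::tibble(image_id = sample(images, k),
                     source_id = s, replicate = 2L)
    })
    items <- dplyr::bind_rows(rep1, rep2)
    n <- nrow(items)
    items$presentation_id <- random_tokens(n)
    ord <- sample.int(n)
    if (min_gap > 0L) {
      for (try in seq_len(1000L)) {
        if (min_dup_gap(items, ord) > min_gap) break
        ord <- sample.int(n)
      }
      if (min_dup_gap(items, ord) <= min_gap) {
        abort("Could not satisfy `min_gap` after 1000 shuffles.")
      }
    }
    items <- items[ord, ]
  })

  plan <- tibble::tibble(position = seq_len(nrow(items)),
                         presentation_id = items$presentation_id)
  attr(plan, "seed") <- seed
  attr(plan, "duplicates") <- dup
  class(plan) <- c("schedule_plan", class(plan))

  prov <- tibble::as_tibble(
    items[c("presentation_id", "image_id", "source_id", "replicate")]
  )
  class(prov) <- c("provenance_record", class(prov))
  list(plan = plan, provenance = prov)
}

# 128-bit random hex tokens from the current RNG stream
random_tokens <- function(n) {
  hex <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i) {
    paste(sample(hex, 32L, replace = TRUE), collapse = "")
  }, character(1))
}

# smallest position gap between the two showings of any duplicated item
min_dup_gap <- function(items, ord) {
  pos <- integer(nrow(items)); pos[ord] <- seq_along(ord)
  key <- paste(items$image_id, items$source_id, sep = "\r")
  dup_keys <- key[items$replicate == 2L]
  if (!length(dup_keys)) return(Inf)
  min(vapply(dup_keys, function(k) {
    p <- pos[key == k]
    abs(diff(range(p)))
  }, numeric(1)))
}

#' Order of appearance of each source's mask within its image
#'
#' For each image, the presentations of its sources are ranked by schedule
#' position: the source whose mask the validator saw first for that image
#' gets rank 1, and so on. By default covert duplicates (replicate 2) are
#' excluded, so each image receives exactly the ranks `1..S`; with
#' `include_duplicates = TRUE` every presentation of the image is ranked.
#'
#' @param plan,provenance The two halves returned by [build_schedule()].
#' @param include_duplicates Rank replicate-2 presentations too.
#' @return A tibble `image_id`, `source_id`, (`replicate`,) `rank`.
#' @export
order_ranks <- function(plan, provenance, include_duplicates = FALSE) {
  joined <- dplyr::inner_join(plan, provenance, by = "presentation_id")
  if (nrow(joined) != nrow(plan) || nrow(joined) != nrow(provenance)) {
    abort("Plan and provenance are inconsistent.",
          class = "blindval_plan_mismatch")
  }
  if (!include_duplicates) joined <- joined[joined$replicate == 1L, ]
  joined |>
    dplyr::group_by(.data$image_id) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("image_id", "source_id", "replicate",
                                  "rank")))
}

#' Seal and unseal the provenance record
#'
#' The provenance record is the only place where presentation ids are tied
#' back to their origin. `seal_provenance()` writes it to its own JSON file,
#' which must never be handed to the review interface;
#' `unseal_provenance()` reads it back at analysis time, checking that the
#' mapping is still a bijection between presentation ids and (image,
#' source, replicate) triples.
#'
#' @param provenance A `provenance_record`.
#' @param path JSON file path.
#' @return `seal_provenance()` returns `path` invisibly;
#'   `unseal_provenance()` returns the `provenance_record`.
#' @export
seal_provenance <- function(provenance, path) {
  stopifnot(inherits(provenance, "provenance_record"))
  jsonlite::write_json(as.data.frame(provenance), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname seal_provenance
#' @export
unseal_provenance <- function(path) {
  rec <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(sprintf(
                    "Corrupt provenance file: %s", conditionMessage(e))))
  need <- c("presentation_id", "image_id", "source_id", "replicate")
  if (!is.data.frame(rec) || !all(need %in% names(rec))) {
    abort("Provenance file lacks the required fields.",
          class = "blindval_bad_provenance")
  }
  rec <- tibble::as_tibble(rec[need])
  rec$replicate <- as.integer(rec$replicate)
  validate_provenance(rec)
  class(rec) <- c("provenance_record", class(rec))
  rec
}

validate_provenance <- function(rec) {
  if (anyDuplicated(rec$presentation_id)) {
    abort("Provenance is not a bijection: duplicated presentation ids.",
          class = "blindval_bad_provenance")
  }
  triple <- paste(rec$image_id, rec$source_id, rec$replicate, sep = "\r")
  if (anyDuplicated(triple)) {
    abort("Provenance is not a bijection: duplicated triples.",
          class = "blindval_bad_provenance")
  }
  if (!all(rec$replicate %in% 1:2)) {
    abort("Replicate must be 1 or 2.", class = "blindval_bad_provenance")
  }
  rep2 <- rec[rec$replicate == 2L, ]
  if (nrow(rep2)) {
    key1 <- paste(rec$image_id[rec$replicate == 1L],
                  rec$source_id[rec$replicate == 1L], sep = "\r")
    key2 <- paste(rep2$image_id, rep2$source_id, sep = "\r")
    if (!all(key2 %in% key1)) {
      abort("Replicate 2 exists for a pair with no replicate 1.",
            class = "blindval_bad_provenance")
    }
  }
  invisible(rec)
}

#' Write and read a schedule plan
#'
#' The plan file is what the review interface consumes: the ordered array of
#' presentation ids, and nothing else.
#'
#' @param plan A `schedule_plan`.
#' @param path JSON file path.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "schedule_plan"))
  jsonlite::write_json(plan$presentation_id, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  ids <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  if (!length(ids) || anyDuplicated(ids)) {
    abort("Plan file is empty or has duplicated presentation ids.")
  }
  plan <- tibble::tibble(position = seq_along(ids),
                         presentation_id = as.character(ids))
  class(plan) <- c("schedule_plan", class(plan))
  plan
}
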