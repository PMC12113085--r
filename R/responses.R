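#' Label schemes
#'
#' The categories a validator may assign, plus the subset counted as
#' "agreement" when labels are collapsed to binary. The shipped default is
#' the four-category scheme — correct, oversegmented, undersegmented,
#' incorrect — with `agree = "correct"`; any set of unique categories with a
#' nonempty proper agree subset is accepted.
#'
#' @param categories Character vector of unique category names.
#' @param agree Nonempty proper subset of `categories` counted as agreement.
#' @return A `label_scheme` object.
#' @export
label_scheme <- function(categories = c("correct", "oversegmented",
                                        "undersegmented", "incorrect"),
                         agree = "correct") {
  if (anyDuplicated(categories)) abort("Categories must be unique.")
  if (!length(agree) || !all(agree %in% categories) ||
      length(agree) >= length(categories)) {
    abort("`agree` must be a nonempty proper subset of the categories.")
  }
  structure(list(categories = categories, agree = agree),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme>", paste(x$categories, collapse = ", "),
      "| agree:", paste(x$agree, collapse = ", "), "\n")
  invisible(x)
}

#' Collapse labels to agree / disagree
#'
#' @param labels Character vector of labels from the scheme.
#' @param scheme A [label_scheme()].
#' @return Character vector of `"agree"` / `"disagree"`.
#' @examples
#' collapse_binary(c("correct", "oversegmented"), label_scheme())
#' @export
collapse_binary <- function(labels, scheme = label_scheme()) {
  stopifnot(inherits(scheme, "label_scheme"))
  bad <- setdiff(labels, scheme$categories)
  if (length(bad)) {
    abort(sprintf("Unknown label(s): %s", paste(unique(bad), collapse = ", ")),
          class = "blindval_bad_label")
  }
  ifelse(labels %in% scheme$agree, "agree", "disagree")
}

#' Response logs
#'
#' A response log is the append-only record of a validator's judgments: one
#' row per presentation with the label chosen, an optional free-text
#' comment, and two UTC timestamps — when the item was displayed
#' (`shown_at`) and when the label was committed (`answered_at`).
#'
#' @param scheme The [label_scheme()] in force for the log.
#' @return An empty `response_log` tibble.
#' @export
response_log <- function(scheme = label_scheme()) {
  log <- tibble::tibble(
    presentation_id = character(),
    label = character(),
    comment = character(),
    shown_at = as.POSIXct(character(), tz = "UTC"),
    answered_at = as.POSIXct(character(), tz = "UTC")
  )
  attr(log, "scheme") <- scheme
  class(log) <- c("response_log", class(log))
  log
}

#' @rdname response_log
#' @param log A `response_log`.
#' @export
log_scheme <- function(log) attr(log, "scheme") %||% label_scheme()

#' Append one validated judgment to a log
#'
#' Rejects duplicate presentation ids, labels outside the scheme, and
#' answer times earlier than display times. With `path` set, the new row is
#' also appended to the CSV file immediately, so a crash never loses
#' committed judgments.
#'
#' @param log A [response_log()].
#' @param presentation_id Id of the presented item; must not be answered yet.
#' @param label A category of the log's scheme.
#' @param comment Optional free text (stored verbatim, never analysed).
#' @param shown_at,answered_at POSIXct timestamps, `answered_at >= shown_at`.
#' @param path Optional CSV file to append the row to.
#' @return The grown log.
#' @export
append_response <- function(log, presentation_id, label, comment = "",
                            shown_at, answered_at, path = NULL) {
  scheme <- log_scheme(log)
  if (presentation_id %in% log$presentation_id) {
    abort(sprintf("Presentation %s already answered.", presentation_id),
          class = "blindval_duplicate_response")
  }
  if (!label %in% scheme$categories) {
    abort(sprintf("Label '%s' is not in the scheme.", label),
          class = "blindval_bad_label")
  }
  shown_at <- as.POSIXct(shown_at, tz = "UTC")
  answered_at <- as.POSIXct(answered_at, tz = "UTC")
  if (!is.finite(shown_at) || !is.finite(answered_at) ||
      answered_at < shown_at) {
    abort("Need finite timestamps with answered_at >= shown_at.")
  }
  row <- tibble::tibble(presentation_id = presentation_id, label = label,
                        comment = as.character(comment),
                        shown_at = shown_at, answered_at = answered_at)
  out <- dplyr::bind_rows(log, row)
  attr(out, "scheme") <- scheme
  class(out) <- c("response_log", setdiff(class(out), "response_log"))
  if (!is.null(path)) {
    readr::write_csv(row, path, append = file.exists(path),
                     col_names = !file.exists(path))
  }
  out
}

#' Write / read a response log
#'
#' CSV is the primary format (header
#' `presentation_id,label,comment,shown_at,answered_at`, RFC 4180 quoting so
#' comments may contain commas and newlines, ISO-8601 UTC timestamps); a
#' JSONL mirror with identical fields is written when `path` ends in
#' `.jsonl`.
#'
#' @param log A `response_log`.
#' @param path File path ending in `.csv` or `.jsonl`.
#' @param scheme Scheme to attach on read.
#' @export
write_responses <- function(log, path) {
  if (grepl("\\.jsonl$", path)) {
    df <- as.data.frame(log)
    df$shown_at <- format(df$shown_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    df$answered_at <- format(df$answered_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(df, con, verbose = FALSE)
  } else {
    readr::write_csv(tibble::as_tibble(log), path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, scheme = label_scheme()) {
  if (grepl("\\.jsonl$", path)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
    df$shown_at <- as.POSIXct(df$shown_at, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%OS")
    df$answered_at <- as.POSIXct(df$answered_at, tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%OS")
    tbl <- tibble::as_tibble(df)
  } else {
    tbl <- readr::read_csv(
      path, progress = FALSE,
      col_types = readr::cols(presentation_id = "c", label = "c",
                              comment = "c", shown_at = "T",
                              answered_at = "T"))
    tbl$shown_at <- as.POSIXct(tbl$shown_at, tz = "UTC")
    tbl$answered_at <- as.POSIXct(tbl$answered_at, tz = "UTC")
  }
  tbl$comment[is.na(tbl$comment)] <- ""
  bad <- setdiff(tbl$label, scheme$categories)
  if (length(bad)) {
    abort(sprintf("Log contains labels outside the scheme: %s",
                  paste(unique(bad), collapse = ", ")),
          class = "blindval_bad_label")
  }
  attr(tbl, "scheme") <- scheme
  class(tbl) <- c("response_log", class(tbl))
  tbl
}

#' Check a log against its plan
#'
#' @param log A `response_log`.
#' @param plan A `schedule_plan`.
#' @return A list with `missing` (plan ids without responses), `extra`
#'   (responses without a plan entry), and `complete` (both empty).
#' @export
completeness_check <- function(log, plan) {
  missing <- setdiff(plan$presentation_id, log$presentation_id)
  extra <- setdiff(log$presentation_id, plan$presentation_id)
  list(missing = missing, extra = extra,
       complete = !length(missing) && !length(extra))
}

#' Build the blinded bundle handed to the review interface
#'
#' Joins the plan with provenance and catalog *once, on the design side*, to
#' resolve which mask each presentation shows — and then strips every
#' provenance field. Each bundle item carries only `presentation_id`,
#' `position`, and the mask itself, so the review loop cannot leak origin
#' even in principle.
#'
#' @param plan,provenance The two halves from [build_schedule()].
#' @param catalog An [annotation_catalog()] with a `mask` list-column.
#' @return A list of items in schedule order, named by presentation id.
#' @export
make_review_bundle <- function(plan, provenance, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (is.null(catalog$mask)) abort("Catalog has no `mask` column.")
  joined <- dplyr::inner_join(plan, provenance, by = "presentation_id") |>
    dplyr::arrange(.data$position)
  lookup <- stats::setNames(catalog$mask,
                            paste(catalog$image_id, catalog$source_id,
                                  sep = "\r"))
  items <- purrr::pmap(
    joined[c("presentation_id", "position", "image_id", "source_id")],
    function(presentation_id, position, image_id, source_id) {
      m <- lookup[[paste(image_id, source_id, sep = "\r")]]
      # strip identity: the mask pixels only, no ids of any kind
      list(presentation_id = presentation_id, position = position,
           mask = m$mask)
    }
  )
  stats::setNames(items, joined$presentation_id)
}

#' Write / read a blinded bundle directory
#'
#' `write_review_bundle()` materialises the blinding boundary on disk: each
#' mask is copied to `<presentation_id>.png` and an index `bundle.json`
#' lists only presentation ids, positions and file names. This is the only
#' artifact a review interface is ever given; the provenance file lives
#' elsewhere. `read_review_bundle()` loads it back into the in-memory form
#' [review_loop()] consumes, auditing the index schema for provenance
#' fields.
#'
#' @inheritParams make_review_bundle
#' @param dir Bundle directory.
#' @export
write_review_bundle <- function(plan, provenance, catalog, dir) {
  bundle <- make_review_bundle(plan, provenance, catalog)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- purrr::map_dfr(bundle, function(item) {
    f <- paste0(item$presentation_id, ".png")
    png::writePNG(item$mask * 1, file.path(dir, f))
    tibble::tibble(presentation_id = item$presentation_id,
                   position = item$position, mask_file = f)
  })
  jsonlite::write_json(as.data.frame(idx), file.path(dir, "bundle.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_review_bundle
#' @export
read_review_bundle <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "bundle.json"),
                             simplifyVector = TRUE)
  forbidden <- intersect(names(idx),
                         c("image_id", "source_id", "replicate"))
  if (length(forbidden)) {
    abort(sprintf("Bundle index leaks provenance fields: %s",
                  paste(forbidden, collapse = ", ")),
          class = "blindval_blinding_violation")
  }
  items <- purrr::pmap(idx, function(presentation_id, position, mask_file) {
    px <- png::readPNG(file.path(dir, mask_file))
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    list(presentation_id = presentation_id, position = position,
         mask = px > 0)
  })
  stats::setNames(items, idx$presentation_id)
}

#' Run the review loop over a blinded bundle
#'
#' Presents items strictly in schedule order, one at a time, with no
#' indication of origin or of how many covert repeats remain. `driver` is
#' called with a single bundle item and must return
#' `list(label = ..., comment = ...)`; a scripted function makes the loop
#' fully testable, an interactive one makes it a console tool. Returning
#' `NULL` quits mid-run, leaving a partial (but internally valid) log. An
#' invalid label keeps the item pending and re-presents it.
#'
#' @param plan A `schedule_plan`.
#' @param bundle The blinded bundle from [make_review_bundle()].
#' @param scheme The [label_scheme()].
#' @param driver Function `item -> list(label, comment)` or `NULL` to quit.
#' @param clock Time source, default [Sys.time()]; injectable for tests.
#' @param path Optional CSV to append each committed response to.
#' @param max_retries How many invalid answers to tolerate per item.
#' @return A `response_log`.
#' @export
review_loop <- function(plan, bundle, scheme = label_scheme(), driver,
                        clock = Sys.time, path = NULL, max_retries = 100L) {
  log <- response_log(scheme)
  for (pid in plan$presentation_id) {
    item <- bundle[[pid]]
    if (is.null(item)) abort(sprintf("Bundle lacks presentation %s.", pid))
    done <- FALSE
    for (try in seq_len(max_retries)) {
      shown <- clock()
      ans <- driver(item)
      if (is.null(ans)) return(log)            # validator quit mid-run
      if (!is.null(ans$label) && ans$label %in% scheme$categories) {
        log <- append_response(log, pid, ans$label,
                               comment = ans$comment %||% "",
                               shown_at = shown, answered_at = clock(),
                               path = path)
        done <- TRUE
        break
      }
      # no valid label: the item stays pending and is shown again
    }
    if (!done) abort(sprintf("No valid label for %s after %d attempts.",
                             pid, max_retries))
  }
  log
}
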