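#' Wilson score interval for a binomial proportion
#'
#' The score-test inversion interval, used for all proportion confidence
#' intervals reported by this package (it behaves well at the sample sizes
#' and high proportions typical of agreement studies, where the Wald
#' interval does not).
#'
#' @param successes,n Nonnegative counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf_level Confidence level, default `0.95`.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' wilson_ci(277, 300)
#' @export
wilson_ci <- function(successes, n, conf_level = 0.95) {
  if (n < 1) abort("`n` must be at least 1.")
  if (successes < 0 || successes > n) {
    abort("`successes` must lie in [0, n].")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c(low = (centre - half) / denom, high = (centre + half) / denom)
}

#' Cohen's kappa for a square confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with full marginals;
#' works for the binary collapse and for the full k-category matrix alike.
#' When expected agreement `p_e` is 1 (degenerate marginals) kappa is
#' undefined and returned as `NA` with a warning, never silently 0.
#'
#' @param mat Square nonnegative count matrix, rows = first evaluation,
#'   columns = second evaluation.
#' @return Kappa in `[-1, 1]`, or `NA` if undefined.
#' @export
cohens_kappa <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  n <- sum(mat)
  if (n < 1) abort("Confusion matrix must have at least one count.")
  po <- sum(diag(mat)) / n
  pe <- sum(rowSums(mat) * colSums(mat)) / n^2
  if (pe >= 1 - 1e-12) {
    warn("Expected agreement is 1: kappa is undefined.")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Per-source agreement breakdown
#'
#' Tallies the validator's replicate-1 judgments per annotation source: the
#' count of each label category and the percentage collapsing to agreement.
#' Covert duplicates (replicate 2) are deliberately excluded — they are
#' reserved for the intra-observer analysis, so that per-source denominators
#' equal the image count.
#'
#' @param log A [response_log()] covering every replicate-1 presentation.
#' @param provenance A `provenance_record`.
#' @param scheme The [label_scheme()].
#' @return A tibble with one row per source: `source_id`, `n`, one count
#'   column per category, `n_agree`, `pct_agree` (0–100).
#' @export
agreement_by_source <- function(log, provenance, scheme = log_scheme(log)) {
  rep1 <- provenance[provenance$replicate == 1L, ]
  missing <- setdiff(rep1$presentation_id, log$presentation_id)
  if (length(missing)) {
    abort(sprintf("Missing replicate-1 responses for %d presentation(s): %s",
                  length(missing),
                  paste(head(missing, 5L), collapse = ", ")),
          class = "blindval_incomplete_log")
  }
  joined <- dplyr::inner_join(tibble::as_tibble(log), rep1,
                              by = "presentation_id")
  joined$label <- factor(joined$label, levels = scheme$categories)
  counts <- joined |>
    dplyr::count(.data$source_id, .data$label, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  joined$binary <- collapse_binary(as.character(joined$label), scheme)
  agree <- joined |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(n = dplyr::n(),
                     n_agree = sum(.data$binary == "agree"),
                     pct_agree = 100 * .data$n_agree / .data$n,
                     .groups = "drop")
  dplyr::inner_join(agree[c("source_id", "n")], counts, by = "source_id") |>
    dplyr::inner_join(agree[c("source_id", "n_agree", "pct_agree")],
                      by = "source_id")
}

#' Intra-observer confusion matrices from covert repeats
#'
#' For every (image, source) pair the validator unknowingly judged twice,
#' cross-tabulates the first judgment (rows) against the second (columns):
#' once over the full category set and once after binary collapse. Per-source
#' matrices are returned alongside the pooled ones.
#'
#' @param log A [response_log()] with both responses for every duplicated
#'   pair.
#' @param provenance A `provenance_record`.
#' @param scheme The [label_scheme()].
#' @return A `repeat_confusion` object: list with `multi` (k x k matrix),
#'   `binary` (2 x 2 matrix, agree/disagree), `per_source` (same pair of
#'   matrices per source), and `n`.
#' @export
confusion_from_repeats <- function(log, provenance,
                                   scheme = log_scheme(log)) {
  dup_keys <- provenance[provenance$replicate == 2L,
                         c("image_id", "source_id")]
  if (!nrow(dup_keys)) abort("No duplicated presentations in provenance.")
  joined <- dplyr::inner_join(tibble::as_tibble(log), provenance,
                              by = "presentation_id")
  dups <- dplyr::semi_join(joined, dup_keys,
                           by = c("image_id", "source_id"))
  wide <- dups |>
    dplyr::select(dplyr::all_of(c("image_id", "source_id", "replicate",
                                  "label"))) |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "label",
                       names_prefix = "rep")
  if (!all(c("rep1", "rep2") %in% names(wide)) ||
      anyNA(wide$rep1) || anyNA(wide$rep2) || nrow(wide) != nrow(dup_keys)) {
    abort("Every duplicated (image, source) needs both replicate responses.",
          class = "blindval_unpaired_duplicate")
  }
  tab <- function(df) {
    lv <- scheme$categories
    multi <- table(factor(df$rep1, lv), factor(df$rep2, lv))
    bin <- table(factor(collapse_binary(df$rep1, scheme),
                        c("agree", "disagree")),
                 factor(collapse_binary(df$rep2, scheme),
                        c("agree", "disagree")))
    list(multi = unclass(as.matrix(multi)), binary = unclass(as.matrix(bin)))
  }
  pooled <- tab(wide)
  per_source <- lapply(split(wide, wide$source_id), tab)
  structure(list(multi = pooled$multi, binary = pooled$binary,
                 per_source = per_source, n = nrow(wide)),
            class = "repeat_confusion")
}

#' @export
print.repeat_confusion <- function(x, ...) {
  cat(sprintf("<repeat_confusion> %d repeated items\n", x$n))
  print(x$binary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy repeat_confusion
#' @export
tidy.repeat_confusion <- function(x, ...) {
  m <- x$multi
  tibble::tibble(
    first = rep(rownames(m), times = ncol(m)),
    second = rep(colnames(m), each = nrow(m)),
    n = as.vector(m)
  )
}

#' Reliability metrics from a binary repeat confusion matrix
#'
#' Treats the first evaluation as reference and the second as prediction,
#' with "agree" the positive class, and derives: accuracy (diagonal / total)
#' with a Wilson interval, Cohen's kappa, balanced accuracy (mean of recall
#' and specificity), F1, precision and recall.
#'
#' @param mat A 2 x 2 count matrix, rows = first evaluation, columns =
#'   second, in the order (agree, disagree) — as produced by
#'   [confusion_from_repeats()].
#' @param conf_level Confidence level for the accuracy interval.
#' @return A `rater_metrics` object; see [tidy.rater_metrics()] and
#'   [glance.rater_metrics()].
#' @examples
#' m <- matrix(c(245, 11, 12, 32), 2, 2,
#'             dimnames = list(c("agree", "disagree"),
#'                             c("agree", "disagree")))
#' glance(rater_metrics(m))
#' @export
rater_metrics <- function(mat, conf_level = 0.95) {
  stopifnot(is.matrix(mat), all(dim(mat) == 2L))
  n <- sum(mat)
  if (n < 1) abort("Confusion matrix must have at least one count.")
  tp <- mat[1, 1]; fn <- mat[1, 2]; fp <- mat[2, 1]; tn <- mat[2, 2]
  acc <- (tp + tn) / n
  ci <- wilson_ci(tp + tn, n, conf_level)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bacc <- mean(c(recall, specificity))
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  kappa <- withCallingHandlers(cohens_kappa(mat),
                               warning = function(w) invokeRestart("muffleWarning"))
  structure(list(accuracy = acc, acc_ci_low = ci[["low"]],
                 acc_ci_high = ci[["high"]], kappa = kappa,
                 balanced_accuracy = bacc, f1 = f1, precision = precision,
                 recall = recall, n = n, conf_level = conf_level,
                 matrix = mat),
            class = "rater_metrics")
}

#' @export
print.rater_metrics <- function(x, ...) {
  cat(sprintf(paste0("<rater_metrics> n = %d\n",
                     "  accuracy %.3f (%.3f, %.3f)  kappa %.3f\n",
                     "  balanced accuracy %.3f  F1 %.3f  precision %.3f",
                     "  recall %.3f\n"),
              x$n, x$accuracy, x$acc_ci_low, x$acc_ci_high, x$kappa,
              x$balanced_accuracy, x$f1, x$precision, x$recall))
  invisible(x)
}

#' Tidy methods for rater metrics
#'
#' `tidy()` returns one row per metric; `glance()` returns a one-row
#' summary in the column order agreement studies conventionally report.
#'
#' @param x A `rater_metrics` object.
#' @param ... Unused.
#' @method tidy rater_metrics
#' @export
tidy.rater_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "kappa", "balanced_accuracy", "f1",
               "precision", "recall"),
    estimate = c(x$accuracy, x$kappa, x$balanced_accuracy, x$f1,
                 x$precision, x$recall),
    conf.low = c(x$acc_ci_low, rep(NA_real_, 5)),
    conf.high = c(x$acc_ci_high, rep(NA_real_, 5))
  )
}

#' @rdname tidy.rater_metrics
#' @method glance rater_metrics
#' @export
glance.rater_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, acc_ci_low = x$acc_ci_low,
                 acc_ci_high = x$acc_ci_high, kappa = x$kappa,
                 balanced_accuracy = x$balanced_accuracy, f1 = x$f1,
                 precision = x$precision, recall = x$recall, n = x$n)
}

#' Concordance-stratified DSC
#'
#' For every pair of sources, splits the images by whether the validator's
#' binary judgment (agree/disagree) was the *same* for both sources' masks,
#' and summarises the inter-source DSC within each stratum (n, mean, sd,
#' Student-t interval). Masks the validator judged concordantly tend to be
#' the ones the sources drew similarly — this table quantifies that.
#'
#' @param log A complete replicate-1 [response_log()].
#' @param provenance A `provenance_record`.
#' @param dsc A pairwise DSC table from [pairwise_dsc()].
#' @param scheme The [label_scheme()].
#' @param conf_level Confidence level for the t intervals.
#' @return A tibble: `source_a`, `source_b`, `same_label`, `n`, `mean`,
#'   `sd`, `ci_low`, `ci_high`. Strata with `n < 2` get `NA` intervals and
#'   a warning.
#' @export
stratified_dsc <- function(log, provenance, dsc,
                           scheme = log_scheme(log), conf_level = 0.95) {
  rep1 <- provenance[provenance$replicate == 1L, ]
  labels <- dplyr::inner_join(tibble::as_tibble(log), rep1,
                              by = "presentation_id")
  labels$binary <- collapse_binary(labels$label, scheme)
  lab <- labels[c("image_id", "source_id", "binary")]
  joined <- dsc |>
    dplyr::inner_join(lab, by = c(image_id = "image_id",
                                  source_a = "source_id")) |>
    dplyr::rename(binary_a = "binary") |>
    dplyr::inner_join(lab, by = c(image_id = "image_id",
                                  source_b = "source_id")) |>
    dplyr::rename(binary_b = "binary")
  if (nrow(joined) != nrow(dsc)) {
    abort("Replicate-1 responses missing for some image/source in `dsc`.",
          class = "blindval_incomplete_log")
  }
  joined$same_label <- joined$binary_a == joined$binary_b
  out <- joined |>
    dplyr::group_by(.data$source_a, .data$source_b, .data$same_label) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$dsc),
                     sd = ifelse(dplyr::n() > 1, sd(.data$dsc), NA_real_),
                     .groups = "drop")
  ci <- purrr::pmap_dfr(out[c("mean", "sd", "n")], function(mean, sd, n) {
    if (n < 2) {
      tibble::tibble(ci_low = NA_real_, ci_high = NA_real_)
    } else {
      v <- mean_ci_t(mean, sd, n, conf_level)
      tibble::tibble(ci_low = v[["ci_low"]], ci_high = v[["ci_high"]])
    }
  })
  if (any(out$n < 2)) {
    warn("Stratum with fewer than 2 images: interval omitted.")
  }
  dplyr::bind_cols(out, ci)
}

#' Agreement by order of appearance
#'
#' The percentage of replicate-1 judgments collapsing to agreement, broken
#' down by source and by whether that source's mask was the first, second,
#' ... version of the image the validator saw. A trend across ranks is the
#' signature of an order-of-appearance bias.
#'
#' @param log A complete replicate-1 [response_log()].
#' @param plan,provenance The two halves from [build_schedule()].
#' @param scheme The [label_scheme()].
#' @return A tibble: `source_id`, `rank`, `n`, `n_agree`, `pct_agree`.
#' @export
order_effect <- function(log, plan, provenance,
                         scheme = log_scheme(log)) {
  ranks <- order_ranks(plan, provenance)
  rep1 <- provenance[provenance$replicate == 1L, ]
  joined <- dplyr::inner_join(tibble::as_tibble(log), rep1,
                              by = "presentation_id") |>
    dplyr::inner_join(ranks[c("image_id", "source_id", "rank")],
                      by = c("image_id", "source_id"))
  joined$binary <- collapse_binary(joined$label, scheme)
  joined |>
    dplyr::group_by(.data$source_id, .data$rank) |>
    dplyr::summarise(n = dplyr::n(),
                     n_agree = sum(.data$binary == "agree"),
                     pct_agree = 100 * .data$n_agree / .data$n,
                     .groups = "drop")
}

#' Split a response log into annotation sessions
#'
#' A session is a maximal run of consecutive validations with no long break:
#' sorting the log by `answered_at`, a new session starts whenever the gap
#' from the previous item's answer to the next item's display *exceeds*
#' `gap_threshold` (a gap of exactly the threshold stays in-session).
#' Duration runs from the session's first `shown_at` to its last
#' `answered_at`, which for a single-item session is simply that item's
#' display-to-answer time.
#'
#' @param log A [response_log()] with finite timestamps.
#' @param gap_threshold Break length in seconds that starts a new session;
#'   default 3600 (one hour).
#' @param scheme The [label_scheme()], for the per-session agreement rate.
#' @return A tibble: `session`, `start`, `end`, `n_items`,
#'   `duration_hours`, `items_per_hour`, `pct_agree`.
#' @export
detect_sessions <- function(log, gap_threshold = 3600,
                            scheme = log_scheme(log)) {
  if (!nrow(log)) abort("Empty response log.")
  if (anyNA(log$shown_at) || anyNA(log$answered_at)) {
    abort("Non-finite timestamps in the log.")
  }
  tbl <- dplyr::arrange(tibble::as_tibble(log), .data$answered_at)
  gap <- as.numeric(tbl$shown_at[-1L]) - as.numeric(tbl$answered_at[-nrow(tbl)])
  tbl$session <- cumsum(c(1L, as.integer(gap > gap_threshold)))
  tbl$binary <- collapse_binary(tbl$label, scheme)
  tbl |>
    dplyr::group_by(.data$session) |>
    dplyr::summarise(
      start = min(.data$shown_at), end = max(.data$answered_at),
      n_items = dplyr::n(),
      duration_hours = as.numeric(difftime(max(.data$answered_at),
                                           min(.data$shown_at),
                                           units = "hours")),
      pct_agree = 100 * mean(.data$binary == "agree"),
      .groups = "drop") |>
    dplyr::mutate(items_per_hour = .data$n_items / .data$duration_hours) |>
    dplyr::select(dplyr::all_of(c("session", "start", "end", "n_items",
                                  "duration_hours", "items_per_hour",
                                  "pct_agree")))
}

#' Run the full reliability analysis
#'
#' Convenience wrapper joining a complete response log with its unsealed
#' provenance and (optionally) the mask catalog, and computing every table
#' this package reports: agreement breakdown, repeat confusion matrices and
#' rater metrics (pooled and per source), concordance-stratified DSC,
#' order-of-appearance effects, and session statistics.
#'
#' @param log A [response_log()].
#' @param plan,provenance The two halves from [build_schedule()].
#' @param dsc Optional pairwise DSC table from [pairwise_dsc()]; when
#'   `NULL` the stratified-DSC table is skipped.
#' @param scheme The [label_scheme()].
#' @param conf_level Confidence level for all intervals.
#' @param gap_threshold Session break threshold in seconds.
#' @return A named list of results (class `blindval_analysis`).
#' @export
analyze_study <- function(log, plan, provenance, dsc = NULL,
                          scheme = log_scheme(log), conf_level = 0.95,
                          gap_threshold = 3600) {
  conf <- confusion_from_repeats(log, provenance, scheme)
  per_source_metrics <- purrr::imap_dfr(conf$per_source, function(cm, src) {
    dplyr::bind_cols(tibble::tibble(source_id = src),
                     glance(rater_metrics(cm$binary, conf_level)))
  })
  res <- list(
    agreement = agreement_by_source(log, provenance, scheme),
    confusion = conf,
    metrics = rater_metrics(conf$binary, conf_level),
    metrics_by_source = per_source_metrics,
    order_effect = order_effect(log, plan, provenance, scheme),
    sessions = detect_sessions(log, gap_threshold, scheme),
    stratified = if (!is.null(dsc)) {
      stratified_dsc(log, provenance, dsc, scheme, conf_level)
    },
    dsc = dsc
  )
  structure(res, class = "blindval_analysis")
}

#' Write the analysis report bundle
#'
#' Emits one CSV per analysis table with fixed headers, so the report can be
#' consumed by any downstream tool. Regenerating from the same inputs gives
#' byte-identical files.
#'
#' @param analysis A `blindval_analysis` from [analyze_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
build_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "blindval_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(tbl, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tbl, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  emit(analysis$agreement, "agreement_by_source")
  emit(tidy(analysis$confusion), "confusion_multi")
  bin <- analysis$confusion$binary
  emit(tibble::tibble(first = rep(rownames(bin), times = 2),
                      second = rep(colnames(bin), each = 2),
                      n = as.vector(bin)),
       "confusion_binary")
  emit(dplyr::bind_cols(tibble::tibble(source_id = "all"),
                        glance(analysis$metrics)) |>
         dplyr::bind_rows(analysis$metrics_by_source),
       "rater_metrics")
  emit(analysis$order_effect, "order_effect")
  emit(analysis$sessions, "sessions")
  if (!is.null(analysis$stratified)) emit(analysis$stratified,
                                          "stratified_dsc")
  if (!is.null(analysis$dsc)) emit(analysis$dsc, "dsc_pairwise")
  invisible(paths)
}
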