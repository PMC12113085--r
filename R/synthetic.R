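#' Synthetic study cohort configuration
#'
#' Parameters of the synthetic cohort generator, which emulates the
#' structure of a blinded validation study — N images each annotated by S
#' sources, with controllable pairwise mask overlap and per-source covert
#' duplicates — without any real images. The defaults reproduce the study
#' scale this package was designed around: 500 images, three sources (two
#' human-style labelers and one model), 100 duplicates per source, i.e.
#' 1800 presentations.
#'
#' `perturbation` is the per-source boundary jitter amplitude in pixels:
#' each source's mask is the shared base region deformed by an independent
#' smooth radial perturbation of that amplitude, so expected pairwise DSC
#' decreases monotonically as the amplitude grows.
#'
#' @param n_images Number of images.
#' @param width,height Mask raster size in pixels.
#' @param source_ids Annotation source identifiers.
#' @param perturbation Named numeric vector of boundary jitter amplitudes
#'   (pixels), one per source.
#' @param duplicates Named integer vector of covert duplicate counts per
#'   source.
#' @param seed Master seed; per-image and per-source streams are derived
#'   from it, so extending `n_images` never reshuffles earlier images.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_images = 500L, width = 64L, height = 64L,
                          source_ids = c("L1", "L2", "model"),
                          perturbation = c(L1 = 2, L2 = 2, model = 3),
                          duplicates = c(L1 = 100L, L2 = 100L,
                                         model = 100L),
                          seed = 1L) {
  if (n_images < 1L) abort("`n_images` must be at least 1.")
  if (any(perturbation < 0)) abort("`perturbation` must be nonnegative.")
  if (!all(source_ids %in% names(perturbation))) {
    abort("`perturbation` must name every source.")
  }
  if (width < 8L || height < 8L) {
    abort("Masks smaller than 8 x 8 px are degenerate.")
  }
  structure(list(n_images = as.integer(n_images), width = as.integer(width),
                 height = as.integer(height), source_ids = source_ids,
                 perturbation = perturbation, duplicates = duplicates,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate the synthetic mask catalog
#'
#' Per image, draws a base smooth convex-ish region (an ellipse whose
#' boundary radius is modulated by low-order harmonics); per source, deforms
#' that base with an independent smooth radial jitter of the configured
#' amplitude. Fully reproducible from the master seed. Optionally writes the
#' masks as single-channel PNGs plus a `manifest.csv`, in exactly the
#' formats real studies use.
#'
#' @param config A [cohort_config()].
#' @param dir Optional directory to write PNG masks and a manifest into.
#' @return An [annotation_catalog()] with a `mask` list-column (and
#'   `mask_path` when `dir` is given).
#' @export
gen_masks <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  w <- config$width; h <- config$height
  images <- sprintf("img%04d", seq_len(config$n_images))
  px <- expand.grid(x = seq_len(w) - 0.5, y = seq_len(h) - 0.5)

  grid <- tidyr::expand_grid(image_id = images,
                             source_id = config$source_ids)
  grid$mask <- purrr::pmap(grid, function(image_id, source_id) {
    base <- withr::with_seed(
      child_seed(config$seed, paste0("base/", image_id)),
      random_region_params(w, h))
    jit <- withr::with_seed(
      child_seed(config$seed, paste0("mask/", image_id, "/", source_id)),
      random_harmonics())
    amp <- config$perturbation[[source_id]]
    m <- region_mask(px, w, h, base, jit, amp)
    if (!any(m)) abort("Degenerate region (zero area); adjust the config.")
    binary_mask(m, image_id, source_id)
  })

  if (!is.null(dir)) {
    dir.create(file.path(dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    grid$mask_path <- purrr::map_chr(grid$mask, function(m) {
      p <- file.path(dir, "masks",
                     sprintf("%s_%s.png", m$image_id, m$source_id))
      write_mask(m, p)
      p
    })
    readr::write_csv(grid[c("image_id", "source_id", "mask_path")],
                     file.path(dir, "manifest.csv"), progress = FALSE)
  }
  annotation_catalog(grid)
}

# base region: ellipse centre/axes plus a gentle shape modulation
random_region_params <- function(w, h) {
  list(cx = w / 2 + runif(1, -w / 12, w / 12),
       cy = h / 2 + runif(1, -h / 12, h / 12),
       a = runif(1, w / 5, w / 3.2),
       b = runif(1, h / 5, h / 3.2),
       shape = random_harmonics())
}

# smooth periodic boundary perturbation: 3 random harmonics, unit amplitude
random_harmonics <- function() {
  list(amp = runif(3, 0.3, 1), phase = runif(3, 0, 2 * pi))
}

eval_harmonics <- function(hh, theta) {
  s <- hh$amp[1] * cos(theta + hh$phase[1]) +
    hh$amp[2] * cos(2 * theta + hh$phase[2]) +
    hh$amp[3] * cos(3 * theta + hh$phase[3])
  s / sqrt(sum(hh$amp^2))
}

region_mask <- function(px, w, h, base, jitter, amp) {
  dx <- px$x - base$cx; dy <- px$y - base$cy
  theta <- atan2(dy, dx)
  r_ell <- base$a * base$b /
    sqrt((base$b * cos(theta))^2 + (base$a * sin(theta))^2)
  r_bound <- r_ell * (1 + 0.08 * eval_harmonics(base$shape, theta)) +
    amp * eval_harmonics(jitter, theta)
  inside <- sqrt(dx^2 + dy^2) <= pmax(r_bound, 0)
  matrix(inside, nrow = h, ncol = w, byrow = TRUE)
}

#' Stochastic validator behavior
#'
#' The generative model of a blinded validator, covering the three
#' phenomena the reliability analysis measures. For a replicate-1
#' presentation of a source at order-of-appearance rank r, the latent
#' binary judgment is "agree" with probability
#' `base_agree[source] + rank_offsets[r]` (clipped to `[0, 1]`); a
#' disagreeing judgment is assigned one of the disagree categories by
#' `disagree_split`. Each *evaluation* of a duplicated item — both showings
#' — independently flips the latent binary judgment with probability
#' `flip_prob`, so the expected intra-observer discordance is
#' `2 * eps * (1 - eps)`. Timestamps follow `session_plan`.
#'
#' Defaults mirror the study conditions this package was designed around:
#' per-source agreement around 83–85%, a flip probability of 0.045
#' (expected discordance about 8.6%), no order bias, and 28 work sessions.
#'
#' @param base_agree Named probability per source.
#' @param disagree_split Named probabilities over the disagree categories,
#'   summing to 1.
#' @param flip_prob Per-evaluation binary flip probability for duplicated
#'   items.
#' @param rank_offsets Additive agree-probability offset per
#'   order-of-appearance rank (recycled/truncated to the number of
#'   sources).
#' @param session_plan Optional list with `sizes` (items per session,
#'   summing to the schedule length) and `gap_seconds` (between-session
#'   breaks, length `length(sizes) - 1`). `NULL` picks a 28-session plan
#'   with two-hour breaks.
#' @param item_seconds Mean seconds spent per item.
#' @param seed Seed for the response stream.
#' @return A `validator_behavior` object.
#' @export
validator_behavior <- function(base_agree = c(L1 = 0.850, L2 = 0.828,
                                              model = 0.832),
                               disagree_split = c(oversegmented = 0.5,
                                                  undersegmented = 0.35,
                                                  incorrect = 0.15),
                               flip_prob = 0.045,
                               rank_offsets = c(0, 0, 0),
                               session_plan = NULL,
                               item_seconds = 40,
                               seed = 1L) {
  if (any(base_agree < 0 | base_agree > 1)) {
    abort("`base_agree` must be probabilities.")
  }
  if (flip_prob < 0 || flip_prob > 1) {
    abort("`flip_prob` must be a probability.")
  }
  if (abs(sum(disagree_split) - 1) > 1e-8) {
    abort("`disagree_split` must sum to 1.")
  }
  structure(list(base_agree = base_agree, disagree_split = disagree_split,
                 flip_prob = flip_prob, rank_offsets = rank_offsets,
                 session_plan = session_plan,
                 item_seconds = item_seconds, seed = as.integer(seed)),
            class = "validator_behavior")
}

default_session_plan <- function(n, n_sessions = 28L, gap_seconds = 7200) {
  n_sessions <- min(n_sessions, n)
  sizes <- rep(n %/% n_sessions, n_sessions)
  extra <- n %% n_sessions
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  list(sizes = sizes, gap_seconds = rep(gap_seconds, n_sessions - 1L))
}

#' Simulate a blinded validator over a schedule
#'
#' Walks the schedule in presentation order and draws one
#' [ValidationResponse][response_log()] per item from the behavior model,
#' producing a complete response log in exactly the format a real review
#' session yields. Driven entirely by `behavior$seed`.
#'
#' @param plan,provenance The two halves from [build_schedule()].
#' @param behavior A [validator_behavior()].
#' @param scheme The [label_scheme()]; its disagree categories must cover
#'   `names(behavior$disagree_split)`.
#' @param start_time Timestamp of the first presentation (UTC).
#' @return A complete `response_log`.
#' @export
simulate_validator <- function(plan, provenance, behavior,
                               scheme = label_scheme(),
                               start_time = as.POSIXct("2024-01-08 09:00:00",
                                                       tz = "UTC")) {
  stopifnot(inherits(behavior, "validator_behavior"))
  disagree_cats <- names(behavior$disagree_split)
  if (!all(disagree_cats %in% setdiff(scheme$categories, scheme$agree))) {
    abort("`disagree_split` names must be disagree categories of the scheme.")
  }
  items <- dplyr::inner_join(plan, provenance, by = "presentation_id") |>
    dplyr::arrange(.data$position)
  n <- nrow(items)
  ranks <- order_ranks(plan, provenance)
  items <- dplyr::left_join(
    items, ranks[c("image_id", "source_id", "rank")],
    by = c("image_id", "source_id"))

  sp <- behavior$session_plan %||% default_session_plan(n)
  if (sum(sp$sizes) != n) {
    abort("`session_plan$sizes` must sum to the schedule length.")
  }
  if (length(sp$gap_seconds) != length(sp$sizes) - 1L) {
    abort("Need one gap per adjacent session pair.")
  }
  session_of <- rep(seq_along(sp$sizes), sp$sizes)

  withr::with_seed(behavior$seed, {
    # latent binary judgment per (image, source), drawn at that pair's rank
    key <- paste(items$image_id, items$source_id, sep = "\r")
    first_idx <- !duplicated(key)
    off <- behavior$rank_offsets
    p_agree <- behavior$base_agree[items$source_id] +
      ifelse(items$rank <= length(off), off[pmax(items$rank, 1L)], 0)
    clipped <- pmin(pmax(p_agree, 0), 1)
    if (any(p_agree != clipped)) {
      warn("Agree probabilities clipped to [0, 1] after rank offsets.")
    }
    latent_first <- runif(n) < clipped
    latent <- stats::setNames(latent_first[first_idx], key[first_idx])[key]
    # latent disagree category is a property of the item, not the showing
    cat_first <- sample(disagree_cats, n, replace = TRUE,
                        prob = behavior$disagree_split)
    latent_cat <- stats::setNames(cat_first[first_idx], key[first_idx])[key]
    # per-evaluation flip for duplicated items only
    dup_key <- key %in% key[items$replicate == 2L]
    flip <- dup_key & (runif(n) < behavior$flip_prob)
    agree <- xor(latent, flip)
    fresh_cat <- sample(disagree_cats, n, replace = TRUE,
                        prob = behavior$disagree_split)
    label <- ifelse(agree, scheme$agree[[1L]],
                    ifelse(flip, fresh_cat, latent_cat))
    # timing: gamma-distributed per-item work, session gaps on top
    work <- pmax(rgamma(n, shape = 4, rate = 4 / behavior$item_seconds), 2)
    think_gap <- runif(n, 1, 5)
  })

  shown <- numeric(n); answered <- numeric(n)
  cursor <- as.numeric(start_time)
  for (i in seq_len(n)) {
    if (i > 1L && session_of[i] != session_of[i - 1L]) {
      cursor <- cursor + sp$gap_seconds[session_of[i] - 1L]
    }
    shown[i] <- cursor
    answered[i] <- cursor + work[i]
    cursor <- answered[i] + think_gap[i]
  }

  log <- tibble::tibble(
    presentation_id = items$presentation_id,
    label = label,
    comment = "",
    shown_at = as.POSIXct(shown, origin = "1970-01-01", tz = "UTC"),
    answered_at = as.POSIXct(answered, origin = "1970-01-01", tz = "UTC")
  )
  attr(log, "scheme") <- scheme
  class(log) <- c("response_log", class(log))
  log
}
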