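# Small fixtures built in code.

# a mask from explicit foreground coordinates on a w x h canvas
mask_from_coords <- function(coords, w = 8, h = 8, image_id = "img",
                             source_id = "src") {
  m <- matrix(FALSE, h, w)
  for (xy in coords) m[xy[2], xy[1]] <- TRUE
  binary_mask(m, image_id, source_id)
}

random_mask <- function(w = 16, h = 16, p = 0.3, image_id = "img",
                        source_id = "src") {
  binary_mask(matrix(runif(w * h) < p, h, w), image_id, source_id)
}

# a tiny 2-image x 2-source catalog without masks (grid only)
tiny_grid <- function(n_images = 2, sources = c("L1", "L2")) {
  annotation_catalog(tidyr::expand_grid(
    image_id = sprintf("i%02d", seq_len(n_images)),
    source_id = sources))
}

# a complete log answering `label_fn(image_id, source_id, replicate)` for
# every presentation, with evenly spaced timestamps
scripted_log <- function(plan, provenance, label_fn,
                         scheme = label_scheme(), item_seconds = 30) {
  joined <- dplyr::inner_join(plan, provenance, by = "presentation_id")
  joined <- joined[order(joined$position), ]
  t0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
  log <- response_log(scheme)
  for (i in seq_len(nrow(joined))) {
    shown <- t0 + (i - 1) * item_seconds
    log <- append_response(
      log, joined$presentation_id[i],
      label_fn(joined$image_id[i], joined$source_id[i],
               joined$replicate[i]),
      shown_at = shown, answered_at = shown + item_seconds - 5)
  }
  log
}
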