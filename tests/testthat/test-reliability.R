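test_that("wilson_ci matches the score-test inversion from stats", {
  withr::with_seed(11, {
    for (i in 1:25) {
      n <- sample(5:500, 1)
      x <- sample(0:n, 1)
      ours <- wilson_ci(x, n)
      ref <- stats::prop.test(x, n, correct = FALSE)$conf.int
      expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
    }
  })
  expect_equal(wilson_ci(0, 50)[["low"]], 0)
  expect_error(wilson_ci(3, 0))
  expect_error(wilson_ci(5, 3))
})

test_that("wilson_ci has near-nominal coverage (Monte-Carlo)", {
  withr::with_seed(21, {
    p <- 0.85; n <- 120; reps <- 2000
    x <- rbinom(reps, n, p)
    covered <- vapply(x, function(xi) {
      ci <- wilson_ci(xi, n)
      p >= ci[["low"]] && p <= ci[["high"]]
    }, logical(1))
    expect_gte(mean(covered), 0.93)
    expect_lte(mean(covered), 0.97)
  })
})

test_that("cohens_kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(13, {
    for (i in 1:20) {
      k <- sample(2:4, 1)
      m <- matrix(rpois(k * k, 12), k, k)
      expect_equal(cohens_kappa(m),
                   e1071::classAgreement(m)$kappa, tolerance = 1e-10)
    }
  })
  # chance-level agreement: rows proportional to column marginals
  m0 <- outer(c(30, 70), c(0.4, 0.6))
  expect_equal(cohens_kappa(m0), 0, tolerance = 1e-12)
  expect_warning(expect_true(is.na(cohens_kappa(matrix(c(10, 0, 0, 0),
                                                       2, 2)))),
                 "undefined")
})

test_that("rater_metrics reproduces both published metric rows", {
  lv <- list(c("agree", "disagree"), c("agree", "disagree"))
  m1 <- matrix(c(245, 11, 12, 32), 2, 2, dimnames = lv)
  g1 <- glance(rater_metrics(m1))
  expect_equal(round(g1$accuracy, 3), 0.923)
  expect_equal(round(g1$acc_ci_low, 3), 0.888)
  expect_equal(round(g1$acc_ci_high, 3), 0.948)
  expect_equal(round(g1$kappa, 3), 0.691)
  expect_equal(round(g1$balanced_accuracy, 3), 0.849)
  expect_equal(round(g1$f1, 3), 0.955)
  expect_equal(round(g1$precision, 3), 0.957)
  expect_equal(round(g1$recall, 3), 0.953)

  m2 <- matrix(c(249, 22, 4, 25), 2, 2, dimnames = lv)
  g2 <- glance(rater_metrics(m2))
  expect_equal(round(g2$accuracy, 3), 0.913)
  expect_equal(round(g2$kappa, 3), 0.611)
  expect_equal(round(g2$balanced_accuracy, 3), 0.758)
  expect_equal(round(g2$f1, 3), 0.950)
  expect_equal(round(g2$precision, 3), 0.919)
  expect_equal(round(g2$recall, 3), 0.984)
})

test_that("rater_metrics degenerate cases behave", {
  diag2 <- matrix(c(40, 0, 0, 10), 2, 2)
  g <- glance(rater_metrics(diag2))
  expect_equal(g$accuracy, 1); expect_equal(g$kappa, 1)
  td <- tidy(rater_metrics(diag2))
  expect_equal(nrow(td), 6)
  expect_true(all(td$estimate >= -1 & td$estimate <= 1))
})

test_that("agreement_by_source matches hand-counted tallies", {
  cat <- tiny_grid(4, c("L1", "L2", "model"))
  sch <- build_schedule(cat, c(L1 = 1), seed = 14)
  # crafted labels: L1 always correct; L2 alternates; model never agrees
  lab <- function(i, s, r) {
    if (s == "L1") "correct"
    else if (s == "model") "oversegmented"
    else if (i %in% c("i01", "i02")) "correct" else "undersegmented"
  }
  log <- scripted_log(sch$plan, sch$provenance, lab)
  br <- agreement_by_source(log, sch$provenance)
  br <- br[order(br$source_id), ]
  expect_equal(br$n, c(4, 4, 4)) # denominators = image count, dups excluded
  expect_equal(br$pct_agree, c(100, 50, 0))
  expect_equal(br$correct, c(4L, 2L, 0L))
  expect_equal(br$oversegmented, c(0L, 0L, 4L))
  # dropping a replicate-1 response is rejected with the missing ids
  rep1_ids <- sch$provenance$presentation_id[sch$provenance$replicate == 1]
  expect_error(
    agreement_by_source(log[log$presentation_id != rep1_ids[1], ],
                        sch$provenance),
    class = "blindval_incomplete_log")
})

test_that("confusion_from_repeats matches an enumerated hand count", {
  cat <- tiny_grid(6, c("L1", "L2"))
  sch <- build_schedule(cat, c(L1 = 3, L2 = 3), seed = 15)
  # first evaluation: correct everywhere; second: flip on chosen pairs
  dup <- sch$provenance[sch$provenance$replicate == 2, ]
  flip_keys <- paste(dup$image_id, dup$source_id)[1:2]
  lab <- function(i, s, r) {
    if (r == 2 && paste(i, s) %in% flip_keys) "incorrect" else "correct"
  }
  log <- scripted_log(sch$plan, sch$provenance, lab)
  conf <- confusion_from_repeats(log, sch$provenance)
  expect_equal(conf$n, 6)
  expect_equal(unname(conf$binary),
               matrix(c(4, 0, 2, 0), 2, 2))
  expect_equal(conf$multi["correct", "incorrect"], 2)
  expect_equal(sum(conf$multi), 6)
  # per-source matrices partition the pooled one
  per_sum <- Reduce(`+`, lapply(conf$per_source, function(x) x$binary))
  expect_equal(per_sum, conf$binary)
  # discordance rate = binary off-diagonal / n
  expect_equal(sum(conf$binary) - sum(diag(conf$binary)), 2)
  # unpaired duplicate is rejected
  dup_id <- dup$presentation_id[1]
  expect_error(confusion_from_repeats(log[log$presentation_id != dup_id, ],
                                      sch$provenance),
               class = "blindval_unpaired_duplicate")
})

test_that("stratified_dsc splits by label concordance and partitions", {
  cat <- tiny_grid(10, c("L1", "L2"))
  sch <- build_schedule(cat, seed = 16)
  # images i01..i04: same binary label for both sources; rest differ
  lab <- function(i, s, r) {
    same <- i %in% sprintf("i%02d", 1:4)
    if (same) "correct"
    else if (s == "L1") "correct" else "oversegmented"
  }
  log <- scripted_log(sch$plan, sch$provenance, lab)
  withr::with_seed(17, {
    dsc <- tibble::tibble(image_id = sprintf("i%02d", 1:10),
                          source_a = "L1", source_b = "L2",
                          dsc = runif(10))
  })
  out <- stratified_dsc(log, sch$provenance, dsc)
  expect_equal(sum(out$n), 10) # strata partition the images
  same <- out[out$same_label, ]; diff <- out[!out$same_label, ]
  expect_equal(same$n, 4)
  expect_equal(same$mean, mean(dsc$dsc[1:4]))
  expect_equal(diff$mean, mean(dsc$dsc[5:10]))
  expect_equal(unname(round(c(same$ci_low, same$ci_high), 10)),
               unname(round(mean_ci_t(mean(dsc$dsc[1:4]),
                                      sd(dsc$dsc[1:4]), 4), 10)))
})

test_that("a single-image stratum is flagged and loses its interval", {
  cat <- tiny_grid(3, c("L1", "L2"))
  sch <- build_schedule(cat, seed = 18)
  lab <- function(i, s, r) {
    if (i == "i01" && s == "L2") "oversegmented" else "correct"
  }
  log <- scripted_log(sch$plan, sch$provenance, lab)
  dsc <- tibble::tibble(image_id = sprintf("i%02d", 1:3),
                        source_a = "L1", source_b = "L2",
                        dsc = c(0.5, 0.8, 0.9))
  expect_warning(out <- stratified_dsc(log, sch$provenance, dsc),
                 "fewer than 2")
  expect_true(is.na(out$ci_low[out$n == 1]))
})

test_that("order_effect recovers rank-dependent agreement probabilities", {
  cat <- tiny_grid(3000, c("L1", "L2", "model"))
  sch <- build_schedule(cat, seed = 19)
  beh <- validator_behavior(
    base_agree = c(L1 = 0.8, L2 = 0.8, model = 0.8),
    rank_offsets = c(-0.1, 0, 0.1), flip_prob = 0, seed = 20)
  log <- simulate_validator(sch$plan, sch$provenance, beh)
  oe <- order_effect(log, sch$plan, sch$provenance)
  # per-source ranks partition the images
  tot <- tapply(oe$n, oe$source_id, sum)
  expect_true(all(tot == 3000))
  # cell estimates sit within 3 points of the generating probabilities
  expected <- c(70, 80, 90)[oe$rank]
  expect_true(all(abs(oe$pct_agree - expected) < 3))
  expect_true(all(oe$pct_agree >= 0 & oe$pct_agree <= 100))
})

test_that("order_effect is flat at 100% for an always-agree validator", {
  cat <- tiny_grid(20, c("L1", "L2"))
  sch <- build_schedule(cat, c(L1 = 5), seed = 22)
  log <- scripted_log(sch$plan, sch$provenance, function(i, s, r) "correct")
  oe <- order_effect(log, sch$plan, sch$provenance)
  expect_true(all(oe$pct_agree == 100))
})

test_that("detect_sessions applies the strictly-greater one-hour rule", {
  log <- response_log()
  t0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
  # answered at minutes 0+50s, 10, 130; shown just before each answer
  shown <- t0 + c(0, 600, 7800) - 50
  ans <- t0 + c(0, 600, 7800)
  for (i in 1:3) {
    log <- append_response(log, paste0("p", i), "correct",
                           shown_at = shown[i], answered_at = ans[i])
  }
  s <- detect_sessions(log)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_items, c(2, 1))
  # gap of exactly 3600 s stays in the same session
  log2 <- response_log()
  log2 <- append_response(log2, "a", "correct", shown_at = t0,
                          answered_at = t0 + 60)
  log2 <- append_response(log2, "b", "correct",
                          shown_at = t0 + 60 + 3600,
                          answered_at = t0 + 60 + 3660)
  expect_equal(nrow(detect_sessions(log2)), 1)
  # one second beyond the threshold splits
  log3 <- response_log()
  log3 <- append_response(log3, "a", "correct", shown_at = t0,
                          answered_at = t0 + 60)
  log3 <- append_response(log3, "b", "correct",
                          shown_at = t0 + 60 + 3601,
                          answered_at = t0 + 60 + 3661)
  expect_equal(nrow(detect_sessions(log3)), 2)
})

test_that("single-item session duration runs from display to answer", {
  log <- response_log()
  t0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
  log <- append_response(log, "only", "correct", shown_at = t0,
                         answered_at = t0 + 66)
  s <- detect_sessions(log)
  expect_equal(s$duration_hours, 66 / 3600)
  expect_equal(s$items_per_hour, 3600 / 66)
})

test_that("every response lands in exactly one ordered session", {
  cat <- tiny_grid(60, c("L1", "L2"))
  sch <- build_schedule(cat, c(L1 = 10), seed = 23)
  beh <- validator_behavior(
    base_agree = c(L1 = 0.9, L2 = 0.9), rank_offsets = c(0, 0),
    session_plan = list(sizes = c(50, 40, 40),
                        gap_seconds = c(7200, 5400)),
    seed = 24)
  log <- simulate_validator(sch$plan, sch$provenance, beh)
  s <- detect_sessions(log)
  expect_equal(nrow(s), 3)
  expect_equal(sum(s$n_items), nrow(log))
  expect_true(all(s$end[-nrow(s)] < s$start[-1])) # non-overlapping, ordered
})

test_that("the report bundle is complete, schema-stable, and deterministic", {
  cfg <- cohort_config(n_images = 12, width = 24, height = 24,
                       duplicates = c(L1 = 4, L2 = 4, model = 4), seed = 25)
  catalog <- gen_masks(cfg)
  sch <- build_schedule(catalog, cfg$duplicates, seed = 26)
  log <- simulate_validator(sch$plan, sch$provenance,
                            validator_behavior(seed = 27))
  an <- suppressWarnings(
    analyze_study(log, sch$plan, sch$provenance, pairwise_dsc(catalog)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- build_report(an, d1); p2 <- build_report(an, d2)
  expect_setequal(basename(p1),
                  c("agreement_by_source.csv", "confusion_multi.csv",
                    "confusion_binary.csv", "rater_metrics.csv",
                    "order_effect.csv", "sessions.csv",
                    "stratified_dsc.csv", "dsc_pairwise.csv"))
  for (f in basename(p1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # row counts match the analysis outputs
  expect_equal(nrow(readr::read_csv(file.path(d1, "order_effect.csv"),
                                    show_col_types = FALSE)),
               nrow(an$order_effect))
})
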