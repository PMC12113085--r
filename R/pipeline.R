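#' Study run configuration
#'
#' One configuration object wires the whole pipeline: design ->
#' (review | simulate) -> analyze -> report. It can be built in code or read
#' from a YAML file; explicit arguments override file keys.
#'
#' @param paths Named list of file paths: `manifest`, `plan`, `provenance`,
#'   `responses`, `report_dir`.
#' @param scheme A [label_scheme()] or a list with `categories` and
#'   `agree`.
#' @param duplicates Named duplicate counts per source.
#' @param seed Design seed.
#' @param validator_seed Seed for the simulated validator.
#' @param gap_seconds Session break threshold.
#' @param conf_level Confidence level in `(0, 1)`.
#' @param cohort Optional [cohort_config()] (or list of its arguments) for
#'   the simulate stage.
#' @return A `run_config` object.
#' @export
run_config <- function(paths, scheme = label_scheme(),
                       duplicates = integer(), seed = 1L,
                       validator_seed = 2L, gap_seconds = 3600,
                       conf_level = 0.95, cohort = NULL) {
  if (conf_level <= 0 || conf_level >= 1) {
    abort("`conf_level` must be in (0, 1).")
  }
  if (!inherits(scheme, "label_scheme")) {
    scheme <- label_scheme(scheme$categories, scheme$agree)
  }
  if (!is.null(cohort) && !inherits(cohort, "cohort_config")) {
    cohort <- do.call(cohort_config, cohort)
  }
  structure(list(paths = paths, scheme = scheme,
                 duplicates = duplicates, seed = as.integer(seed),
                 validator_seed = as.integer(validator_seed),
                 gap_seconds = gap_seconds, conf_level = conf_level,
                 cohort = cohort),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    paths = y$paths,
    scheme = if (is.null(y$scheme)) label_scheme() else y$scheme,
    duplicates = unlist(y$duplicates) %||% integer(),
    seed = y$seed %||% 1L,
    validator_seed = y$validator_seed %||% 2L,
    gap_seconds = y$gap_seconds %||% 3600,
    conf_level = y$conf_level %||% 0.95,
    cohort = y$cohort
  )
}

config_hash <- function(config) rlang::hash(unclass(config))

write_run_metadata <- function(config, stage, dir) {
  meta <- list(
    tool = "blindval",
    version = as.character(utils::packageVersion("blindval")),
    stage = stage,
    config_hash = config_hash(config),
    seed = config$seed,
    validator_seed = config$validator_seed,
    written_files = TRUE
  )
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(meta, file.path(dir, paste0("run-", stage, ".json")),
                       auto_unbox = TRUE)
}

#' Run one pipeline stage
#'
#' Stages: `"design"` builds the blinded schedule from the manifest and
#' writes the plan and the sealed provenance; `"simulate"` generates a full
#' synthetic bundle (masks + manifest + schedule + responses); `"review"`
#' runs the review loop over the blinded bundle (it *refuses* any attempt to
#' hand it the provenance file — the blinding guard); `"analyze"` joins the
#' responses with the unsealed provenance and writes the report tables
#' (`"report"` is an alias). Each stage writes a run-metadata JSON with the
#' tool version, config hash and seeds; identical inputs give identical
#' artifacts.
#'
#' @param stage One of `"design"`, `"simulate"`, `"review"`, `"analyze"`,
#'   `"report"`.
#' @param config A [run_config()].
#' @param driver Review driver (see [review_loop()]); required for the
#'   review stage.
#' @return A list with `status` (0 on success) and `artifacts` (paths).
#'   Validation failures signal classed errors.
#' @export
run_stage <- function(stage, config, driver = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- match.arg(stage, c("design", "simulate", "review", "analyze",
                              "report"))
  p <- config$paths
  need <- function(key) {
    if (is.null(p[[key]]) || !file.exists(p[[key]])) {
      abort(sprintf("Stage '%s' needs an existing `%s` path.", stage, key),
            class = "blindval_missing_prerequisite")
    }
    p[[key]]
  }

  if (stage == "design") {
    with_masks <- !is.null(p$bundle)
    catalog <- load_catalog(need("manifest"), read_masks = with_masks)
    sch <- build_schedule(catalog, config$duplicates, config$seed)
    write_plan(sch$plan, p$plan)
    seal_provenance(sch$provenance, p$provenance)
    artifacts <- c(p$plan, p$provenance)
    if (with_masks) {
      write_review_bundle(sch$plan, sch$provenance, catalog, p$bundle)
      artifacts <- c(artifacts, p$bundle)
    }
    write_run_metadata(config, stage, dirname(p$plan))
    return(list(status = 0L, artifacts = artifacts))
  }

  if (stage == "simulate") {
    if (is.null(config$cohort)) {
      abort("Simulate stage needs a `cohort` configuration.",
            class = "blindval_missing_prerequisite")
    }
    out_dir <- dirname(p$manifest)
    catalog <- gen_masks(config$cohort, dir = out_dir)
    sch <- build_schedule(catalog, config$cohort$duplicates, config$seed)
    write_plan(sch$plan, p$plan)
    seal_provenance(sch$provenance, p$provenance)
    behavior <- validator_behavior(seed = config$validator_seed)
    log <- simulate_validator(sch$plan, sch$provenance, behavior,
                              config$scheme)
    write_responses(log, p$responses)
    write_run_metadata(config, stage, out_dir)
    return(list(status = 0L,
                artifacts = c(p$manifest, p$plan, p$provenance,
                              p$responses)))
  }

  if (stage == "review") {
    # Blinding guard, path level: the review stage reads only the plan and
    # the blinded bundle. A provenance file offered inside the bundle
    # directory is refused outright.
    bundle_dir <- need("bundle")
    if (!is.null(p$provenance) && file.exists(p$provenance)) {
      prov_path <- normalizePath(p$provenance)
      if (dirname(prov_path) == normalizePath(bundle_dir)) {
        abort("Provenance refused at the review stage.",
              class = "blindval_blinding_violation")
      }
    }
    plan <- read_plan(need("plan"))
    bundle <- read_review_bundle(bundle_dir)   # schema audit inside
    if (is.null(driver)) {
      abort("Review stage needs a `driver` function.",
            class = "blindval_missing_prerequisite")
    }
    log <- review_loop(plan, bundle, config$scheme, driver,
                       path = p$responses)
    write_responses(log, p$responses)
    write_run_metadata(config, stage, dirname(p$responses))
    return(list(status = 0L, artifacts = p$responses))
  }

  # analyze / report
  if (is.null(p$provenance) || !file.exists(p$provenance)) {
    abort("Sealed provenance required to analyze.",
          class = "blindval_missing_prerequisite")
  }
  plan <- read_plan(need("plan"))
  prov <- unseal_provenance(p$provenance)
  log <- read_responses(need("responses"), config$scheme)
  dsc <- NULL
  if (!is.null(p$manifest) && file.exists(p$manifest)) {
    dsc <- pairwise_dsc(load_catalog(p$manifest))
  }
  analysis <- analyze_study(log, plan, prov, dsc, config$scheme,
                            config$conf_level, config$gap_seconds)
  paths <- build_report(analysis, p$report_dir)
  write_run_metadata(config, stage, p$report_dir)
  list(status = 0L, artifacts = paths, analysis = analysis)
}
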