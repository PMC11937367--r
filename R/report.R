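.known_config_keys <- c("seed", "output_dir", "simulate", "funnel",
                        "organoids", "histology")

#' Read and validate a run configuration
#'
#' The configuration is a YAML mapping with a master `seed`, an
#' `output_dir`, and optional per-module blocks `simulate`, `funnel`,
#' `organoids`, `histology`. Unknown top-level keys are rejected so that
#' typos never silently disable a stage. Every parameter is echoed
#' verbatim into the run report.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop_input("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "funnelomics_out"
  structure(cfg, class = "run_config")
}

#' Validate declared inputs without running anything
#'
#' Checks file existence and basic schema of every input declared in the
#' configuration. Problems are reported, never thrown, and the data are
#' never mutated.
#'
#' @param config a `run_config` (or path / list accepted by
#'   [read_run_config()]).
#' @return data.frame with columns `level` ("error"/"warning"), `module`,
#'   `message`; zero rows when everything checks out.
#' @export
validate_inputs <- function(config) {
  config <- if (inherits(config, "run_config")) config else read_run_config(config)
  findings <- data.frame(level = character(), module = character(),
                         message = character(), stringsAsFactors = FALSE)
  note <- function(level, module, msg) {
    findings[nrow(findings) + 1L, ] <<- list(level, module, msg)
  }
  need_file <- function(module, label, p) {
    if (is.null(p)) { note("error", module, sprintf("missing input: %s", label)); FALSE }
    else if (!file.exists(p)) { note("error", module, sprintf("%s not found: %s", label, p)); FALSE }
    else TRUE
  }
  fn <- config$funnel
  if (!is.null(fn) && is.null(fn$use_simulated)) {
    if (need_file("funnel", "detections", fn$detections)) {
      tab <- tryCatch(read_detection_table(fn$detections, dialect = fn$dialect),
                      error = function(e) e)
      if (inherits(tab, "error"))
        note("error", "funnel", conditionMessage(tab))
      else if (any(tab$replicate < 1L))
        note("error", "funnel", "replicate indices below 1")
    }
    for (lbl in c("gene_sets", "secretion", "ligand_receptor", "expression"))
      need_file("funnel", lbl, fn[[lbl]])
  }
  og <- config$organoids
  if (!is.null(og) && is.null(og$use_simulated)) {
    if (need_file("organoids", "counts", og$counts)) {
      tb <- tryCatch(read_organoid_experiment(og$counts, og$diameters),
                     error = function(e) e)
      if (inherits(tb, "error")) note("error", "organoids", conditionMessage(tb))
      else if (any(tb$counts$n_seeded <= 0))
        note("error", "organoids", "n_seeded must be positive")
    }
  }
  hs <- config$histology
  if (!is.null(hs) && is.null(hs$use_simulated)) {
    if (!is.null(hs$image)) need_file("histology", "image", hs$image)
    if (!is.null(hs$mask)) need_file("histology", "mask", hs$mask)
    if (is.null(hs$image) && is.null(hs$mask))
      note("error", "histology", "histology block declares neither image nor mask")
    if (!is.null(hs$pixel_size) && hs$pixel_size <= 0)
      note("error", "histology", "pixel_size must be > 0")
  }
  findings
}

#' Run all configured analysis stages
#'
#' Executes the requested stages in dependency order (simulation first,
#' so later stages can consume simulated inputs via `use_simulated: true`),
#' collects per-module results into a run report, and writes the report
#' as JSON into the output directory. Identical config + inputs + seed
#' produce an identical report; all randomness flows from the master seed
#' through fixed per-module substreams.
#'
#' @param config a `run_config`, YAML path, or config list.
#' @return object of class `run_report`: list with `version`, `config`,
#'   `results`, `warnings`.
#' @export
run_all <- function(config) {
  config <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(); warn_log <- character(0)
  log_warn <- function(w) { warn_log <<- c(warn_log, conditionMessage(w)); invokeRestart("muffleWarning") }
  sim <- list()

  if (!is.null(config$simulate)) {
    s <- config$simulate
    if (!is.null(s$secretome)) {
      args <- s$secretome; args$seed <- args$seed %||% config$seed
      sim$secretome <- generate_secretome_fixture(do.call(secretome_fixture_config, args))
      fdir <- file.path(config$output_dir, "fixtures")
      dir.create(fdir, showWarnings = FALSE)
      write_detection_table(sim$secretome$table, file.path(fdir, "detections.tsv"))
      write_annotation_bundle(sim$secretome$bundle, fdir)
      write_fixture_truth(sim$secretome$truth, file.path(fdir, "secretome_truth.json"))
      results$simulate$secretome <- list(
        n_records = nrow(sim$secretome$table),
        expected_candidates = sim$secretome$truth$expected_candidate_set)
    }
    if (!is.null(s$organoid)) {
      args <- s$organoid; args$seed <- args$seed %||% config$seed
      sim$organoid <- generate_organoid_experiment(do.call(organoid_fixture_config, args))
      fdir <- file.path(config$output_dir, "fixtures")
      dir.create(fdir, showWarnings = FALSE)
      write_organoid_experiment(sim$organoid$experiment, fdir)
      results$simulate$organoid <- list(
        n_cultures = nrow(sim$organoid$experiment$counts),
        planted_effect_ratio = sim$organoid$truth$planted_effect_ratio)
    }
  }

  if (!is.null(config$funnel)) {
    fn <- config$funnel
    inputs <- if (isTRUE(fn$use_simulated)) {
      if (is.null(sim$secretome))
        stop_input("funnel.use_simulated requires a simulate.secretome block")
      list(table = sim$secretome$table, bundle = sim$secretome$bundle)
    } else {
      list(table = read_detection_table(fn$detections, dialect = fn$dialect),
           bundle = read_annotation_bundle(fn$gene_sets, fn$secretion,
                                           fn$ligand_receptor, fn$expression))
    }
    fr <- withCallingHandlers(
      run_funnel(inputs$table, inputs$bundle,
                 secretion_mode = fn$secretion_mode %||% "any"),
      warning = log_warn)
    write_funnel_result(fr, file.path(config$output_dir, "funnel"))
    results$funnel <- list(stage_counts = fr$stage_counts, candidates = fr$candidates)
  }

  if (!is.null(config$organoids)) {
    og <- config$organoids
    exp <- if (isTRUE(og$use_simulated)) {
      if (is.null(sim$organoid))
        stop_input("organoids.use_simulated requires a simulate.organoid block")
      sim$organoid$experiment
    } else read_organoid_experiment(og$counts, og$diameters)
    ctl <- og$control %||% "control"; trt <- og$treated %||% "treated"
    ct <- exp$counts
    eff <- withCallingHandlers(
      effect_estimate(ct[ct$condition == trt, ], ct[ct$condition == ctl, ],
                      seed = config$seed),
      warning = log_warn)
    results$organoids <- list(effect = eff[c("estimate", "ci", "n_pairs")])
    dm <- exp$diameters
    if (nrow(dm) && all(c(ctl, trt) %in% dm$condition)) {
      ks <- ks_two_sample(filter_diameters(dm$diameter[dm$condition == trt]),
                          filter_diameters(dm$diameter[dm$condition == ctl]))
      results$organoids$diameter_ks <- ks
    }
  }

  if (!is.null(config$histology)) {
    hs <- config$histology
    if (!is.null(hs$image)) {
      img <- read_stain_image(hs$image, pixel_size = hs$pixel_size %||% 1)
      q <- withCallingHandlers(
        ihc_quantify(img, threshold = hs$threshold %||% "otsu"),
        warning = log_warn)
      results$histology$ihc <- unclass(q)
    }
    if (!is.null(hs$mask)) {
      mk <- read_mask(hs$mask, "airspace")
      lr <- withCallingHandlers(
        lmi(mk, pixel_size = hs$pixel_size %||% 1,
            line_spacing = hs$line_spacing),
        warning = log_warn)
      results$histology$lmi <- lr[c("mean_chord", "n_chords", "n_lines",
                                    "line_spacing", "orientation")]
    }
  }

  report <- structure(list(
    version = as.character(packageVersion("funnelomics")),
    config = unclass(config),
    results = results,
    warnings = warn_log
  ), class = "run_report")
  jsonlite::write_json(unclass(report),
                       file.path(config$output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("funnelomics run report (v%s)\n", x$version))
  cat(sprintf("  stages run: %s\n",
              if (length(x$results)) paste(names(x$results), collapse = ", ") else "none"))
  if (length(x$warnings)) cat(sprintf("  warnings: %d\n", length(x$warnings)))
  invisible(x)
}
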