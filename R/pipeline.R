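## cli_report surface: configuration-driven pipeline runner and renderers
## of the tabular outputs. The exported functions (not an OS executable)
## are the front end; `runPipeline` consumes a YAML/list config and writes
## every artifact with its seed and config hash embedded.

#' Load and validate a run configuration
#'
#' A config is a named list (or a YAML file containing one) with optional
#' blocks: \code{synth} (arguments to \code{\link{synthConfig}}),
#' \code{layers}/\code{labels} (paths to per-layer CSVs and a label CSV,
#' used instead of \code{synth}), \code{grid} (\code{paradigms}, \code{R},
#' \code{baseSeed}, \code{combinations} as "P+M"-style strings),
#' \code{augment} (\code{nPerClass}, \code{smoothing}), \code{learner}
#' (\code{retention}, \code{epsilon}), \code{threshold},
#' \code{fcThresholds} and \code{nPerm}. Missing entries take the study
#' defaults (R = 20, theta = 0.5, 500 virtual subjects per class,
#' retention 0.2, thresholds 1/1.1/1.2/1.3/2/3, 1000 permutations).
#'
#' @param config named list or path to a YAML file.
#' @return validated config list of class \code{"RunConfig"}.
#' @export
runConfig <- function(config = list()) {
  if (is.character(config))
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    synth = list(),
    layers = NULL, labels = NULL,
    grid = list(paradigms = paradigms(), R = 20L, baseSeed = 1L,
                combinations = NULL),
    augment = list(nPerClass = 500L, smoothing = 1.0),
    learner = list(retention = 0.2, epsilon = 1e-8),
    threshold = 0.5,
    fcThresholds = c(1, 1.1, 1.2, 1.3, 2.0, 3.0),
    nPerm = 1000L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]]))
        if (is.null(config[[nm]][[sub]]))
          config[[nm]][[sub]] <- defaults[[nm]][[sub]]
    }
  }
  config$grid$R <- as.integer(config$grid$R)
  config$grid$baseSeed <- as.integer(config$grid$baseSeed)
  config$augment$nPerClass <- as.integer(config$augment$nPerClass)
  config$nPerm <- as.integer(config$nPerm)
  if (!is.null(config$layers) && is.null(config$labels))
    stop("config with 'layers' paths also needs a 'labels' path")
  bad <- setdiff(config$grid$paradigms, paradigms())
  if (length(bad))
    stop("unknown paradigm(s): ", paste(bad, collapse = ", "))
  if (config$threshold <= 0 || config$threshold >= 1)
    stop("threshold must lie in (0, 1)")
  structure(config, class = c("RunConfig", "list"))
}

## Resolve the cohort a config describes (synthetic or from files).
.configCohort <- function(config) {
  if (!is.null(config$layers)) {
    lay_specs <- config$layers
    layerList <- lapply(names(lay_specs), function(id)
      readOmicLayer(lay_specs[[id]], id))
    assembleCohort(layerList, readSampleLabels(config$labels))
  } else {
    generateCohort(do.call(synthConfig, config$synth))$cohort
  }
}

.configHash <- function(config) {
  ser <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE)
  ## tiny polynomial rolling hash; enough to fingerprint a config in
  ## output metadata
  bytes <- utf8ToInt(as.character(ser))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

.writeCsvWithMeta <- function(df, path, config, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", .configHash(config),
                     as.integer(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline end to end and write all artifacts
#'
#' Stages (all optional, on by default): \code{curate} writes the curated
#' layers and curation report; \code{run} executes the experiment grid and
#' writes the accuracy summary table plus the per-instance heatmap matrix;
#' \code{permtest} runs the permutation test per selection-capable paradigm
#' on the full combination and writes the feature-summary table
#' (set size, p-value, per-layer composition); \code{foldchange} writes the
#' retention-curve table and plot. A consolidated \code{report.json}
#' records config, seeds and versions.
#'
#' @param config a \code{\link{runConfig}} (list or YAML path).
#' @param outDir output directory, created if needed.
#' @param stages character subset of
#'   \code{c("curate", "run", "permtest", "foldchange")}.
#' @param seed integer master seed (overrides \code{grid$baseSeed}).
#' @return named list of written file paths, invisibly; the computed
#'   objects are attached as attribute \code{"results"}.
#' @export
runPipeline <- function(config = runConfig(), outDir,
                        stages = c("curate", "run", "permtest", "foldchange"),
                        seed = NULL) {
  config <- runConfig(config)
  if (!is.null(seed))
    config$grid$baseSeed <- as.integer(seed)
  baseSeed <- as.integer(config$grid$baseSeed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  results <- list()

  cohort_raw <- .configCohort(config)
  cur <- curateCohort(cohort_raw)
  cohort <- cur$cohort
  results$curation <- curationSummary(cur$report)

  spec <- learnerSpec(retention = config$learner$retention,
                      epsilon = config$learner$epsilon)
  aug <- augmentConfig(nPerClass = config$augment$nPerClass,
                       smoothing = config$augment$smoothing,
                       seed = baseSeed)
  combos <- if (is.null(config$grid$combinations))
    enumerateCombinations(layerIds(cohort))
  else
    lapply(strsplit(config$grid$combinations, "+", fixed = TRUE), trimws)

  if ("curate" %in% stages) {
    paths$curation <- .writeCsvWithMeta(results$curation,
                                        file.path(outDir, "curation_report.csv"),
                                        config, baseSeed)
    writeCohort(cohort, file.path(outDir, "curated"))
  }

  if ("run" %in% stages) {
    grid <- runExperimentGrid(cohort, combinations = combos,
                              paradigmSet = config$grid$paradigms,
                              spec = spec, augment = aug,
                              R = config$grid$R, baseSeed = baseSeed,
                              threshold = config$threshold)
    results$grid <- grid
    paths$summary <- .writeCsvWithMeta(
      cbind(combination = rownames(summaryTable(grid)), summaryTable(grid)),
      file.path(outDir, "accuracy_summary.csv"), config, baseSeed)
    paths$long <- .writeCsvWithMeta(grid,
                                    file.path(outDir, "accuracy_long.csv"),
                                    config, baseSeed)
    m <- instanceAccuracyMatrix(grid,
                                combinations = unique(grid$combination),
                                paradigmSet = config$grid$paradigms)
    paths$instance <- .writeCsvWithMeta(
      cbind(configuration = rownames(m), as.data.frame(m)),
      file.path(outDir, "instance_accuracy.csv"), config, baseSeed)
  }

  sel_pars <- intersect(config$grid$paradigms,
                        c("LASSO", "RIDGE", "MULTI-VIEW LASSO",
                          "MULTI-VIEW RIDGE"))
  full_combo <- layerIds(cohort)
  if ("permtest" %in% stages && length(sel_pars)) {
    rows <- list()
    results$permtest <- list()
    for (par in sel_pars) {
      if (length(full_combo) < 2L && startsWith(par, "MULTI-VIEW")) next
      pt <- permutationTest(cohort, full_combo, par, spec = spec,
                            augment = aug, nPerm = config$nPerm,
                            seed = mixSeed(baseSeed, match(par, paradigms())),
                            threshold = config$threshold)
      results$permtest[[par]] <- pt
      obs_run <- loocvOnce(cohort, full_combo, par, spec, aug,
                           seed = mixSeed(mixSeed(baseSeed,
                                                  match(par, paradigms())), 0L),
                           threshold = config$threshold)
      cfs <- consistentFeatures(obs_run$selected, par)
      results$consistent[[par]] <- cfs
      comp <- composition(cfs)
      comp_full <- stats::setNames(rep(NA_real_, length(full_combo)),
                                   full_combo)
      comp_full[names(comp)] <- comp
      rows[[par]] <- data.frame(paradigm = par,
                                n_features = length(cfs@features),
                                p_value = pt@pValue,
                                as.list(stats::setNames(signif(comp_full, 3),
                                                        paste0("pct_",
                                                               full_combo))),
                                stringsAsFactors = FALSE)
    }
    paths$features <- .writeCsvWithMeta(do.call(rbind, rows),
                                        file.path(outDir,
                                                  "feature_summary.csv"),
                                        config, baseSeed)
  }

  if ("foldchange" %in% stages && length(sel_pars)) {
    curves <- list()
    for (par in sel_pars) {
      if (length(full_combo) < 2L && startsWith(par, "MULTI-VIEW")) next
      cfs <- results$consistent[[par]]
      if (is.null(cfs)) {
        obs_run <- loocvOnce(cohort, full_combo, par, spec, aug,
                             seed = mixSeed(mixSeed(baseSeed,
                                                    match(par, paradigms())),
                                            0L),
                             threshold = config$threshold)
        cfs <- consistentFeatures(obs_run$selected, par)
        results$consistent[[par]] <- cfs
      }
      if (length(cfs@features) == 0L) next
      prof <- foldChangeProfile(cohort, cfs)
      curves[[par]] <- retentionCurves(prof, config$fcThresholds, par)
    }
    if (length(curves)) {
      all_curves <- do.call(rbind, curves)
      results$curves <- all_curves
      paths$curves <- .writeCsvWithMeta(all_curves,
                                        file.path(outDir,
                                                  "fold_change_retention.csv"),
                                        config, baseSeed)
      grDevices::pdf(file.path(outDir, "fold_change_retention.pdf"),
                     width = 7, height = 5)
      plotRetentionCurves(all_curves)
      grDevices::dev.off()
      paths$curvePlot <- file.path(outDir, "fold_change_retention.pdf")
    }
  }

  report <- list(config = unclass(config),
                 config_hash = .configHash(config),
                 seed = baseSeed,
                 r_version = as.character(getRversion()),
                 package_version =
                   as.character(utils::packageVersion("MultiViewOmics")),
                 artifacts = paths)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  paths$report <- file.path(outDir, "report.json")
  attr(paths, "results") <- results
  invisible(paths)
}
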