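## evaluate: repeated LOOCV harness, experiment-grid manifest, accuracy
## summaries and per-instance accuracy matrices.

#' One leave-one-out cross-validation pass
#'
#' For each of the n folds (canonical sample order): the standardizer is fit
#' on the n-1 training rows only and applied to train and held-out rows; the
#' smoothed bootstrap augments the standardized training rows only; the
#' model is fit on the augmented virtual subjects; the held-out sample is
#' predicted; the fold's selected-feature set is recorded (union over base
#' learners for multi-view paradigms). Nothing derived from the held-out
#' row ever reaches the fitted model.
#'
#' @param cohort curated \linkS4class{ParallelCohort} (no missing cells in
#'   the combination's layers).
#' @param combination character vector of layer ids.
#' @param strategy an \code{\link{integrationStrategy}} (or a paradigm label
#'   accepted by \code{\link{paradigmStrategy}}).
#' @param spec a \code{\link{learnerSpec}} for the (base) learners.
#' @param augment an \code{\link{augmentConfig}}; its seed is re-derived
#'   per fold from \code{seed}.
#' @param seed integer seed for the augmentation streams of this pass.
#' @param threshold consensus threshold theta (late integration).
#' @param returnModels keep each fold's fitted model (memory-heavy; used by
#'   leakage diagnostics).
#' @return list with \code{folds} (data.frame: fold, sample_id, truth,
#'   predicted, correct, n_selected), \code{selected} (list of per-fold
#'   feature-ref sets), \code{accuracy} (fraction of correct folds),
#'   \code{models} (list or NULL), and \code{augmentedPerClass}.
#' @export
loocvOnce <- function(cohort, combination, strategy,
                      spec = learnerSpec(), augment = augmentConfig(),
                      seed = 1L, threshold = 0.5, returnModels = FALSE) {
  stopifnot(is(cohort, "ParallelCohort"))
  if (is.character(strategy))
    strategy <- paradigmStrategy(strategy)
  y <- sampleLabels(cohort)
  n <- length(y)
  if (n < 3L)
    stop("LOOCV needs at least 3 samples")
  Xall <- concatMatrix(cohort, combination)
  samples <- names(y)
  sel <- vector("list", n)
  mods <- if (returnModels) vector("list", n) else NULL
  res <- data.frame(fold = seq_len(n), sample_id = samples,
                    truth = as.integer(y), predicted = NA_integer_,
                    correct = NA, n_selected = NA_integer_,
                    stringsAsFactors = FALSE)
  augPerClass <- NA_integer_
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L)
      stop(sprintf("training fold %d has a single class; cannot fit", i))
    std <- fitStandardizer(Xall[tr, , drop = FALSE])
    Xtr <- applyStandardizer(std, Xall[tr, , drop = FALSE])
    Xte <- applyStandardizer(std, Xall[i, , drop = FALSE])
    augFold <- augment
    augFold$seed <- mixSeed(seed, i)
    aug <- smoothedBootstrap(Xtr, ytr, augFold)
    augPerClass <- sum(aug$y == 0L)
    model <- fitIntegrated(aug$X, aug$y, combination, strategy,
                           spec = spec, threshold = threshold)
    pred <- predictLabel(model, Xte)
    refs <- modelSelectedFeatures(model, spec)
    sel[[i]] <- refs
    if (returnModels) mods[[i]] <- model
    res$predicted[i] <- pred
    res$correct[i] <- pred == res$truth[i]
    res$n_selected[i] <- length(refs)
  }
  list(folds = res, selected = sel,
       accuracy = mean(res$correct), models = mods,
       augmentedPerClass = augPerClass)
}

#' Repeated LOOCV
#'
#' Repetition r (r = 1..R) reruns \code{\link{loocvOnce}} with seed
#' \code{baseSeed + r}, so trials differ only through the augmentation
#' stream. Reports the mean and SD of the R repetition-level accuracies and
#' the per-instance mean correctness over repetitions.
#'
#' @inheritParams loocvOnce
#' @param R number of repetitions (default 20).
#' @param baseSeed integer base seed.
#' @return list of class \code{"RunSummary"}: \code{meanAccuracy},
#'   \code{sdAccuracy}, \code{perInstance} (named mean-correctness vector),
#'   \code{perRepetition} (accuracy per repetition), \code{R},
#'   \code{selected} (per-fold selected sets of repetition 1, the
#'   designated repetition for stability analysis).
#' @export
repeatLoocv <- function(cohort, combination, strategy,
                        spec = learnerSpec(), augment = augmentConfig(),
                        R = 20L, baseSeed = 1L, threshold = 0.5) {
  R <- as.integer(R)
  stopifnot(R >= 1L)
  if (is.character(strategy))
    strategy <- paradigmStrategy(strategy)
  acc <- numeric(R)
  per_inst <- NULL
  sel_first <- NULL
  for (r in seq_len(R)) {
    run <- loocvOnce(cohort, combination, strategy, spec, augment,
                     seed = baseSeed + r, threshold = threshold)
    acc[r] <- run$accuracy
    ci <- as.numeric(run$folds$correct)
    per_inst <- if (is.null(per_inst)) ci else per_inst + ci
    if (r == 1L) sel_first <- run$selected
  }
  per_inst <- per_inst / R
  names(per_inst) <- sampleIds(cohort)
  structure(list(meanAccuracy = mean(acc),
                 sdAccuracy = stats::sd(acc),
                 perInstance = per_inst,
                 perRepetition = acc,
                 R = R,
                 combination = combination,
                 selected = sel_first),
            class = "RunSummary")
}

#' Experiment-grid manifest counts
#'
#' Closed-form model counts for a grid of 6 learning paradigms over all
#' non-empty layer combinations with R repetitions: multi-view paradigms
#' are excluded for single-layer combinations, so single-layer cells use 3
#' paradigms and multi-layer cells all 6.
#'
#' @param layerIds character vector of layer ids (or an integer count).
#' @param R repetitions per cell (default 20).
#' @return list with \code{total}, \code{singleLayer}, \code{multiLayer},
#'   \code{nCombinations}.
#' @examples
#' manifestCounts(c("P", "M", "L", "T"), R = 20)  # 1560 models
#' @export
manifestCounts <- function(layerIds, R = 20L) {
  if (is.numeric(layerIds) && length(layerIds) == 1L)
    layerIds <- LETTERS[seq_len(layerIds)]
  combos <- enumerateCombinations(layerIds)
  sizes <- lengths(combos)
  n1 <- sum(sizes == 1L)
  nm <- sum(sizes >= 2L)
  single <- 3L * n1 * as.integer(R)
  multi <- 6L * nm * as.integer(R)
  list(total = single + multi, singleLayer = single, multiLayer = multi,
       nCombinations = length(combos))
}

#' Run the full experiment grid
#'
#' Repeated LOOCV for every (combination, paradigm) cell, skipping
#' multi-view paradigms on single-layer combinations. Returns a long-format
#' data.frame; see \code{\link{summaryTable}} and
#' \code{\link{instanceAccuracyMatrix}} for the rendered views.
#'
#' @param cohort curated \linkS4class{ParallelCohort}.
#' @param combinations list of layer-id vectors (default: all non-empty
#'   combinations of the cohort's layers).
#' @param paradigmSet character vector of paradigm labels (default all 6).
#' @param spec,augment,threshold passed to \code{\link{repeatLoocv}}.
#' @param R repetitions per cell.
#' @param baseSeed base seed; cell c uses \code{mixSeed(baseSeed, c)}.
#' @return data.frame with one row per evaluated cell: combination,
#'   paradigm, mean_accuracy, sd_accuracy, and one
#'   \code{instance_<sample id>} column per sample. The per-cell
#'   \code{RunSummary} objects are attached as attribute
#'   \code{"summaries"}.
#' @export
runExperimentGrid <- function(cohort,
                              combinations = enumerateCombinations(layerIds(cohort)),
                              paradigmSet = paradigms(),
                              spec = learnerSpec(),
                              augment = augmentConfig(),
                              R = 20L, baseSeed = 1L, threshold = 0.5) {
  rows <- list()
  summaries <- list()
  cell <- 0L
  for (combo in combinations) {
    for (par in paradigmSet) {
      cell <- cell + 1L
      if (length(combo) < 2L && startsWith(par, "MULTI-VIEW"))
        next
      run <- repeatLoocv(cohort, combo, par, spec = spec,
                         augment = augment, R = R,
                         baseSeed = mixSeed(baseSeed, cell),
                         threshold = threshold)
      key <- paste(comboString(combo), par, sep = " | ")
      summaries[[key]] <- run
      inst <- as.list(run$perInstance)
      names(inst) <- paste0("instance_", names(run$perInstance))
      rows[[key]] <- data.frame(combination = comboString(combo),
                                paradigm = par,
                                mean_accuracy = run$meanAccuracy,
                                sd_accuracy = run$sdAccuracy,
                                inst,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summaries") <- summaries
  out
}

#' Accuracy summary table (combinations x paradigms)
#'
#' Wide rendering of an experiment-grid result with "mean +/- SD" cells
#' (3 display digits) and blanks where a paradigm was not evaluated.
#'
#' @param grid long-format data.frame from \code{\link{runExperimentGrid}}.
#' @return character data.frame, rows = combinations, cols = paradigms.
#' @export
summaryTable <- function(grid) {
  combos <- unique(grid$combination)
  pars <- unique(grid$paradigm)
  out <- matrix("", length(combos), length(pars),
                dimnames = list(combos, pars))
  for (i in seq_len(nrow(grid))) {
    out[grid$combination[i], grid$paradigm[i]] <-
      sprintf("%.3g ± %.2g", grid$mean_accuracy[i], grid$sd_accuracy[i])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Per-instance accuracy matrix
#'
#' One row per evaluated (combination, paradigm) configuration, one column
#' per sample; cells are the mean correctness of that sample over
#' repetitions, \code{NA} for configurations that were not evaluated
#' (multi-view on a single layer).
#'
#' @param grid long-format data.frame from \code{\link{runExperimentGrid}}.
#' @param combinations,paradigmSet full row set to render; defaults to
#'   those present in \code{grid} (plus excluded cells as NA rows when the
#'   full grids are supplied).
#' @return numeric matrix, rownames "combination | paradigm".
#' @export
instanceAccuracyMatrix <- function(grid,
                                   combinations = unique(grid$combination),
                                   paradigmSet = unique(grid$paradigm)) {
  inst_cols <- grep("^instance_", colnames(grid), value = TRUE)
  samples <- sub("^instance_", "", inst_cols)
  rows <- as.vector(t(outer(combinations, paradigmSet, paste, sep = " | ")))
  out <- matrix(NA_real_, length(rows), length(samples),
                dimnames = list(rows, samples))
  key <- paste(grid$combination, grid$paradigm, sep = " | ")
  for (i in seq_len(nrow(grid)))
    out[key[i], ] <- as.numeric(grid[i, inst_cols])
  out
}
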