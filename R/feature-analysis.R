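## feature_analysis: consistent features across LOOCV folds, the
## label-permutation null, fold-change validation and composition
## summaries.

#' Intersect per-fold selected-feature sets
#'
#' A feature is "consistent" when it survives shrinkage in every LOOCV fold
#' of the designated repetition. For multi-view paradigms each fold's set is
#' the union of per-layer selections (already applied by
#' \code{\link{modelSelectedFeatures}}).
#'
#' @param selectedSets list with one character vector of feature refs per
#'   fold.
#' @param paradigm label recorded on the result.
#' @return a \linkS4class{ConsistentFeatureSet}.
#' @export
consistentFeatures <- function(selectedSets, paradigm = "unknown") {
  if (length(selectedSets) < 1L)
    stop("at least one fold's selected set required")
  inter <- Reduce(intersect, selectedSets)
  inter <- inter[order(match(inter, selectedSets[[1L]]))]
  new("ConsistentFeatureSet", paradigm = paradigm,
      features = as.character(inter),
      composition = composition(as.character(inter)))
}

#' Per-layer composition of a feature set
#'
#' Percentage contribution of each omic layer, \code{100 * count / total}.
#' Empty sets have no defined composition and return an empty vector.
#'
#' @param features character vector of feature refs, or a
#'   \linkS4class{ConsistentFeatureSet}.
#' @return named numeric vector of percentages (names = layer ids, in
#'   first-appearance order), summing to 100 for non-empty input.
#' @examples
#' composition(c(featureRef("P", "a"), featureRef("T", c("x", "y", "z"))))
#' @export
composition <- function(features) {
  if (is(features, "ConsistentFeatureSet"))
    features <- features@features
  if (length(features) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  lay <- featureRefLayer(features)
  counts <- table(factor(lay, levels = unique(lay)))
  pct <- 100 * as.numeric(counts) / length(features)
  stats::setNames(pct, names(counts))
}

#' Label-permutation null for the consistent-set size
#'
#' Repeats the full LOOCV-with-augmentation selection pipeline under
#' uniformly permuted class labels (class counts preserved) and records the
#' null consistent-set size each time. The p-value is the plain proportion
#' of null sizes >= the observed size (or the smoothed
#' \code{(1 + k) / (1 + N)} variant).
#'
#' @param cohort curated \linkS4class{ParallelCohort}.
#' @param combination character vector of layer ids.
#' @param strategy selection-capable strategy or paradigm label
#'   (intermediate or late stage).
#' @param spec,augment,threshold as in \code{\link{loocvOnce}}.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed governing both the observed run's augmentation
#'   stream and the permutation draws.
#' @param smoothed use the \code{(1+k)/(1+N)} p-value convention.
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(cohort, combination, strategy,
                            spec = learnerSpec(), augment = augmentConfig(),
                            nPerm = 1000L, seed = 1L, threshold = 0.5,
                            smoothed = FALSE) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L)
    stop("nPerm must be >= 1")
  if (is.character(strategy))
    strategy <- paradigmStrategy(strategy)
  if (strategy$stage == "early")
    stop("the permutation test requires a selection-capable paradigm ",
         "(intermediate or late integration)")
  obs_run <- loocvOnce(cohort, combination, strategy, spec, augment,
                       seed = mixSeed(seed, 0L), threshold = threshold)
  observed <- length(consistentFeatures(obs_run$selected)@features)
  y <- sampleLabels(cohort)
  perms <- withSeed(seed, {
    lapply(seq_len(nPerm), function(i) sample(as.integer(y)))
  })
  nullSizes <- vapply(seq_len(nPerm), function(i) {
    ylab <- perms[[i]]
    names(ylab) <- names(y)
    perm_cohort <- new("ParallelCohort", layers = layers(cohort),
                       labels = ylab)
    run <- loocvOnce(perm_cohort, combination, strategy, spec, augment,
                     seed = mixSeed(seed, i), threshold = threshold)
    length(consistentFeatures(run$selected)@features)
  }, integer(1))
  k <- sum(nullSizes >= observed)
  p <- if (smoothed) (1 + k) / (1 + nPerm) else k / nPerm
  new("PermutationResult", observed = as.integer(observed),
      nullSizes = as.integer(nullSizes), pValue = p,
      nPerm = nPerm, seed = as.integer(seed))
}

#' Fold-change profile of a feature set
#'
#' Fold change \code{FC = mean(case) / mean(control)} on curated
#' decimal-scale values over all subjects, and the symmetric score
#' \code{F = max(FC, 1/FC)} so down-regulated features can pass thresholds.
#' Features with a non-positive class mean are flagged undefined and fail
#' every threshold above 1.
#'
#' @param cohort curated, linear-scale \linkS4class{ParallelCohort}.
#' @param features character vector of feature refs (or a
#'   \linkS4class{ConsistentFeatureSet}).
#' @return data.frame: feature_ref, layer_id, mean_case, mean_control, fc,
#'   score, defined.
#' @export
foldChangeProfile <- function(cohort, features) {
  stopifnot(is(cohort, "ParallelCohort"))
  if (is(features, "ConsistentFeatureSet"))
    features <- features@features
  y <- sampleLabels(cohort)
  lay <- featureRefLayer(features)
  feat <- featureRefFeature(features)
  bad_scale <- vapply(unique(lay), function(id)
    !is.na(scaleBase(layers(cohort)[[id]])), logical(1))
  if (any(bad_scale))
    stop("fold changes require linear-scale layers; delog first: ",
         paste(unique(lay)[bad_scale], collapse = ", "))
  rows <- lapply(seq_along(features), function(i) {
    v <- layerValues(layers(cohort)[[lay[i]]])[, feat[i]]
    m1 <- mean(v[y == 1L])
    m0 <- mean(v[y == 0L])
    defined <- is.finite(m1) && is.finite(m0) && m1 > 0 && m0 > 0
    fc <- if (defined) m1 / m0 else NA_real_
    data.frame(feature_ref = features[i], layer_id = lay[i],
               mean_case = m1, mean_control = m0, fc = fc,
               score = if (defined) max(fc, 1 / fc) else NA_real_,
               defined = defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## The published fold-change threshold ladder.
.fc_thresholds_default <- c(1, 1.1, 1.2, 1.3, 2.0, 3.0)

#' Retention curves over fold-change thresholds
#'
#' For each omic layer in the profile, the proportion of its features whose
#' symmetric fold-change score meets each threshold. Undefined features
#' count as failing every threshold above 1; every feature passes the
#' minimal threshold 1 by convention. Curves are non-increasing in the
#' threshold.
#'
#' @param profile data.frame from \code{\link{foldChangeProfile}}.
#' @param thresholds threshold ladder (default 1, 1.1, 1.2, 1.3, 2, 3).
#' @param paradigm label copied into the output.
#' @return long-format data.frame: paradigm, layer_id, threshold,
#'   n_features, retained_proportion.
#' @export
retentionCurves <- function(profile, thresholds = .fc_thresholds_default,
                            paradigm = "unknown") {
  stopifnot(is.data.frame(profile), !is.unsorted(thresholds))
  rows <- list()
  for (id in unique(profile$layer_id)) {
    sub <- profile[profile$layer_id == id, ]
    for (th in thresholds) {
      pass <- if (th <= 1) rep(TRUE, nrow(sub))
              else sub$defined & !is.na(sub$score) & sub$score >= th
      rows[[length(rows) + 1L]] <-
        data.frame(paradigm = paradigm, layer_id = id, threshold = th,
                   n_features = nrow(sub),
                   retained_proportion = mean(pass),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot retention curves
#'
#' One line per (paradigm, layer) showing the proportion of consistent
#' features surviving each fold-change threshold.
#'
#' @param curves data.frame from \code{\link{retentionCurves}} (possibly
#'   row-bound across paradigms).
#' @param main plot title.
#' @return invisibly, the input.
#' @export
plotRetentionCurves <- function(curves, main = "Fold-change retention") {
  groups <- unique(curves[, c("paradigm", "layer_id")])
  ths <- sort(unique(curves$threshold))
  plot(range(ths), c(0, 1), type = "n", xlab = "fold-change threshold",
       ylab = "proportion retained", main = main)
  for (g in seq_len(nrow(groups))) {
    sub <- curves[curves$paradigm == groups$paradigm[g] &
                    curves$layer_id == groups$layer_id[g], ]
    sub <- sub[order(sub$threshold), ]
    graphics::lines(sub$threshold, sub$retained_proportion,
                    col = g, lty = 1 + (g - 1) %% 4)
    graphics::points(sub$threshold, sub$retained_proportion,
                     col = g, pch = 16)
  }
  graphics::legend("bottomleft",
                   legend = paste(groups$paradigm, groups$layer_id),
                   col = seq_len(nrow(groups)),
                   lty = 1 + (seq_len(nrow(groups)) - 1) %% 4,
                   cex = 0.7, bty = "n")
  invisible(curves)
}
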