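#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' OmicLayer: one omic feature matrix
#'
#' Container for a single omic layer: a samples-by-features numeric matrix
#' with unique sample and feature ids. Missing measurements are stored as
#' \code{NA}. \code{scaleBase} records whether values are still on a
#' logarithmic scale (base 2, 10 or e); \code{NA_real_} means linear
#' (decimal) scale. All modelling requires linear scale; see
#' \code{\link{delog}}.
#'
#' @slot layerId single short label, e.g. "P", "M", "L", "T".
#' @slot values numeric matrix, rows = samples, cols = features; dimnames
#'   carry the ids.
#' @slot scaleBase numeric(1); log base of the stored values, or
#'   \code{NA_real_} for linear scale.
#'
#' @seealso \code{\link{readOmicLayer}}, \code{\link{delog}},
#'   \code{\link{assembleCohort}}
#' @export
setClass("OmicLayer",
  representation(layerId = "character", values = "matrix",
                 scaleBase = "numeric"),
  prototype(layerId = NA_character_,
            values = matrix(numeric(0), 0, 0),
            scaleBase = NA_real_))

setValidity("OmicLayer", function(object) {
  msg <- character(0)
  if (length(object@layerId) != 1L || is.na(object@layerId) ||
      !nzchar(object@layerId))
    msg <- c(msg, "layerId must be a single non-empty string")
  if (length(object@layerId) == 1L && !is.na(object@layerId) &&
      grepl(":", object@layerId, fixed = TRUE))
    msg <- c(msg, "layerId must not contain ':'")
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have sample (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate feature ids")
  }
  if (any(is.infinite(v)))
    msg <- c(msg, "non-missing values must be finite")
  if (length(object@scaleBase) != 1L)
    msg <- c(msg, "scaleBase must be length 1")
  else if (!is.na(object@scaleBase) &&
           (object@scaleBase <= 0 || object@scaleBase == 1))
    msg <- c(msg, "scaleBase must be > 0 and != 1")
  if (length(msg)) msg else TRUE
})

#' ParallelCohort: aligned multi-omic layers with binary labels
#'
#' Holds k >= 1 \linkS4class{OmicLayer} objects measured on the identical
#' sample set, plus a 0/1 label per sample (0 = control, 1 = case/high-risk).
#' Sample order is canonical (lexicographic in sample id) and identical in
#' every layer and in the labels; both classes must be present.
#'
#' @slot layers named list of \linkS4class{OmicLayer}, names = layer ids.
#' @slot labels named integer vector of 0/1, names = sample ids in canonical
#'   order.
#'
#' @seealso \code{\link{assembleCohort}}, \code{\link{curateCohort}},
#'   \code{\link{generateCohort}}
#' @export
setClass("ParallelCohort",
  representation(layers = "list", labels = "integer"))

setValidity("ParallelCohort", function(object) {
  msg <- character(0)
  if (length(object@layers) < 1L)
    msg <- c(msg, "at least one layer required")
  if (!all(vapply(object@layers, is, logical(1), "OmicLayer")))
    return("layers must all be OmicLayer objects")
  ids <- vapply(object@layers, function(l) l@layerId, character(1))
  if (!identical(unname(names(object@layers)), unname(ids)))
    msg <- c(msg, "layer list names must equal layer ids")
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate layer ids")
  samp <- names(object@labels)
  if (is.null(samp) || anyDuplicated(samp))
    msg <- c(msg, "labels must be uniquely named by sample id")
  if (!identical(samp, sort(samp)))
    msg <- c(msg, "labels must be in canonical (sorted) sample order")
  for (l in object@layers) {
    if (!identical(rownames(l@values), samp))
      msg <- c(msg, sprintf("layer '%s' sample order differs from labels",
                            l@layerId))
  }
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (control) or 1 (case)")
  if (length(unique(object@labels)) < 2L)
    msg <- c(msg, "both classes must be present")
  if (length(msg)) msg else TRUE
})

#' FittedModel: a fitted (possibly penalized) logistic learner
#'
#' Coefficients are stored over the training columns, keyed by feature
#' reference (\code{"layer:feature"}). \code{lambda} is \code{NA} for the
#' unpenalized-surrogate LR family.
#'
#' @slot family one of "LR", "LASSO", "RIDGE".
#' @slot coefficients named numeric vector (names = feature refs).
#' @slot intercept numeric(1).
#' @slot lambda numeric(1) penalty used, NA for LR.
#'
#' @seealso \code{\link{fitLR}}, \code{\link{tuneAndFitPenalized}},
#'   \code{\link{predictProba}}, \code{\link{selectFeatures}}
#' @export
setClass("FittedModel",
  representation(family = "character", coefficients = "numeric",
                 intercept = "numeric", lambda = "numeric"))

setValidity("FittedModel", function(object) {
  msg <- character(0)
  if (!object@family %in% c("LR", "LASSO", "RIDGE"))
    msg <- c(msg, "family must be LR, LASSO or RIDGE")
  if (is.null(names(object@coefficients)))
    msg <- c(msg, "coefficients must be named by feature ref")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  if (length(object@lambda) != 1L)
    msg <- c(msg, "lambda must be length 1")
  if (length(msg)) msg else TRUE
})

#' MultiViewModel: late-integration consensus ensemble
#'
#' One base \linkS4class{FittedModel} per omic layer, all trained on the same
#' augmented virtual subjects; prediction averages the per-layer predicted
#' probabilities and calls "case" when the mean strictly exceeds the
#' consensus threshold theta.
#'
#' @slot models named list of \linkS4class{FittedModel} (names = layer ids).
#' @slot threshold numeric(1) in (0, 1); consensus threshold theta.
#' @slot vote "probability" (default, average predicted probabilities) or
#'   "label" (average hard 0/1 votes).
#'
#' @seealso \code{\link{fitIntegrated}}, \code{\link{consensusPredict}}
#' @export
setClass("MultiViewModel",
  representation(models = "list", threshold = "numeric", vote = "character"),
  prototype(threshold = 0.5, vote = "probability"))

setValidity("MultiViewModel", function(object) {
  msg <- character(0)
  if (length(object@models) < 2L)
    msg <- c(msg, "a multi-view model needs at least two layers")
  if (!all(vapply(object@models, is, logical(1), "FittedModel")))
    msg <- c(msg, "models must be FittedModel objects")
  if (is.null(names(object@models)) || anyDuplicated(names(object@models)))
    msg <- c(msg, "models must be uniquely named by layer id")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (!object@vote %in% c("probability", "label"))
    msg <- c(msg, "vote must be 'probability' or 'label'")
  if (length(msg)) msg else TRUE
})

#' ConsistentFeatureSet: features selected in every LOOCV fold
#'
#' The intersection of per-fold selected-feature sets, with the per-layer
#' composition of the set (percentages summing to 100 for non-empty sets).
#'
#' @slot paradigm label of the learning paradigm that produced the set.
#' @slot features character vector of feature refs.
#' @slot composition named numeric vector of per-layer percentages
#'   (empty for an empty feature set).
#'
#' @seealso \code{\link{consistentFeatures}}, \code{\link{composition}}
#' @export
setClass("ConsistentFeatureSet",
  representation(paradigm = "character", features = "character",
                 composition = "numeric"))

setValidity("ConsistentFeatureSet", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@features))
    msg <- c(msg, "feature refs must be unique")
  if (length(object@features) > 0) {
    if (abs(sum(object@composition) - 100) > 0.2)
      msg <- c(msg, "composition must sum to 100 (within rounding)")
  }
  if (length(msg)) msg else TRUE
})

#' PermutationResult: label-permutation null for consistent-set size
#'
#' @slot observed integer(1); consistent-set size on the real labels.
#' @slot nullSizes integer vector of null consistent-set sizes.
#' @slot pValue numeric(1); proportion of null sizes >= observed (or the
#'   smoothed (1+k)/(1+N) variant).
#' @slot nPerm integer(1) number of permutations.
#' @slot seed integer(1) base seed used.
#'
#' @seealso \code{\link{permutationTest}}
#' @export
setClass("PermutationResult",
  representation(observed = "integer", nullSizes = "integer",
                 pValue = "numeric", nPerm = "integer", seed = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- character(0)
  if (length(object@nullSizes) != object@nPerm)
    msg <- c(msg, "nullSizes length must equal nPerm")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
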