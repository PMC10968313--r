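#' Accessors for MultiViewOmics classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an \linkS4class{OmicLayer} or \linkS4class{ParallelCohort}.
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{layerId}: the layer's id string.
#' @export
setGeneric("layerId", function(x) standardGeneric("layerId"))

#' @rdname accessors
#' @return \code{layerValues}: the numeric sample-by-feature matrix.
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))

#' @rdname accessors
#' @return \code{scaleBase}: log base of stored values (NA = linear scale).
#' @export
setGeneric("scaleBase", function(x) standardGeneric("scaleBase"))

#' @rdname accessors
#' @return \code{sampleIds}: character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @return \code{featureIds}: character vector of feature ids (for a cohort,
#'   feature refs across all layers).
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @return \code{layers}: named list of \linkS4class{OmicLayer}.
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' @rdname accessors
#' @return \code{layerIds}: character vector of layer ids.
#' @export
setGeneric("layerIds", function(x) standardGeneric("layerIds"))

#' @rdname accessors
#' @return \code{sampleLabels}: named integer 0/1 vector in canonical order.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' Convert a log-scale layer to linear (decimal) scale
#'
#' @param layer an \linkS4class{OmicLayer}.
#' @param ... unused.
#' @return an \linkS4class{OmicLayer} on linear scale.
#' @export
setGeneric("delog", function(layer, ...) standardGeneric("delog"))

#' Predicted case probabilities
#'
#' @param model a fitted model.
#' @param X numeric matrix of standardized measurements whose columns match
#'   the model's training columns (for a multi-view model, the concatenated
#'   matrix containing every layer's columns).
#' @return numeric vector of probabilities in (0, 1).
#' @export
setGeneric("predictProba", function(model, X) standardGeneric("predictProba"))

setMethod("layerId", "OmicLayer", function(x) x@layerId)
setMethod("layerValues", "OmicLayer", function(x) x@values)
setMethod("scaleBase", "OmicLayer", function(x) x@scaleBase)
setMethod("sampleIds", "OmicLayer", function(x) rownames(x@values))
setMethod("featureIds", "OmicLayer", function(x) colnames(x@values))

setMethod("layers", "ParallelCohort", function(x) x@layers)
setMethod("layerIds", "ParallelCohort", function(x) names(x@layers))
setMethod("sampleIds", "ParallelCohort", function(x) names(x@labels))
setMethod("sampleLabels", "ParallelCohort", function(x) x@labels)
setMethod("featureIds", "ParallelCohort", function(x) {
  unlist(lapply(x@layers, function(l)
    featureRef(l@layerId, colnames(l@values))), use.names = FALSE)
})

setMethod("show", "OmicLayer", function(object) {
  v <- object@values
  cat(sprintf("OmicLayer '%s': %d samples x %d features (%d missing cells)%s\n",
              object@layerId, nrow(v), ncol(v), sum(is.na(v)),
              if (is.na(object@scaleBase)) ", linear scale"
              else sprintf(", log base %g", object@scaleBase)))
})

setMethod("show", "ParallelCohort", function(object) {
  cat(sprintf("ParallelCohort: %d samples (%d control / %d case), %d layers\n",
              length(object@labels), sum(object@labels == 0L),
              sum(object@labels == 1L), length(object@layers)))
  for (l in object@layers)
    cat(sprintf("  %s: %d features (%d missing cells)\n", l@layerId,
                ncol(l@values), sum(is.na(l@values))))
})

setMethod("show", "FittedModel", function(object) {
  nz <- sum(abs(object@coefficients) > 1e-8)
  cat(sprintf("FittedModel [%s]: %d coefficients (%d above 1e-8)%s\n",
              object@family, length(object@coefficients), nz,
              if (is.na(object@lambda)) ""
              else sprintf(", lambda = %g", object@lambda)))
})

setMethod("show", "MultiViewModel", function(object) {
  cat(sprintf("MultiViewModel: %d base learners (%s), theta = %g, %s vote\n",
              length(object@models),
              paste(names(object@models), collapse = "+"),
              object@threshold, object@vote))
})

setMethod("show", "ConsistentFeatureSet", function(object) {
  cat(sprintf("ConsistentFeatureSet [%s]: %d features\n", object@paradigm,
              length(object@features)))
  if (length(object@features)) {
    comp <- paste(sprintf("%%%s=%.1f", names(object@composition),
                          object@composition), collapse = " ")
    cat(" ", comp, "\n")
  }
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed %d consistent features, p = %.4g (%d permutations)\n",
    object@observed, object@pValue, object@nPerm))
})
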