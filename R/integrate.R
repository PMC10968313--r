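## integrate: the three integration strategies; in particular the
## late-integration multi-view consensus ensemble.

#' Integration strategy
#'
#' Pairs an integration stage with a learner family. "early" concatenates
#' layers and fits unpenalized LR; "intermediate" concatenates and fits a
#' tuned penalized model (LASSO/RIDGE); "late" fits one base learner per
#' layer (any family) and aggregates predictions by consensus, and requires
#' at least two layers.
#'
#' @param stage "early", "intermediate" or "late".
#' @param family base learner family (see \code{\link{learnerSpec}}).
#' @return list of class \code{"IntegrationStrategy"}.
#' @export
integrationStrategy <- function(stage = c("early", "intermediate", "late"),
                                family = c("LR", "LASSO", "RIDGE")) {
  stage <- match.arg(stage)
  family <- match.arg(family)
  if (stage == "early" && family != "LR")
    stop("early integration pairs only with LR")
  if (stage == "intermediate" && family == "LR")
    stop("intermediate integration pairs with LASSO or RIDGE")
  structure(list(stage = stage, family = family),
            class = "IntegrationStrategy")
}

## The six published learning paradigms.
.paradigms <- c("LR", "LASSO", "RIDGE",
                "MULTI-VIEW LR", "MULTI-VIEW LASSO", "MULTI-VIEW RIDGE")

#' Map a paradigm label to its integration strategy
#'
#' "LR" is early integration; "LASSO"/"RIDGE" are intermediate;
#' "MULTI-VIEW <family>" is late integration with that base family.
#'
#' @param paradigm one of \code{paradigms()}.
#' @return an \code{\link{integrationStrategy}}.
#' @export
paradigmStrategy <- function(paradigm) {
  paradigm <- match.arg(paradigm, .paradigms)
  if (paradigm == "LR")
    integrationStrategy("early", "LR")
  else if (paradigm %in% c("LASSO", "RIDGE"))
    integrationStrategy("intermediate", paradigm)
  else
    integrationStrategy("late", sub("^MULTI-VIEW ", "", paradigm))
}

#' @rdname paradigmStrategy
#' @return \code{paradigms}: the six paradigm labels.
#' @export
paradigms <- function() .paradigms

#' Fit a model under an integration strategy
#'
#' The training matrix is the standardized, augmented concatenation of the
#' combination's layers (columns named by feature ref); late integration
#' slices this matrix by layer so all base learners see the same virtual
#' subjects, preserving cross-layer pairing.
#'
#' @param X standardized (augmented) training matrix with feature-ref
#'   column names.
#' @param y 0/1 training labels.
#' @param combination character vector of layer ids present in \code{X}.
#' @param strategy an \code{\link{integrationStrategy}}.
#' @param spec a \code{\link{learnerSpec}} for the (base) learner; its
#'   family is overridden by the strategy's.
#' @param threshold consensus threshold theta for late integration.
#' @return a \linkS4class{FittedModel} (early/intermediate) or
#'   \linkS4class{MultiViewModel} (late).
#' @export
fitIntegrated <- function(X, y, combination, strategy,
                          spec = learnerSpec(strategy$family),
                          threshold = 0.5) {
  stopifnot(inherits(strategy, "IntegrationStrategy"), is.matrix(X))
  spec$family <- strategy$family
  if (strategy$stage == "early") {
    fitLR(X, y, spec)
  } else if (strategy$stage == "intermediate") {
    tuneAndFitPenalized(X, y, spec)
  } else {
    if (length(combination) < 2L)
      stop("late integration requires at least two layers")
    colLayer <- featureRefLayer(colnames(X))
    models <- lapply(combination, function(id) {
      Xl <- X[, colLayer == id, drop = FALSE]
      if (ncol(Xl) == 0L)
        stop(sprintf("no columns for layer '%s' in the training matrix", id))
      if (spec$family == "LR") fitLR(Xl, y, spec)
      else tuneAndFitPenalized(Xl, y, spec)
    })
    names(models) <- combination
    new("MultiViewModel", models = models, threshold = threshold,
        vote = "probability")
  }
}

#' Consensus prediction of a multi-view ensemble
#'
#' Per-layer predicted probabilities (or hard labels, in \code{"label"}
#' vote mode) are aggregated by arithmetic mean; the consensus label is
#' case/high-risk iff the mean strictly exceeds the threshold theta, so a
#' tie at theta classifies as control.
#'
#' @param model a \linkS4class{MultiViewModel}.
#' @param X matrix (or named vector for one sample) containing every base
#'   layer's columns, named by feature ref.
#' @return list with \code{score} (mean prediction per sample) and
#'   \code{label} (integer 0/1 per sample).
#' @export
consensusPredict <- function(model, X) {
  stopifnot(is(model, "MultiViewModel"))
  if (is.null(dim(X)))
    X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  per_layer <- lapply(model@models, function(m) {
    have <- names(m@coefficients) %in% colnames(X)
    if (!all(have))
      stop("missing layer slice: columns absent for some base learner")
    p <- predictProba(m, X)
    if (model@vote == "label") as.numeric(p > 0.5) else p
  })
  score <- Reduce(`+`, per_layer) / length(per_layer)
  list(score = score, label = as.integer(score > model@threshold))
}

#' @describeIn predictProba consensus score of the ensemble (arithmetic
#'   mean of per-layer probabilities).
#' @export
setMethod("predictProba", "MultiViewModel", function(model, X) {
  consensusPredict(model, X)$score
})

#' Hard label from any fitted model
#'
#' For a single learner: case iff probability > 0.5. For a multi-view
#' ensemble: case iff the consensus score strictly exceeds theta.
#'
#' @param model \linkS4class{FittedModel} or \linkS4class{MultiViewModel}.
#' @param X measurement matrix as in \code{\link{predictProba}}.
#' @return integer vector of 0/1 labels.
#' @export
predictLabel <- function(model, X) {
  if (is(model, "MultiViewModel"))
    consensusPredict(model, X)$label
  else
    as.integer(predictProba(model, X) > 0.5)
}

#' Union of selected features across an ensemble's base learners
#'
#' For a single penalized model this is just \code{\link{selectFeatures}};
#' for a multi-view model it is the union of per-layer selections, which is
#' the per-fold selected set used by the stability analysis.
#'
#' @param model \linkS4class{FittedModel} or \linkS4class{MultiViewModel}.
#' @param spec the \code{\link{learnerSpec}} in force.
#' @return character vector of feature refs.
#' @export
modelSelectedFeatures <- function(model, spec) {
  if (is(model, "MultiViewModel")) {
    sets <- lapply(model@models, function(m) {
      s <- spec
      s$family <- m@family
      selectFeatures(m, s)
    })
    unique(unlist(sets, use.names = FALSE))
  } else {
    s <- spec
    s$family <- model@family
    selectFeatures(model, s)
  }
}
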