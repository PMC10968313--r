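## learners: (penalized) logistic regression with a lambda grid targeting
## ~20% feature retention, plus selected-feature extraction.

#' Learner specification
#'
#' @param family "LR" (maximum-likelihood surrogate), "LASSO" (L1) or
#'   "RIDGE" (L2).
#' @param lambdaGrid strictly increasing positive penalty grid; default 25
#'   log-spaced points in [1e-4, 1e4] (a deliberately coarse grid).
#' @param retention target fraction rho of features retained after
#'   shrinkage (default 0.20); the tuned fit is the grid point whose
#'   selected-feature count is closest to \code{ceiling(rho * p)}.
#' @param epsilon magnitude below which a coefficient counts as zero
#'   (default 1e-8).
#' @param maxit maximum optimizer iterations.
#' @param thresh optimizer convergence tolerance.
#' @return list of class \code{"LearnerSpec"}.
#' @export
learnerSpec <- function(family = c("LASSO", "RIDGE", "LR"),
                        lambdaGrid = 10^seq(-4, 4, length.out = 25),
                        retention = 0.20, epsilon = 1e-8,
                        maxit = 1e5, thresh = 1e-8) {
  family <- match.arg(family)
  if (length(lambdaGrid) < 1L || any(lambdaGrid <= 0) ||
      is.unsorted(lambdaGrid, strictly = TRUE))
    stop("lambdaGrid must be a non-empty, strictly increasing positive vector")
  if (retention <= 0 || retention > 1)
    stop("retention must lie in (0, 1]")
  structure(list(family = family, lambdaGrid = lambdaGrid,
                 retention = retention, epsilon = epsilon,
                 maxit = maxit, thresh = thresh),
            class = "LearnerSpec")
}

## glmnet wrapper tolerating p = 1 (glmnet requires >= 2 columns; a zero
## dummy column is appended and its coefficient discarded).
.glmnetFit <- function(X, y, alpha, lambda, spec) {
  p <- ncol(X)
  Xfit <- X
  if (p == 1L)
    Xfit <- cbind(X, `.dummy.` = 0)
  ## glmnet warns unconditionally when a class has < 8 observations; that
  ## is this package's operating regime (7-subject cohorts), so the known
  ## warning is muffled rather than spamming every fold.
  fit <- withCallingHandlers(
    glmnet::glmnet(Xfit, y, family = "binomial", alpha = alpha,
                   lambda = lambda, standardize = FALSE,
                   maxit = spec$maxit, thresh = spec$thresh),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- as.matrix(fit$beta)[seq_len(p), , drop = FALSE]
  rownames(beta) <- colnames(X)
  list(beta = beta, a0 = as.numeric(fit$a0), lambda = fit$lambda,
       converged = fit$jerr == 0)
}

.checkTwoClasses <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("both classes must be present")
  y
}

#' Fit unpenalized-surrogate logistic regression
#'
#' Maximum-likelihood logistic fit approximated with a very weak ridge
#' penalty (lambda = 1e-6) so the estimate exists under the complete
#' separation that is generic when p >> n. Deterministic given the data.
#'
#' @param X standardized numeric matrix (columns named by feature ref).
#' @param y 0/1 labels.
#' @param spec a \code{\link{learnerSpec}} (family forced to "LR").
#' @return a \linkS4class{FittedModel} with \code{lambda = NA}.
#' @export
fitLR <- function(X, y, spec = learnerSpec("LR")) {
  y <- .checkTwoClasses(y)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  lam <- 1e-6
  fit <- .glmnetFit(X, y, alpha = 0,
                    lambda = c(10, 1, 0.1, 0.01, lam), spec = spec)
  if (!fit$converged)
    warning("logistic fit did not fully converge at max iterations")
  j <- length(fit$lambda)
  w <- fit$beta[, j]
  names(w) <- colnames(X)
  new("FittedModel", family = "LR", coefficients = w,
      intercept = fit$a0[j], lambda = NA_real_)
}

#' Tune a penalized logistic fit to the retention target
#'
#' Fits the full lambda grid and returns the fit whose selected-feature
#' count (per \code{\link{selectFeatures}}) is closest to
#' \code{ceiling(retention * p)}; ties break toward larger lambda
#' (stronger shrinkage).
#'
#' @inheritParams fitLR
#' @param spec a \code{\link{learnerSpec}} with family "LASSO" or "RIDGE".
#' @return a \linkS4class{FittedModel} carrying the winning lambda.
#' @export
tuneAndFitPenalized <- function(X, y, spec = learnerSpec("LASSO")) {
  y <- .checkTwoClasses(y)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (!spec$family %in% c("LASSO", "RIDGE"))
    stop("penalized tuning requires family LASSO or RIDGE")
  if (length(spec$lambdaGrid) < 1L)
    stop("empty lambda grid")
  alpha <- if (spec$family == "LASSO") 1 else 0
  fit <- .glmnetFit(X, y, alpha = alpha,
                    lambda = rev(spec$lambdaGrid), spec = spec)
  p <- ncol(X)
  target <- ceiling(spec$retention * p)
  ## selected-count per grid point, inlined from the selectFeatures rules
  ## (constructing an S4 model per lambda is needlessly slow here)
  nonzero <- colSums(abs(fit$beta) > spec$epsilon)
  counts <- if (spec$family == "LASSO") as.integer(nonzero)
            else ifelse(nonzero > 0L, min(ceiling(spec$retention * p), p), 0L)
  dist <- abs(counts - target)
  ## fit$lambda is decreasing, so the first index with minimal distance is
  ## the largest (sparsest) lambda among ties
  j <- which.min(dist)
  w <- fit$beta[, j]
  names(w) <- rownames(fit$beta)   # matrix subsetting drops names at p = 1
  new("FittedModel", family = spec$family,
      coefficients = w, intercept = fit$a0[j],
      lambda = fit$lambda[j])
}

#' Features surviving shrinkage
#'
#' For LASSO and LR, the features with \code{|w| > epsilon}. RIDGE never
#' produces exact zeros, so its selection rule is the
#' \code{ceiling(retention * p)} features of largest absolute coefficient
#' (ties broken by column order), honoring the same retention target.
#'
#' @param model a \linkS4class{FittedModel}.
#' @param spec the \code{\link{learnerSpec}} (supplies epsilon and
#'   retention).
#' @return character vector of selected feature refs (model column order).
#' @export
selectFeatures <- function(model, spec = learnerSpec(model@family)) {
  stopifnot(is(model, "FittedModel"))
  w <- model@coefficients
  if (model@family == "RIDGE") {
    if (all(abs(w) <= spec$epsilon))
      return(character(0))
    k <- min(ceiling(spec$retention * length(w)), length(w))
    ord <- order(-abs(w), seq_along(w))
    sort_idx <- sort(ord[seq_len(k)])
    names(w)[sort_idx]
  } else {
    names(w)[abs(w) > spec$epsilon]
  }
}

#' @describeIn predictProba logistic of the affine score
#'   \code{intercept + X \%*\% w}. Columns are matched by name when the
#'   matrix carries the model's feature refs; otherwise by position (with a
#'   count check).
#' @export
setMethod("predictProba", "FittedModel", function(model, X) {
  if (is.null(dim(X)))
    X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  w <- model@coefficients
  if (!is.null(colnames(X)) && all(names(w) %in% colnames(X))) {
    X <- X[, names(w), drop = FALSE]
  } else if (ncol(X) != length(w)) {
    stop(sprintf("dimension mismatch: model has %d columns, matrix has %d",
                 length(w), ncol(X)))
  }
  as.numeric(stats::plogis(model@intercept + X %*% w))
})
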