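## preprocess: feature curation, combination enumeration, standardization,
## and matrix assembly for the integration strategies.

#' Drop features with any missing measurement
#'
#' A feature is retained only if it is observed in every sample of the
#' layer. Column order is preserved. This "complete features only" curation
#' is used instead of imputation throughout the pipeline.
#'
#' @param layer an \linkS4class{OmicLayer}.
#' @return list with \code{layer} (curated \linkS4class{OmicLayer}) and
#'   \code{report} (one-row data.frame: layer_id, n_original, n_retained,
#'   retained_fraction).
#' @export
curateLayer <- function(layer) {
  stopifnot(is(layer, "OmicLayer"))
  v <- layerValues(layer)
  keep <- colSums(is.na(v)) == 0L
  if (!any(keep))
    stop(sprintf("layer '%s': all features have missing cells", layerId(layer)))
  out <- initialize(layer, values = v[, keep, drop = FALSE])
  rep <- data.frame(layer_id = layerId(layer),
                    n_original = ncol(v),
                    n_retained = sum(keep),
                    retained_fraction = sum(keep) / ncol(v),
                    stringsAsFactors = FALSE)
  list(layer = out, report = rep)
}

#' Curate every layer of a cohort
#'
#' @param cohort a \linkS4class{ParallelCohort}.
#' @return list with \code{cohort} (all layers curated) and \code{report}
#'   (per-layer data.frame as in \code{\link{curateLayer}}).
#' @export
curateCohort <- function(cohort) {
  stopifnot(is(cohort, "ParallelCohort"))
  res <- lapply(layers(cohort), curateLayer)
  newLayers <- lapply(res, `[[`, "layer")
  report <- do.call(rbind, lapply(res, `[[`, "report"))
  rownames(report) <- NULL
  list(cohort = new("ParallelCohort", layers = newLayers,
                    labels = sampleLabels(cohort)),
       report = report)
}

#' Summarize a curation report
#'
#' Adds display percentages (nearest integer) per layer and a total row.
#' Raw fractions are kept alongside the rounded display values.
#'
#' @param report per-layer curation data.frame (columns layer_id,
#'   n_original, n_retained, retained_fraction).
#' @return data.frame with an added \code{retained_percent_display} column
#'   and a final \code{TOTAL} row.
#' @examples
#' rep <- data.frame(layer_id = c("P", "M", "L", "T"),
#'                   n_original = c(2330, 238, 66, 329),
#'                   n_retained = c(1714, 122, 65, 329),
#'                   retained_fraction = c(1714/2330, 122/238, 65/66, 1))
#' curationSummary(rep)
#' @export
curationSummary <- function(report) {
  if (nrow(report) < 1L)
    stop("at least one layer report required")
  stopifnot(all(report$n_retained <= report$n_original))
  report$retained_fraction <- report$n_retained / report$n_original
  report$retained_percent_display <- round(100 * report$retained_fraction)
  total <- data.frame(layer_id = "TOTAL",
                      n_original = sum(report$n_original),
                      n_retained = sum(report$n_retained),
                      retained_fraction =
                        sum(report$n_retained) / sum(report$n_original),
                      retained_percent_display =
                        round(100 * sum(report$n_retained) /
                                sum(report$n_original)),
                      stringsAsFactors = FALSE)
  out <- rbind(report, total)
  rownames(out) <- NULL
  out
}

#' Enumerate all non-empty layer combinations
#'
#' Returns the 2^k - 1 non-empty subsets of the layer ids, ordered by size
#' ascending then lexicographically within size; within each combination
#' layers keep the order given in \code{layerIds}. For the quadra-omics
#' layers P, M, L, T this yields the 15 datasets evaluated in the
#' experiment grid.
#'
#' @param layerIds character vector of distinct layer ids (1 to 16).
#' @return list of character vectors.
#' @examples
#' length(enumerateCombinations(c("P", "M", "L", "T")))  # 15
#' @export
enumerateCombinations <- function(layerIds) {
  k <- length(layerIds)
  if (k < 1L)
    stop("at least one layer id required")
  if (k > 16L)
    stop("at most 16 layers supported")
  if (anyDuplicated(layerIds))
    stop("layer ids must be distinct")
  combos <- list()
  for (size in seq_len(k)) {
    idx <- utils::combn(k, size, simplify = FALSE)
    subs <- lapply(idx, function(i) layerIds[i])
    key <- vapply(subs, function(s) paste(sort(s), collapse = "\r"),
                  character(1))
    combos <- c(combos, subs[order(key)])
  }
  combos
}

#' Fit / apply per-feature standardization
#'
#' Centers and scales each column to mean 0, SD 1 using the population SD
#' (divide by n) computed on the training rows only. Constant columns
#' (SD = 0) are mapped to 0 rather than dropped, so column indexing stays
#' stable across folds.
#'
#' @param X numeric training matrix (no missing values).
#' @return \code{fitStandardizer}: list with \code{mean} and \code{sd}
#'   vectors (one per column).
#' @export
fitStandardizer <- function(X) {
  stopifnot(is.matrix(X), !anyNA(X))
  m <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2L, m)^2))
  list(mean = m, sd = sd_pop)
}

#' @rdname fitStandardizer
#' @param params standardization parameters from \code{fitStandardizer}.
#' @param X matrix to transform (training or held-out rows).
#' @return \code{applyStandardizer}: the transformed matrix.
#' @export
applyStandardizer <- function(params, X) {
  stopifnot(is.matrix(X))
  if (ncol(X) != length(params$mean))
    stop(sprintf("feature count mismatch: params have %d, matrix has %d",
                 length(params$mean), ncol(X)))
  out <- sweep(X, 2L, params$mean)
  nz <- params$sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, params$sd[nz], "/")
  out[, !nz] <- 0
  out
}

#' Concatenate curated layers of a combination into one matrix
#'
#' Early/intermediate integration input: columns ordered layer-by-layer in
#' combination order, then feature order within each layer; column names are
#' globally unique feature refs (\code{"layer:feature"}). Missing cells are
#' an error — curation must precede concatenation.
#'
#' @param cohort a curated \linkS4class{ParallelCohort}.
#' @param combination character vector of layer ids (subset of the cohort's).
#' @return numeric matrix with feature-ref column names.
#' @export
concatMatrix <- function(cohort, combination) {
  stopifnot(is(cohort, "ParallelCohort"))
  missing_layers <- setdiff(combination, layerIds(cohort))
  if (length(missing_layers))
    stop("unknown layer id(s): ", paste(missing_layers, collapse = ", "))
  parts <- lapply(combination, function(id) {
    v <- layerValues(layers(cohort)[[id]])
    if (anyNA(v))
      stop(sprintf("layer '%s' has missing cells; curate before concatenation",
                   id))
    colnames(v) <- featureRef(id, colnames(v))
    v
  })
  do.call(cbind, parts)
}
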