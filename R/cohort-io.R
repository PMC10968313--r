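## cohort_model: data model and I/O for parallel multi-omics cohorts.

.missing_tokens_default <- c("", "NA", "NaN")

#' Read one omic layer from a delimited file
#'
#' The file must have a header row of feature ids and a first column of
#' sample ids (samples x features). Missing cells may be encoded by any of
#' the \code{missingTokens} (matched case-insensitively); any other
#' non-numeric cell is an error, so dialect drift fails loudly instead of
#' silently coercing.
#'
#' @param path path to a CSV/TSV file.
#' @param layerId short label for the layer (e.g. "P").
#' @param sep field delimiter; \code{","} (default) or \code{"\t"}.
#' @param missingTokens tokens treated as missing (case-insensitive).
#'   Default \code{c("", "NA", "NaN")}.
#' @param scaleBase log base of the stored values (\code{NA} = already
#'   linear). The study's deposited matrices are ingested on whatever scale
#'   they were exported; log-scale layers must be converted with
#'   \code{\link{delog}} before modelling.
#' @return an \linkS4class{OmicLayer}.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,f1,f2", "s1,1.5,2", "s2,NA,0.3"), tf)
#' readOmicLayer(tf, "M")
#' @export
readOmicLayer <- function(path, layerId, sep = ",",
                          missingTokens = .missing_tokens_default,
                          scaleBase = NA_real_) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) < 1L)
    stop("layer file must have a sample-id column plus >= 1 feature and >= 1 sample")
  samples <- raw[[1L]]
  features <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in ", path)
  if (anyDuplicated(features))
    stop("duplicate feature ids in ", path)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  is_missing <- matrix(tolower(trimws(cells)) %in%
                         tolower(missingTokens), nrow(cells), ncol(cells))
  vals <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  bad <- !is_missing & is.na(vals)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at sample '%s', feature '%s': '%s'",
                 samples[i[1L]], features[i[2L]], cells[i[1L], i[2L]]))
  }
  vals[is_missing] <- NA_real_
  dimnames(vals) <- list(samples, features)
  new("OmicLayer", layerId = layerId, values = vals,
      scaleBase = as.numeric(scaleBase))
}

#' Write an omic layer back to a delimited file
#'
#' Inverse of \code{\link{readOmicLayer}}: header of feature ids, first
#' column \code{sample_id}, missing cells written as \code{NA}. Values are
#' written with full double precision (17 significant digits) so finite
#' cells round-trip bit-identically.
#'
#' @param layer an \linkS4class{OmicLayer}.
#' @param path output path.
#' @param sep field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeOmicLayer <- function(layer, path, sep = ",") {
  stopifnot(is(layer, "OmicLayer"))
  v <- layerValues(layer)
  chr <- array(sprintf("%.17g", v), dim(v))
  chr[is.na(v)] <- "NA"
  header <- paste(c("sample_id", colnames(v)), collapse = sep)
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], chr[i, ]), collapse = sep), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-label table
#'
#' Expects columns \code{sample_id} and \code{label}; labels may be
#' \code{control}/\code{case} (case-insensitive; \code{high-risk} is a
#' synonym for \code{case}) or \code{0}/\code{1}.
#'
#' @param path CSV path.
#' @param sep field delimiter.
#' @return named integer vector of 0/1 labels.
#' @export
readSampleLabels <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(tab)))
    stop("label file must have columns sample_id,label")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in label file")
  lab <- tolower(trimws(tab$label))
  out <- ifelse(lab %in% c("0", "control"), 0L,
                ifelse(lab %in% c("1", "case", "high-risk"), 1L, NA_integer_))
  if (anyNA(out))
    stop("unrecognized label(s): ",
         paste(unique(tab$label[is.na(out)]), collapse = ", "))
  names(out) <- tab$sample_id
  out
}

#' @describeIn delog Replace each non-missing cell x by base^x and mark the
#'   layer linear-scale. A layer already on linear scale is returned
#'   unchanged.
#' @param base log base; defaults to the layer's recorded \code{scaleBase}.
#' @export
setMethod("delog", "OmicLayer", function(layer, base = scaleBase(layer)) {
  if (is.na(scaleBase(layer)))
    return(layer)
  base <- as.numeric(base)
  if (is.na(base) || base <= 0 || base == 1)
    stop("log base must be positive and != 1")
  v <- base^layer@values
  if (any(is.infinite(v)))
    stop("delog produced non-finite values; check the recorded base")
  initialize(layer, values = v, scaleBase = NA_real_)
})

#' Assemble aligned layers and labels into a cohort
#'
#' Canonicalizes sample order (lexicographic sort of sample ids), applies it
#' to every layer and the labels, and validates alignment: every layer must
#' carry exactly the same sample set, labels must cover it, and both classes
#' must be present. Idempotent and independent of input row order.
#'
#' @param layerList list of \linkS4class{OmicLayer} objects.
#' @param labels named 0/1 vector (or a vector as returned by
#'   \code{\link{readSampleLabels}}).
#' @return a \linkS4class{ParallelCohort}.
#' @examples
#' l1 <- new("OmicLayer", layerId = "A",
#'           values = matrix(1:6, 3, 2,
#'                           dimnames = list(c("s1", "s2", "s3"),
#'                                           c("f1", "f2"))) * 1.0)
#' assembleCohort(list(l1), c(s1 = 0, s2 = 1, s3 = 1))
#' @export
assembleCohort <- function(layerList, labels) {
  if (length(layerList) < 1L)
    stop("at least one layer required")
  ref <- sort(sampleIds(layerList[[1L]]))
  for (l in layerList) {
    s <- sampleIds(l)
    if (!setequal(s, ref)) {
      diff <- c(setdiff(ref, s), setdiff(s, ref))
      stop(sprintf("layer '%s' sample set differs; symmetric difference: %s",
                   layerId(l), paste(sort(diff), collapse = ", ")))
    }
  }
  if (is.null(names(labels)))
    stop("labels must be named by sample id")
  miss <- setdiff(ref, names(labels))
  if (length(miss))
    stop("label missing for sample(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(labels), ref)
  if (length(extra))
    stop("label for unknown sample(s): ", paste(extra, collapse = ", "))
  lab <- as.integer(labels[ref])
  names(lab) <- ref
  if (length(unique(lab)) < 2L)
    stop("both classes (control and case) must be present")
  ordered <- lapply(layerList, function(l)
    initialize(l, values = layerValues(l)[ref, , drop = FALSE]))
  names(ordered) <- vapply(ordered, layerId, character(1))
  new("ParallelCohort", layers = ordered, labels = lab)
}

#' Cohort manifest
#'
#' Per-layer dimensions, missing-cell counts and scale metadata, as a plain
#' list suitable for JSON serialization.
#'
#' @param cohort a \linkS4class{ParallelCohort}.
#' @return list with elements \code{n_samples}, \code{n_control},
#'   \code{n_case} and \code{layers} (one entry per layer).
#' @export
cohortManifest <- function(cohort) {
  stopifnot(is(cohort, "ParallelCohort"))
  list(
    n_samples = length(cohort@labels),
    n_control = sum(cohort@labels == 0L),
    n_case = sum(cohort@labels == 1L),
    layers = lapply(layers(cohort), function(l) list(
      layer_id = layerId(l),
      n_features = ncol(layerValues(l)),
      n_missing_cells = sum(is.na(layerValues(l))),
      scale = if (is.na(scaleBase(l))) "linear"
              else sprintf("log%g", scaleBase(l)))))
}

#' Write a cohort to per-layer CSVs plus a labels CSV and manifest JSON
#'
#' @param cohort a \linkS4class{ParallelCohort}.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (l in layers(cohort)) {
    p <- file.path(dir, sprintf("layer_%s.csv", layerId(l)))
    writeOmicLayer(l, p)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "labels.csv")
  writeLines(c("sample_id,label",
               paste(names(cohort@labels), cohort@labels, sep = ",")), lp)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(cohortManifest(cohort), mp, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, lp, mp))
}
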