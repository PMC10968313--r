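## synthetic_data: generator of parallel multi-omics HDLSS cohorts with the
## statistical structure the pipeline assumes.

#' Synthetic quadra-omics cohort configuration
#'
#' Defaults emulate the study regime: four layers (P/M/L/T) with
#' pre-curation feature counts 2330/238/66/329, 4 control and 3 case
#' subjects, layer-specific missing-cell rates highest in metabolomics, and
#' positive log-normal intensities. Per-feature log10 means are drawn
#' uniformly from \code{mu0Range} and natural-log SDs from
#' \code{sigma0Range}; a planted feature's case log-mean is shifted by
#' \code{log(targetFC)} so its expected case/control intensity ratio equals
#' the target fold change exactly.
#'
#' @param featureCounts named integer vector: features per layer.
#' @param nControl,nCase class sizes (defaults 4 and 3).
#' @param missingRates named numeric vector in [0, 1): per-layer
#'   completely-at-random missing-cell rates.
#' @param mu0Range range of per-feature baseline log10 means.
#' @param sigma0Range range of per-feature natural-log SDs.
#' @param planted data.frame with columns \code{feature_ref} and
#'   \code{target_fc} (or NULL for none); refs must exist in the declared
#'   dimensions.
#' @param nPlanted,plantedFC convenience: when \code{planted} is NULL and
#'   \code{nPlanted > 0}, \code{nPlanted} planted features with fold change
#'   \code{plantedFC} are spread across layers proportionally to layer
#'   size.
#' @param seed integer generator seed.
#' @return list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(featureCounts = c(P = 2330L, M = 238L, L = 66L,
                                          T = 329L),
                        nControl = 4L, nCase = 3L,
                        missingRates = c(P = 0.05, M = 0.30, L = 0.01,
                                         T = 0.0),
                        mu0Range = c(1, 4), sigma0Range = c(0.1, 0.5),
                        planted = NULL, nPlanted = 0L, plantedFC = 3,
                        seed = 1L) {
  stopifnot(length(featureCounts) >= 1L, !is.null(names(featureCounts)),
            all(featureCounts >= 1L), nControl >= 1L, nCase >= 1L)
  missingRates <- missingRates[names(featureCounts)]
  missingRates[is.na(missingRates)] <- 0
  names(missingRates) <- names(featureCounts)
  if (any(missingRates < 0 | missingRates >= 1))
    stop("missing rates must lie in [0, 1)")
  cfg <- structure(list(featureCounts = as.integer(featureCounts) |>
                          stats::setNames(names(featureCounts)),
                        nControl = as.integer(nControl),
                        nCase = as.integer(nCase),
                        missingRates = missingRates,
                        mu0Range = mu0Range, sigma0Range = sigma0Range,
                        planted = planted, seed = as.integer(seed)),
                   class = "SynthConfig")
  if (is.null(planted) && nPlanted > 0L) {
    ids <- names(featureCounts)
    share <- featureCounts / sum(featureCounts)
    alloc <- floor(nPlanted * share)
    rem <- nPlanted - sum(alloc)
    if (rem > 0) {
      ord <- order(-(nPlanted * share - alloc))
      alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
    }
    refs <- unlist(lapply(ids, function(id) {
      if (alloc[[id]] == 0L) return(character(0))
      featureRef(id, sprintf("%s_f%04d", id, seq_len(alloc[[id]])))
    }), use.names = FALSE)
    cfg$planted <- data.frame(feature_ref = refs,
                              target_fc = rep(plantedFC, length(refs)),
                              stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$planted)) {
    if (any(cfg$planted$target_fc <= 0))
      stop("target fold changes must be positive")
    lay <- featureRefLayer(cfg$planted$feature_ref)
    idx <- suppressWarnings(as.integer(sub("^.*_f", "", cfg$planted$feature_ref)))
    bad <- is.na(idx) | !(lay %in% names(featureCounts)) |
      idx > featureCounts[lay]
    bad[is.na(bad)] <- TRUE
    if (any(bad))
      stop("planted feature ref(s) outside declared dimensions: ",
           paste(cfg$planted$feature_ref[bad], collapse = ", "))
  }
  cfg
}

#' Generate a synthetic parallel cohort with ground truth
#'
#' Intensities are log-normal: for feature j of a layer, measurement
#' \code{exp(rnorm(mu_j + case * log(fc_j), sigma_j))} with
#' \code{mu_j = log(10) * U(mu0Range)} and \code{sigma_j = U(sigma0Range)};
#' \code{fc_j} is 1 except for planted features. Missing cells are then
#' injected independently at the layer's rate. Deterministic given the
#' config seed; sample ids are \code{S1..S<n>} with controls first, so the
#' canonical (sorted) order interleaves predictably for n <= 9.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list with \code{cohort} (a \linkS4class{ParallelCohort}, missing
#'   cells included) and \code{groundTruth} (list: planted data.frame with
#'   realized class means, seed).
#' @export
generateCohort <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  n0 <- config$nControl
  n1 <- config$nCase
  n <- n0 + n1
  samples <- sprintf("S%d", seq_len(n))
  y <- stats::setNames(c(rep(0L, n0), rep(1L, n1)), samples)
  planted <- config$planted
  withSeed(config$seed, {
    layerList <- lapply(names(config$featureCounts), function(id) {
      p <- config$featureCounts[[id]]
      feats <- sprintf("%s_f%04d", id, seq_len(p))
      mu <- log(10) * stats::runif(p, config$mu0Range[1], config$mu0Range[2])
      sig <- stats::runif(p, config$sigma0Range[1], config$sigma0Range[2])
      shift <- rep(0, p)
      if (!is.null(planted)) {
        here <- planted[featureRefLayer(planted$feature_ref) == id, ]
        if (nrow(here)) {
          j <- match(featureRefFeature(here$feature_ref), feats)
          shift[j] <- log(here$target_fc)
        }
      }
      logv <- matrix(stats::rnorm(n * p), n, p)
      logv <- sweep(logv, 2L, sig, "*")
      logv <- sweep(logv, 2L, mu, "+")
      logv[y == 1L, ] <- sweep(logv[y == 1L, , drop = FALSE], 2L, shift, "+")
      v <- exp(logv)
      rate <- config$missingRates[[id]]
      if (rate > 0) {
        mask <- matrix(stats::runif(n * p) < rate, n, p)
        v[mask] <- NA_real_
      }
      dimnames(v) <- list(samples, feats)
      new("OmicLayer", layerId = id, values = v, scaleBase = NA_real_)
    })
    cohort <- assembleCohort(layerList, y)
    gt_planted <- if (is.null(planted)) {
      data.frame(feature_ref = character(0), target_fc = numeric(0))
    } else {
      means <- t(vapply(seq_len(nrow(planted)), function(i) {
        ref <- planted$feature_ref[i]
        v <- layerValues(layers(cohort)[[featureRefLayer(ref)]])[,
               featureRefFeature(ref)]
        yy <- sampleLabels(cohort)
        c(mean(v[yy == 0L], na.rm = TRUE), mean(v[yy == 1L], na.rm = TRUE))
      }, numeric(2)))
      cbind(planted,
            data.frame(realized_control_mean = means[, 1L],
                       realized_case_mean = means[, 2L]))
    }
    list(cohort = cohort,
         groundTruth = list(planted = gt_planted, seed = config$seed))
  })
}

#' Generate a null cohort (no planted signal)
#'
#' Identical to \code{\link{generateCohort}} with an empty planted list;
#' labels carry no association with any feature. Used for
#' permutation-test calibration.
#'
#' @param config a \code{\link{synthConfig}}; any planted list is dropped.
#' @return as \code{\link{generateCohort}}.
#' @export
generateNullCohort <- function(config = synthConfig()) {
  config$planted <- NULL
  generateCohort(config)
}
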