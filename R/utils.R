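## Internal helpers shared across modules.

#' Run an expression under a private RNG stream
#'
#' Saves and restores \code{.Random.seed} so package internals never disturb
#' the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic seed derivation; keeps derived seeds inside 32-bit range.
mixSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 1000003) %% 2147483629)
}

#' Compose and split globally unique feature references
#'
#' A feature reference is the string \code{"<layer_id>:<feature_id>"}; the
#' layer prefix makes feature ids that recur across omic layers globally
#' unique, so selection and reporting can operate on flat sets.
#'
#' @param layerId character vector of layer ids.
#' @param featureId character vector of feature ids.
#' @return \code{featureRef}: character vector of references.
#' @examples
#' featureRef("P", c("ALB", "APOA1"))
#' featureRefLayer(c("P:ALB", "T:miR-21"))
#' @export
featureRef <- function(layerId, featureId) {
  stopifnot(is.character(layerId) || is.factor(layerId),
            is.character(featureId))
  if (any(grepl(":", layerId, fixed = TRUE)))
    stop("layer ids must not contain ':'")
  paste(as.character(layerId), featureId, sep = ":")
}

#' @rdname featureRef
#' @param ref character vector of feature references.
#' @return \code{featureRefLayer}: the layer-id component of each reference.
#' @export
featureRefLayer <- function(ref) {
  sub(":.*$", "", ref)
}

#' @rdname featureRef
#' @return \code{featureRefFeature}: the feature-id component of each
#'   reference.
#' @export
featureRefFeature <- function(ref) {
  sub("^[^:]*:", "", ref)
}

## Format a combination as the display string used throughout outputs,
## e.g. c("P","M","L") -> "P+M+L".
comboString <- function(combination) {
  paste(combination, collapse = "+")
}
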