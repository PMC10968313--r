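## augment: smoothed-bootstrap oversampling of the training set.

#' Augmentation configuration
#'
#' @param nPerClass virtual subjects generated per class (default 500, so a
#'   6-subject training fold becomes 1000 balanced virtual observations).
#' @param smoothing non-negative shrinkage scalar s multiplying the
#'   Silverman-style bandwidth; 0 reduces to a plain within-class bootstrap.
#' @param seed integer seed for the augmentation stream.
#' @return list of class \code{"AugmentConfig"}.
#' @export
augmentConfig <- function(nPerClass = 500L, smoothing = 1.0, seed = 1L) {
  nPerClass <- as.integer(nPerClass)
  if (is.na(nPerClass) || nPerClass < 1L)
    stop("nPerClass must be a positive integer")
  if (smoothing < 0)
    stop("smoothing must be non-negative")
  structure(list(nPerClass = nPerClass, smoothing = smoothing,
                 seed = as.integer(seed)),
            class = "AugmentConfig")
}

#' Smoothed-bootstrap oversampling to a balanced augmented set
#'
#' Each virtual observation is a uniformly resampled original row of its
#' class plus independent Gaussian noise per feature with standard deviation
#' \code{h_c * sigma_jc}, where \code{sigma_jc} is the within-class
#' per-feature SD and \code{h_c = s * n_c^(-1/(d+4))} is a Silverman-style
#' bandwidth for class size \code{n_c} and dimension \code{d}. The output
#' contains exactly \code{nPerClass} rows per class (originals are not
#' included), so class balance is exact regardless of input imbalance, and
#' with \code{s > 0} no virtual row coincides with an original.
#'
#' @param X numeric matrix of standardized training rows (no missing
#'   values).
#' @param y 0/1 labels, one per row of \code{X}; both classes required.
#' @param config an \code{\link{augmentConfig}}.
#' @return list with \code{X} ((2 * nPerClass) x d matrix) and \code{y}
#'   (0/1 vector); class-0 rows first. Deterministic given
#'   \code{config$seed}.
#' @examples
#' X <- matrix(rnorm(12), 4, 3)
#' aug <- smoothedBootstrap(X, c(0, 0, 1, 1), augmentConfig(nPerClass = 10))
#' table(aug$y)
#' @export
smoothedBootstrap <- function(X, y, config = augmentConfig()) {
  stopifnot(is.matrix(X), !anyNA(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be 0/1")
  classes <- c(0L, 1L)
  if (!all(classes %in% y))
    stop("both classes must be present in the training labels")
  d <- ncol(X)
  n <- config$nPerClass
  sd_pop <- function(M) sqrt(colMeans(sweep(M, 2L, colMeans(M))^2))
  withSeed(config$seed, {
    parts <- lapply(classes, function(cl) {
      rows <- which(y == cl)
      n_c <- length(rows)
      Xc <- X[rows, , drop = FALSE]
      if (config$smoothing > 0) {
        if (n_c == 1L) {
          warning(sprintf(
            "class %d has a single member; noise SD falls back to the pooled per-feature SD",
            cl))
          sigma <- sd_pop(X)
        } else {
          sigma <- sd_pop(Xc)
        }
        h <- config$smoothing * n_c^(-1 / (d + 4))
        noise_sd <- h * sigma
      } else {
        noise_sd <- rep(0, d)
      }
      picks <- sample.int(n_c, n, replace = TRUE)
      noise <- matrix(stats::rnorm(n * d), n, d) *
        matrix(noise_sd, n, d, byrow = TRUE)
      Xc[picks, , drop = FALSE] + noise
    })
    Xa <- do.call(rbind, parts)
    rownames(Xa) <- sprintf("v%04d_c%d", seq_len(2L * n), rep(classes, each = n))
    list(X = Xa, y = rep(classes, each = n))
  })
}
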