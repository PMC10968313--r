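# Shared fixtures, built in code.

# Minimal hand-built layer: values matrix with dimnames, linear scale.
makeLayer <- function(id, values) {
  new("OmicLayer", layerId = id, values = values, scaleBase = NA_real_)
}

# A tiny complete two-layer cohort (7 samples, 4 control / 3 case) with a
# crude planted separation in the first feature of each layer.
tinyCohort <- function(pA = 6L, pB = 4L, seed = 42L) {
  set.seed(seed)
  samples <- sprintf("S%d", 1:7)
  y <- stats::setNames(c(0L, 0L, 0L, 0L, 1L, 1L, 1L), samples)
  mk <- function(id, p) {
    v <- matrix(exp(rnorm(7 * p, mean = 2, sd = 0.3)), 7, p,
                dimnames = list(samples, sprintf("%s_f%04d", id, seq_len(p))))
    v[, 1] <- v[, 1] * ifelse(y == 1L, 3, 1)   # planted fold change 3
    makeLayer(id, v)
  }
  assembleCohort(list(mk("A", pA), mk("B", pB)), y)
}

# Small augmentation config so unit tests stay fast.
fastAug <- function(n = 25L, s = 1, seed = 1L) {
  augmentConfig(nPerClass = n, smoothing = s, seed = seed)
}

# Standardized matrix + labels drawn from a logistic model, for learner
# tests.
logisticToy <- function(n = 60L, p = 5L, w = c(2, rep(0, 4)), b = 0,
                        seed = 9L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, featureRef("A", sprintf("f%d", 1:p))))
  prob <- plogis(b + X %*% w[seq_len(p)])
  y <- as.integer(runif(n) < prob)
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}
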