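test_that("LR separates a 1-D separable toy and rejects constant labels", {
  X <- matrix(c(-1, -1, 1, 1), 4, 1,
              dimnames = list(NULL, featureRef("A", "f1")))
  y <- c(0L, 0L, 1L, 1L)
  m <- fitLR(X, y)
  expect_gt(m@coefficients[["A:f1"]], 0)
  expect_identical(as.integer(predictProba(m, X) > 0.5), y)

  expect_error(fitLR(X, c(1L, 1L, 1L, 1L)), "both classes")
})

test_that("LR recovers known logistic parameters within 3 SE (glm oracle)", {
  set.seed(10)
  n <- 200L
  x <- rnorm(n)
  prob <- plogis(0 + 1.5 * x)
  y <- as.integer(runif(n) < prob)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, featureRef("A", "f1")))
  m <- fitLR(X, y)
  oracle <- glm(y ~ x, family = binomial())
  se <- summary(oracle)$coefficients["x", "Std. Error"]
  expect_lt(abs(m@coefficients[["A:f1"]] - 1.5), 3 * se)
  # and the weak-ridge surrogate agrees with unpenalized ML here
  expect_lt(abs(m@coefficients[["A:f1"]] - coef(oracle)[["x"]]), 0.05)
})

test_that("penalized tuning lands the selected count nearest the 20% target", {
  toy <- logisticToy(n = 40L, p = 10L, w = c(2, -1.5, 1, rep(0, 7)))
  spec <- learnerSpec("LASSO", retention = 0.2)
  m <- tuneAndFitPenalized(toy$X, toy$y, spec)
  target <- ceiling(0.2 * 10)
  # the winner must be the grid-achievable count closest to the target
  fitAll <- glmnet::glmnet(toy$X, toy$y, family = "binomial", alpha = 1,
                           lambda = rev(spec$lambdaGrid), standardize = FALSE)
  achievable <- colSums(abs(as.matrix(fitAll$beta)) > spec$epsilon)
  expect_identical(as.integer(abs(length(selectFeatures(m, spec)) - target)),
                   as.integer(min(abs(achievable - target))))

  # heavy-penalty limit: max-grid LASSO on weak data zeroes everything
  weak <- logisticToy(n = 20L, p = 8L, w = rep(0, 8), seed = 30L)
  mWeak <- tuneAndFitPenalized(
    weak$X, weak$y, learnerSpec("LASSO", lambdaGrid = 1e4, retention = 0.99))
  expect_length(selectFeatures(mWeak, learnerSpec("LASSO")), 0L)

  expect_error(learnerSpec("LASSO", lambdaGrid = numeric(0)))
  expect_error(tuneAndFitPenalized(toy$X, toy$y, learnerSpec("LR")),
               "LASSO or RIDGE")
})

test_that("LASSO selected-count is non-increasing in lambda over the grid", {
  set.seed(1)
  X <- matrix(rnorm(20 * 50), 20, 50,
              dimnames = list(NULL, featureRef("A", sprintf("f%02d", 1:50))))
  y <- as.integer(X[, 1] - X[, 2] + rnorm(20, sd = 0.5) > 0)
  spec <- learnerSpec("LASSO")
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                   lambda = rev(spec$lambdaGrid), standardize = FALSE))
  counts <- colSums(abs(as.matrix(fit$beta)) > spec$epsilon)
  # fit$lambda is decreasing, so counts must be non-decreasing along it
  expect_true(all(diff(counts) >= 0))
  # heavy-shrinkage end empties the model entirely
  expect_identical(unname(counts[1]), 0)
})

test_that("selection rules: epsilon threshold for LASSO/LR, top-20% for RIDGE", {
  w <- c(0, 0.3, -0.2)
  names(w) <- featureRef("A", c("f1", "f2", "f3"))
  mL <- new("FittedModel", family = "LASSO", coefficients = w,
            intercept = 0, lambda = 0.1)
  expect_identical(selectFeatures(mL, learnerSpec("LASSO")),
                   c("A:f2", "A:f3"))

  w0 <- setNames(rep(0, 3), names(w))
  m0 <- new("FittedModel", family = "LASSO", coefficients = w0,
            intercept = 0, lambda = 0.1)
  expect_length(selectFeatures(m0, learnerSpec("LASSO")), 0L)

  # RIDGE: exactly ceiling(0.2 * 20) = 4, equal to brute-force top-|w|
  set.seed(13)
  wr <- setNames(rnorm(20), featureRef("A", sprintf("f%02d", 1:20)))
  mR <- new("FittedModel", family = "RIDGE", coefficients = wr,
            intercept = 0, lambda = 1)
  got <- selectFeatures(mR, learnerSpec("RIDGE", retention = 0.2))
  expect_length(got, 4L)
  expect_setequal(got, names(sort(abs(wr), decreasing = TRUE))[1:4])
})

test_that("predicted probabilities equal the closed-form logistic", {
  set.seed(14)
  p <- 6L
  w <- setNames(rnorm(p), featureRef("A", sprintf("f%d", 1:p)))
  m <- new("FittedModel", family = "LR", coefficients = w,
           intercept = 0.7, lambda = NA_real_)
  X <- matrix(rnorm(5 * p), 5, p, dimnames = list(NULL, names(w)))
  expect_equal(predictProba(m, X),
               as.numeric(1 / (1 + exp(-(0.7 + X %*% w)))),
               tolerance = 1e-12)

  # symmetric case: zero model gives exactly 0.5
  m0 <- new("FittedModel", family = "LR",
            coefficients = setNames(numeric(p), names(w)),
            intercept = 0, lambda = NA_real_)
  expect_identical(unique(predictProba(m0, X)), 0.5)

  # saturation
  mSat <- new("FittedModel", family = "LR",
              coefficients = setNames(numeric(p), names(w)),
              intercept = 50, lambda = NA_real_)
  expect_gt(min(predictProba(mSat, X)), 1 - 1e-9)

  expect_error(predictProba(m, matrix(0, 2, 2)), "mismatch")
})

test_that("penalized fits are deterministic and equivariant to column permutation", {
  toy <- logisticToy(n = 30L, p = 8L, w = c(1.5, -1, rep(0, 6)), seed = 15L)
  spec <- learnerSpec("LASSO")
  m1 <- tuneAndFitPenalized(toy$X, toy$y, spec)
  m2 <- tuneAndFitPenalized(toy$X, toy$y, spec)
  expect_identical(m1@coefficients, m2@coefficients)

  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  m3 <- tuneAndFitPenalized(toy$X[, perm], toy$y, spec)
  expect_equal(m3@coefficients[names(m1@coefficients)],
               m1@coefficients, tolerance = 1e-6)
})
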