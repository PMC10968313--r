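test_that("strategy pairing rules are enforced", {
  expect_error(integrationStrategy("early", "LASSO"), "only with LR")
  expect_error(integrationStrategy("intermediate", "LR"), "LASSO or RIDGE")
  expect_s3_class(integrationStrategy("late", "RIDGE"),
                  "IntegrationStrategy")
  expect_identical(paradigmStrategy("MULTI-VIEW LASSO")$stage, "late")
  expect_identical(paradigmStrategy("LR")$stage, "early")
  expect_identical(paradigmStrategy("RIDGE")$stage, "intermediate")
  expect_length(paradigms(), 6L)
})

test_that("late integration builds one base learner per layer; single layer errors", {
  coh <- tinyCohort(pA = 5L, pB = 4L)
  X <- concatMatrix(coh, c("A", "B"))
  y <- sampleLabels(coh)
  Z <- applyStandardizer(fitStandardizer(X), X)
  m <- fitIntegrated(Z, y, c("A", "B"), integrationStrategy("late", "LR"))
  expect_s4_class(m, "MultiViewModel")
  expect_identical(names(m@models), c("A", "B"))
  expect_length(m@models$A@coefficients, 5L)
  expect_length(m@models$B@coefficients, 4L)

  expect_error(
    fitIntegrated(Z[, 1:5], y, "A", integrationStrategy("late", "LR")),
    "at least two layers")
})

test_that("early integration equals a direct LR fit on the concatenation", {
  coh <- tinyCohort(pA = 3L, pB = 2L)
  X <- concatMatrix(coh, c("A", "B"))
  y <- sampleLabels(coh)
  Z <- applyStandardizer(fitStandardizer(X), X)
  early <- fitIntegrated(Z, y, c("A", "B"), integrationStrategy("early", "LR"))
  direct <- fitLR(Z, y)
  expect_identical(early@coefficients, direct@coefficients)
  expect_identical(early@intercept, direct@intercept)
})

test_that("consensus is the arithmetic mean with a strict threshold", {
  # base learners that emit fixed probabilities via intercept-only models
  fixed <- function(p, cols) {
    new("FittedModel", family = "LR",
        coefficients = setNames(numeric(length(cols)), cols),
        intercept = qlogis(p), lambda = NA_real_)
  }
  cols <- lapply(c("A", "B", "C", "D"), function(id)
    featureRef(id, paste0(id, "_f1")))
  probs <- c(0.9, 0.8, 0.2, 0.7)
  mods <- Map(fixed, probs, cols)
  names(mods) <- c("A", "B", "C", "D")
  mv <- new("MultiViewModel", models = mods, threshold = 0.5,
            vote = "probability")
  x <- setNames(rep(0, 4), unlist(cols))
  out <- consensusPredict(mv, x)
  expect_equal(out$score, 0.65, tolerance = 1e-12)
  expect_identical(out$label, 1L)

  # tie at theta classifies as control (strict inequality)
  mv2 <- new("MultiViewModel", models = mods[1:2], threshold = 0.5,
             vote = "probability")
  x2 <- setNames(rep(0, 2), unlist(cols[1:2]))
  mv2@models[[1]]@intercept <- qlogis(0.5)
  mv2@models[[2]]@intercept <- qlogis(0.5)
  out2 <- consensusPredict(mv2, x2)
  expect_identical(out2$score, 0.5)
  expect_identical(out2$label, 0L)

  # missing layer slice errors
  expect_error(consensusPredict(mv, x[1:2]), "missing layer")
})

test_that("consensus equals majority vote for hard votes over all patterns (k <= 5)", {
  for (k in c(3L, 5L)) {
    ids <- LETTERS[seq_len(k)]
    cols <- vapply(ids, function(id) featureRef(id, "f1"), character(1))
    x <- setNames(rep(0, k), cols)
    patterns <- expand.grid(rep(list(c(0L, 1L)), k))
    for (r in seq_len(nrow(patterns))) {
      votes <- as.integer(patterns[r, ])
      mods <- lapply(seq_len(k), function(j)
        new("FittedModel", family = "LR",
            coefficients = setNames(0, cols[j]),
            # saturated intercepts make the base probabilities 0 or 1
            intercept = if (votes[j] == 1L) 500 else -500,
            lambda = NA_real_))
      names(mods) <- ids
      mv <- new("MultiViewModel", models = mods, threshold = 0.5,
                vote = "probability")
      expect_identical(consensusPredict(mv, x)$label,
                       as.integer(sum(votes) > k / 2))
    }
  }
})

test_that("consensus is layer-permutation invariant and idempotent on equal scores", {
  coh <- tinyCohort(pA = 4L, pB = 3L)
  X <- concatMatrix(coh, c("A", "B"))
  y <- sampleLabels(coh)
  Z <- applyStandardizer(fitStandardizer(X), X)
  mv <- fitIntegrated(Z, y, c("A", "B"), integrationStrategy("late", "LR"))
  mvRev <- mv
  mvRev@models <- rev(mv@models)
  expect_equal(consensusPredict(mv, Z)$score,
               consensusPredict(mvRev, Z)$score, tolerance = 1e-15)

  # all base learners emitting probability p give consensus p
  cols <- c(featureRef("A", "f1"), featureRef("B", "f1"))
  mods <- lapply(1:2, function(j)
    new("FittedModel", family = "LR", coefficients = setNames(0, cols[j]),
        intercept = qlogis(0.73), lambda = NA_real_))
  names(mods) <- c("A", "B")
  mvP <- new("MultiViewModel", models = mods, threshold = 0.5,
             vote = "probability")
  expect_equal(consensusPredict(mvP, setNames(c(0, 0), cols))$score, 0.73,
               tolerance = 1e-12)
})

test_that("label-vote mode thresholds base predictions before averaging", {
  cols <- c(featureRef("A", "f1"), featureRef("B", "f1"),
            featureRef("C", "f1"))
  probs <- c(0.6, 0.55, 0.1)     # mean 0.4167 but 2/3 hard votes
  mods <- lapply(1:3, function(j)
    new("FittedModel", family = "LR", coefficients = setNames(0, cols[j]),
        intercept = qlogis(probs[j]), lambda = NA_real_))
  names(mods) <- c("A", "B", "C")
  x <- setNames(rep(0, 3), cols)
  soft <- new("MultiViewModel", models = mods, threshold = 0.5,
              vote = "probability")
  hard <- new("MultiViewModel", models = mods, threshold = 0.5,
              vote = "label")
  expect_identical(consensusPredict(soft, x)$label, 0L)
  expect_identical(consensusPredict(hard, x)$label, 1L)
})

test_that("selected features of an ensemble are the union over base learners", {
  coh <- tinyCohort(pA = 6L, pB = 5L)
  X <- concatMatrix(coh, c("A", "B"))
  y <- sampleLabels(coh)
  Z <- applyStandardizer(fitStandardizer(X), X)
  spec <- learnerSpec("LASSO")
  mv <- fitIntegrated(Z, y, c("A", "B"),
                      integrationStrategy("late", "LASSO"), spec = spec)
  manual <- union(selectFeatures(mv@models$A, spec),
                  selectFeatures(mv@models$B, spec))
  expect_setequal(modelSelectedFeatures(mv, spec), manual)
})
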