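test_that("curation keeps exactly the all-complete features", {
  v <- matrix(1.0, 3, 3,
              dimnames = list(c("s1", "s2", "s3"), c("f1", "f2", "f3")))
  v[2, 2] <- NA
  res <- curateLayer(makeLayer("M", v))
  expect_identical(featureIds(res$layer), c("f1", "f3"))
  expect_identical(res$report$n_retained, 2L)

  # no missing cells: identity, retained fraction 1
  res2 <- curateLayer(makeLayer("M", v[, c(1, 3)]))
  expect_identical(res2$report$retained_fraction, 1)
  expect_identical(layerValues(res2$layer), v[, c(1, 3)])

  # all features incomplete is an error
  v3 <- v; v3[1, ] <- NA
  expect_error(curateLayer(makeLayer("M", v3)), "all features")

  # brute-force oracle on a random 7x50 missing mask
  set.seed(11)
  m <- matrix(rexp(350), 7, 50,
              dimnames = list(sprintf("s%d", 1:7), sprintf("f%02d", 1:50)))
  m[sample(length(m), 40)] <- NA
  brute <- sum(apply(m, 2, function(col) all(!is.na(col))))
  res3 <- curateLayer(makeLayer("P", m))
  expect_identical(res3$report$n_retained, as.integer(brute))

  # idempotence: curating a curated layer changes nothing
  again <- curateLayer(res3$layer)
  expect_identical(layerValues(again$layer), layerValues(res3$layer))
})

test_that("curation summary reproduces the study's totals and display percentages", {
  rep <- data.frame(layer_id = c("P", "M", "L", "T"),
                    n_original = c(2330L, 238L, 66L, 329L),
                    n_retained = c(1714L, 122L, 65L, 329L),
                    retained_fraction = c(1714 / 2330, 122 / 238, 65 / 66, 1))
  s <- curationSummary(rep)
  total <- s[s$layer_id == "TOTAL", ]
  expect_identical(total$n_retained, 2230L)
  expect_identical(s$retained_percent_display[s$layer_id == "P"], 74)
  expect_identical(s$retained_percent_display[s$layer_id == "L"], 98)
  expect_identical(s$retained_percent_display[s$layer_id == "T"], 100)
})

test_that("combination enumeration is the ordered power set minus the empty set", {
  quad <- enumerateCombinations(c("P", "M", "L", "T"))
  expect_length(quad, 15L)
  sizes <- lengths(quad)
  expect_identical(as.integer(table(sizes)), c(4L, 6L, 4L, 1L))
  expect_true(!is.unsorted(sizes))                     # size-ascending
  expect_identical(quad[[15]], c("P", "M", "L", "T"))  # layer order kept

  expect_identical(enumerateCombinations("L"), list("L"))
  expect_error(enumerateCombinations(character(0)))
  expect_error(enumerateCombinations(c("A", "A")))

  # brute-force power-set oracle for k <= 6
  for (k in c(3L, 5L, 6L)) {
    ids <- LETTERS[seq_len(k)]
    combos <- enumerateCombinations(ids)
    expect_length(combos, 2L^k - 1L)
    keys <- vapply(combos, function(s) paste(sort(s), collapse = ","),
                   character(1))
    brute <- unlist(lapply(seq_len(k), function(sz)
      utils::combn(ids, sz, FUN = function(s) paste(sort(s), collapse = ","),
                   simplify = FALSE)))
    expect_setequal(keys, brute)
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("standardization uses train-only population moments; SD-0 maps to 0", {
  X <- matrix(c(1, 3, 5, 5), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  p <- fitStandardizer(X)
  expect_identical(unname(p$mean), c(2, 5))
  expect_identical(unname(p$sd), c(1, 0))
  Z <- applyStandardizer(p, X)
  expect_identical(unname(Z[, "a"]), c(-1, 1))
  expect_identical(unname(Z[, "b"]), c(0, 0))

  expect_error(applyStandardizer(p, X[, 1, drop = FALSE]), "mismatch")

  # numeric check: post-transform means ~0, population SDs ~1
  set.seed(5)
  M <- matrix(rnorm(180, sd = 4), 6, 30)
  Z2 <- applyStandardizer(fitStandardizer(M), M)
  expect_lt(max(abs(colMeans(Z2))), 1e-10)
  popSd <- sqrt(colMeans(sweep(Z2, 2, colMeans(Z2))^2))
  expect_lt(max(abs(popSd - 1)), 1e-10)
})

test_that("concatenation orders columns layer-by-layer with feature refs", {
  coh <- tinyCohort(pA = 3L, pB = 2L)
  X <- concatMatrix(coh, c("A", "B"))
  expect_identical(ncol(X), 5L)
  expect_identical(colnames(X)[1:3], featureRef("A", featureIds(layers(coh)$A)))
  expect_identical(colnames(X)[4:5], featureRef("B", featureIds(layers(coh)$B)))

  # single-layer combination: values unchanged
  XA <- concatMatrix(coh, "A")
  expect_identical(unname(XA), unname(layerValues(layers(coh)$A)))

  # missing cells must be curated first
  v <- layerValues(layers(coh)$A); v[1, 1] <- NA
  dirty <- assembleCohort(list(makeLayer("A", v), layers(coh)$B),
                          sampleLabels(coh))
  expect_error(concatMatrix(dirty, c("A", "B")), "curate")

  # column count equals the per-layer sum for all 15 quadra combinations
  cfg <- synthConfig(featureCounts = c(P = 9L, M = 7L, L = 5L, T = 3L),
                     missingRates = c(P = 0, M = 0, L = 0, T = 0),
                     seed = 2L)
  coh4 <- generateCohort(cfg)$cohort
  sizes <- c(P = 9L, M = 7L, L = 5L, T = 3L)
  for (combo in enumerateCombinations(c("P", "M", "L", "T")))
    expect_identical(ncol(concatMatrix(coh4, combo)),
                     as.integer(sum(sizes[combo])))
})

test_that("curation then concatenation yields a complete matrix", {
  cfg <- synthConfig(featureCounts = c(A = 40L, B = 30L),
                     missingRates = c(A = 0.2, B = 0.1), seed = 8L)
  coh <- generateCohort(cfg)$cohort
  cur <- curateCohort(coh)
  X <- concatMatrix(cur$cohort, c("A", "B"))
  expect_false(anyNA(X))
  expect_identical(ncol(X), sum(cur$report$n_retained))
})
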