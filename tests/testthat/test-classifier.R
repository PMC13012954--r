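test_that("training and prediction are deterministic for a fixed seed", {
  d <- separableFeatures(30, seed = 5)
  m1 <- trainStageClassifier(d$features, d$labels, seed = 9)
  m2 <- trainStageClassifier(d$features, d$labels, seed = 9)
  expect_identical(classifyAndTally(m1, d$features)$labels,
                   classifyAndTally(m2, d$features)$labels)
  expect_identical(featureImportances(m1), featureImportances(m2))
})

test_that("label problems are reported explicitly", {
  d <- separableFeatures(10, seed = 2)
  empty <- factor(d$labels, levels = c(stageLevels(), "mitotic"))
  expect_error(trainStageClassifier(d$features, empty), "0 examples")
  expect_error(trainStageClassifier(d$features, rep("blob", nrow(d$features))),
               "labels must be one of")
  ann <- data.frame(cell_ref = c(1L, nrow(d$features) + 1L),
                    label = c("negative", "dead"))
  expect_error(trainStageClassifier(d$features, ann), "not in the feature")
  expect_error(trainStageClassifier(d$features[, ] * 0 + 1, d$labels),
               "informative")
})

test_that("cross-validation is stratified and perfect on separable classes", {
  d <- separableFeatures(25, seed = 1)
  cv <- crossValidate(d$features, d$labels, k = 5, seed = 4)
  expect_equal(unname(cv$metrics$f1), rep(1, 5))
  expect_equal(unname(diag(cv$confusion)), rep(1, 5))
  expect_equal(unname(rowSums(cv$confusion)), rep(1, 5))
  expect_equal(sum(cv$confusionCounts), nrow(d$features))
  expect_error(crossValidate(d$features[1:30, ], d$labels[1:30], k = 20),
               "fewer than k")
})

test_that("shuffled labels give chance-level accuracy", {
  d <- separableFeatures(200, seed = 6)   # n = 1000
  set.seed(77)
  shuffled <- sample(d$labels)
  cv <- crossValidate(d$features, shuffled, k = 5, seed = 8)
  acc <- sum(diag(cv$confusionCounts)) / sum(cv$confusionCounts)
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(acc - 0.2), 3 * se)
})

test_that("Gini importances are normalised and rank the informative feature", {
  set.seed(10)
  n <- 100
  labels <- rep(stageLevels(), each = n / 5)
  feats <- data.frame(informative = as.integer(factor(labels)) +
                        rnorm(n, 0, 0.05),
                      noiseA = rnorm(n), noiseB = rnorm(n), noiseC = rnorm(n))
  m <- trainStageClassifier(feats, labels, seed = 3)
  imp <- featureImportances(m)
  expect_equal(sum(imp), 1)
  expect_true(all(imp >= 0))
  expect_equal(names(imp)[1], "informative")
  expect_gt(imp[[1]], 0.5)
  expect_length(featureImportances(m, top = 2), 2L)
})

test_that("pure-noise features get near-uniform importances", {
  set.seed(12)
  n <- 150
  labels <- sample(rep(stageLevels(), each = n / 5))
  feats <- as.data.frame(matrix(rnorm(n * 6), n,
                                dimnames = list(NULL, paste0("n", 1:6))))
  m <- trainStageClassifier(feats, labels, nTrees = 200, seed = 5)
  imp <- featureImportances(m)
  expect_lt(max(imp) / min(imp), 3)
})

test_that("hit tables conserve cell counts per image", {
  d <- separableFeatures(20, seed = 3)
  feats <- d$features
  feats$well <- rep(c("B1", "B2"), length.out = nrow(feats))
  feats$hours_elapsed <- rep(c(0, 1), each = nrow(feats) / 2)
  m <- trainStageClassifier(feats, d$labels, seed = 2)
  ct <- classifyAndTally(m, feats)
  expect_equal(length(ct$labels), nrow(feats))
  ht <- ct$hitTable
  expect_equal(unname(rowSums(ht[, stageLevels()])), ht$total)
  expect_equal(sum(ht$total), nrow(feats))
  expect_equal(as.integer(table(ct$labels)[stageLevels()]),
               unname(colSums(ht[, stageLevels()])))
})

test_that("empty input yields empty, well-formed output", {
  d <- separableFeatures(10, seed = 4)
  m <- trainStageClassifier(d$features, d$labels, seed = 1)
  ct <- classifyAndTally(m, d$features[0, , drop = FALSE])
  expect_equal(length(ct$labels), 0L)
  expect_equal(nrow(ct$hitTable), 0L)
  expect_true(all(stageLevels() %in% names(ct$hitTable)))
})

test_that("a model with fewer classes still emits full five-class tallies", {
  d <- separableFeatures(20, seed = 8)
  keep <- d$labels %in% c("negative", "dead")
  m <- trainStageClassifier(d$features[keep, ], d$labels[keep], seed = 6)
  ct <- classifyAndTally(m, d$features[keep, ])
  expect_true(all(as.character(ct$labels) %in% c("negative", "dead")))
  expect_equal(sum(ct$hitTable[, c("spread", "disintegrated", "netosis")]), 0L)
})

test_that("constant features do not affect predictions", {
  d <- separableFeatures(20, seed = 9)
  m1 <- trainStageClassifier(d$features, d$labels, seed = 7)
  aug <- d$features
  aug$always_5 <- 5
  m2 <- trainStageClassifier(aug, d$labels, seed = 7)
  expect_identical(classifyAndTally(m1, d$features)$labels,
                   classifyAndTally(m2, aug)$labels)
  # but prediction with a mismatched schema is refused
  expect_error(predictStageMatrix(m1, d$features[, 1:2]), "schema")
})

test_that("pairwise feature tests flag the separating feature", {
  d <- separableFeatures(15, seed = 11)
  pw <- pairwiseFeatureTests(d$features, d$labels,
                             whichFeatures = c("f1", "f3"))
  f1p <- pw$p_adjusted[pw$feature == "f1"]
  f3p <- pw$p_adjusted[pw$feature == "f3"]
  expect_true(all(f1p < 0.01))
  expect_gt(min(f3p), 0.05)
  expect_equal(nrow(pw), 2 * choose(5, 2))
})
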