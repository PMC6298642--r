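# Benchmark property checks run on scaled-down generator configurations
# (120-300 promoters, 24-60 marks per region) so the full suite stays
# fast; the full-scale contrast lives in the acceptance checks.

betaConfig <- function(seed, nPromoters = 150L, ...) {
  generatorConfig(nPromoters = nPromoters, marksPerRegion = 24L,
                  profileMode = "beta", seed = seed, ...)
}

test_that("fold-level results are deterministic in the run seed", {
  ds <- simulateEPDataset(smallConfig(3L, nPromoters = 25L))
  part <- randomFolds(ds, 3, seed = 3L)
  spec <- modelSpec("random_forest", nTrees = 50)
  a <- runBenchmark(ds, part, spec = spec, seed = 5L)
  b <- runBenchmark(ds, part, spec = spec, seed = 5L)
  expect_identical(a, b)
})

test_that("a test fold without positives is flagged, not fatal", {
  ds <- groupDataset(data.frame(n_pos = c(2L, 0L, 0L), n_neg = c(2L, 4L, 3L)),
                     marks = 4L)
  part <- promoterFolds(ds, 2, seed = 1L)
  expect_warning(
    res <- runBenchmark(ds, part, spec = modelSpec("random_forest",
                                                   nTrees = 20), seed = 1L),
    "no positive pairs")
  expect_true(any(is.na(res$test_f1)))
  expect_true(all(!is.na(res$train_f1)))
})

test_that("random CV inflates test F1 far above leakage-free CV", {
  # zero-signal pure-mixture data: everything above random is leakage
  ds <- simulateEPDataset(generatorConfig(nPromoters = 200L,
                                          marksPerRegion = 60L, seed = 5L))
  spec <- modelSpec("gradient_boosting", nTrees = 1000)
  rand <- suppressWarnings(
    runBenchmark(ds, randomFolds(ds, 10, seed = 5L), spec = spec, seed = 5L))
  chrom <- suppressWarnings(
    runBenchmark(ds, chromosomalFolds(ds, 10), spec = spec, seed = 5L))
  gap <- mean(rand$test_f1, na.rm = TRUE) - mean(chrom$test_f1, na.rm = TRUE)
  expect_gte(gap, 0.5)
})

test_that("high-capacity boosting fits the training set", {
  ds <- simulateEPDataset(smallConfig(6L, nPromoters = 80L,
                                      marksPerRegion = 24L))
  res <- suppressWarnings(
    runBenchmark(ds, randomFolds(ds, 3, seed = 6L),
                 spec = modelSpec("gradient_boosting", nTrees = 4000),
                 seed = 6L))
  expect_gte(mean(res$train_f1), 0.95)
  # training F1 does not degrade as trees are added
  scan <- suppressWarnings(parameterScan(
    ds, randomFolds(ds, 3, seed = 6L),
    lapply(c(50L, 200L, 1000L), function(nt)
      list(blocks = c("E", "P", "W"),
           spec = modelSpec("gradient_boosting", nTrees = nt))),
    seed = 6L))
  summ <- summarizeBenchmark(scan)
  summ <- summ[order(summ$n_trees), ]
  expect_true(all(diff(summ$train_f1) >= -0.02))
})

test_that("leakage-free null evaluation is calibrated near AUROC 0.5", {
  aurocs <- vapply(1:8, function(s) {
    ds <- simulateEPDataset(betaConfig(s, nPromoters = 300L))
    res <- suppressWarnings(
      runBenchmark(ds, chromosomalFolds(ds, 10),
                   spec = modelSpec("gradient_boosting", nTrees = 300),
                   seed = s))
    mean(res$test_auroc, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(aurocs), 0.45)
  expect_lte(mean(aurocs), 0.55)
})

test_that("genuine signal is recovered under leakage-free CV", {
  deltas <- c(0, 0.5, 1, 2)
  by_seed <- sapply(1:3, function(s) {
    vapply(deltas, function(d) {
      ds <- simulateEPDataset(betaConfig(s + 10L, signalStrength = d))
      res <- suppressWarnings(
        runBenchmark(ds, chromosomalFolds(ds, 10),
                     spec = modelSpec("gradient_boosting", nTrees = 300),
                     seed = s))
      mean(res$test_auroc, na.rm = TRUE)
    }, numeric(1))
  })
  expect_true(all(diff(rowMeans(by_seed)) > -0.03))
  # strong signal: near-perfect ranking with a random forest
  ds2 <- simulateEPDataset(betaConfig(21L, signalStrength = 2))
  rf <- suppressWarnings(
    runBenchmark(ds2, chromosomalFolds(ds2, 10),
                 spec = modelSpec("random_forest", nTrees = 500), seed = 1L))
  expect_gt(mean(rf$test_auroc, na.rm = TRUE), 0.9)
})

test_that("report plots build from benchmark and audit results", {
  ds <- groupDataset(data.frame(n_pos = c(3L, 1L), n_neg = c(1L, 3L)),
                     marks = 3L)
  res <- suppressWarnings(parameterScan(
    ds, randomFolds(ds, 2, seed = 1L),
    lapply(c(5L, 10L), function(nt)
      list(blocks = c("E", "P", "W"),
           spec = modelSpec("random_forest", nTrees = nt))),
    seed = 1L))
  expect_s3_class(plotTrainTestCurves(res), "ggplot")
  expect_s3_class(plotSchemeComparison(res, posFraction = 0.5), "ggplot")
  sm <- sharingMatrix(promoterGroups(ds), "pair")
  expect_s3_class(plotSharingMatrix(sm), "ggplot")
})

test_that("RBF SVM memorizes the training set as gamma grows", {
  ds <- simulateEPDataset(smallConfig(31L, nPromoters = 120L,
                                      marksPerRegion = 24L))
  part <- chromosomalFolds(ds, 5)
  scan <- suppressWarnings(parameterScan(
    ds, part,
    list(list(blocks = c("E", "P", "W"), spec = modelSpec("rbf_svm")),
         list(blocks = c("E", "P", "W"),
              spec = modelSpec("rbf_svm", gamma = 100))),
    seed = 1L))
  summ <- summarizeBenchmark(scan)
  large_gamma <- summ[!is.na(summ$gamma) & summ$gamma == 100, ]
  default_gamma <- summ[is.na(summ$gamma), ]
  expect_gte(large_gamma$train_f1, 0.99)
  expect_gte(large_gamma$train_f1, default_gamma$train_f1 - 1e-9)
  # with default C and gamma = 1/n_features, leakage-free test F1 sits
  # inside the all-negative/all-positive baseline envelope
  prevalence <- mean(pairLabels(ds))
  expect_lte(mean(default_gamma$test_f1, na.rm = TRUE),
             allPositiveF1(prevalence) + 0.05)
})
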