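test_that("simulation is deterministic in the seed", {
  cfg <- smallConfig(9L)
  a <- simulateEPDataset(cfg)
  b <- simulateEPDataset(cfg)
  expect_identical(featureMatrix(a), featureMatrix(b))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  c <- simulateEPDataset(smallConfig(10L))
  expect_false(identical(SummarizedExperiment::colData(a)$enh_start,
                         SummarizedExperiment::colData(c)$enh_start))
})

test_that("pure-mixture profiles hit the target positive fraction", {
  # Monte-Carlo check of the sampler against its stated expectation:
  # the realized pair-level positive fraction, averaged over replicate
  # profiles of 400 promoters, matches 1/21
  fracs <- vapply(1:10, function(s) withr::with_seed(s, {
    p <- sampleGroupProfile(generatorConfig())
    sum(p$n_pos) / sum(p$n_pos + p$n_neg)
  }), numeric(1))
  expect_lt(abs(mean(fracs) - 1 / 21), 0.02)
  # law of large numbers at n = 2000 promoters
  p2k <- withr::with_seed(1L, sampleGroupProfile(generatorConfig(nPromoters = 2000L)))
  expect_lt(abs(sum(p2k$n_pos) / sum(p2k$n_pos + p2k$n_neg) - 1 / 21), 0.01)
})

test_that("profile boundary and beta-mode behaviour", {
  p0 <- withr::with_seed(3L,
    sampleGroupProfile(generatorConfig(targetPosFraction = 0)))
  expect_true(all(p0$n_pos == 0L))
  expect_true(all(p0$n_neg >= 2L))
  # pure groups: every group all-positive or all-negative
  pp <- withr::with_seed(4L, sampleGroupProfile(generatorConfig()))
  expect_true(all(pp$n_pos == 0L | pp$n_neg == 0L))
  expect_true(all(pp$n_pos + pp$n_neg >= 2L &
                    pp$n_pos + pp$n_neg <= 30L))
  # symmetric Beta gives expected positive fraction 1/2
  pb <- withr::with_seed(5L, sampleGroupProfile(
    generatorConfig(nPromoters = 2000L, profileMode = "beta",
                    betaA = 2, betaB = 2)))
  expect_lt(abs(sum(pb$n_pos) / sum(pb$n_pos + pb$n_neg) - 0.5), 0.02)
})

test_that("layout respects distance bounds and same-side windows nest", {
  ds <- simulateEPDataset(smallConfig(6L))
  cd <- SummarizedExperiment::colData(ds)
  gap <- pmax(cd$enh_start, cd$prom_start) - pmin(cd$enh_end, cd$prom_end)
  cfg <- smallConfig(6L)
  expect_true(all(gap >= cfg@minDistance & gap <= cfg@maxDistance))
  # elements never overlap anywhere in the genome
  elements <- c(enhancerRanges(ds), unique(promoterRanges(ds)))
  hits <- GenomicRanges::findOverlaps(elements, minoverlap = 1L,
                                      drop.self = TRUE)
  expect_length(hits, 0L)
  # two enhancers of one promoter on the same side share window signal
  comp <- windowSharingComponents(ds)
  right_of <- cd$enh_start > cd$prom_end
  same_side <- tapply(seq_len(ncol(ds)), cd$promoter_id, function(idx) {
    idx_r <- idx[right_of[idx]]
    if (length(idx_r) >= 2L) length(unique(comp[idx_r])) == 1L else NA
  })
  expect_true(all(unlist(same_side), na.rm = TRUE))
  # layout refuses a genome that cannot host the requested distances
  expect_error(simulateEPDataset(smallConfig(1L, chromLength = 1e6)),
               "too short")
})

test_that("promoter-shared P features are bit-identical within groups", {
  ds <- simulateEPDataset(smallConfig(7L))
  P <- featureMatrix(featureSubset(ds, "P"))
  by_prom <- split(seq_len(nPairs(ds)), promoterIds(ds))
  for (idx in by_prom[lengths(by_prom) > 1L]) {
    ref <- P[idx[1L], ]
    for (j in idx[-1L]) expect_identical(P[j, ], ref)
  }
  # E features carry the label signal only when requested
  dss <- simulateEPDataset(smallConfig(7L, signalStrength = 2,
                                       nSignalFeatures = 3L))
  E <- featureMatrix(featureSubset(dss, "E"))
  lab <- pairLabels(dss)
  shift <- colMeans(E[lab == 1L, 1:3]) - colMeans(E[lab == 0L, 1:3])
  expect_true(all(shift > 1))
})

test_that("with zero signal no feature separates the classes", {
  # one pair per promoter group, so observations are independent across
  # groups; Bonferroni-corrected two-sample t-tests over all 408 features
  ds <- defaultDataset()
  first <- !duplicated(promoterIds(ds))
  X <- featureMatrix(ds)[first, ]
  y <- pairLabels(ds)[first]
  pvals <- apply(X, 2, function(col)
    stats::t.test(col[y == 1L], col[y == 0L])$p.value)
  expect_gt(min(pvals) * ncol(X), 0.01)
})

test_that("track integrals match a naive per-segment sum", {
  set.seed(42)
  vals <- matrix(rnorm(15), 5, 3)
  seg <- 10
  naive <- function(x) {
    sapply(seq_len(ncol(vals)), function(m) {
      total <- 0
      for (s in seq_len(nrow(vals))) {
        lo <- (s - 1) * seg; hi <- s * seg
        total <- total + vals[s, m] * max(0, min(x, hi) - lo)
      }
      total
    })
  }
  xs <- c(0, 3, 10, 23, 50)
  got <- EPLeakage:::.trackIntegral(xs, vals, seg)
  for (i in seq_along(xs)) expect_equal(unname(got[i, ]), naive(xs[i]))
})

test_that("window-feature correlation increases with overlap fraction", {
  L <- 2e5
  s <- 1e6
  f <- c(0.25, 0.5, 0.75, 0.99)
  offs <- round((1 - f) * L)
  pairs <- rbind(pairForWindow("ref", s, s + L),
                 do.call(rbind, lapply(seq_along(f), function(i)
                   pairForWindow(sprintf("f%02.0f", 100 * f[i]),
                                 s + offs[i], s + offs[i] + L))))
  ds <- EPDataset(pairs)
  cfg <- generatorConfig(nChromosomes = 1L, marksPerRegion = 2000L,
                         nSignalFeatures = 0L, seed = 1L)
  feat <- withr::with_seed(1L, generateFeatures(ds, cfg))
  W <- featureMatrix(featureSubset(feat, "W"))
  cors <- vapply(seq_along(f) + 1L, function(i) cor(W[1L, ], W[i, ]),
                 numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[length(f)], 0.95)
})
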