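test_that("constructor validates pair structure", {
  pairs <- data.frame(pair_id = c("a", "b"), chrom = "chr1",
                      enh_start = c(1000, 9000), enh_end = c(2000, 10000),
                      prom_start = 5000, prom_end = 7000,
                      promoter_id = "pA", label = c(1L, 0L))
  expect_s4_class(EPDataset(pairs), "EPDataset")

  dup <- pairs; dup$pair_id <- c("a", "a")
  expect_error(EPDataset(dup), "duplicate pair_id")

  rev <- pairs; rev$enh_start[1] <- 3000; rev$enh_end[1] <- 1000
  expect_error(EPDataset(rev), "start >= end")

  ovl <- pairs; ovl$enh_start[1] <- 6000; ovl$enh_end[1] <- 8000
  expect_error(EPDataset(ovl), "overlaps")

  # same promoter interval under two ids breaks the one-to-one map
  twoid <- pairs; twoid$promoter_id <- c("pA", "pB")
  expect_error(EPDataset(twoid), "one-to-one")
})

test_that("window is the gap between the elements, in either orientation", {
  enh_left <- EPDataset(data.frame(
    pair_id = "p", chrom = "chr1", enh_start = 100, enh_end = 200,
    prom_start = 500, prom_end = 600, promoter_id = "A", label = 1L))
  w <- windowRanges(enh_left)
  expect_equal(GenomicRanges::start(w), 201)  # BED [200, 500)
  expect_equal(GenomicRanges::end(w), 500)

  enh_right <- EPDataset(data.frame(
    pair_id = "p", chrom = "chr1", enh_start = 500, enh_end = 600,
    prom_start = 100, prom_end = 200, promoter_id = "A", label = 1L))
  expect_identical(windowRanges(enh_right), w)

  adjacent <- EPDataset(data.frame(
    pair_id = "p", chrom = "chr1", enh_start = 100, enh_end = 200,
    prom_start = 200, prom_end = 300, promoter_id = "A", label = 1L))
  expect_error(windowRanges(adjacent), "zero-width")
})

test_that("windows never overlap their elements and have width = element gap", {
  ds <- simulateEPDataset(smallConfig(4L))
  cd <- SummarizedExperiment::colData(ds)
  w <- windowRanges(ds)
  gap <- pmax(cd$enh_start, cd$prom_start) - pmin(cd$enh_end, cd$prom_end)
  expect_equal(GenomicRanges::width(w), gap)
  # BED window [w1, w2) lies strictly between the two elements
  w1 <- GenomicRanges::start(w) - 1
  w2 <- GenomicRanges::end(w)
  left_end <- pmin(cd$enh_end, cd$prom_end)
  right_start <- pmax(cd$enh_start, cd$prom_start)
  expect_true(all(w1 == left_end & w2 == right_start))
})

test_that("feature subsets select blocks and partition the EPW columns", {
  ds <- simulateEPDataset(generatorConfig(nPromoters = 15L, seed = 2L))
  expect_equal(nrow(featureSubset(ds, c("E", "P", "W"))), 408L)
  expect_equal(nrow(featureSubset(ds, c("E", "P"))), 272L)
  expect_equal(nrow(featureSubset(ds, "W")), 136L)
  parts <- lapply(c("E", "P", "W"), function(b)
    rownames(featureSubset(ds, b)))
  expect_length(unique(unlist(parts)), 408L)
  expect_setequal(unlist(parts), rownames(ds))
  expect_error(featureSubset(ds, character()), "non-empty")
  expect_error(featureSubset(ds, "Q"), "unknown block")
})

test_that("write/read round trip is the identity on valid datasets", {
  for (seed in 1:3) {
    ds <- simulateEPDataset(smallConfig(seed, nPromoters = 8L,
                                        marksPerRegion = 5L))
    pp <- withr::local_tempfile(fileext = ".tsv")
    fp <- withr::local_tempfile(fileext = ".tsv")
    writeEPDataset(ds, pp, fp)
    back <- readEPDataset(pp, fp)
    expect_identical(pairIds(back), pairIds(ds))
    expect_identical(pairLabels(back), pairLabels(ds))
    expect_equal(as.data.frame(SummarizedExperiment::colData(back)),
                 as.data.frame(SummarizedExperiment::colData(ds)))
    relerr <- abs(featureMatrix(back) - featureMatrix(ds)) /
      pmax(abs(featureMatrix(ds)), 1e-300)
    expect_lt(max(relerr), 1e-9)
    expect_identical(featureBlocks(back), featureBlocks(ds))
  }
})

test_that("an empty dataset writes header-only files and reads back", {
  empty <- EPDataset(data.frame(pair_id = character(), chrom = character(),
                                enh_start = numeric(), enh_end = numeric(),
                                prom_start = numeric(), prom_end = numeric(),
                                promoter_id = character(),
                                label = integer()))
  pp <- withr::local_tempfile(fileext = ".tsv")
  writeEPDataset(empty, pp)
  expect_length(readLines(pp), 1L)
  expect_equal(nPairs(readEPDataset(pp)), 0L)
})

test_that("loader reports joins, duplicates and malformed intervals", {
  pp <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "pair_id\tchrom\tenh_start\tenh_end\tprom_start\tprom_end\tpromoter_id\tlabel"
  writeLines(c(hdr,
               "a\tchr1\t1000\t2000\t5000\t7000\tpA\t1",
               "b\tchr1\t9000\t10000\t5000\t7000\tpA\t0"), pp)
  writeLines(c("pair_id\tE|M1", "a\t0.5", "zzz\t0.25"), fp)
  expect_error(readEPDataset(pp, fp), "zzz")

  writeLines(c("pair_id\tE|M1", "a\t0.5"), fp)
  expect_error(readEPDataset(pp, fp), "\\bb\\b")

  writeLines(c(hdr,
               "a\tchr1\t1000\t2000\t5000\t7000\tpA\t1",
               "a\tchr1\t9000\t10000\t5000\t7000\tpA\t0"), pp)
  expect_error(readEPDataset(pp), "duplicate pair_id")

  writeLines(c(hdr,
               "a\tchr1\t2000\t1000\t5000\t7000\tpA\t1"), pp)
  expect_error(readEPDataset(pp), "line\\(s\\) 2")
})
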