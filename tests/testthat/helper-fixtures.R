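# Hand-built dataset with prescribed per-promoter (n_pos, n_neg) counts.
# Promoter g sits at 10 Mb * g on chr1 (or a given chromosome), its
# enhancers 20 kb apart on the right, so same-group windows are nested
# (overlapping) while different groups never share window signal.
groupDataset <- function(counts, chrom = "chr1", marks = 0L) {
  rows <- lapply(seq_len(nrow(counts)), function(g) {
    size <- counts$n_pos[g] + counts$n_neg[g]
    ps <- 1e7 * g
    es <- ps + 2000 + 20000 * seq_len(size)
    data.frame(
      pair_id = sprintf("g%02d_e%02d", g, seq_len(size)),
      chrom = if (length(chrom) > 1L) chrom[g] else chrom,
      enh_start = es, enh_end = es + 1000,
      prom_start = ps, prom_end = ps + 2000,
      promoter_id = sprintf("g%02d", g),
      label = rep(c(1L, 0L), c(counts$n_pos[g], counts$n_neg[g])))
  })
  pairs <- do.call(rbind, rows)
  features <- if (marks > 0L) {
    m <- matrix(stats::rnorm(nrow(pairs) * 3L * marks), nrow(pairs))
    colnames(m) <- paste0(rep(c("E|", "P|", "W|"), each = marks),
                          sprintf("M%02d", seq_len(marks)))
    m
  }
  EPDataset(pairs, features)
}

# A pair whose window is the BED interval [w1, w2): promoter immediately
# left of the window, enhancer immediately right.
pairForWindow <- function(id, w1, w2, chrom = "chr1", label = 0L) {
  data.frame(pair_id = id, chrom = chrom,
             enh_start = w2, enh_end = w2 + 1000,
             prom_start = w1 - 2000, prom_end = w1,
             promoter_id = paste0("prom_", id), label = label)
}

smallConfig <- function(seed, nPromoters = 30L, marksPerRegion = 6L, ...) {
  generatorConfig(nPromoters = nPromoters, marksPerRegion = marksPerRegion,
                  seed = seed, ...)
}

# Expensive shared fixtures, built once per test run.
.cache <- new.env(parent = emptyenv())

defaultDataset <- function() {
  if (is.null(.cache$default))
    .cache$default <- simulateEPDataset(generatorConfig())
  .cache$default
}

# Gradient boosting (4000 trees) on the default zero-signal dataset under
# random and chromosomal 10-fold CV -- the central leakage contrast,
# shared by the acceptance checks.
leakageContrast <- function() {
  if (is.null(.cache$contrast)) {
    ds <- defaultDataset()
    spec <- modelSpec("gradient_boosting", nTrees = 4000)
    rand <- suppressWarnings(
      runBenchmark(ds, randomFolds(ds, 10, seed = 1L), spec = spec, seed = 1L))
    chromPart <- chromosomalFolds(ds, 10)
    chrom <- suppressWarnings(
      runBenchmark(ds, chromPart, spec = spec, seed = 1L))
    .cache$contrast <- list(random = rand, chrom = chrom,
                            chromPart = chromPart)
  }
  .cache$contrast
}
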