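# Independent brute-force oracles used to cross-check the package's
# vectorized implementations on small inputs.

# Window intervals in BED coordinates, straight from the definition.
bedWindows <- function(dataset) {
  cd <- SummarizedExperiment::colData(dataset)
  data.frame(chrom = cd$chrom,
             w1 = pmin(cd$enh_end, cd$prom_end),
             w2 = pmax(cd$enh_start, cd$prom_start))
}

# All-pairs positive-width window overlap test.
windowsOverlap <- function(w, i, j) {
  w$chrom[i] == w$chrom[j] &&
    max(w$w1[i], w$w1[j]) < min(w$w2[i], w$w2[j])
}

# Connected components by explicit transitive closure (label propagation).
bruteWindowComponents <- function(dataset) {
  n <- ncol(dataset)
  w <- bedWindows(dataset)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && windowsOverlap(w, i, j) && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stats::setNames(comp, colnames(dataset))
}

# Two component labellings describe the same partition?
sameClustering <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Quadratic certificate: count cross-fold promoter-sharing and
# window-overlapping pair pairs by double loop.
bruteCertificate <- function(partition, dataset) {
  fold <- foldOf(partition)[colnames(dataset)]
  prom <- SummarizedExperiment::colData(dataset)$promoter_id
  w <- bedWindows(dataset)
  n <- ncol(dataset)
  pl <- 0L; wl <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (fold[i] != fold[j]) {
      if (prom[i] == prom[j]) pl <- pl + 1L
      if (windowsOverlap(w, i, j)) wl <- wl + 1L
    }
  }
  list(prom = pl, win = wl)
}

# Average precision straight from the definition: for every distinct
# score threshold, build the confusion table from scratch.
bruteAveragePrecision <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels == 1)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
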