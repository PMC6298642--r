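## Natural chromosome order: split an optional "chr" prefix from a numeric
## suffix so that chr2 sorts before chr10; non-numeric names (chrX, chrM)
## sort after numeric ones, lexicographically.
.chromOrderKey <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", chrom)))
  order(is.na(num), num, chrom)
}

.newPartition <- function(fold, k, scheme, seed = NA_integer_) {
  new("CVPartition", fold = fold, k = as.integer(k), scheme = scheme,
      seed = as.integer(seed))
}

#' Random cross-validation folds (the leaky scheme)
#'
#' Deals pairs into \code{k} folds uniformly at random, ignoring all
#' sharing structure -- the conventional scheme whose held-out
#' performance is inflated whenever pairs share promoter or window
#' features across folds.  Fold sizes differ by at most one pair.
#'
#' @param dataset An [EPDataset-class].
#' @param k Fold count (default 10).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return A [CVPartition-class].
#' @export
randomFolds <- function(dataset, k = 10L, seed = 1L) {
  stopifnot(is(dataset, "EPDataset"))
  n <- ncol(dataset)
  if (k > n) stop("k = ", k, " exceeds the number of pairs (", n, ")")
  perm <- withr::with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k) - 1L, length.out = n)
  .newPartition(stats::setNames(fold, colnames(dataset)), k, "random", seed)
}

## Minimal union-find over 1..n.
.unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  list(find = find,
       union = function(i, j) parent[find(i)] <<- find(j),
       labels = function() vapply(seq_len(n), find, integer(1)))
}

## Merge units for chromosomal folds: the coarsest partition refining
## nothing -- pairs linked by a shared promoter or a shared window
## component end up in one unit.
.mergeUnits <- function(dataset) {
  n <- ncol(dataset)
  uf <- .unionFind(n)
  link <- function(groups) {
    for (idx in groups) if (length(idx) > 1L)
      for (j in idx[-1L]) uf$union(idx[1L], j)
  }
  link(split(seq_len(n), colData(dataset)$promoter_id))
  link(split(seq_len(n), windowSharingComponents(dataset)))
  uf$labels()
}

#' Chromosomally sorted, sharing-safe cross-validation folds
#'
#' Sorts pairs by genomic position (natural chromosome order, then window
#' midpoint, then pair id), cuts the sorted list into \code{k} contiguous
#' blocks of near-equal size, and snaps each cut forward to the nearest
#' position where no promoter group and no window-overlap component
#' straddles the boundary.  The resulting partition is deterministic and
#' certifiably leakage-free: its [certify()] certificate reports zero
#' cross-fold promoter links and zero cross-fold window links, so
#' held-out performance measures genuine generalization.
#'
#' @param dataset An [EPDataset-class].
#' @param k Fold count (default 10).  Must not exceed the number of
#'   mergeable units (promoter groups joined with window components).
#' @return A [CVPartition-class].
#' @export
chromosomalFolds <- function(dataset, k = 10L) {
  stopifnot(is(dataset, "EPDataset"))
  n <- ncol(dataset)
  if (k > n) stop("k = ", k, " exceeds the number of pairs (", n, ")")
  cd <- colData(dataset)
  mid <- .windowMidpoint(dataset)
  chrom_rank <- match(cd$chrom, unique(cd$chrom)[.chromOrderKey(unique(cd$chrom))])
  ord <- order(chrom_rank, mid, colnames(dataset))
  units <- .mergeUnits(dataset)[ord]
  ## a cut after sorted position i is valid iff no unit spans it
  last_of_unit <- vapply(split(seq_len(n), units), max, numeric(1))
  valid <- which(cummax(last_of_unit[as.character(units)]) == seq_len(n))
  valid <- valid[valid < n]  # a cut after the last pair creates no fold
  n_units <- length(unique(units))
  if (n_units < k)
    stop("only ", n_units, " mergeable units (promoter groups joined with ",
         "window components) for k = ", k, " folds")
  cuts <- integer(k - 1L)
  prev <- 0L
  for (i in seq_len(k - 1L)) {
    target <- round(i * n / k)
    cand <- valid[valid >= max(target, prev + 1L)]
    if (!length(cand))
      stop("cannot place ", k, " fold boundaries: sharing components are ",
           "too large near the end of the genome order")
    cuts[i] <- cand[1L]
    prev <- cuts[i]
  }
  fold_sorted <- findInterval(seq_len(n), cuts + 1L)
  fold <- integer(n)
  fold[ord] <- fold_sorted
  .newPartition(stats::setNames(fold, colnames(dataset)), k, "chromosomal")
}

#' Promoter-segregated cross-validation folds
#'
#' Shuffles promoter groups and assigns each to the currently smallest
#' fold (by pair count), so all pairs sharing a promoter share a fold.
#' This eliminates promoter-feature leakage by construction
#' (\code{crossFoldPromoterLinks} is always 0) but does not prevent
#' window-feature leakage: pairs of different promoters with overlapping
#' windows can still land in different folds.
#'
#' @param dataset An [EPDataset-class].
#' @param k Fold count (default 10).  Must not exceed the number of
#'   promoter groups.
#' @param seed Integer seed for the group shuffle.
#' @return A [CVPartition-class].
#' @export
promoterFolds <- function(dataset, k = 10L, seed = 1L) {
  stopifnot(is(dataset, "EPDataset"))
  groups <- split(seq_len(ncol(dataset)), colData(dataset)$promoter_id)
  if (k > length(groups))
    stop("k = ", k, " exceeds the number of promoter groups (",
         length(groups), ")")
  ord <- withr::with_seed(seed, sample.int(length(groups)))
  fold <- integer(ncol(dataset))
  fold_sizes <- integer(k)
  for (g in ord) {
    target <- which.min(fold_sizes)
    fold[groups[[g]]] <- target - 1L
    fold_sizes[target] <- fold_sizes[target] + length(groups[[g]])
  }
  .newPartition(stats::setNames(fold, colnames(dataset)), k,
                "promoter_segregated", seed)
}

#' Certify a partition for cross-fold feature sharing
#'
#' Counts, exactly, the unordered pairs of EP pairs assigned to different
#' folds that (a) share a promoter or (b) have positively overlapping
#' window intervals.  A certificate with both counts zero guarantees that
#' neither promoter nor window features are shared between any training
#' fold and its test fold.
#'
#' @param partition A [CVPartition-class] covering \code{dataset}.
#' @param dataset The [EPDataset-class] the partition was built for.
#' @return A [ContaminationCertificate-class].
#' @rdname certify
#' @export
setMethod("certify", signature("CVPartition", "EPDataset"),
          function(partition, dataset) {
  if (!setequal(names(partition@fold), colnames(dataset)))
    stop("partition does not cover this dataset")
  fold <- partition@fold[colnames(dataset)]
  choose2 <- function(x) x * (x - 1) / 2
  ## promoter links: per group, all cross-fold pair pairs
  prom_links <- sum(vapply(
    split(fold, colData(dataset)$promoter_id),
    function(f) choose2(length(f)) - sum(choose2(tabulate(f + 1L))),
    numeric(1)))
  ## window links: overlapping windows in different folds
  w <- windowRanges(dataset)
  hits <- findOverlaps(w, minoverlap = 1L, drop.self = TRUE,
                       drop.redundant = TRUE)
  win_links <- sum(fold[S4Vectors::queryHits(hits)] !=
                     fold[S4Vectors::subjectHits(hits)])
  new("ContaminationCertificate",
      crossFoldPromoterLinks = prom_links,
      crossFoldWindowLinks = win_links)
})
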