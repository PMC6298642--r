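#' Group EP pairs by promoter
#'
#' Every pair belongs to exactly one promoter group; groups with two or
#' more pairs are the carriers of promoter-feature sharing, since all
#' their pairs have identical P features.
#'
#' @param dataset An [EPDataset-class].
#' @return A \code{data.frame} with one row per distinct promoter:
#'   \code{promoter_id}, \code{n_pos}, \code{n_neg}, and a list column
#'   \code{pair_ids}.
#' @export
promoterGroups <- function(dataset) {
  stopifnot(is(dataset, "EPDataset"))
  if (ncol(dataset) == 0L)
    return(data.frame(promoter_id = character(), n_pos = integer(),
                      n_neg = integer(),
                      pair_ids = I(list())))
  cd <- colData(dataset)
  ids <- sort(unique(cd$promoter_id))
  f <- factor(cd$promoter_id, levels = ids)
  n_pos <- as.integer(tapply(cd$label == 1L, f, sum))
  n_tot <- as.integer(tapply(cd$label, f, length))
  data.frame(promoter_id = ids, n_pos = n_pos, n_neg = n_tot - n_pos,
             pair_ids = I(unname(split(colnames(dataset), f))))
}

#' Build a promoter-sharing matrix
#'
#' Aggregates promoter groups by their (positive count, negative count)
#' signature.  Pair weighting counts the EP pairs falling in each cell --
#' the relevant view for test-set contamination, since models are trained
#' on pairs; promoter weighting counts distinct promoters.  A cell at
#' \code{(a, b)} therefore holds \code{(a + b)} times as many pairs as
#' promoters.
#'
#' @param groups Output of [promoterGroups()] (or any data frame with
#'   \code{n_pos}, \code{n_neg} columns, one row per promoter).
#' @param weighting \code{"pair"} or \code{"promoter"}.
#' @return A [SharingMatrix-class].
#' @examples
#' g <- data.frame(n_pos = rep(7, 3), n_neg = rep(2, 3))
#' sharingCount(sharingMatrix(g, "pair"), 7, 2)      # 27 EP pairs
#' sharingCount(sharingMatrix(g, "promoter"), 7, 2)  # 3 promoters
#' @export
sharingMatrix <- function(groups, weighting = c("pair", "promoter")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("n_pos", "n_neg") %in% colnames(groups)))
  if (nrow(groups) == 0L)
    return(new("SharingMatrix",
               cells = data.frame(n_pos = integer(), n_neg = integer(),
                                  count = numeric()),
               weighting = weighting))
  w <- if (weighting == "pair") groups$n_pos + groups$n_neg else
    rep(1, nrow(groups))
  agg <- stats::aggregate(count ~ n_pos + n_neg,
                          data = data.frame(n_pos = groups$n_pos,
                                            n_neg = groups$n_neg, count = w),
                          FUN = sum)
  agg <- agg[order(agg$n_pos, agg$n_neg), , drop = FALSE]
  rownames(agg) <- NULL
  new("SharingMatrix", cells = agg, weighting = weighting)
}

#' @rdname sharingMatrix
#' @param x A [SharingMatrix-class].
#' @param n_pos,n_neg Cell coordinates.
setMethod("sharingCells", "SharingMatrix", function(x) x@cells)

#' @rdname sharingMatrix
setMethod("sharingCount", "SharingMatrix", function(x, n_pos, n_neg) {
  hit <- x@cells$n_pos == n_pos & x@cells$n_neg == n_neg
  if (any(hit)) sum(x@cells$count[hit]) else 0
})

#' Majority-rule contamination accuracy of a promoter group
#'
#' The accuracy achievable on a promoter group's pairs by a rule that
#' memorizes the promoter's features and predicts the group's majority
#' class: \code{max(n_pos, n_neg) / (n_pos + n_neg)}.  When a group is
#' split across cross-validation folds, this is the test accuracy
#' available with zero generalization -- e.g. a (7, 2) group is predicted
#' at 7/9, about 78\%.  Always at least 0.5, and exactly 1 on pure
#' groups.
#'
#' @param n_pos,n_neg Non-negative pair counts (vectorized).
#' @return Numeric vector of accuracies in \code{[0.5, 1]}.
#' @export
contaminationAccuracy <- function(n_pos, n_neg) {
  stopifnot(length(n_pos) == length(n_neg))
  if (any(n_pos < 0 | n_neg < 0))
    stop("counts must be non-negative")
  if (any(n_pos + n_neg < 1))
    stop("a group must contain at least one pair")
  pmax(n_pos, n_neg) / (n_pos + n_neg)
}

#' Classify a promoter group's class imbalance
#'
#' A group is \code{"pos_skew"} when \code{n_pos >= fold_threshold * n_neg}
#' (pure positive groups included), \code{"neg_skew"} symmetrically, and
#' \code{"balanced"} otherwise.  Skewed groups are the contaminating
#' ones: their majority class is predictable from shared promoter
#' features.
#'
#' @param n_pos,n_neg Non-negative pair counts (vectorized).
#' @param foldThreshold Imbalance ratio defining skew (default 2).
#' @return Character vector in
#'   \code{c("pos_skew", "neg_skew", "balanced")}.
#' @export
imbalanceClass <- function(n_pos, n_neg, foldThreshold = 2) {
  stopifnot(length(n_pos) == length(n_neg))
  if (foldThreshold < 1) stop("foldThreshold must be >= 1")
  if (any(n_pos + n_neg < 1))
    stop("a group must contain at least one pair")
  ifelse(n_pos >= foldThreshold * n_neg, "pos_skew",
         ifelse(n_neg >= foldThreshold * n_pos, "neg_skew", "balanced"))
}

#' Fraction of pairs exposed to promoter-feature contamination
#'
#' The fraction of all EP pairs that (a) share their promoter with at
#' least one other pair and (b) sit in a group with a
#' \code{foldThreshold}-fold or greater class imbalance.  Singleton
#' groups cannot contaminate through P features; balanced groups share
#' features but their majority rule is uninformative.
#'
#' @param groups Output of [promoterGroups()].
#' @param foldThreshold Imbalance ratio defining skew (default 2).
#' @return A fraction in \code{[0, 1]}.
#' @export
leakyPairFraction <- function(groups, foldThreshold = 2) {
  sizes <- groups$n_pos + groups$n_neg
  total <- sum(sizes)
  if (total < 1) stop("groups cover no pairs")
  cls <- imbalanceClass(groups$n_pos, groups$n_neg, foldThreshold)
  leaky <- sizes >= 2L & cls != "balanced"
  sum(sizes[leaky]) / total
}

#' Window-sharing components
#'
#' Connected components of the graph on EP pairs with an edge whenever
#' two pairs' window intervals overlap (positive-width overlap on the
#' same chromosome).  Pairs in one component can share window (W)
#' features through the overlapping portion of their windows; any
#' leakage-free partition must keep each component within a single fold.
#' For genomic intervals, overlap-connectivity equals membership in the
#' same merged interval, so components are computed by reducing the
#' windows with zero gap tolerance.
#'
#' @param dataset An [EPDataset-class].
#' @return Named integer vector: a component id per pair.
#' @export
windowSharingComponents <- function(dataset) {
  stopifnot(is(dataset, "EPDataset"))
  if (ncol(dataset) == 0L)
    return(stats::setNames(integer(), character()))
  w <- windowRanges(dataset)
  merged <- reduce(w, min.gapwidth = 0L)  # merge only positive overlaps
  hits <- findOverlaps(w, merged, minoverlap = 1L)
  comp <- integer(length(w))
  comp[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  stats::setNames(comp, names(w))
}
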