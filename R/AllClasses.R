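#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames
#' @importFrom IRanges IRanges
NULL

#' EPDataset: enhancer-promoter pairs with E/P/W feature blocks
#'
#' An \code{EPDataset} stores a set of candidate enhancer-promoter (EP)
#' pairs together with an aligned feature table.  It extends
#' \linkS4class{SummarizedExperiment}: columns are EP pairs (one column per
#' pair, column names are the pair identifiers) and rows are features.  Pair
#' metadata lives in \code{colData}: chromosome, enhancer and promoter
#' intervals (0-based half-open, BED convention), a promoter identifier
#' shared by all pairs with the same promoter interval, and a binary
#' interaction label.  \code{rowData} carries a \code{block} tag assigning
#' every feature to the enhancer (\code{"E"}), promoter (\code{"P"}) or
#' window (\code{"W"}) block, where the window is the genomic interval
#' between the two elements.
#'
#' Validity requires: unique pair identifiers; \code{start < end} and
#' \code{start >= 0} for both elements; enhancer and promoter on the same
#' chromosome and non-overlapping; a one-to-one correspondence between
#' promoter identifiers and promoter intervals; labels in \{0, 1\}; and
#' every feature tagged with exactly one of E/P/W.
#'
#' @seealso [EPDataset()] (constructor), [readEPDataset()],
#'   [featureSubset()], [windowRanges()]
#' @name EPDataset-class
#' @aliases EPDataset-class
#' @exportClass EPDataset
setClass("EPDataset", contains = "SummarizedExperiment")

.PAIR_COLUMNS <- c("chrom", "enh_start", "enh_end", "prom_start", "prom_end",
                   "promoter_id", "label")

.validEPDataset <- function(object) {
  msg <- character()
  cd <- colData(object)
  if (is.null(colnames(object)))
    return("pair identifiers (column names) are required")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate pair_id: %s",
                          paste(unique(colnames(object)[duplicated(colnames(object))]),
                                collapse = ", ")))
  missing_cols <- setdiff(.PAIR_COLUMNS, colnames(cd))
  if (length(missing_cols))
    return(c(msg, paste("missing colData columns:",
                        paste(missing_cols, collapse = ", "))))
  if (ncol(object) > 0L) {
    if (!all(cd$label %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0 or 1")
    bad <- cd$enh_start >= cd$enh_end | cd$prom_start >= cd$prom_end
    if (any(bad))
      msg <- c(msg, sprintf("interval with start >= end for pair(s): %s",
                            paste(colnames(object)[bad], collapse = ", ")))
    if (any(cd$enh_start < 0 | cd$prom_start < 0))
      msg <- c(msg, "negative interval start")
    ovl <- cd$enh_start < cd$prom_end & cd$prom_start < cd$enh_end
    if (any(ovl))
      msg <- c(msg, sprintf("enhancer overlaps promoter for pair(s): %s",
                            paste(colnames(object)[ovl], collapse = ", ")))
    key <- paste(cd$chrom, cd$prom_start, cd$prom_end)
    if (anyDuplicated(unique(data.frame(key, id = cd$promoter_id))$key) ||
        anyDuplicated(unique(data.frame(key, id = cd$promoter_id))$id))
      msg <- c(msg, "promoter_id must map one-to-one to promoter intervals")
  }
  if (nrow(object) > 0L) {
    rd <- rowData(object)
    if (!"block" %in% colnames(rd) || !all(rd$block %in% c("E", "P", "W")))
      msg <- c(msg, "every feature needs a block tag in {E, P, W}")
  }
  if (length(msg)) msg else TRUE
}

setValidity("EPDataset", .validEPDataset)

#' Construct an EPDataset
#'
#' @param pairs A \code{data.frame} with one row per EP pair and columns
#'   \code{pair_id}, \code{chrom}, \code{enh_start}, \code{enh_end},
#'   \code{prom_start}, \code{prom_end}, \code{promoter_id}, \code{label}.
#'   Coordinates are 0-based half-open (BED convention).
#' @param features Optional numeric matrix, pairs x features, rows aligned
#'   with (or named by) \code{pair_id}.  Column names must be
#'   \code{"<BLOCK>|<mark>"} with BLOCK in E/P/W unless \code{blocks} is
#'   given.
#' @param blocks Optional character vector (one of \code{"E"}, \code{"P"},
#'   \code{"W"} per feature column), overriding block tags parsed from the
#'   column names of \code{features}.
#'
#' @return A validated [EPDataset-class] object.
#' @examples
#' pairs <- data.frame(
#'   pair_id = c("p1", "p2"), chrom = "chr1",
#'   enh_start = c(1000L, 9000L), enh_end = c(2000L, 10000L),
#'   prom_start = 5000L, prom_end = 7000L,
#'   promoter_id = "promA", label = c(1L, 0L))
#' feat <- matrix(rnorm(4), 2, dimnames = list(NULL, c("E|H3K4me1", "P|H3K4me3")))
#' EPDataset(pairs, feat)
#' @export
EPDataset <- function(pairs, features = NULL, blocks = NULL) {
  stopifnot(is.data.frame(pairs))
  need <- c("pair_id", .PAIR_COLUMNS)
  missing_cols <- setdiff(need, colnames(pairs))
  if (length(missing_cols))
    stop("pairs is missing column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(pairs)
  if (is.null(features)) {
    features <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  features <- as.matrix(features)
  if (nrow(features) != n)
    stop("features has ", nrow(features), " rows for ", n, " pairs")
  if (!is.null(rownames(features))) {
    if (!setequal(rownames(features), pairs$pair_id))
      stop("feature row names do not match pair_id values")
    features <- features[match(pairs$pair_id, rownames(features)), , drop = FALSE]
  }
  if (is.null(blocks)) {
    if (ncol(features) > 0L && is.null(colnames(features)))
      stop("features needs '<BLOCK>|<mark>' column names or an explicit 'blocks'")
    blocks <- sub("\\|.*$", "", colnames(features))
  }
  marks <- if (ncol(features)) sub("^[EPW]\\|", "", colnames(features)) else character()
  cd <- DataFrame(pairs[.PAIR_COLUMNS], row.names = pairs$pair_id)
  cd$chrom <- as.character(cd$chrom)
  cd$promoter_id <- as.character(cd$promoter_id)
  for (f in c("enh_start", "enh_end", "prom_start", "prom_end"))
    cd[[f]] <- as.numeric(cd[[f]])
  cd$label <- as.integer(cd$label)
  rd <- DataFrame(block = as.character(blocks), mark = marks)
  se <- SummarizedExperiment(
    assays = list(features = t(features)),
    rowData = rd, colData = cd)
  colnames(se) <- pairs$pair_id
  rownames(se) <- if (ncol(features)) paste0(blocks, "|", marks) else NULL
  new("EPDataset", se)
}

#' Cross-validation partition of an EPDataset
#'
#' Assigns every EP pair to one of \code{k} folds.  \code{scheme} records
#' how the folds were built: \code{"random"} (pairs dealt uniformly at
#' random -- the leaky scheme), \code{"chromosomal"} (contiguous blocks in
#' genome order with boundaries snapped so no promoter group or
#' window-overlap component spans folds), or \code{"promoter_segregated"}
#' (all pairs of a promoter share a fold).
#'
#' @slot fold integer vector, one fold index in \code{[0, k)} per pair,
#'   named by pair identifier.
#' @slot k integer fold count (>= 2).
#' @slot scheme character scalar.
#' @slot seed integer seed used by randomized schemes, \code{NA} otherwise.
#' @seealso [randomFolds()], [chromosomalFolds()], [promoterFolds()],
#'   [certify()]
#' @exportClass CVPartition
setClass("CVPartition",
  representation(fold = "integer", k = "integer", scheme = "character",
                 seed = "integer"))

setValidity("CVPartition", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 2L)
    msg <- c(msg, "k must be a single integer >= 2")
  if (is.null(names(object@fold)))
    msg <- c(msg, "fold must be named by pair_id")
  if (any(object@fold < 0L) || any(object@fold >= object@k))
    msg <- c(msg, "fold indices must lie in [0, k)")
  if (length(unique(object@fold)) < object@k)
    msg <- c(msg, "every fold must be non-empty")
  if (!object@scheme %in% c("random", "chromosomal", "promoter_segregated"))
    msg <- c(msg, "unknown scheme")
  if (length(msg)) msg else TRUE
})

#' Contamination certificate for a cross-validation partition
#'
#' Exact counts of feature-sharing links that cross fold boundaries: pairs
#' of EP pairs assigned to different folds that share a promoter
#' (\code{crossFoldPromoterLinks}) or have overlapping window intervals
#' (\code{crossFoldWindowLinks}).  Either count being positive means a
#' model can score held-out pairs by memorizing features seen in training.
#'
#' @slot crossFoldPromoterLinks non-negative integer.
#' @slot crossFoldWindowLinks non-negative integer.
#' @seealso [certify()]
#' @exportClass ContaminationCertificate
setClass("ContaminationCertificate",
  representation(crossFoldPromoterLinks = "numeric",
                 crossFoldWindowLinks = "numeric"))

#' Promoter-sharing matrix
#'
#' Counts of promoter groups -- or of the EP pairs they contain -- indexed
#' by the group's number of positive (\code{n_pos}) and negative
#' (\code{n_neg}) pairs.  With \code{weighting = "pair"} each group
#' contributes its size \code{n_pos + n_neg} to cell
#' \code{(n_pos, n_neg)}; with \code{weighting = "promoter"} it contributes
#' 1.  The two forms satisfy
#' \code{pairCell(a, b) == (a + b) * promoterCell(a, b)} cell by cell.
#'
#' @slot cells \code{data.frame} with columns \code{n_pos}, \code{n_neg},
#'   \code{count}.
#' @slot weighting \code{"pair"} or \code{"promoter"}.
#' @seealso [sharingMatrix()], [plotSharingMatrix()]
#' @exportClass SharingMatrix
setClass("SharingMatrix",
  representation(cells = "data.frame", weighting = "character"))

setValidity("SharingMatrix", function(object) {
  msg <- character()
  if (!object@weighting %in% c("pair", "promoter"))
    msg <- c(msg, "weighting must be 'pair' or 'promoter'")
  if (!all(c("n_pos", "n_neg", "count") %in% colnames(object@cells)))
    msg <- c(msg, "cells needs columns n_pos, n_neg, count")
  if (length(msg)) msg else TRUE
})

#' Synthetic EP-dataset generator configuration
#'
#' Parameters of the synthetic genome, promoter-group profile and feature
#' model used by [simulateEPDataset()].  Defaults emulate the structure of
#' real EP training sets: a ~1:20 positive:negative ratio, 136 epigenomic
#' marks measured over each of the enhancer, promoter and window regions
#' (408 features total), several pairs per promoter, and megabase-scale
#' enhancer-promoter separations.  \code{signalStrength} (a mean shift
#' added to the first \code{nSignalFeatures} enhancer features of positive
#' pairs) is 0 by default, so the label carries no genuine feature signal
#' and any above-random cross-validated performance is attributable purely
#' to feature-sharing leakage.
#'
#' @slot nChromosomes,chromLength synthetic genome shape (bp).
#' @slot nPromoters number of promoter groups.
#' @slot marksPerRegion epigenomic marks per region block (E, P and W each
#'   get this many features).
#' @slot targetPosFraction target global positive fraction (default 1/21,
#'   i.e. 1:20).
#' @slot profileMode \code{"pure_mixture"} (every promoter group all
#'   positive or all negative; maximal promoter-feature leakage) or
#'   \code{"beta"} (group positive fraction drawn from a Beta
#'   distribution, giving mixed groups).
#' @slot groupSizeMean,groupSizeMax expected and maximal pairs per
#'   promoter (sizes are 2 + a truncated geometric draw).
#' @slot betaA,betaB Beta shape parameters for \code{"beta"} mode.
#' @slot trackSegmentBp segment length of the piecewise-constant latent
#'   window track; sets the genomic scale over which window features of
#'   overlapping pairs are correlated.
#' @slot signalStrength,nSignalFeatures genuine label signal (see above).
#' @slot featureNoiseSd per-pair additive Gaussian noise on all features.
#' @slot minDistance,maxDistance enhancer-promoter gap bounds (bp).
#' @slot seed integer RNG seed; the generator is fully deterministic given
#'   the configuration.
#' @seealso [generatorConfig()], [simulateEPDataset()]
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(
    nChromosomes = "integer", chromLength = "numeric", nPromoters = "integer",
    marksPerRegion = "integer", targetPosFraction = "numeric",
    profileMode = "character", groupSizeMean = "numeric",
    groupSizeMax = "integer", betaA = "numeric", betaB = "numeric",
    trackSegmentBp = "numeric", signalStrength = "numeric",
    nSignalFeatures = "integer", featureNoiseSd = "numeric",
    minDistance = "numeric", maxDistance = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  pos <- c(nChromosomes = object@nChromosomes, chromLength = object@chromLength,
           nPromoters = object@nPromoters, marksPerRegion = object@marksPerRegion,
           trackSegmentBp = object@trackSegmentBp,
           minDistance = object@minDistance, maxDistance = object@maxDistance)
  if (any(pos <= 0))
    msg <- c(msg, paste("must be positive:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@targetPosFraction < 0 || object@targetPosFraction >= 1)
    msg <- c(msg, "targetPosFraction must lie in [0, 1)")
  if (!object@profileMode %in% c("pure_mixture", "beta"))
    msg <- c(msg, "profileMode must be 'pure_mixture' or 'beta'")
  if (object@groupSizeMax < 2L)
    msg <- c(msg, "groupSizeMax must be >= 2")
  if (object@groupSizeMean < 2 || object@groupSizeMean > object@groupSizeMax)
    msg <- c(msg, "groupSizeMean must lie in [2, groupSizeMax]")
  if (object@signalStrength < 0)
    msg <- c(msg, "signalStrength must be >= 0")
  if (object@nSignalFeatures < 0 || object@nSignalFeatures > object@marksPerRegion)
    msg <- c(msg, "nSignalFeatures must lie in [0, marksPerRegion]")
  if (object@featureNoiseSd < 0)
    msg <- c(msg, "featureNoiseSd must be >= 0")
  if (object@minDistance >= object@maxDistance)
    msg <- c(msg, "minDistance must be < maxDistance")
  if (length(msg)) msg else TRUE
})

#' Model specification for the benchmark harness
#'
#' @slot family one of \code{"gradient_boosting"}, \code{"random_forest"},
#'   \code{"rbf_svm"}, \code{"linear_svm"}.
#' @slot nTrees tree count for the tree families (gradient boosting
#'   defaults to 4000, random forests to 500).
#' @slot cost misclassification-cost parameter (the SVM \code{C}).
#' @slot gamma RBF kernel scale; \code{NA} means the conventional default
#'   \code{1 / n_features}, resolved at fit time.
#' @seealso [modelSpec()], [runBenchmark()]
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(family = "character", nTrees = "integer", cost = "numeric",
                 gamma = "numeric"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@family %in% c("gradient_boosting", "random_forest",
                            "rbf_svm", "linear_svm"))
    msg <- c(msg, "unknown model family")
  if (object@nTrees < 1L) msg <- c(msg, "nTrees must be >= 1")
  if (object@cost <= 0) msg <- c(msg, "C must be > 0")
  if (!is.na(object@gamma) && object@gamma <= 0)
    msg <- c(msg, "gamma must be > 0")
  if (length(msg)) msg else TRUE
})
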