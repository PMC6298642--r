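#' Accessors for EPDataset
#'
#' \code{pairIds} returns the pair identifiers; \code{pairLabels} the
#' binary interaction labels (named integer vector); \code{promoterIds}
#' the promoter identifier of each pair; \code{enhancerRanges} and
#' \code{promoterRanges} the element intervals as \link[GenomicRanges]{GRanges}
#' (converted from the stored 0-based half-open coordinates);
#' \code{featureMatrix} the pairs x features matrix; \code{featureBlocks}
#' the E/P/W block tag of each feature; \code{nPairs} the number of pairs.
#'
#' @param x An [EPDataset-class].
#' @return See individual descriptions above.
#' @name EPDataset-accessors
#' @aliases pairIds pairLabels promoterIds enhancerRanges promoterRanges
#'   featureMatrix featureBlocks nPairs
NULL

#' @rdname EPDataset-accessors
setMethod("pairIds", "EPDataset", function(x) colnames(x))

#' @rdname EPDataset-accessors
setMethod("pairLabels", "EPDataset", function(x) {
  stats::setNames(colData(x)$label, colnames(x))
})

#' @rdname EPDataset-accessors
setMethod("promoterIds", "EPDataset", function(x) {
  stats::setNames(colData(x)$promoter_id, colnames(x))
})

.bedToGRanges <- function(chrom, start, end, names) {
  gr <- GRanges(chrom, IRanges(start + 1, end))
  names(gr) <- names
  gr
}

#' @rdname EPDataset-accessors
setMethod("enhancerRanges", "EPDataset", function(x) {
  cd <- colData(x)
  .bedToGRanges(cd$chrom, cd$enh_start, cd$enh_end, colnames(x))
})

#' @rdname EPDataset-accessors
setMethod("promoterRanges", "EPDataset", function(x) {
  cd <- colData(x)
  .bedToGRanges(cd$chrom, cd$prom_start, cd$prom_end, colnames(x))
})

#' @rdname EPDataset-accessors
setMethod("featureMatrix", "EPDataset", function(x) t(assay(x, "features")))

#' @rdname EPDataset-accessors
setMethod("featureBlocks", "EPDataset", function(x) {
  stats::setNames(rowData(x)$block, rownames(x))
})

#' @rdname EPDataset-accessors
setMethod("nPairs", "EPDataset", function(x) ncol(x))

#' Window intervals of EP pairs
#'
#' The window of an EP pair is the genomic interval strictly between the
#' enhancer and the promoter: in BED coordinates,
#' \code{[min(enh_end, prom_end), max(enh_start, prom_start))} on the
#' pair's chromosome, regardless of which element lies upstream.  Window
#' (W) features summarize epigenomic signal over this interval, so pairs
#' with overlapping windows share W signal.
#'
#' @param x An [EPDataset-class].
#' @param ... Unused.
#' @return A \link[GenomicRanges]{GRanges} (1-based) with one window per
#'   pair, named by pair identifier.  Adjacent elements (zero-width
#'   window) are an error: such a pair has no intervening interval.
#' @examples
#' pairs <- data.frame(pair_id = "p1", chrom = "chr1",
#'   enh_start = 100L, enh_end = 200L, prom_start = 500L, prom_end = 600L,
#'   promoter_id = "promA", label = 1L)
#' windowRanges(EPDataset(pairs))  # 1-based [201, 500] i.e. BED [200, 500)
#' @rdname windowRanges
#' @export
setMethod("windowRanges", "EPDataset", function(x, ...) {
  cd <- colData(x)
  wstart <- pmin(cd$enh_end, cd$prom_end)
  wend <- pmax(cd$enh_start, cd$prom_start)
  zero <- wstart >= wend
  if (any(zero))
    stop("zero-width window (adjacent enhancer and promoter) for pair(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  .bedToGRanges(cd$chrom, wstart, wend, colnames(x))
})

.windowMidpoint <- function(x) {
  cd <- colData(x)
  (pmin(cd$enh_end, cd$prom_end) + pmax(cd$enh_start, cd$prom_start)) / 2
}

#' Select feature blocks
#'
#' Restricts the feature table to the requested blocks (any non-empty
#' subset of E, P, W), preserving column order.  The full set EPW holds
#' E + P + W features; with the default generator's 136 marks per region
#' the subsets have 408 (EPW), 272 (EP) and 136 (W) features.
#'
#' @param x An [EPDataset-class].
#' @param blocks Character vector, non-empty subset of
#'   \code{c("E", "P", "W")}.
#' @return An [EPDataset-class] containing only the selected features.
#' @rdname featureSubset
#' @export
setMethod("featureSubset", "EPDataset", function(x, blocks) {
  if (length(blocks) == 0L)
    stop("'blocks' must be a non-empty subset of c('E', 'P', 'W')")
  if (!all(blocks %in% c("E", "P", "W")))
    stop("unknown block(s): ", paste(setdiff(blocks, c("E", "P", "W")),
                                     collapse = ", "))
  x[rowData(x)$block %in% blocks, ]
})

setMethod("show", "EPDataset", function(object) {
  cd <- colData(object)
  blocks <- table(factor(rowData(object)$block, levels = c("E", "P", "W")))
  cat("EPDataset with", ncol(object), "EP pairs on",
      length(unique(cd$chrom)), "chromosome(s)\n")
  if (ncol(object)) {
    cat(sprintf("  %d promoter groups; %d positive / %d negative pairs\n",
                length(unique(cd$promoter_id)),
                sum(cd$label == 1L), sum(cd$label == 0L)))
  }
  cat(sprintf("  features: %d (E=%d, P=%d, W=%d)\n",
              nrow(object), blocks[["E"]], blocks[["P"]], blocks[["W"]]))
  invisible(NULL)
})

#' @rdname CVPartition-accessors
#' @name CVPartition-accessors
#' @aliases foldOf nFolds cvScheme
#' @param x A [CVPartition-class].
#' @return \code{foldOf}: named integer vector of fold indices in
#'   \code{[0, k)}; \code{nFolds}: the fold count \code{k};
#'   \code{cvScheme}: the scheme name.
setMethod("foldOf", "CVPartition", function(x) x@fold)

#' @rdname CVPartition-accessors
setMethod("nFolds", "CVPartition", function(x) x@k)

#' @rdname CVPartition-accessors
setMethod("cvScheme", "CVPartition", function(x) x@scheme)

setMethod("show", "CVPartition", function(object) {
  cat(sprintf("CVPartition: %s, k = %d, %d pairs\n", object@scheme,
              object@k, length(object@fold)))
  sizes <- tabulate(object@fold + 1L, nbins = object@k)
  cat("  fold sizes:", paste(sizes, collapse = ", "), "\n")
  if (!is.na(object@seed)) cat("  seed:", object@seed, "\n")
  invisible(NULL)
})

#' @rdname ContaminationCertificate-accessors
#' @name ContaminationCertificate-accessors
#' @aliases crossFoldPromoterLinks crossFoldWindowLinks
#' @param x A [ContaminationCertificate-class].
#' @return The respective cross-fold link count.
setMethod("crossFoldPromoterLinks", "ContaminationCertificate",
          function(x) x@crossFoldPromoterLinks)

#' @rdname ContaminationCertificate-accessors
setMethod("crossFoldWindowLinks", "ContaminationCertificate",
          function(x) x@crossFoldWindowLinks)

setMethod("show", "ContaminationCertificate", function(object) {
  cat("ContaminationCertificate\n")
  cat("  cross-fold promoter links:", object@crossFoldPromoterLinks, "\n")
  cat("  cross-fold window links:  ", object@crossFoldWindowLinks, "\n")
  clean <- object@crossFoldPromoterLinks == 0 && object@crossFoldWindowLinks == 0
  cat(if (clean) "  partition is leakage-free\n" else
    "  partition allows feature-sharing leakage\n")
  invisible(NULL)
})

setMethod("show", "SharingMatrix", function(object) {
  cat(sprintf("SharingMatrix (%s-weighted) with %d occupied cells, total %g\n",
              object@weighting, nrow(object@cells), sum(object@cells$count)))
  invisible(NULL)
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@family)
  if (object@family %in% c("gradient_boosting", "random_forest"))
    cat(", nTrees =", object@nTrees)
  if (object@family %in% c("rbf_svm", "linear_svm"))
    cat(", C =", object@cost)
  if (object@family == "rbf_svm")
    cat(", gamma =", if (is.na(object@gamma)) "1/n_features" else object@gamma)
  cat("\n")
  invisible(NULL)
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:\n")
  cat(sprintf("  genome: %d chromosome(s) x %g bp; %d promoters\n",
              object@nChromosomes, object@chromLength, object@nPromoters))
  cat(sprintf("  profile: %s, mean group size %g (max %d), target pos fraction %.4g\n",
              object@profileMode, object@groupSizeMean, object@groupSizeMax,
              object@targetPosFraction))
  cat(sprintf("  features: %d marks/region (EPW = %d), signal delta = %g on %d E features\n",
              object@marksPerRegion, 3L * object@marksPerRegion,
              object@signalStrength, object@nSignalFeatures))
  cat(sprintf("  seed: %d\n", object@seed))
  invisible(NULL)
})
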