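#' @rdname windowRanges
#' @export
setGeneric("windowRanges", function(x, ...) standardGeneric("windowRanges"))

#' @rdname featureSubset
#' @export
setGeneric("featureSubset", function(x, blocks) standardGeneric("featureSubset"))

#' @rdname EPDataset-accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname EPDataset-accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname EPDataset-accessors
#' @export
setGeneric("promoterIds", function(x) standardGeneric("promoterIds"))

#' @rdname EPDataset-accessors
#' @export
setGeneric("enhancerRanges", function(x) standardGeneric("enhancerRanges"))

#' @rdname EPDataset-accessors
#' @export
setGeneric("promoterRanges", function(x) standardGeneric("promoterRanges"))

#' @rdname EPDataset-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname EPDataset-accessors
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' @rdname EPDataset-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname CVPartition-accessors
#' @export
setGeneric("foldOf", function(x) standardGeneric("foldOf"))

#' @rdname CVPartition-accessors
#' @export
setGeneric("nFolds", function(x) standardGeneric("nFolds"))

#' @rdname CVPartition-accessors
#' @export
setGeneric("cvScheme", function(x) standardGeneric("cvScheme"))

#' @rdname certify
#' @export
setGeneric("certify", function(partition, dataset)
  standardGeneric("certify"))

#' @rdname ContaminationCertificate-accessors
#' @export
setGeneric("crossFoldPromoterLinks",
           function(x) standardGeneric("crossFoldPromoterLinks"))

#' @rdname ContaminationCertificate-accessors
#' @export
setGeneric("crossFoldWindowLinks",
           function(x) standardGeneric("crossFoldWindowLinks"))

#' @rdname sharingMatrix
#' @export
setGeneric("sharingCells", function(x) standardGeneric("sharingCells"))

#' @rdname sharingMatrix
#' @export
setGeneric("sharingCount", function(x, n_pos, n_neg)
  standardGeneric("sharingCount"))
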