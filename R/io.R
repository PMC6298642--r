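#' Read an EP-pair dataset from its two tab-separated files
#'
#' The pairs file has header
#' \code{pair_id chrom enh_start enh_end prom_start prom_end promoter_id
#' label}, one row per EP pair, coordinates 0-based half-open, label 0/1.
#' The features file has a \code{pair_id} column followed by numeric
#' feature columns named \code{<BLOCK>|<mark>} with BLOCK one of E, P, W
#' (e.g. \code{P|H3K4me3}).  Rows are joined on \code{pair_id}; the
#' feature file may list pairs in any order but must cover exactly the
#' pairs in the pairs file.
#'
#' @param pairsPath,featuresPath Paths to the two files.  If
#'   \code{featuresPath} is \code{NULL} the dataset is loaded without
#'   features.
#' @return A validated [EPDataset-class].
#' @seealso [writeEPDataset()]
#' @export
readEPDataset <- function(pairsPath, featuresPath = NULL) {
  pairs <- utils::read.delim(pairsPath, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             colClasses = c(pair_id = "character",
                                            chrom = "character",
                                            promoter_id = "character"))
  need <- c("pair_id", "chrom", "enh_start", "enh_end", "prom_start",
            "prom_end", "promoter_id", "label")
  missing_cols <- setdiff(need, colnames(pairs))
  if (length(missing_cols))
    stop("pairs file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- duplicated(pairs$pair_id)
  if (any(dup))
    stop("duplicate pair_id in pairs file: ",
         paste(unique(pairs$pair_id[dup]), collapse = ", "))
  bad <- which(pairs$enh_start >= pairs$enh_end |
                 pairs$prom_start >= pairs$prom_end)
  if (length(bad))
    stop("malformed interval (start >= end) at pairs-file line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  features <- NULL
  if (!is.null(featuresPath)) {
    ft <- utils::read.delim(featuresPath, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            colClasses = c(pair_id = "character"))
    if (!"pair_id" %in% colnames(ft))
      stop("features file has no pair_id column")
    extra <- setdiff(ft$pair_id, pairs$pair_id)
    if (length(extra))
      stop("pair_id in features file absent from pairs file: ",
           paste(extra, collapse = ", "))
    absent <- setdiff(pairs$pair_id, ft$pair_id)
    if (length(absent))
      stop("pair_id in pairs file absent from features file: ",
           paste(absent, collapse = ", "))
    features <- as.matrix(ft[setdiff(colnames(ft), "pair_id")])
    rownames(features) <- ft$pair_id
    badname <- !grepl("^[EPW]\\|", colnames(features))
    if (any(badname))
      stop("feature column(s) not named '<BLOCK>|<mark>': ",
           paste(colnames(features)[badname], collapse = ", "))
  }
  EPDataset(pairs, features)
}

#' Write an EP-pair dataset to its two tab-separated files
#'
#' Writes the formats read by [readEPDataset()].  Feature values are
#' serialized with 15 significant digits so that a read/write round trip
#' preserves them to well below 1e-9 relative error.
#'
#' @param dataset An [EPDataset-class].
#' @param pairsPath,featuresPath Output paths.  If \code{featuresPath} is
#'   \code{NULL} only the pairs file is written.
#' @return Invisibly, \code{NULL}.
#' @export
writeEPDataset <- function(dataset, pairsPath, featuresPath = NULL) {
  stopifnot(is(dataset, "EPDataset"))
  cd <- colData(dataset)
  pairs <- data.frame(pair_id = colnames(dataset),
                      chrom = cd$chrom,
                      enh_start = format(cd$enh_start, scientific = FALSE,
                                         trim = TRUE),
                      enh_end = format(cd$enh_end, scientific = FALSE,
                                       trim = TRUE),
                      prom_start = format(cd$prom_start, scientific = FALSE,
                                          trim = TRUE),
                      prom_end = format(cd$prom_end, scientific = FALSE,
                                        trim = TRUE),
                      promoter_id = cd$promoter_id,
                      label = cd$label)
  utils::write.table(pairs, pairsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(featuresPath)) {
    fm <- featureMatrix(dataset)
    ft <- data.frame(pair_id = colnames(dataset), check.names = FALSE)
    if (ncol(fm)) {
      vals <- as.data.frame(signif(fm, 15))
      colnames(vals) <- colnames(fm)
      ft <- cbind(ft, vals)
    }
    utils::write.table(ft, featuresPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
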