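#' Heatmap of a promoter-sharing matrix
#'
#' Tile plot of cell counts over (n_pos, n_neg), outlining cells with a
#' 2-fold or greater class imbalance: positively skewed groups in blue,
#' negatively skewed in red.  Skewed cells mark the pairs predictable
#' from shared promoter features alone.
#'
#' @param x A [SharingMatrix-class].
#' @param foldThreshold Imbalance ratio defining skew (default 2).
#' @return A ggplot object.
#' @export
plotSharingMatrix <- function(x, foldThreshold = 2) {
  stopifnot(is(x, "SharingMatrix"))
  df <- sharingCells(x)
  df$skew <- imbalanceClass(df$n_pos, df$n_neg, foldThreshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_pos, y = .data$n_neg)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(.data$count),
                                    colour = .data$skew), linewidth = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(pos_skew = "blue", neg_skew = "red", balanced = "grey60"),
      name = "imbalance") +
    ggplot2::scale_fill_viridis_c(name = "log10 count") +
    ggplot2::labs(
      x = "positive EP pairs per promoter",
      y = "negative EP pairs per promoter",
      title = sprintf("Promoter sharing (%s-weighted)", x@weighting)) +
    ggplot2::theme_minimal()
}

#' Fold-averaged test performance by CV scheme and feature subset
#'
#' Bar chart of mean held-out performance for each combination of
#' partition scheme and feature block subset, with the all-positive
#' baseline drawn as a horizontal line when the positive prevalence is
#' supplied.  Leakage shows up as bars that tower over the baseline
#' under random folds and collapse onto it under segregated folds.
#'
#' @param result A \code{data.frame} from [runBenchmark()] or
#'   [parameterScan()].
#' @param metric Metric stem to plot (default \code{"f1"}).
#' @param posFraction Optional positive prevalence for the baseline
#'   line.
#' @return A ggplot object.
#' @export
plotSchemeComparison <- function(result, metric = "f1",
                                 posFraction = NULL) {
  summ <- summarizeBenchmark(result)
  summ$value <- summ[[paste0("test_", metric)]]
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$scheme,
                                          y = .data$value,
                                          fill = .data$blocks)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "CV scheme", y = paste("test", toupper(metric))) +
    ggplot2::theme_minimal()
  if (!is.null(posFraction))
    p <- p + ggplot2::geom_hline(yintercept = allPositiveF1(posFraction),
                                 linetype = "dotted")
  p
}

#' Train versus test metric across a scanned parameter
#'
#' Line plot of fold-averaged training (dashed) and test (solid)
#' performance against a model parameter, faceted by CV scheme --
#' the standard view of the generalization gap: training performance
#' climbs with capacity while leakage-free test performance does not.
#'
#' @param result A \code{data.frame} from [parameterScan()].
#' @param param Column to place on the x axis (default \code{"n_trees"}).
#' @param metric Metric stem to plot (default \code{"f1"}).
#' @return A ggplot object.
#' @export
plotTrainTestCurves <- function(result, param = "n_trees", metric = "f1") {
  summ <- summarizeBenchmark(result)
  long <- rbind(
    data.frame(summ[c(param, "scheme", "family")], split = "train",
               value = summ[[paste0("train_", metric)]]),
    data.frame(summ[c(param, "scheme", "family")], split = "test",
               value = summ[[paste0("test_", metric)]]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[param]], y = .data$value,
                                     colour = .data$family,
                                     linetype = .data$split)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_linetype_manual(values = c(train = "dashed",
                                              test = "solid")) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = param, y = toupper(metric)) +
    ggplot2::theme_minimal()
}
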