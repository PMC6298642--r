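#' Create a model specification
#'
#' @param family \code{"gradient_boosting"} (histogram-based XGBoost,
#'   logistic objective, learning rate 0.1, depth 3, 64 histogram bins),
#'   \code{"random_forest"} (ranger probability forest),
#'   \code{"rbf_svm"} or \code{"linear_svm"} (e1071, standardized inputs).
#' @param nTrees Tree count; defaults to 4000 for gradient boosting and
#'   500 for random forests, matching the regimes scanned in the
#'   benchmark.
#' @param C SVM misclassification cost (default 1).
#' @param gamma RBF kernel scale; \code{NA} (default) resolves to
#'   \code{1 / n_features} at fit time.
#' @return A [ModelSpec-class].
#' @examples
#' modelSpec("gradient_boosting")
#' modelSpec("rbf_svm", C = 1000, gamma = 0.1)
#' @export
modelSpec <- function(family = c("gradient_boosting", "random_forest",
                                 "rbf_svm", "linear_svm"),
                      nTrees = NULL, C = 1, gamma = NA_real_) {
  family <- match.arg(family)
  if (is.null(nTrees))
    nTrees <- switch(family, gradient_boosting = 4000L,
                     random_forest = 500L, 1L)
  new("ModelSpec", family = family, nTrees = as.integer(nTrees),
      cost = as.numeric(C), gamma = as.numeric(gamma))
}

## Fit on (X, y) and return positive-class scores on a probability-like
## scale for the rows of `newdata` (list of matrices).
.fitAndScore <- function(X, y, spec, seed, newdata) {
  if (length(unique(y)) == 1L) {
    ## degenerate training fold: predict the only observed class
    return(lapply(newdata, function(nd) rep(as.numeric(y[1L]), nrow(nd))))
  }
  if (spec@family == "gradient_boosting") {
    params <- list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                   tree_method = "hist", max_bin = 64, nthread = 1,
                   seed = seed)
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = spec@nTrees, verbose = 0)
    lapply(newdata, function(nd)
      stats::predict(fit, xgboost::xgb.DMatrix(nd, nthread = 1)))
  } else if (spec@family == "random_forest") {
    fit <- ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                          num.trees = spec@nTrees, probability = TRUE,
                          num.threads = 1, seed = seed)
    lapply(newdata, function(nd) {
      pr <- stats::predict(fit, data = nd, num.threads = 1)$predictions
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(nd))
    })
  } else {
    kern <- if (spec@family == "rbf_svm") "radial" else "linear"
    g <- if (is.na(spec@gamma)) 1 / ncol(X) else spec@gamma
    fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                      kernel = kern, cost = spec@cost, gamma = g,
                      scale = TRUE)
    lapply(newdata, function(nd) {
      dv <- attr(stats::predict(fit, nd, decision.values = TRUE),
                 "decision.values")
      ## orient so larger means more positive, then map through the
      ## logistic so the 0.5 threshold coincides with the SVM decision
      flip <- if (strsplit(colnames(dv), "/")[[1]][1] == "1") 1 else -1
      stats::plogis(flip * as.numeric(dv))
    })
  }
}

.metricsRow <- function(prefix, m) {
  stats::setNames(as.numeric(m[c("precision", "recall", "f1", "auroc",
                                 "auprc")]),
                  paste0(prefix, c("precision", "recall", "f1", "auroc",
                                   "auprc")))
}

#' Cross-validated train/test benchmark of one model configuration
#'
#' For each fold of the partition: fits the model on all other folds,
#' scores both the training folds and the held-out fold, and records
#' precision, recall, F1 (threshold 0.5 on the probability-scale score),
#' AUROC and AUPRC for each.  Comparing the train columns with the test
#' columns across partition schemes is the core leakage diagnostic: a
#' large train-test gap under a leakage-free partition combined with
#' high test scores under random folds indicates memorization of shared
#' features rather than generalization.
#'
#' SVM families standardize features internally using training-fold
#' statistics only; tree families consume raw features.  Per-fold model
#' seeds are derived deterministically from \code{seed}.
#'
#' @param dataset An [EPDataset-class].
#' @param partition A [CVPartition-class] covering the dataset.
#' @param blocks Feature blocks to train on (subset of E/P/W; default
#'   all).
#' @param spec A [ModelSpec-class].
#' @param seed Integer run seed for the per-fold model seeds.
#' @return A \code{data.frame} with one row per fold: scheme, blocks,
#'   model fields, fold index, and \code{train_}/\code{test_} prefixed
#'   metrics.  Test metrics of a fold without positive pairs are
#'   \code{NA} (with a warning).
#' @seealso [parameterScan()], [summarizeBenchmark()]
#' @export
runBenchmark <- function(dataset, partition, blocks = c("E", "P", "W"),
                         spec = modelSpec(), seed = 1L) {
  stopifnot(is(dataset, "EPDataset"), is(partition, "CVPartition"),
            is(spec, "ModelSpec"))
  sub <- featureSubset(dataset, blocks)
  X <- featureMatrix(sub)
  y <- as.integer(pairLabels(sub))
  fold <- foldOf(partition)[pairIds(sub)]
  if (anyNA(fold)) stop("partition does not cover this dataset")
  rows <- vector("list", nFolds(partition))
  for (f in seq_len(nFolds(partition)) - 1L) {
    test <- fold == f
    scores <- .fitAndScore(X[!test, , drop = FALSE], y[!test], spec,
                           seed = seed * 1000L + f,
                           newdata = list(train = X[!test, , drop = FALSE],
                                          test = X[test, , drop = FALSE]))
    train_m <- computeMetrics(y[!test], scores$train)
    if (any(y[test] == 1L)) {
      test_m <- computeMetrics(y[test], scores$test)
    } else {
      warning("fold ", f, " has no positive pairs; test metrics undefined")
      test_m <- list(precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                     auroc = NA_real_, auprc = NA_real_)
    }
    rows[[f + 1L]] <- data.frame(
      scheme = cvScheme(partition),
      blocks = paste(blocks, collapse = ""),
      family = spec@family, n_trees = spec@nTrees, C = spec@cost,
      gamma = spec@gamma, fold = f,
      t(c(.metricsRow("train_", train_m), .metricsRow("test_", test_m))))
  }
  do.call(rbind, rows)
}

#' Benchmark a grid of configurations over multiple partitions
#'
#' Runs [runBenchmark()] for every combination of partition and grid
#' entry and concatenates the per-fold results.  Use for tree-count or
#' SVM \code{(C, gamma)} scans contrasting training and test
#' performance.
#'
#' @param dataset An [EPDataset-class].
#' @param partitions List of [CVPartition-class] objects.
#' @param grid List of entries, each a list with elements \code{blocks}
#'   (character) and \code{spec} (a [ModelSpec-class]).
#' @param seed Integer run seed.
#' @return Row-bound \code{data.frame} of [runBenchmark()] results.
#' @export
parameterScan <- function(dataset, partitions, grid, seed = 1L) {
  if (!length(grid)) stop("grid must be non-empty")
  if (is(partitions, "CVPartition")) partitions <- list(partitions)
  res <- list()
  for (part in partitions)
    for (entry in grid)
      res[[length(res) + 1L]] <-
        runBenchmark(dataset, part, blocks = entry$blocks,
                     spec = entry$spec, seed = seed)
  do.call(rbind, res)
}

#' Aggregate per-fold benchmark rows
#'
#' Means of the train/test metrics over folds (NA folds dropped) for each
#' configuration, the usual quantity reported for a CV scheme.
#'
#' @param result A \code{data.frame} from [runBenchmark()] or
#'   [parameterScan()].
#' @return One row per (scheme, blocks, model configuration) with
#'   fold-averaged metrics.
#' @export
summarizeBenchmark <- function(result) {
  keys <- c("scheme", "blocks", "family", "n_trees", "C", "gamma")
  metric_cols <- grep("^(train|test)_", colnames(result), value = TRUE)
  ## NA is a legitimate key value (gamma = 1/n_features), so group on
  ## NA-inclusive factors rather than aggregate()'s NA-dropping `by`
  grp <- interaction(lapply(result[keys], addNA), drop = TRUE)
  first <- which(!duplicated(grp))
  means <- do.call(rbind, lapply(split(result[metric_cols], grp),
                                 function(d) colMeans(d, na.rm = TRUE)))
  out <- cbind(result[first, keys, drop = FALSE],
               means[as.character(grp[first]), , drop = FALSE])
  rownames(out) <- NULL
  out
}
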