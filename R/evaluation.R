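#' Leave-one-site cross-validation over a cohort
#'
#' For each acquisition site in turn: all other sites form the training
#' fold; edgewise t-test selection (per layer) runs on training subjects
#' only; selected features are fused across layers, z-scored with training
#' statistics, and a classifier is trained and applied to the held-out
#' site. Accuracy is reported in percent per fold, then mean +/- sd across
#' folds. For the DANN the held-out site's features (without labels) serve
#' as the unlabeled target domain, and both reporting senses are recorded:
#' "test" (accuracy at the epoch of best training accuracy) and
#' "best_test" (maximum over epochs). For the SVM the two senses coincide.
#'
#' @param cohort list of [RoiTimeSeries-class], or a named list of
#'   precomputed [EdgeFeatureTable-class] (one per layer) to skip network
#'   construction.
#' @param layers layers to build and fuse, subset of
#'   `c("LOFC", "tHOFC", "aHOFC")`.
#' @param classifier `"svm"` or `"dann"`.
#' @param pThreshold p-value cutoff for edge selection (0.01 or 0.05 in the
#'   study design).
#' @param dannArgs named list overriding [DannConfig()] arguments
#'   (`inputDim` is filled per fold).
#' @param useTargetDomain expose the held-out site as unlabeled target
#'   domain during DANN training (default TRUE).
#' @param svmCost linear SVM cost.
#' @param seed base seed for the fold models.
#' @return A [CvReport-class]; its `perFold` slot also records the per-fold
#'   selections via attribute `"selections"` on the report.
#' @export
runLoscv <- function(cohort, layers = "LOFC", classifier = c("svm", "dann"),
                     pThreshold = 0.05, dannArgs = list(),
                     useTargetDomain = TRUE, svmCost = 1, seed = 1L) {
  classifier <- match.arg(classifier)
  tables <- if (is(cohort[[1]], "RoiTimeSeries"))
    buildEdgeFeatures(cohort, layers) else cohort[layers]
  layers <- names(tables)
  cd <- SummarizedExperiment::colData(tables[[1]])
  sites <- unique(cd$site_id)
  if (length(sites) < 2L) stop("leave-one-site CV needs at least 2 sites")
  y <- as.integer(cd$label == "patient")
  perFold <- NULL
  allSelections <- list()
  for (s in sites) {
    test <- cd$site_id == s
    train <- !test
    if (length(unique(y[train])) < 2L)
      stop("training fold for held-out site ", s, " has a single class")
    sel <- lapply(tables, function(tb) {
      p <- edgewiseTTest(featureMatrix(tb)[train, , drop = FALSE],
                         cd$label[train])
      selectEdges(p, pThreshold, layer = layerName(tb), foldId = s)
    })
    allSelections[[s]] <- sel
    fusedTrain <- fuseFeatures(
      lapply(tables, function(tb) featureMatrix(tb)[train, , drop = FALSE]),
      sel)
    fusedTest <- fuseFeatures(
      lapply(tables, function(tb) featureMatrix(tb)[test, , drop = FALSE]),
      sel)
    std <- standardizeFeatures(fusedTrain$features, fusedTest$features)
    nTest <- sum(test)
    if (classifier == "svm") {
      model <- trainSvm(std$train, y[train], cost = svmCost,
                        center = std$center, scale = std$scale)
      pred <- predictLabels(model, fusedTest$features)
      acc <- mean(pred$label == y[test]) * 100
      accBest <- acc
    } else {
      args <- utils::modifyList(
        list(inputDim = ncol(std$train), seed = seed + match(s, sites)),
        dannArgs)
      args$inputDim <- ncol(std$train)
      cfg <- do.call(DannConfig, args)
      model <- trainDann(std$train, y[train], cfg,
                         targetX = if (useTargetDomain) std$test,
                         testX = std$test, testY = y[test],
                         center = std$center, scale = std$scale)
      lg <- model@trainingLog
      bestTrain <- which.max(lg$train_acc)[1]
      acc <- lg$test_acc[bestTrain]
      accBest <- max(lg$test_acc)
    }
    perFold <- rbind(perFold, data.frame(
      site = s, n_test = nTest, accuracy = acc, accuracy_best = accBest))
  }
  report <- new("CvReport",
                configuration = list(layers = layers, classifier = classifier,
                                     pThreshold = pThreshold, seed = seed),
                perFold = perFold, meanSd = summarizeFolds(perFold))
  attr(report, "selections") <- allSelections
  report
}

summarizeFolds <- function(perFold) {
  c(mean = mean(perFold$accuracy), sd = stats::sd(perFold$accuracy),
    mean_best = mean(perFold$accuracy_best),
    sd_best = stats::sd(perFold$accuracy_best),
    pooled = sum(perFold$accuracy * perFold$n_test) / sum(perFold$n_test))
}

#' @rdname runLoscv
#' @param x a [CvReport-class].
#' @export
perFold <- function(x) x@perFold

#' @rdname runLoscv
#' @export
cvSummary <- function(x) x@meanSd

#' Compare two cross-validated configurations
#'
#' Paired two-sided t-test on per-fold accuracies, pairing folds by
#' held-out site. If all per-fold differences are exactly zero, the
#' statistic is 0 and p = 1 (the degenerate identical-report case).
#'
#' @param reportA,reportB [CvReport-class] objects over the same folds.
#' @param sense which accuracy sense to compare, `"test"` or `"best_test"`.
#' @return List with `meanDiff` (A minus B, percentage points),
#'   `statistic`, `df`, `pValue` and `direction` (+1, -1 or 0).
#' @export
compareConfigurations <- function(reportA, reportB,
                                  sense = c("test", "best_test")) {
  sense <- match.arg(sense)
  a <- perFold(reportA); b <- perFold(reportB)
  if (!identical(a$site, b$site))
    stop("reports cover different folds; cannot pair")
  col <- if (sense == "test") "accuracy" else "accuracy_best"
  d <- a[[col]] - b[[col]]
  if (all(d == 0))
    return(list(meanDiff = 0, statistic = 0, df = length(d) - 1L,
                pValue = 1, direction = 0))
  tt <- stats::t.test(a[[col]], b[[col]], paired = TRUE)
  list(meanDiff = mean(d), statistic = unname(tt$statistic),
       df = unname(tt$parameter), pValue = tt$p.value,
       direction = sign(mean(d)))
}

setMethod("show", "CvReport", function(object) {
  cfg <- object@configuration
  cat(sprintf("CvReport: %s, %s, p < %g over %d sites\n",
              paste(cfg$layers, collapse = "+"), cfg$classifier,
              cfg$pThreshold, nrow(object@perFold)))
  cat(sprintf("  accuracy %.2f +/- %.2f %%", object@meanSd["mean"],
              object@meanSd["sd"]))
  if (cfg$classifier == "dann")
    cat(sprintf(" (best_test %.2f +/- %.2f %%)", object@meanSd["mean_best"],
                object@meanSd["sd_best"]))
  cat("\n")
})
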