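#' @import methods
#' @importFrom stats cor pt sd var rnorm runif setNames t.test
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

LAYERS <- c("LOFC", "tHOFC", "aHOFC")

#' Configuration of a synthetic multi-site cohort
#'
#' Describes a simulated resting-state cohort: per-site sample sizes for the
#' two diagnostic groups, a latent correlation structure shared by all
#' subjects, a set of edges on which the patient group's latent correlation
#' is shifted, and site-level distortions (per-ROI scanner gain/offset plus
#' a site-specific perturbation of the latent correlation structure).
#'
#' @slot nRois number of regions of interest (default 116, the AAL atlas).
#' @slot nTimepoints length of each regional time series (default 230).
#' @slot sites data.frame with columns `site_id`, `n_patients`, `n_controls`.
#' @slot effectEdges two-column integer matrix of ROI pairs (i < j) whose
#'   latent correlation is shifted by `effectSize` in patients.
#' @slot effectSize shift added to the latent correlation on effect edges
#'   before projection back to a valid correlation matrix; in [0, 1).
#' @slot baseDensity fraction of nonzero off-diagonal latent correlations.
#' @slot siteShiftSd sd of per-site, per-ROI lognormal gain and Gaussian
#'   offset applied to the signal (invisible to correlation-based networks;
#'   emulates scanner units).
#' @slot siteCorrSd sd of the per-site symmetric perturbation of the latent
#'   correlation matrix; this is what makes sites separable in connectivity
#'   space (the structure domain-adversarial training is meant to fight).
#' @slot seed integer seed governing all randomness of the generator.
#' @export
setClass("CohortConfig", representation(
  nRois = "integer", nTimepoints = "integer", sites = "data.frame",
  effectEdges = "matrix", effectSize = "numeric", baseDensity = "numeric",
  siteShiftSd = "numeric", siteCorrSd = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nRois < 3L) msg <- c(msg, "nRois must be >= 3")
  if (object@nTimepoints < 3L) msg <- c(msg, "nTimepoints must be >= 3")
  s <- object@sites
  if (!all(c("site_id", "n_patients", "n_controls") %in% names(s)))
    msg <- c(msg, "sites needs columns site_id, n_patients, n_controls")
  else {
    if (anyDuplicated(s$site_id)) msg <- c(msg, "duplicate site ids")
    if (any(s$n_patients < 0) || any(s$n_controls < 0) ||
        any(s$n_patients + s$n_controls <= 0))
      msg <- c(msg, "each site needs a nonnegative group split with >= 1 subject")
  }
  ee <- object@effectEdges
  if (nrow(ee)) {
    if (any(ee[, 1L] >= ee[, 2L]))
      msg <- c(msg, "effectEdges must be strict upper-triangle pairs (i < j)")
    if (any(ee < 1L) || any(ee > object@nRois))
      msg <- c(msg, "effectEdges index out of range")
  }
  if (object@effectSize < 0 || object@effectSize >= 1)
    msg <- c(msg, "effectSize must satisfy 0 <= effectSize < 1")
  if (object@baseDensity < 0 || object@baseDensity > 1)
    msg <- c(msg, "baseDensity must lie in [0, 1]")
  if (object@siteShiftSd < 0 || object@siteCorrSd < 0)
    msg <- c(msg, "site effect sds must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' One subject's regional time series
#'
#' @slot data T x N numeric matrix: one column per ROI, one row per scan
#'   timepoint, arbitrary signal units.
#' @slot subjectId,siteId character scalars.
#' @slot label diagnostic group, `"patient"` or `"control"`.
#' @export
setClass("RoiTimeSeries", representation(
  data = "matrix", subjectId = "character", siteId = "character",
  label = "character"))

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "data must be numeric")
  if (nrow(d) < 3L) msg <- c(msg, "need at least 3 timepoints")
  if (ncol(d) < 3L) msg <- c(msg, "need at least 3 ROIs")
  if (!object@label %in% c("patient", "control"))
    msg <- c(msg, "label must be 'patient' or 'control'")
  v <- apply(d, 2L, stats::var)
  if (any(v == 0))
    msg <- c(msg, paste0("zero-variance ROI column(s): ",
                         paste(which(v == 0), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A single-subject connectivity network
#'
#' One N x N weighted network for one subject in one layer: `LOFC`
#' (Pearson correlation of time series), `tHOFC` (correlation of LOFC
#' profiles) or `aHOFC` (cross-layer correlation, symmetrized).
#'
#' @slot values N x N numeric matrix of correlation-like weights.
#' @slot layer one of `"LOFC"`, `"tHOFC"`, `"aHOFC"`.
#' @slot subjectId character scalar.
#' @export
setClass("ConnectivityMatrix", representation(
  values = "matrix", layer = "character", subjectId = "character"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  if (!object@layer %in% LAYERS)
    msg <- c(msg, "layer must be one of LOFC, tHOFC, aHOFC")
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
  if (max(abs(v)) > 1 + 1e-8) msg <- c(msg, "entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Edge features for a cohort, one layer
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' the vectorized strict upper triangles: rows are edges (row-major
#' upper-triangle order, see [edgePairs()]; `rowData` columns `i` and `j`
#' give the ROI pair), columns are subjects with `colData` columns
#' `subject_id`, `site_id`, `label`.
#'
#' @slot layer which network layer the features come from.
#' @export
setClass("EdgeFeatureTable", contains = "SummarizedExperiment",
         representation(layer = "character"))

setValidity("EdgeFeatureTable", function(object) {
  msg <- character()
  if (!object@layer %in% LAYERS) msg <- c(msg, "invalid layer tag")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("i", "j") %in% names(rd))) msg <- c(msg, "rowData needs i, j")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "site_id", "label") %in% names(cd)))
    msg <- c(msg, "colData needs subject_id, site_id, label")
  if (length(msg)) msg else TRUE
})

#' Result of edgewise feature selection on one training fold
#'
#' @slot layer layer tag.
#' @slot pValues per-edge two-sided p-values, length N(N-1)/2.
#' @slot selected ascending edge indices with p < threshold.
#' @slot threshold the p-value cutoff used (the study design uses 0.01 and
#'   0.05 on raw, uncorrected p-values).
#' @slot foldId identifier of the training fold (held-out site).
#' @export
setClass("SelectionResult", representation(
  layer = "character", pValues = "numeric", selected = "integer",
  threshold = "numeric", foldId = "character"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (any(object@pValues < 0 | object@pValues > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  expect <- which(object@pValues < object@threshold)
  if (!identical(as.integer(expect), object@selected))
    msg <- c(msg, "selected must equal {e : p[e] < threshold}, ascending")
  if (length(msg)) msg else TRUE
})

#' Configuration of the domain-adversarial network
#'
#' The network has three parts: a feature extractor (one fully connected
#' layer with BatchNorm-ReLU-Dropout), a label predictor and a domain
#' classifier. The two heads are identical stacks of two fully connected
#' layers with BatchNorm-ReLU-Dropout between them, the second layer half
#' the width of the first, and per-class sigmoid outputs. A gradient
#' reversal layer between extractor and domain classifier multiplies the
#' back-propagated sensitivity by -lambda.
#'
#' @slot inputDim number of input features.
#' @slot extractorWidth width of the extractor layer (default inputDim / 2,
#'   floored, minimum 2).
#' @slot lambdaGrl nonnegative gradient-reversal multiplier (default 1).
#' @slot dropout dropout probability between layers (default 0.5).
#' @slot learningRate Adam learning rate (default 0.001).
#' @slot epochs,batchSize training schedule (defaults 200 and 64).
#' @slot seed integer seed for initialization, dropout and shuffling.
#' @export
setClass("DannConfig", representation(
  inputDim = "integer", extractorWidth = "integer", lambdaGrl = "numeric",
  dropout = "numeric", learningRate = "numeric", epochs = "integer",
  batchSize = "integer", seed = "integer"))

setValidity("DannConfig", function(object) {
  msg <- character()
  if (object@inputDim < 1L) msg <- c(msg, "inputDim must be positive")
  if (object@extractorWidth < 2L) msg <- c(msg, "extractorWidth must be >= 2")
  if (object@lambdaGrl < 0) msg <- c(msg, "lambdaGrl must be >= 0")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@epochs < 1L || object@batchSize < 2L)
    msg <- c(msg, "epochs must be >= 1 and batchSize >= 2")
  if (length(msg)) msg else TRUE
})

#' A fitted classifier bundle
#'
#' Holds the fitted state plus everything needed to apply it to new
#' subjects: the training-fold standardization (mean/sd per feature) and,
#' for the domain-adversarial network, the per-epoch training log.
#'
#' @slot kind `"svm"` or `"dann"`.
#' @slot fit opaque fitted state (an e1071 svm object, or the network's
#'   parameter list).
#' @slot center,scale standardization vectors learned on the training fold.
#' @slot trainingLog data.frame with columns epoch, train_acc, test_acc
#'   (dann only; zero rows for svm).
#' @export
setClass("TrainedModel", representation(
  kind = "character", fit = "ANY", center = "numeric", scale = "numeric",
  trainingLog = "data.frame"))

#' A leave-one-site cross-validation report
#'
#' @slot configuration list describing the run: layers, classifier,
#'   p-value threshold.
#' @slot perFold data.frame with one row per held-out site: `site`,
#'   `n_test`, `accuracy` (percent; the "test" sense for the DANN: accuracy
#'   at the epoch of best training accuracy) and `accuracy_best` (percent;
#'   max over epochs; equal to `accuracy` for the SVM).
#' @slot meanSd named numeric: mean and sd over folds for both senses.
#' @export
setClass("CvReport", representation(
  configuration = "list", perFold = "data.frame", meanSd = "numeric"))

setValidity("CvReport", function(object) {
  pf <- object@perFold
  msg <- character()
  if (!all(c("site", "n_test", "accuracy", "accuracy_best") %in% names(pf)))
    msg <- c(msg, "perFold needs site, n_test, accuracy, accuracy_best")
  else if (nrow(pf) &&
           (any(pf$accuracy < 0 | pf$accuracy > 100) ||
            any(pf$accuracy_best < 0 | pf$accuracy_best > 100)))
    msg <- c(msg, "accuracies must be percentages in [0, 100]")
  if (length(msg)) msg else TRUE
})
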