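#' Exponential inverse-frequency class weights
#'
#' Weights each class c by exp(1/N_c) / sum_c' exp(1/N_c'), where N_c is
#' the class sample count: the smaller class gets the strictly larger
#' weight, and equal counts give uniform weights. Used inside the weighted
#' binary cross-entropy to counter diagnostic class imbalance.
#'
#' @param labels vector of class labels (factor, character or 0/1), every
#'   class present at least once; or a named vector of counts via `counts`.
#' @param counts optional named integer vector of per-class counts,
#'   bypassing `labels`.
#' @return Named numeric vector of weights summing to 1, ordered by class
#'   name, with attribute `counts`.
#' @examples
#' classWeights(c("a", "a", "b"))  # smaller class 'b' gets ~0.622
#' @export
classWeights <- function(labels = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (!length(labels)) stop("no labels given")
    counts <- table(labels)
  }
  counts <- c(counts)
  if (any(counts < 1)) stop("every class must be present at least once")
  w <- exp(1 / as.numeric(counts))
  w <- w / sum(w)
  names(w) <- names(counts)
  attr(w, "counts") <- as.integer(counts)
  w
}

#' Class-weighted binary cross-entropy
#'
#' For per-sample, per-class predicted probabilities yhat and one-hot
#' truths y, computes (1/N) * sum_n sum_c W_c * E(y_nc, yhat_nc), with E
#' the standard binary cross-entropy -[y log yhat + (1-y) log(1-yhat)].
#' Probabilities are clamped to [1e-7, 1 - 1e-7] so exact 0/1 predictions
#' yield a finite loss.
#'
#' @param predicted N x C matrix (or vector) of probabilities in (0, 1).
#' @param truth N x C matrix (or vector) of 0/1 targets.
#' @param weights per-class weights, e.g. from [classWeights()]; default
#'   uniform.
#' @return Scalar loss (nonnegative).
#' @export
weightedBCE <- function(predicted, truth, weights = NULL) {
  p <- rbind(predicted); y <- rbind(truth)
  if (!all(dim(p) == dim(y))) stop("prediction/truth shape mismatch")
  if (is.null(weights)) weights <- rep(1 / ncol(p), ncol(p))
  if (length(weights) != ncol(p)) stop("need one weight per class")
  p <- pmin(pmax(p, CLAMP_EPS), 1 - CLAMP_EPS)
  E <- -(y * log(p) + (1 - y) * log(1 - p))
  sum(sweep(E, 2L, weights, `*`)) / nrow(p)
}

#' Gradient reversal (forward pass)
#'
#' The gradient-reversal layer is the identity in the forward direction;
#' during backpropagation the sensitivity flowing through it is multiplied
#' by -lambda, so the feature extractor is trained to *increase* the domain
#' classifier's loss — the adversarial mechanism that drives site-invariant
#' features. The reversal itself acts inside [trainDann()]'s backward pass;
#' this function documents and exposes the forward contract.
#'
#' @param x input activations.
#' @param lambda nonnegative reversal strength (unused in the forward pass).
#' @return `x`, unchanged.
#' @export
gradientReversal <- function(x, lambda = 1) {
  if (lambda < 0) stop("lambda must be nonnegative")
  x
}

#' Construct a domain-adversarial network configuration
#'
#' @param inputDim number of (fused, standardized) input features.
#' @param extractorWidth width of the single extractor layer; default half
#'   the input dimension (minimum 2).
#' @param lambdaGrl gradient-reversal strength, constant over training.
#' @param dropout,learningRate,epochs,batchSize,seed see
#'   [DannConfig-class].
#' @return A [DannConfig-class].
#' @export
DannConfig <- function(inputDim, extractorWidth = NULL, lambdaGrl = 1,
                       dropout = 0.5, learningRate = 0.001, epochs = 200L,
                       batchSize = 64L, seed = 1L) {
  if (is.null(extractorWidth))
    extractorWidth <- max(2L, as.integer(inputDim) %/% 2L)
  new("DannConfig", inputDim = as.integer(inputDim),
      extractorWidth = as.integer(extractorWidth),
      lambdaGrl = as.numeric(lambdaGrl), dropout = as.numeric(dropout),
      learningRate = as.numeric(learningRate), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

## Shared trainer. targetX = NULL trains a plain MLP (no domain path);
## otherwise the held-out domain's unlabeled features join the adversarial
## domain-classification task. testX/testY, if given, populate the
## per-epoch log used for the "test" / "best_test" reporting senses.
trainNet <- function(X, y, config, targetX = NULL, testX = NULL,
                     testY = NULL) {
  if (ncol(X) == 0L)
    stop("no input features: the edge selection is empty; relax the p-value threshold")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  stopifnot(ncol(X) == config@inputDim)
  params <- nnInit(config@inputDim, config@extractorWidth, config@seed)
  wLab <- classWeights(counts = c(`0` = sum(y == 0), `1` = sum(y == 1)))
  useDomain <- !is.null(targetX) && nrow(targetX) > 0L
  if (useDomain)
    wDom <- classWeights(counts = c(src = nrow(X), tgt = nrow(targetX)))
  state <- list()
  n <- nrow(X); bs <- min(config@batchSize, n)
  log <- data.frame(epoch = integer(), train_acc = numeric(),
                    test_acc = numeric())
  t <- 0L
  for (epoch in seq_len(config@epochs)) {
    perm <- withSeed(subSeed(config@seed, RNG_SHUF, epoch), sample.int(n))
    nb <- ceiling(n / bs)
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * bs + 1L):min(b * bs, n)]
      if (length(idx) < 2L) next  # BN needs a batch
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      ctr <- epoch * 10000L + b
      mE <- dropoutMask(c(length(idx), config@extractorWidth),
                        config@dropout, subSeed(config@seed, RNG_DROP_EXT, ctr))
      mL <- dropoutMask(c(length(idx), params$width2), config@dropout,
                        subSeed(config@seed, RNG_DROP_LAB, ctr))
      fw <- nnForward(params, Xb, head = "lab", train = TRUE,
                      maskExt = mE, maskHead = mL)
      params$ext$bn1 <- bnUpdateRunning(params$ext$bn1, fw$extc$bnc)
      params$lab$bn1 <- bnUpdateRunning(params$lab$bn1, fw$hc$bnc)
      grads <- nnBackward(params, fw,
                          bceLogitGrad(fw$probs, oneHot(yb), wLab))
      if (useDomain) {
        ti <- withSeed(subSeed(config@seed, RNG_TGT, ctr),
                       sample.int(nrow(targetX), min(length(idx),
                                                     nrow(targetX))))
        Xd <- rbind(Xb, targetX[ti, , drop = FALSE])
        yd <- c(rep(0L, length(idx)), rep(1L, length(ti)))
        mEd <- dropoutMask(c(nrow(Xd), config@extractorWidth),
                           config@dropout,
                           subSeed(config@seed, RNG_DROP_DOM, ctr * 2L))
        mD <- dropoutMask(c(nrow(Xd), params$width2), config@dropout,
                          subSeed(config@seed, RNG_DROP_DOM, ctr * 2L + 1L))
        ## domain-path forward does NOT update extractor running stats:
        ## inference-time normalization must reflect labeled source data
        ## only (no unlabeled-target leakage into the deployed path).
        fwd <- nnForward(params, Xd, head = "dom", train = TRUE,
                         maskExt = mEd, maskHead = mD)
        params$dom$bn1 <- bnUpdateRunning(params$dom$bn1, fwd$hc$bnc)
        gd <- nnBackward(params, fwd,
                         bceLogitGrad(fwd$probs, oneHot(yd), wDom),
                         lambdaMult = -config@lambdaGrl)
        grads <- addExtGrads(grads, gd)
      }
      t <- t + 1L
      st <- adamStep(params, grads, state, config@learningRate, t)
      params <- st$params; state <- st$state
    }
    log <- rbind(log, data.frame(
      epoch = epoch, train_acc = nnAccuracy(params, X, y),
      test_acc = if (!is.null(testX)) nnAccuracy(params, testX, testY)
                 else NA_real_))
  }
  list(params = params, log = log)
}

#' Train the domain-adversarial network
#'
#' Jointly minimizes the class-weighted BCE on the source labels and,
#' through the gradient-reversal layer, maximizes confusion between source
#' and target domains, pushing the extractor toward site-invariant
#' features. Optimized with Adam; fully deterministic given the
#' configuration seed.
#'
#' @param X subjects x features numeric matrix (standardize first, e.g.
#'   with [standardizeFeatures()]; pass `center`/`scale` for test-time
#'   reuse).
#' @param y 0/1 labels (1 = patient).
#' @param config a [DannConfig-class].
#' @param targetX unlabeled feature matrix of the target domain (the
#'   held-out site); NULL disables the adversarial path.
#' @param testX,testY optional held-out set for the per-epoch accuracy log
#'   behind the "test" (accuracy at the epoch of best training accuracy)
#'   and "best_test" (maximum over epochs) reporting senses.
#' @param center,scale standardization to store with the model.
#' @return A [TrainedModel-class] of kind `"dann"`.
#' @export
trainDann <- function(X, y, config, targetX = NULL, testX = NULL,
                      testY = NULL, center = rep(0, ncol(X)),
                      scale = rep(1, ncol(X))) {
  validObject(config)
  r <- trainNet(X, y, config, targetX = targetX, testX = testX,
                testY = testY)
  new("TrainedModel", kind = "dann", fit = r$params, center = center,
      scale = scale, trainingLog = r$log)
}

#' Train a plain multilayer perceptron (no domain head)
#'
#' Identical to [trainDann()] with the domain-classification path removed;
#' with `lambdaGrl = 0` the two produce bit-identical extractor and
#' label-predictor trajectories under the same seed.
#'
#' @inheritParams trainDann
#' @return A [TrainedModel-class] of kind `"dann"` (the label path is the
#'   same network).
#' @export
trainMlp <- function(X, y, config, testX = NULL, testY = NULL,
                     center = rep(0, ncol(X)), scale = rep(1, ncol(X))) {
  trainDann(X, y, config, targetX = NULL, testX = testX, testY = testY,
            center = center, scale = scale)
}

#' Train a linear support vector machine
#'
#' Linear soft-margin SVM (cost C = 1 by default) on standardized features;
#' deterministic.
#'
#' @param X subjects x features matrix.
#' @param y 0/1 labels (1 = patient).
#' @param cost soft-margin cost parameter.
#' @param center,scale standardization to store with the model.
#' @return A [TrainedModel-class] of kind `"svm"`.
#' @export
trainSvm <- function(X, y, cost = 1, center = rep(0, ncol(X)),
                     scale = rep(1, ncol(X))) {
  if (ncol(X) == 0L)
    stop("no input features: the edge selection is empty; relax the p-value threshold")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  new("TrainedModel", kind = "svm", fit = fit, center = center,
      scale = scale,
      trainingLog = data.frame(epoch = integer(), train_acc = numeric(),
                               test_acc = numeric()))
}

#' Predict labels and scores for new subjects
#'
#' Applies the model's stored training-fold standardization, then the
#' fitted classifier; the DANN uses its label-predictor head only, with
#' batch normalization in inference mode.
#'
#' @param model a [TrainedModel-class].
#' @param X subjects x features matrix on the *raw* (unstandardized) scale,
#'   with the same feature width the model was trained on.
#' @return data.frame with `label` (0/1) and `score` (patient probability
#'   for the DANN; decision value for the SVM).
#' @export
predictLabels <- function(model, X) {
  X <- rbind(X)
  if (ncol(X) != length(model@center))
    stop("feature width ", ncol(X), " does not match the model (",
         length(model@center), ")")
  Xs <- sweep(sweep(X, 2L, model@center, `-`), 2L, model@scale, `/`)
  if (model@kind == "svm") {
    pr <- stats::predict(model@fit, Xs, decision.values = TRUE)
    data.frame(label = as.integer(as.character(pr)),
               score = as.numeric(attr(pr, "decision.values")))
  } else {
    p <- nnForward(model@fit, Xs, head = "lab", train = FALSE)$probs
    data.frame(label = as.integer(p[, 2L] > p[, 1L]), score = p[, 2L])
  }
}

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel [%s]: %d features%s\n", object@kind,
              length(object@center),
              if (nrow(object@trainingLog))
                sprintf(", %d epochs logged", nrow(object@trainingLog))
              else ""))
})
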