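#' Edgewise two-sample t-tests between diagnostic groups
#'
#' For every edge, a two-sided pooled-variance (Student) two-sample t-test
#' compares patients against controls; the vector of raw p-values drives
#' threshold-based feature selection. Welch's unequal-variance form is
#' available behind `welch = TRUE`. Degenerate edges with zero pooled
#' variance get p = 1 (never selected) with a warning.
#'
#' @param table an [EdgeFeatureTable-class], or a subjects x edges matrix.
#' @param labels per-subject group labels (`"patient"`/`"control"`); taken
#'   from `colData` when `table` is an [EdgeFeatureTable-class].
#' @param welch use Welch's t-test instead of the pooled-variance form.
#' @return Numeric vector of per-edge p-values in [0, 1].
#' @export
edgewiseTTest <- function(table, labels = NULL, welch = FALSE) {
  if (is(table, "EdgeFeatureTable")) {
    if (is.null(labels))
      labels <- SummarizedExperiment::colData(table)$label
    X <- featureMatrix(table)
  } else X <- as.matrix(table)
  g1 <- labels == "patient"; g2 <- labels == "control"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 subjects (have ", n1, " patients, ",
         n2, " controls)")
  m1 <- colMeans(X[g1, , drop = FALSE]); m2 <- colMeans(X[g2, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(X[g2, , drop = FALSE], 2L, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, length(se2))
  }
  p <- rep.int(1, ncol(X))
  bad <- se2 == 0
  if (any(bad))
    warning(sum(bad), " edge(s) with zero pooled variance; p set to 1",
            call. = FALSE)
  ok <- !bad
  t <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  p[ok] <- 2 * stats::pt(-abs(t), df[ok])
  p
}

#' Threshold p-values into a selection result
#'
#' Strict-inequality selection (p < threshold) on raw, uncorrected
#' p-values, mirroring the study design's cutoffs of 0.01 and 0.05. An
#' empty selection is legal and propagates downstream.
#'
#' @param pValues per-edge p-values.
#' @param threshold cutoff in (0, 1).
#' @param layer,foldId bookkeeping tags stored on the result.
#' @return A [SelectionResult-class].
#' @export
selectEdges <- function(pValues, threshold, layer = "LOFC", foldId = "all") {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  new("SelectionResult", layer = layer, pValues = as.numeric(pValues),
      selected = which(pValues < threshold), threshold = threshold,
      foldId = foldId)
}

#' @rdname selectEdges
#' @param x a [SelectionResult-class].
#' @export
selectedEdges <- function(x) x@selected

#' Fuse selected features across network layers
#'
#' Concatenates the selected columns of each layer's feature table, in
#' canonical layer order (LOFC, tHOFC, aHOFC), into one multi-layer feature
#' matrix. A single-layer run is the degenerate case with one block; an
#' empty selection contributes zero columns.
#'
#' @param tables named list of [EdgeFeatureTable-class] (or subjects x edges
#'   matrices), one per layer.
#' @param selections named list of [SelectionResult-class] aligned with
#'   `tables`.
#' @return A list with `features` (subjects x total-selected matrix) and
#'   `provenance` (data.frame `layer`, `edge` mapping each column back to
#'   its source).
#' @export
fuseFeatures <- function(tables, selections) {
  layers <- LAYERS[LAYERS %in% names(tables)]
  if (!length(layers)) stop("no recognizable layers in 'tables'")
  mats <- lapply(layers, function(l) {
    X <- if (is(tables[[l]], "EdgeFeatureTable")) featureMatrix(tables[[l]])
         else as.matrix(tables[[l]])
    X[, selectedEdges(selections[[l]]), drop = FALSE]
  })
  subj <- lapply(layers, function(l) {
    if (is(tables[[l]], "EdgeFeatureTable"))
      SummarizedExperiment::colData(tables[[l]])$subject_id
    else rownames(tables[[l]])
  })
  for (k in seq_along(subj)[-1])
    if (!identical(subj[[k]], subj[[1]]))
      stop("subject ordering differs between layers")
  prov <- do.call(rbind, lapply(seq_along(layers), function(k) {
    sel <- selectedEdges(selections[[layers[k]]])
    if (!length(sel)) return(NULL)
    data.frame(layer = layers[k], edge = sel)
  }))
  if (is.null(prov)) prov <- data.frame(layer = character(), edge = integer())
  feats <- do.call(cbind, mats)
  if (is.null(feats)) feats <- matrix(0, length(subj[[1]]), 0L)
  rownames(feats) <- subj[[1]]
  list(features = feats, provenance = prov)
}

#' Edges selected in every cross-validation fold
#'
#' Intersects the selected edge sets across training folds; an edge that
#' survives every round is a stable marker of the group difference. Used to
#' report per-layer stable edges and edges unique to one layer.
#'
#' @param selections list of [SelectionResult-class] (>= 2), one per fold,
#'   all from the same layer.
#' @return Sorted integer vector of edge indices selected in all folds.
#' @export
stableEdges <- function(selections) {
  if (length(selections) < 2L) stop("need selections from at least 2 folds")
  sets <- lapply(selections, selectedEdges)
  sort(Reduce(intersect, sets))
}

#' Standardize features with training-fold statistics
#'
#' Z-scores each column using mean/sd learned on the training fold only;
#' constant columns get scale 1 so they map to 0 rather than NaN. The
#' returned center/scale are stored with the fold's model and reused at
#' test time.
#'
#' @param train,test subjects x features matrices (test optional).
#' @return List with standardized `train`, `test` (or NULL) and the
#'   `center`/`scale` vectors.
#' @export
standardizeFeatures <- function(train, test = NULL) {
  center <- colMeans(train)
  scale <- apply(train, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  std <- function(m) sweep(sweep(m, 2L, center, `-`), 2L, scale, `/`)
  list(train = std(train), test = if (!is.null(test)) std(test),
       center = center, scale = scale)
}

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s, fold %s]: %d / %d edges at p < %g\n",
              object@layer, object@foldId, length(object@selected),
              length(object@pValues), object@threshold))
})
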