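## Pearson correlation of two vectors with a documented degenerate branch:
## a zero-variance argument yields 0 (treated as absent connectivity) with
## a warning, instead of NA or an error, so batch network construction over
## a cohort never aborts mid-run.
corrOrZero <- function(a, b, context = "") {
  va <- sum((a - mean(a))^2); vb <- sum((b - mean(b))^2)
  if (va == 0 || vb == 0) {
    warning("degenerate (zero-variance) profile; entry set to 0 ", context,
            call. = FALSE)
    return(0)
  }
  sum((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
}

#' Low-order functional connectivity (Pearson network)
#'
#' The classical functional connectivity network: entry (i, j) is the
#' Pearson correlation between the time series of ROIs i and j. The matrix
#' is symmetric with unit diagonal.
#'
#' @param ts a [RoiTimeSeries-class].
#' @return A [ConnectivityMatrix-class] with layer `"LOFC"`.
#' @examples
#' cfg <- CohortConfig(nRois = 6, nTimepoints = 40,
#'                     sites = data.frame(site_id = "s1", n_patients = 1,
#'                                        n_controls = 0), seed = 3)
#' lofc <- computeLOFC(generateCohort(cfg)[[1]])
#' @export
computeLOFC <- function(ts) {
  d <- tsData(ts)
  if (nrow(d) < 3L) stop("need at least 3 timepoints for correlation")
  v <- apply(d, 2L, stats::var)
  if (any(v == 0))
    stop("correlation undefined: zero-variance ROI column(s) ",
         paste(which(v == 0), collapse = ", "))
  W <- unname(stats::cor(d))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  new("ConnectivityMatrix", values = W, layer = "LOFC",
      subjectId = subjectId(ts))
}

#' Topographical high-order functional connectivity
#'
#' Entry (i, j) is the Pearson correlation between the LOFC connectivity
#' profiles of ROIs i and j — their rows of the LOFC matrix restricted to
#' partners k with k != i and k != j. Two regions are strongly connected in
#' this layer when they attach to the rest of the brain in a similar
#' pattern, regardless of their direct coupling. Diagonal set to 1 by
#' convention (never enters the feature vector).
#'
#' @param lofc a [ConnectivityMatrix-class] of layer `"LOFC"`.
#' @return A [ConnectivityMatrix-class] with layer `"tHOFC"`.
#' @export
computeTHOFC <- function(lofc) {
  stopifnot(is(lofc, "ConnectivityMatrix"))
  if (lofc@layer != "LOFC") stop("input must be an LOFC matrix")
  W <- lofc@values
  n <- nrow(W)
  if (n < 4L) stop("tHOFC needs at least 4 ROIs (profiles too short)")
  H <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- setdiff(seq_len(n), c(i, j))
    r <- corrOrZero(W[i, k], W[j, k], sprintf("(tHOFC %d,%d)", i, j))
    H[i, j] <- H[j, i] <- r
  }
  new("ConnectivityMatrix", values = H, layer = "tHOFC",
      subjectId = lofc@subjectId)
}

#' Associated high-order functional connectivity
#'
#' Cross-layer coupling: the raw entry (i, j) correlates the tHOFC profile
#' of ROI i with the LOFC profile of ROI j over partners k != i, j. The raw
#' matrix is not symmetric, so it is symmetrized as (A + A')/2, after which
#' upper-triangle vectorization is well defined.
#'
#' @param thofc a [ConnectivityMatrix-class] of layer `"tHOFC"`.
#' @param lofc the matching subject's `"LOFC"` matrix.
#' @return A [ConnectivityMatrix-class] with layer `"aHOFC"`.
#' @export
computeAHOFC <- function(thofc, lofc) {
  stopifnot(is(thofc, "ConnectivityMatrix"), is(lofc, "ConnectivityMatrix"))
  if (thofc@layer != "tHOFC" || lofc@layer != "LOFC")
    stop("arguments must be (tHOFC, LOFC) matrices")
  if (!identical(thofc@subjectId, lofc@subjectId))
    stop("tHOFC and LOFC belong to different subjects")
  H <- thofc@values; W <- lofc@values
  n <- nrow(W)
  if (n < 4L || nrow(H) != n) stop("need matching matrices with >= 4 ROIs")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    k <- setdiff(seq_len(n), c(i, j))
    A[i, j] <- corrOrZero(H[i, k], W[j, k], sprintf("(aHOFC %d,%d)", i, j))
  }
  S <- (A + t(A)) / 2
  diag(S) <- diag(A)
  new("ConnectivityMatrix", values = S, layer = "aHOFC",
      subjectId = lofc@subjectId)
}

#' Vectorize the strict upper triangle of a connectivity matrix
#'
#' Compresses a symmetric N x N network into its N(N-1)/2 edge weights in
#' row-major strict-upper-triangle order (see [edgePairs()]). For the
#' 116-region AAL atlas this yields the familiar 6670-dimensional edge
#' feature vector.
#'
#' @param m a [ConnectivityMatrix-class] or a symmetric numeric matrix.
#' @param tol asymmetry tolerance (absolute), default 1e-8.
#' @return Numeric vector of length N(N-1)/2, with attribute `edgeIndex`
#'   (the [edgePairs()] matrix).
#' @export
vectorizeUpper <- function(m, tol = 1e-8) {
  v <- if (is(m, "ConnectivityMatrix")) m@values else m
  if (nrow(v) != ncol(v)) stop("matrix must be square")
  checkSymmetric(v, tol, "connectivity matrix")
  out <- upperVec(v)
  attr(out, "edgeIndex") <- edgePairs(nrow(v))
  out
}

#' Build per-layer edge feature tables for a cohort
#'
#' Computes the requested network layers for every subject and vectorizes
#' them into one [EdgeFeatureTable-class] per layer (edges in rows,
#' subjects in columns, phenotype in `colData`).
#'
#' @param cohort list of [RoiTimeSeries-class].
#' @param layers subset of `c("LOFC", "tHOFC", "aHOFC")`; high-order layers
#'   imply computing their prerequisites.
#' @return Named list of [EdgeFeatureTable-class], one per requested layer,
#'   in canonical layer order.
#' @export
buildEdgeFeatures <- function(cohort, layers = "LOFC") {
  layers <- match.arg(layers, LAYERS, several.ok = TRUE)
  layers <- LAYERS[LAYERS %in% layers]
  if (!length(cohort)) stop("empty cohort")
  n <- ncol(tsData(cohort[[1]]))
  pairs <- edgePairs(n)
  nE <- nrow(pairs)
  mats <- lapply(layers, function(l) matrix(NA_real_, nE, length(cohort)))
  names(mats) <- layers
  for (s in seq_along(cohort)) {
    lofc <- computeLOFC(cohort[[s]])
    thofc <- if (any(c("tHOFC", "aHOFC") %in% layers)) computeTHOFC(lofc)
    if ("LOFC" %in% layers) mats[["LOFC"]][, s] <- vectorizeUpper(lofc)
    if ("tHOFC" %in% layers) mats[["tHOFC"]][, s] <- vectorizeUpper(thofc)
    if ("aHOFC" %in% layers)
      mats[["aHOFC"]][, s] <- vectorizeUpper(computeAHOFC(thofc, lofc))
  }
  cd <- S4Vectors::DataFrame(subject_id = subjectId(cohort),
                             site_id = siteId(cohort),
                             label = subjectLabel(cohort))
  rd <- S4Vectors::DataFrame(i = pairs[, "i"], j = pairs[, "j"])
  out <- lapply(layers, function(l) {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(features = mats[[l]]), rowData = rd, colData = cd)
    colnames(se) <- cd$subject_id
    new("EdgeFeatureTable", se, layer = l)
  })
  names(out) <- layers
  out
}

#' Accessors for edge feature tables
#' @param x an [EdgeFeatureTable-class].
#' @return `featureMatrix`: subjects x edges numeric matrix; `layerName`:
#'   the layer tag; `edgeTable`: data.frame of ROI pairs.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @rdname featureMatrix
#' @export
layerName <- function(x) x@layer

#' @rdname featureMatrix
#' @export
edgeTable <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x)[, c("i", "j")])

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix [%s] subject %s: %d x %d\n", object@layer,
              object@subjectId, nrow(object@values), ncol(object@values)))
})
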