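## Independent longhand oracles. These deliberately take a different route
## from the package code: the Pearson oracle spells out the moment sums
## (the package's LOFC uses stats::cor), while the high-order oracles build
## the two profile vectors explicitly and hand them to stats::cor (the
## package computes the moments inline).

oraclePearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

oracleLofc <- function(X) {
  n <- ncol(X)
  W <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    W[i, j] <- W[j, i] <- oraclePearson(X[, i], X[, j])
  }
  W
}

oracleThofc <- function(W) {
  n <- ncol(W)
  H <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- setdiff(seq_len(n), c(i, j))
    H[i, j] <- H[j, i] <- stats::cor(W[i, k], W[j, k])
  }
  H
}

oracleAhofc <- function(H, W) {
  n <- ncol(W)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    k <- setdiff(seq_len(n), c(i, j))
    A[i, j] <- stats::cor(H[i, k], W[j, k])
  }
  (A + t(A)) / 2
}

## plain (unweighted) binary cross-entropy averaged over samples, uniform
## over classes
oraclePlainBce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(rowMeans(-(y * log(p) + (1 - y) * log(1 - p))))
}

## brute-force row-major upper-triangle enumeration
oracleEdgeList <- function(n) {
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out <- rbind(out, c(i, j))
  out
}

## a subject with prescribed data for unit fixtures
makeSubject <- function(data, id = "s1", site = "siteA", label = "control") {
  new("RoiTimeSeries", data = data, subjectId = id, siteId = site,
      label = label)
}

## small multi-site config used across tests
smallConfig <- function(seed, nRois = 10, T = 60, nPat = 10, nCon = 10,
                        sites = c("a", "b", "c"), effectEdges = NULL,
                        effectSize = 0, siteCorrSd = 0.05, ...) {
  CohortConfig(
    nRois = nRois, nTimepoints = T,
    sites = data.frame(site_id = sites, n_patients = nPat,
                       n_controls = nCon),
    effectEdges = if (is.null(effectEdges)) matrix(integer(), 0, 2)
                  else effectEdges,
    effectSize = effectSize, baseDensity = 0.1, siteShiftSd = 0.1,
    siteCorrSd = siteCorrSd, seed = seed, ...)
}

randomSymmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
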