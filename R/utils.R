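#' Enumerate the strict upper triangle in row-major order
#'
#' Edge features use a fixed, documented ordering: ROI pairs (i, j) with
#' i < j, listed row by row, i.e. (1,2), (1,3), ..., (1,N), (2,3), ...
#' All vectorized networks, selection results and reported discriminative
#' edges use this convention (1-based ROI indices).
#'
#' @param nRois number of regions of interest (N >= 2).
#' @return A two-column integer matrix with columns `i` and `j` and
#'   N(N-1)/2 rows.
#' @examples
#' edgePairs(4)
#' @export
edgePairs <- function(nRois) {
  nRois <- as.integer(nRois)
  if (is.na(nRois) || nRois < 2L)
    stop("'nRois' must be an integer >= 2")
  i <- rep.int(seq_len(nRois - 1L), times = (nRois - 1L):1L)
  j <- unlist(lapply(seq_len(nRois - 1L), function(k) (k + 1L):nRois),
              use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Map ROI pairs to edge indices
#'
#' Inverse of [edgePairs()]: given pairs (i, j) with i < j, return their
#' position in the row-major strict-upper-triangle ordering.
#'
#' @param pairs two-column matrix of ROI indices, each row (i, j), i < j.
#' @param nRois number of ROIs the ordering refers to.
#' @return Integer vector of edge indices in 1..N(N-1)/2.
#' @export
edgeIndexOf <- function(pairs, nRois) {
  pairs <- rbind(pairs)
  i <- as.integer(pairs[, 1L]); j <- as.integer(pairs[, 2L])
  if (any(i >= j)) stop("edge pairs must satisfy i < j")
  if (any(i < 1L) || any(j > nRois))
    stop("edge pair index out of range for nRois = ", nRois)
  # edges preceding row i: sum_{r<i} (N - r); offset within row: j - i
  as.integer((i - 1L) * nRois - (i - 1L) * i / 2L + (j - i))
}

## Row-major strict-upper-triangle extraction. t(m)[lower.tri(m)] walks the
## transposed matrix column-major, which is exactly row-major on the upper
## triangle of m.
upperVec <- function(m) t(m)[lower.tri(m)]

## Scatter a vector back into a symmetric matrix (diagonal given separately).
upperUnvec <- function(v, nRois, diag = 1) {
  m <- matrix(0, nRois, nRois)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag
  m
}

checkSymmetric <- function(m, tol = 1e-8, what = "matrix") {
  d <- max(abs(m - t(m)))
  if (d > tol)
    stop(sprintf("%s is asymmetric beyond tolerance %g (max |W - W'| = %g)",
                 what, tol, d))
  invisible(TRUE)
}

#' Project a symmetric matrix to a nearby SPD correlation matrix
#'
#' Eigenvalues are clipped at a small positive floor and the result is
#' rescaled to unit diagonal. Because the rescaling is a congruence by a
#' positive diagonal matrix, positive definiteness is preserved, so a single
#' clip-and-rescale pass suffices.
#'
#' @param m symmetric matrix with unit-ish diagonal.
#' @param eigFloor smallest admissible eigenvalue before rescaling.
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @export
nearestCorrelation <- function(m, eigFloor = 1e-4) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eigFloor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- stats::cov2cor(out)
  out <- (out + t(out)) / 2
  if (min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("internal error: SPD projection failed to return a positive-definite matrix")
  out
}

## Deterministic substream seeds: each stochastic component of a model draws
## from its own stream so that adding or removing an unrelated component
## (e.g. the domain head) cannot perturb another component's draws.
subSeed <- function(seed, component, counter = 0L) {
  s <- (as.double(seed %% 100000L) * 7919 +
        as.double(component) * 104729 +
        as.double(counter) * 7907) %% 2147483629
  as.integer(s)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, then
## restore the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
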