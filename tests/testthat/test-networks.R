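test_that("LOFC is the Pearson network with unit diagonal", {
  set.seed(10)
  base <- rnorm(30)
  X <- cbind(a = base, b = 2 * base + 1, c = -base + 5, d = rnorm(30))
  lofc <- computeLOFC(makeSubject(X))
  W <- lofc@values
  expect_equal(W[1, 2], 1)           # exact affine copy
  expect_equal(W[1, 3], -1)          # perfect anticorrelation
  expect_equal(diag(W), rep(1, 4))
  expect_equal(W, t(W))
})

test_that("LOFC matches the longhand moment-sum oracle on a fixed fixture", {
  X <- matrix(c(1, 3, 2, 5, 4, 6,
                2, 1, 4, 3, 6, 5,
                9, 7, 8, 5, 6, 4), nrow = 6)
  lofc <- computeLOFC(makeSubject(X))
  expect_equal(lofc@values, oracleLofc(X), tolerance = 1e-12)
})

test_that("LOFC rejects degenerate input naming the offending ROI", {
  X <- cbind(rnorm(10), rep(2, 10), rnorm(10))
  expect_error(computeLOFC(makeSubject(X)), "zero-variance ROI")
  expect_error(computeLOFC(makeSubject(X)), "2")
})

test_that("tHOFC correlates connectivity profiles with both ROIs excluded", {
  W <- randomSymmetric(6, seed = 21)
  lofc <- new("ConnectivityMatrix", values = W, layer = "LOFC",
              subjectId = "s1")
  th <- computeTHOFC(lofc)
  expect_equal(th@values, oracleThofc(W), tolerance = 1e-12)
  expect_equal(diag(th@values), rep(1, 6))
  expect_equal(th@values, t(th@values))
})

test_that("tHOFC degenerate constant profiles take the zero branch", {
  W <- matrix(0.5, 5, 5); diag(W) <- 1
  lofc <- new("ConnectivityMatrix", values = W, layer = "LOFC",
              subjectId = "s1")
  w <- capture_warnings(th <- computeTHOFC(lofc))
  expect_true(all(grepl("degenerate", w)))
  expect_equal(th@values[1, 2], 0)
})

test_that("aHOFC symmetrizes the cross-layer correlation matrix", {
  W <- randomSymmetric(6, seed = 22)
  lofc <- new("ConnectivityMatrix", values = W, layer = "LOFC",
              subjectId = "s1")
  th <- computeTHOFC(lofc)
  ah <- computeAHOFC(th, lofc)
  ## off-diagonal agreement with the longhand oracle (diagonal is a
  ## documented convention and never enters the feature vector)
  O <- oracleAhofc(th@values, W)
  offd <- !diag(TRUE, 6)
  expect_equal(ah@values[offd], O[offd], tolerance = 1e-12)
  expect_equal(ah@values, t(ah@values))
})

test_that("aHOFC of (tHOFC = LOFC) reduces to symmetrized tHOFC of LOFC", {
  W <- randomSymmetric(6, seed = 23)
  lofc <- new("ConnectivityMatrix", values = W, layer = "LOFC",
              subjectId = "s1")
  fakeTh <- new("ConnectivityMatrix", values = W, layer = "tHOFC",
                subjectId = "s1")
  ah <- computeAHOFC(fakeTh, lofc)
  raw <- oracleThofc(W)       # raw A is symmetric here, so averaging is a
  offd <- !diag(TRUE, 6)      # fixed point off the diagonal
  expect_equal(ah@values[offd], raw[offd], tolerance = 1e-12)
})

test_that("aHOFC refuses mismatched subjects", {
  W <- randomSymmetric(5, seed = 24)
  lofc <- new("ConnectivityMatrix", values = W, layer = "LOFC",
              subjectId = "s1")
  th <- computeTHOFC(lofc)
  th@subjectId <- "s2"
  expect_error(computeAHOFC(th, lofc), "different subjects")
})

test_that("vectorization follows row-major strict upper triangle", {
  m <- matrix(c(1, 0.1, 0.2,
                0.1, 1, 0.3,
                0.2, 0.3, 1), 3, 3)
  cm <- new("ConnectivityMatrix", values = m, layer = "LOFC",
            subjectId = "s")
  expect_equal(as.numeric(vectorizeUpper(cm)), c(0.1, 0.2, 0.3))
  expect_equal(length(vectorizeUpper(randomSymmetric(116, 1))), 6670)
  bad <- m; bad[1, 2] <- 0.9
  expect_error(vectorizeUpper(bad), "asymmetric")
})

test_that("vectorize/devectorize round-trips off-diagonal entries", {
  for (seed in 1:5) {
    W <- randomSymmetric(7, seed)
    v <- vectorizeUpper(W)
    back <- hofcnet:::upperUnvec(as.numeric(v), 7, diag = 1)
    expect_equal(back, W, tolerance = 1e-15)
  }
})

test_that("edge index helpers agree with brute-force enumeration", {
  for (n in c(4, 7, 10)) {
    expect_equal(unname(edgePairs(n)), unname(oracleEdgeList(n)))
    all <- oracleEdgeList(n)
    expect_equal(edgeIndexOf(all, n), seq_len(nrow(all)))
  }
})

test_that("ROI relabeling permutes all three layers conjugately", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40, 6)
  perm <- sample(6)
  P <- diag(6)[perm, ]
  l1 <- computeLOFC(makeSubject(X))
  t1 <- computeTHOFC(l1)
  a1 <- computeAHOFC(t1, l1)
  l2 <- computeLOFC(makeSubject(X[, perm]))
  t2 <- computeTHOFC(l2)
  a2 <- computeAHOFC(t2, l2)
  expect_equal(l2@values, P %*% l1@values %*% t(P), tolerance = 1e-12)
  expect_equal(t2@values, P %*% t1@values %*% t(P), tolerance = 1e-12)
  offd <- !diag(TRUE, 6)
  A1p <- (P %*% a1@values %*% t(P))
  expect_equal(a2@values[offd], A1p[offd], tolerance = 1e-12)
})

test_that("all layer entries stay within correlation bounds, layers differ", {
  cfg <- smallConfig(seed = 12, nRois = 8, T = 50, nPat = 2, nCon = 2,
                     sites = "s1")
  coh <- generateCohort(cfg)
  for (s in coh) {
    l <- computeLOFC(s); t <- computeTHOFC(l); a <- computeAHOFC(t, l)
    for (m in list(l@values, t@values, a@values)) {
      expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
    }
    expect_gt(max(abs(t@values - l@values)), 0)  # tHOFC is not LOFC rewired
  }
})

test_that("buildEdgeFeatures assembles aligned per-layer tables", {
  cfg <- smallConfig(seed = 13, nRois = 6, T = 40, nPat = 3, nCon = 2,
                     sites = c("x", "y"))
  coh <- generateCohort(cfg)
  tabs <- buildEdgeFeatures(coh, c("LOFC", "aHOFC"))
  expect_named(tabs, c("LOFC", "aHOFC"))
  X <- featureMatrix(tabs$LOFC)
  expect_equal(dim(X), c(10, 15))
  ## spot-check: feature column e equals matrix entry at the edge pair
  l <- computeLOFC(coh[[4]])
  et <- edgeTable(tabs$LOFC)
  for (e in c(1, 7, 15))
    expect_equal(as.numeric(X[4, e]), l@values[et$i[e], et$j[e]])
  cd <- SummarizedExperiment::colData(tabs$aHOFC)
  expect_equal(cd$subject_id, subjectId(coh))
})
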