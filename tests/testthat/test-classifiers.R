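test_that("class weights follow the exponential inverse-count rule", {
  w <- classWeights(rep(c("a", "b"), each = 5))
  expect_equal(as.numeric(w), c(0.5, 0.5))
  ## counts (1, 2): direct evaluation of the closed form
  w2 <- classWeights(c("a", "b", "b"))
  expect_equal(unname(w2["a"]), exp(1) / (exp(1) + exp(0.5)),
               tolerance = 1e-12)
  expect_equal(unname(w2["a"]), 0.62246, tolerance = 1e-5)
  expect_equal(unname(w2["b"]), 0.37754, tolerance = 1e-5)
  ## smaller class strictly heavier; weights always normalize
  set.seed(51)
  for (rep in 1:10) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    w <- classWeights(counts = c(a = n1, b = n2))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    if (n1 < n2) expect_gt(w["a"], w["b"])
    if (n1 > n2) expect_lt(w["a"], w["b"])
  }
  expect_error(classWeights(counts = c(a = 0, b = 3)), "present")
})

test_that("weighted BCE matches longhand evaluation and the plain oracle", {
  ## single balanced sample at maximal uncertainty
  L <- weightedBCE(c(0.5, 0.5), c(1, 0), c(0.5, 0.5))
  expect_equal(L, log(2), tolerance = 1e-12)
  ## perfect prediction tends to zero (clamped)
  expect_lt(weightedBCE(c(1, 0), c(1, 0), c(0.5, 0.5)), 1e-6)
  ## uniform weights reduce to plain averaged BCE scaled by 1/C
  set.seed(52)
  for (rep in 1:5) {
    p <- matrix(runif(20, 0.01, 0.99), 10, 2)
    y <- cbind(rbinom(10, 1, 0.5))
    y <- cbind(1 - y, y)
    expect_equal(weightedBCE(p, y, c(0.5, 0.5)), oraclePlainBce(p, y),
                 tolerance = 1e-10)
  }
  expect_error(weightedBCE(c(0.5), c(1, 0)), "mismatch")
})

test_that("gradient reversal is the identity forward", {
  v <- matrix(rnorm(12), 3, 4)
  expect_identical(gradientReversal(v, 2), v)
  expect_error(gradientReversal(v, -1), "nonnegative")
})

test_that("backward sensitivity through the reversal equals -lambda times baseline", {
  set.seed(53)
  D <- 4; n <- 6
  X <- matrix(rnorm(n * D), n, D)
  yd <- rep(c(0L, 1L), 3)
  params <- hofcnet:::nnInit(D, 4L, 7L)
  w <- classWeights(counts = c(src = 3L, tgt = 3L))
  fw <- hofcnet:::nnForward(params, X, head = "dom", train = TRUE)
  dl <- hofcnet:::bceLogitGrad(fw$probs, hofcnet:::oneHot(yd), w)
  lam <- 1.7
  g <- hofcnet:::nnBackward(params, fw, dl, lambdaMult = -lam)
  ## finite differences of the (forward, reversal-free) domain loss
  lossAt <- function(p) {
    f <- hofcnet:::nnForward(p, X, head = "dom", train = TRUE)
    weightedBCE(f$probs, hofcnet:::oneHot(yd), w)
  }
  h <- 1e-6
  for (idx in c(1, 5, 9)) {
    p2 <- params; p2$ext$dense1$W[idx] <- p2$ext$dense1$W[idx] + h
    p3 <- params; p3$ext$dense1$W[idx] <- p3$ext$dense1$W[idx] - h
    fd <- (lossAt(p2) - lossAt(p3)) / (2 * h)
    expect_equal(g$ext$dW1[idx], -lam * fd, tolerance = 1e-5)
  }
})

test_that("label-path gradients match finite differences", {
  set.seed(54)
  D <- 5; n <- 8
  X <- matrix(rnorm(n * D), n, D)
  y <- rep(c(0L, 1L), 4)
  params <- hofcnet:::nnInit(D, 4L, 3L)
  w <- classWeights(counts = table(y))
  fw <- hofcnet:::nnForward(params, X, head = "lab", train = TRUE)
  g <- hofcnet:::nnBackward(params, fw,
                            hofcnet:::bceLogitGrad(fw$probs,
                                                   hofcnet:::oneHot(y), w))
  lossAt <- function(p) {
    f <- hofcnet:::nnForward(p, X, head = "lab", train = TRUE)
    weightedBCE(f$probs, hofcnet:::oneHot(y), w)
  }
  h <- 1e-6
  checks <- list(list(c("ext", "dense1", "W"), "ext", "dW1", 3),
                 list(c("ext", "bn1", "gamma"), "ext", "dgamma1", 2),
                 list(c("lab", "dense1", "W"), "lab", "dW1", 5),
                 list(c("lab", "dense2", "W"), "lab", "dW2", 2),
                 list(c("lab", "bn1", "beta"), "lab", "dbeta1", 1))
  for (ck in checks) {
    p2 <- params; p2[[ck[[1]][1]]][[ck[[1]][2]]][[ck[[1]][3]]][ck[[4]]] <-
      p2[[ck[[1]][1]]][[ck[[1]][2]]][[ck[[1]][3]]][ck[[4]]] + h
    p3 <- params; p3[[ck[[1]][1]]][[ck[[1]][2]]][[ck[[1]][3]]][ck[[4]]] <-
      p3[[ck[[1]][1]]][[ck[[1]][2]]][[ck[[1]][3]]][ck[[4]]] - h
    fd <- (lossAt(p2) - lossAt(p3)) / (2 * h)
    expect_equal(g[[ck[[2]]]][[ck[[3]]]][ck[[4]]], fd, tolerance = 1e-5)
  }
})

test_that("linear SVM behaves like a linear separator", {
  ## two-point toy
  X <- rbind(c(-1, 0), c(1, 0))
  m <- trainSvm(X, c(0L, 1L))
  expect_equal(predictLabels(m, X)$label, c(0L, 1L))
  ## XOR is not linearly separable
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- c(0L, 0L, 1L, 1L)
  mx <- trainSvm(Xx, yx)
  expect_lte(mean(predictLabels(mx, Xx)$label == yx), 0.75)
  expect_error(trainSvm(X, c(1L, 1L)), "single class")
})

test_that("SVM decision agrees with a brute-force max-margin oracle on 2D", {
  ## well-separated clusters: the max-margin boundary is recoverable by a
  ## coarse grid search over line angle/offset
  set.seed(55)
  X <- rbind(matrix(rnorm(40, -2, 0.3), 20, 2),
             matrix(rnorm(40, 2, 0.3), 20, 2))
  y <- rep(c(0L, 1L), each = 20)
  m <- trainSvm(X, y)
  grid <- expand.grid(theta = seq(0, pi, length.out = 60),
                      b = seq(-3, 3, length.out = 120))
  margins <- apply(grid, 1, function(g) {
    w <- c(cos(g["theta"]), sin(g["theta"]))
    s <- X %*% w - g["b"]
    if (all(sign(s) == ifelse(y == 1, 1, -1))) min(abs(s)) else -Inf
  })
  best <- grid[which.max(margins), ]
  wBest <- c(cos(best$theta), sin(best$theta))
  ## oracle and SVM classify a probe set identically
  probe <- matrix(runif(40, -3, 3), 20, 2)
  oracleLab <- as.integer(probe %*% wBest - best$b > 0)
  expect_equal(predictLabels(m, probe)$label, oracleLab)
})

test_that("DANN learns separable features and is reproducible", {
  set.seed(56)
  n <- 60; D <- 6
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rnorm(n * D), n, D) + outer(ifelse(y == 1, 1.5, -1.5),
                                          rep(1, D))
  yT <- rep(c(0L, 1L), 10)
  XT <- matrix(rnorm(20 * D), 20, D) + outer(ifelse(yT == 1, 1.5, -1.5),
                                             rep(1, D))
  cfg <- DannConfig(D, extractorWidth = 8L, epochs = 40L, batchSize = 16L,
                    seed = 3L, lambdaGrl = 0)
  m <- trainMlp(X, y, cfg, testX = XT, testY = yT)
  lg <- m@trainingLog
  expect_equal(nrow(lg), 40)
  expect_gte(max(lg$test_acc), 95)
  ## determinism: bit-identical logs and parameters across runs
  m2 <- trainMlp(X, y, cfg, testX = XT, testY = yT)
  expect_identical(m@trainingLog, m2@trainingLog)
  expect_identical(m@fit, m2@fit)
  ## scores are probabilities
  pr <- predictLabels(m, XT)
  expect_true(all(pr$score > 0 & pr$score < 1))
  ## batch prediction equals row-by-row prediction
  one <- do.call(rbind, lapply(seq_len(5), function(i)
    predictLabels(m, XT[i, , drop = FALSE])))
  expect_equal(pr$label[1:5], one$label)
  ## label head ignores feature-width mismatches loudly
  expect_error(predictLabels(m, XT[, 1:3]), "width")
})

test_that("lambda = 0 reproduces the plain MLP trajectory seed for seed", {
  set.seed(57)
  n <- 30; D <- 5
  X <- matrix(rnorm(n * D), n, D)
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0L, 1L)
  XT <- matrix(rnorm(10 * D), 10, D)
  yT <- rbinom(10, 1, 0.5)
  cfg <- DannConfig(D, epochs = 6L, batchSize = 8L, seed = 9L, lambdaGrl = 0)
  dann <- trainDann(X, y, cfg, targetX = XT, testX = XT, testY = yT)
  mlp <- trainMlp(X, y, cfg, testX = XT, testY = yT)
  expect_identical(dann@fit$ext, mlp@fit$ext)
  expect_identical(dann@fit$lab, mlp@fit$lab)
  expect_identical(dann@trainingLog, mlp@trainingLog)
  ## with lambda > 0 the domain loss reaches the extractor
  cfg1 <- DannConfig(D, epochs = 6L, batchSize = 8L, seed = 9L,
                     lambdaGrl = 1)
  dann1 <- trainDann(X, y, cfg1, targetX = XT, testX = XT, testY = yT)
  expect_false(identical(dann1@fit$ext, mlp@fit$ext))
})

test_that("empty selections and single-class folds fail with guidance", {
  X <- matrix(numeric(), 4, 0)
  expect_error(trainSvm(X, c(0L, 1L, 0L, 1L)), "relax")
  cfg <- DannConfig(4)
  expect_error(trainDann(matrix(rnorm(16), 4, 4), c(1L, 1L, 1L, 1L), cfg),
               "single class")
})
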