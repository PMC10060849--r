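## Minimal feedforward machinery for the domain-adversarial classifier.
## Written against a fixed architecture (one extractor layer, two identical
## two-layer heads) rather than as a generic autodiff framework; every
## backward pass is derived analytically and checked against finite
## differences in the test suite.
##
## RNG discipline: each stochastic component draws from its own substream
## (seed, component, counter), so the presence or absence of the domain
## head cannot perturb the extractor/label-path draws. This is what makes
## "lambda = 0 equals a plain MLP" hold bit-for-bit.

BN_EPS <- 1e-5
CLAMP_EPS <- 1e-7

## component ids for substreams
RNG_EXT <- 1L; RNG_LAB <- 2L; RNG_DOM <- 3L; RNG_SHUF <- 4L
RNG_DROP_EXT <- 5L; RNG_DROP_LAB <- 6L; RNG_DROP_DOM <- 7L; RNG_TGT <- 8L

newDense <- function(nin, nout, seed) {
  W <- withSeed(seed, matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                             nin, nout))
  list(W = W, b = numeric(nout))
}

newBn <- function(n) list(gamma = rep(1, n), beta = numeric(n),
                          runMean = numeric(n), runVar = rep(1, n))

denseForward <- function(layer, X) {
  Z <- X %*% layer$W
  sweep(Z, 2L, layer$b, `+`)
}

denseBackward <- function(layer, X, dZ)
  list(dX = dZ %*% t(layer$W), dW = crossprod(X, dZ), db = colSums(dZ))

bnForward <- function(bn, Z, train, momentum = 0.1) {
  if (train) {
    mu <- colMeans(Z)
    va <- colMeans(sweep(Z, 2L, mu, `-`)^2)  # biased, standard for BN
  } else {
    mu <- bn$runMean; va <- bn$runVar
  }
  xhat <- sweep(sweep(Z, 2L, mu, `-`), 2L, sqrt(va + BN_EPS), `/`)
  out <- sweep(sweep(xhat, 2L, bn$gamma, `*`), 2L, bn$beta, `+`)
  list(out = out, xhat = xhat, va = va, mu = mu)
}

bnUpdateRunning <- function(bn, cache, momentum = 0.1) {
  bn$runMean <- (1 - momentum) * bn$runMean + momentum * cache$mu
  bn$runVar <- (1 - momentum) * bn$runVar + momentum * cache$va
  bn
}

bnBackward <- function(bn, cache, dOut) {
  n <- nrow(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2L, bn$gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  ## dZ = (1 / (n * sqrt(va + eps))) * (n*dxhat - s1 - xhat * s2)
  dZ <- n * dxhat
  dZ <- sweep(dZ, 2L, s1, `-`)
  dZ <- dZ - sweep(cache$xhat, 2L, s2, `*`)
  dZ <- sweep(dZ, 2L, n * sqrt(cache$va + BN_EPS), `/`)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

dropoutMask <- function(dim, p, seed) {
  if (p <= 0) return(NULL)
  keep <- withSeed(seed, matrix(stats::runif(prod(dim)) >= p, dim[1], dim[2]))
  keep / (1 - p)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## One BN-ReLU-Dropout block after a dense layer. Returns output + cache.
blockForward <- function(dense, bn, X, train, mask = NULL) {
  Z <- denseForward(dense, X)
  bnc <- bnForward(bn, Z, train)
  A <- pmax(bnc$out, 0)
  H <- if (!is.null(mask)) A * mask else A
  list(out = H, X = X, Z = Z, bnc = bnc, A = A, mask = mask)
}

blockBackward <- function(dense, bn, cache, dH) {
  if (!is.null(cache$mask)) dH <- dH * cache$mask
  dA <- dH * (cache$bnc$out > 0)
  bb <- bnBackward(bn, cache$bnc, dA)
  db <- denseBackward(dense, cache$X, bb$dZ)
  list(dX = db$dX, dW = db$dW, db = db$db, dgamma = bb$dgamma,
       dbeta = bb$dbeta)
}

## Parameter container: ext (dense+bn), lab and dom heads (dense1+bn+dense2).
nnInit <- function(inputDim, width1, seed) {
  width2 <- max(1L, width1 %/% 2L)
  mk <- function(comp) list(
    dense1 = newDense(if (comp == RNG_EXT) inputDim else width1,
                      if (comp == RNG_EXT) width1 else width2,
                      subSeed(seed, comp, 0L)),
    bn1 = newBn(if (comp == RNG_EXT) width1 else width2),
    dense2 = if (comp != RNG_EXT)
      newDense(width2, 2L, subSeed(seed, comp, 1L)))
  list(ext = mk(RNG_EXT), lab = mk(RNG_LAB), dom = mk(RNG_DOM),
       width1 = width1, width2 = width2, inputDim = inputDim)
}

## Forward through extractor then one head; train mode applies batch-stat
## BN and the supplied dropout masks. Returns sigmoid probabilities for the
## two classes plus caches for the backward pass.
nnForward <- function(params, X, head = c("lab", "dom"), train = FALSE,
                      maskExt = NULL, maskHead = NULL) {
  head <- match.arg(head)
  extc <- blockForward(params$ext$dense1, params$ext$bn1, X, train, maskExt)
  h <- params[[head]]
  hc <- blockForward(h$dense1, h$bn1, extc$out, train, maskHead)
  logits <- denseForward(h$dense2, hc$out)
  list(probs = sigmoid(logits), logits = logits, extc = extc, hc = hc,
       head = head)
}

## Backward from dL/dlogits; lambdaMult scales the gradient as it crosses
## from the head into the extractor (the gradient-reversal layer: identity
## forward, -lambda backward; lambdaMult = 1 on the label path).
nnBackward <- function(params, fw, dLogits, lambdaMult = 1) {
  h <- params[[fw$head]]
  d2 <- denseBackward(h$dense2, fw$hc$out, dLogits)
  bh <- blockBackward(h$dense1, h$bn1, fw$hc, d2$dX)
  dInto <- lambdaMult * bh$dX
  be <- blockBackward(params$ext$dense1, params$ext$bn1, fw$extc, dInto)
  g <- list(ext = list(dW1 = be$dW, db1 = be$db, dgamma1 = be$dgamma,
                       dbeta1 = be$dbeta))
  g[[fw$head]] <- list(dW1 = bh$dW, db1 = bh$db, dgamma1 = bh$dgamma,
                       dbeta1 = bh$dbeta, dW2 = d2$dW, db2 = d2$db)
  g
}

## Weighted BCE gradient w.r.t. logits (sigmoid folded in for stability):
## dL/dz_nc = W_c (p_nc - y_nc) / N.
bceLogitGrad <- function(probs, yOneHot, weights) {
  n <- nrow(probs)
  sweep(probs - yOneHot, 2L, weights, `*`) / n
}

## Flat walk over the parameter tree: apply Adam to every numeric leaf that
## has a matching gradient leaf.
adamStep <- function(params, grads, state, lr, t, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, s = s)
  }
  map <- list(
    c("ext", "dense1", "W", "dW1"), c("ext", "dense1", "b", "db1"),
    c("ext", "bn1", "gamma", "dgamma1"), c("ext", "bn1", "beta", "dbeta1"),
    c("lab", "dense1", "W", "dW1"), c("lab", "dense1", "b", "db1"),
    c("lab", "bn1", "gamma", "dgamma1"), c("lab", "bn1", "beta", "dbeta1"),
    c("lab", "dense2", "W", "dW2"), c("lab", "dense2", "b", "db2"),
    c("dom", "dense1", "W", "dW1"), c("dom", "dense1", "b", "db1"),
    c("dom", "bn1", "gamma", "dgamma1"), c("dom", "bn1", "beta", "dbeta1"),
    c("dom", "dense2", "W", "dW2"), c("dom", "dense2", "b", "db2"))
  for (mp in map) {
    part <- mp[1]; layer <- mp[2]; slot <- mp[3]; gname <- mp[4]
    g <- grads[[part]][[gname]]
    if (is.null(g)) next
    key <- paste(part, layer, slot, sep = ".")
    s <- state[[key]]
    if (is.null(s)) s <- list(m = g * 0, v = g * 0)
    r <- upd(params[[part]][[layer]][[slot]], g, s)
    params[[part]][[layer]][[slot]] <- r$p
    state[[key]] <- r$s
  }
  list(params = params, state = state)
}

## Merge two gradient trees for the extractor (label path + domain path).
addExtGrads <- function(a, b) {
  for (nm in names(a$ext)) a$ext[[nm]] <- a$ext[[nm]] + b$ext[[nm]]
  a$dom <- b$dom
  a
}

oneHot <- function(y) cbind(`0` = 1 - y, `1` = y)

nnAccuracy <- function(params, X, y) {
  p <- nnForward(params, X, head = "lab", train = FALSE)$probs
  mean((p[, 2L] > p[, 1L]) == (y == 1)) * 100
}
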